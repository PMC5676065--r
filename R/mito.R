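#' Construct a mitochondrion agent
#'
#' A single organelle carries its functional OXPHOS capacity `F`, damaged
#' matrix-protein fraction `Pdam`, intact (`n_wt`) and damaged/deleted
#' (`n_mut`) mtDNA copies, a stress-state label, and its age in minutes.
#'
#' @param F functional OXPHOS capacity fraction in `[0, 1]`.
#' @param Pdam damaged matrix-protein fraction in `[0, 1]`.
#' @param n_wt,n_mut intact and damaged mtDNA copy counts (total >= 1).
#' @param state stress-state label, one of `"S0_healthy"`,
#'   `"S1_slightly_stressed"`, `"S2_significantly_stressed"`,
#'   `"S3_severely_damaged"`.
#' @param age minutes since biogenesis.
#' @return a one-row tibble of class `mitosim_mito`.
#' @export
#' @examples
#' mito_state(F = 0.9, n_wt = 10)
mito_state <- function(F = 0.95, Pdam = 0, n_wt = 10L, n_mut = 0L,
                       state = "S0_healthy", age = 0) {
  state <- match.arg(state, stress_state_labels())
  stopifnot(F >= 0, F <= 1, Pdam >= 0, Pdam <= 1, n_wt >= 0, n_mut >= 0,
            n_wt + n_mut >= 1, age >= 0)
  structure(tibble::tibble(
    F = F, Pdam = Pdam, n_wt = as.integer(n_wt), n_mut = as.integer(n_mut),
    state = state, age = age),
    class = c("mitosim_mito", "tbl_df", "tbl", "data.frame"))
}

#' Stress-state labels
#'
#' The four phenotyping labels, ordered from healthy to severely damaged.
#' @return a character vector of length 4.
#' @export
stress_state_labels <- function() {
  c("S0_healthy", "S1_slightly_stressed", "S2_significantly_stressed",
    "S3_severely_damaged")
}

state_to_code <- function(state) {
  match(state, stress_state_labels()) - 1L
}

#' OXPHOS defect fraction
#'
#' The per-organelle dysfunction measure used for stress-state banding:
#' `d = 1 - F * (1 - w_h * h)` where `h = n_mut / (n_wt + n_mut)` is the
#' heteroplasmy and `w_h` weights its contribution (default 0.5). An
#' undamaged organelle has `d = 0`; one with no functional capacity has
#' `d = 1` regardless of heteroplasmy.
#'
#' @param mito a `mitosim_mito` (or any data frame with columns `F`, `n_wt`,
#'   `n_mut`); alternatively pass `F`, `n_wt`, `n_mut` directly.
#' @param F,n_wt,n_mut vectorised alternative to `mito`.
#' @param w_h heteroplasmy weight in `[0, 1]`.
#' @return defect fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' oxphos_defect_fraction(F = 0.5, n_wt = 5, n_mut = 5)  # 0.625
oxphos_defect_fraction <- function(mito = NULL, F = NULL, n_wt = NULL,
                                   n_mut = NULL, w_h = 0.5) {
  if (!is.null(mito)) {
    F <- mito$F; n_wt <- mito$n_wt; n_mut <- mito$n_mut
  }
  tot <- n_wt + n_mut
  if (any(tot < 1)) stop("total mtDNA must be >= 1", call. = FALSE)
  h <- n_mut / tot
  pmin(1, pmax(0, 1 - F * (1 - w_h * h)))
}

#' Superoxide production of one organelle
#'
#' `rate = k_sox * flux * (1 + leak_gain * d) + pq_boost`, strictly
#' increasing in the defect fraction `d` — the free-radical feedback loop in
#' which defective respiratory machinery leaks more superoxide.
#'
#' @param mito a `mitosim_mito` or data frame of organelles.
#' @param respiration_flux electron flux through the respiratory chain
#'   (dimensionless flux units, >= 0).
#' @param pq_boost additive paraquat redox-cycling term (nM/min), >= 0.
#' @param rates mitochondrion rate block (defaults from [sim_config()]).
#' @return superoxide production in nM/min.
#' @export
superoxide_production <- function(mito, respiration_flux,
                                  pq_boost = 0,
                                  rates = default_config()$mitochondrion) {
  if (any(respiration_flux < 0)) stop("`respiration_flux` must be >= 0",
                                      call. = FALSE)
  if (any(pq_boost < 0)) stop("`pq_boost` must be >= 0", call. = FALSE)
  d <- oxphos_defect_fraction(mito, w_h = rates$w_h)
  rates$k_sox * respiration_flux * (1 + rates$leak_gain * d) + pq_boost
}

#' Advance one mitochondrion
#'
#' Operator-split update over `n_steps` increments of `dt` minutes:
#' deterministic flows first (ROS-driven loss of OXPHOS capacity,
#' chaperone-dependent repair scaled down by UPRmt activity and up by NAD+
#' availability; matrix-protein damage mirrors with opposite sign), then
#' stochastic events (Poisson mtDNA damage hits, turnover and homeostatic
#' replication with clonal-expansion bias `adv_mut`), then one stress-state
#' move of at most one band. Identical seed and inputs give a bit-identical
#' successor state.
#'
#' @param mito a `mitosim_mito`.
#' @param env cell-environment view: a list with `ros` (nM), `chaperones`,
#'   `upr`, `g_nad` (all dimensionless scales).
#' @param dt step in minutes (> 0).
#' @param seed integer seed for the organelle's stream.
#' @param n_steps number of consecutive steps to take.
#' @param rates mitochondrion rate block.
#' @return the successor `mitosim_mito`.
#' @export
#' @examples
#' m <- mito_state()
#' step_mito(m, env = list(ros = 10, chaperones = 1, upr = 0, g_nad = 1))
step_mito <- function(mito, env, dt = 1, seed = 1L, n_steps = 1L,
                      rates = default_config()$mitochondrion) {
  stopifnot(inherits(mito, "mitosim_mito") || is.data.frame(mito))
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  env <- utils::modifyList(list(ros = 0, chaperones = 1, upr = 0, g_nad = 1),
                           env)
  out <- cpp_step_mito(
    list(F = mito$F, Pdam = mito$Pdam, age = mito$age,
         n_wt = mito$n_wt, n_mut = mito$n_mut,
         state = state_to_code(mito$state)),
    env, rates, dt, seed, as.integer(n_steps))
  mito_state(F = out$F, Pdam = out$Pdam, n_wt = out$n_wt, n_mut = out$n_mut,
             state = stress_state_labels()[out$state + 1L], age = out$age)
}

#' Stochastic stress-state classification
#'
#' Moves the label at most one band per call toward the band of the current
#' defect fraction (`d < 0.30` S0, `0.30 <= d < 0.60` S1, `0.60 <= d < 0.90`
#' S2, `d >= 0.90` S3; the two upper edges anchor the 60-90% OXPHOS-defect
#' window for deleterious senescence). Moves toward the target band occur
#' with hazard `fast`, away from it with hazard `slow`, so both progression
#' and recovery are possible.
#'
#' @param mito a `mitosim_mito`, or `NULL` if `d` is given directly.
#' @param d defect fraction (overrides `mito`).
#' @param dt minutes per call.
#' @param seed stream seed.
#' @param n_steps number of consecutive calls; the full label path is
#'   returned when `n_steps > 1`.
#' @param fast,slow per-minute transition hazards toward/away from the
#'   target band.
#' @param bands the three band edges.
#' @return a character vector of stress-state labels (length `n_steps`).
#' @export
classify_stress_state <- function(mito = NULL, d = NULL, dt = 1, seed = 1L,
                                  n_steps = 1L,
                                  fast = default_config()$mitochondrion$state_fast,
                                  slow = default_config()$mitochondrion$state_slow,
                                  bands = default_config()$mitochondrion$bands) {
  if (is.null(d)) d <- oxphos_defect_fraction(mito)
  state0 <- if (is.null(mito)) 0L else state_to_code(mito$state)
  path <- cpp_state_path(state0, d, dt, fast, slow, bands, seed,
                         as.integer(n_steps))
  stress_state_labels()[path + 1L]
}

#' Replicate mtDNA copies with clonal-expansion bias
#'
#' Each of `n_new` copies is damaged-class with probability
#' `adv_mut * n_mut / (adv_mut * n_mut + n_wt)`, else intact; totals increase
#' by exactly `n_new`.
#'
#' @param n_wt,n_mut current intact/damaged copy counts (total >= 1).
#' @param n_new number of new copies (>= 0).
#' @param adv_mut replicative advantage of the damaged class (>= 1).
#' @param seed stream seed.
#' @return a tibble with updated `n_wt`, `n_mut`.
#' @export
#' @examples
#' replicate_mtdna(10, 10, 5, adv_mut = 1.1, seed = 3)
replicate_mtdna <- function(n_wt, n_mut, n_new,
                            adv_mut = default_config()$mitochondrion$adv_mut,
                            seed = 1L) {
  if (n_new < 0) stop("`n_new` must be >= 0", call. = FALSE)
  if (n_wt + n_mut == 0) stop("mtDNA pool is empty", call. = FALSE)
  out <- cpp_replicate_mtdna(as.integer(n_wt), as.integer(n_mut),
                             as.integer(n_new), adv_mut, seed)
  tibble::tibble(n_wt = out[1], n_mut = out[2])
}
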