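#' Construct a cell agent
#'
#' A post-mitotic, energetically demanding cell: metabolite pools (superoxide
#' and peroxide in nM, NAD+ relative to t = 0, ATP in mM), transcription
#' factor activities (nuclear ATFS-1, UPRmt, DAF-16, SKN-1, all in `[0, 1]`),
#' its population of mitochondrion agents, a life state, and the cell's own
#' compromise threshold sampled once from triangular(0.60, 0.625, 0.75).
#'
#' @param mitos a data frame of organelles (rows as in [mito_state()]); the
#'   default is `n_mito` fresh, healthy organelles.
#' @param n_mito number of initial mitochondria when `mitos` is not given.
#' @param sox,h2o2 superoxide / peroxide pools (nM).
#' @param nad NAD+ relative to the initial time point.
#' @param atp ATP pool (mM).
#' @param atfs1_nuc,upr,daf16,skn1 activities in `[0, 1]`.
#' @param life `"healthy"`, `"compromised"`, or `"dead"`.
#' @param threshold_c compromise threshold; drawn via
#'   [sample_compromise_threshold()] when `NULL`.
#' @param t_compromised minutes spent in the compromised state.
#' @param seed stream seed used for the threshold draw and initial F values.
#' @return a list of class `mitosim_cell`.
#' @export
#' @examples
#' cell_state(n_mito = 5, seed = 2)
cell_state <- function(mitos = NULL, n_mito = 50L, sox = 0, h2o2 = 0,
                       nad = 1, atp = 2.7, atfs1_nuc = 0, upr = 0,
                       daf16 = 0, skn1 = 0, life = "healthy",
                       threshold_c = NULL, t_compromised = 0, seed = 1L) {
  life <- match.arg(life, c("healthy", "compromised", "dead"))
  if (is.null(threshold_c)) threshold_c <- sample_compromise_threshold(seed)
  if (is.null(mitos)) {
    f0 <- triangular_sample(n_mito, 0.93, 0.97, 1.0, seed = seed + 1L)
    mitos <- tibble::tibble(
      F = f0, Pdam = 0, n_wt = 10L, n_mut = 0L,
      state = "S0_healthy", age = 0)
  }
  stopifnot(all(c("F", "Pdam", "n_wt", "n_mut", "state", "age") %in%
                  names(mitos)),
            sox >= 0, h2o2 >= 0, nad >= 0, atp >= 0,
            threshold_c >= 0.60, threshold_c <= 0.75)
  structure(list(
    sox = sox, h2o2 = h2o2, nad = nad, atp = atp,
    atfs1_nuc = atfs1_nuc, upr = upr, daf16 = daf16, skn1 = skn1,
    threshold_c = threshold_c, t_compromised = t_compromised, life = life,
    mitos = tibble::as_tibble(mitos)),
    class = "mitosim_cell")
}

life_labels <- function() c("healthy", "compromised", "dead")

#' Advance one cell and its mitochondria
#'
#' One operator-split update per `dt`: (1) per-organelle superoxide
#' production pooled into the cell; (2) SOD dismutation and peroxide
#' clearance; (3) nuclear ATFS-1 as the complement of mitochondrial import
#' efficiency; (4) Hill activation of the UPRmt; (5) DAF-16/SKN-1 relaxation
#' toward ROS- and drug-driven targets; (6) antioxidant and chaperone scaling;
#' (7) NAD+ salvage vs stress-driven consumption; (8) ATP production
#' saturating in NAD+; (9) stepping of every organelle; (10) selective
#' mitophagy and biogenesis draws; (11) the compromised/death state machine.
#'
#' @param cell a `mitosim_cell` (must not be dead).
#' @param dt minutes per step (> 0).
#' @param env perturbation environment: list with any of `mitophagy_mult`,
#'   `biog_mult`, `pq_boost`, `pt_daf`, `pt_skn`, `pt_sirt`.
#' @param seed stream seed (identical seed and inputs give an identical
#'   successor).
#' @param n_steps number of consecutive steps.
#' @param config a `mitosim_config` supplying the rate blocks and ablations.
#' @return the successor `mitosim_cell`, with attributes `n_mitophagy` and
#'   `n_biogenesis` counting events during the call.
#' @export
#' @examples
#' cl <- cell_state(n_mito = 5)
#' step_cell(cl, dt = 1, seed = 4)
step_cell <- function(cell, dt = 1, env = list(), seed = 1L, n_steps = 1L,
                      config = default_config()) {
  stopifnot(inherits(cell, "mitosim_cell"))
  if (cell$life == "dead") stop("cannot step a dead cell", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  env <- utils::modifyList(
    list(mitophagy_mult = 1, biog_mult = 1, pq_boost = 0, pt_daf = 0,
         pt_skn = 0, pt_sirt = 1), env)
  cl <- list(
    sox = cell$sox, h2o2 = cell$h2o2, nad = cell$nad, atp = cell$atp,
    atfs1_nuc = cell$atfs1_nuc, upr = cell$upr, daf16 = cell$daf16,
    skn1 = cell$skn1, threshold_c = cell$threshold_c,
    t_compromised = cell$t_compromised,
    life = match(cell$life, life_labels()) - 1L,
    mitos = list(F = cell$mitos$F, Pdam = cell$mitos$Pdam,
                 age = cell$mitos$age, n_wt = cell$mitos$n_wt,
                 n_mut = cell$mitos$n_mut,
                 state = state_to_code(cell$mitos$state)))
  out <- cpp_step_cell(cl, config$mitochondrion, config$cell, env,
                       config$ablations, dt, seed, as.integer(n_steps))
  res <- cell_state(
    mitos = tibble::tibble(
      F = out$mitos$F, Pdam = out$mitos$Pdam, n_wt = out$mitos$n_wt,
      n_mut = out$mitos$n_mut,
      state = stress_state_labels()[out$mitos$state + 1L],
      age = out$mitos$age),
    sox = out$sox, h2o2 = out$h2o2, nad = out$nad, atp = out$atp,
    atfs1_nuc = out$atfs1_nuc, upr = out$upr, daf16 = out$daf16,
    skn1 = out$skn1, life = life_labels()[out$life + 1L],
    threshold_c = out$threshold_c, t_compromised = out$t_compromised)
  attr(res, "n_mitophagy") <- out$n_mitophagy
  attr(res, "n_biogenesis") <- out$n_biogenesis
  res
}

#' Selective mitophagy hazard
#'
#' `hazard = k_mitophagy * state_mult[state] * drug_mult * (1 + d_daf *
#' daf16)` per minute; removal draws are Bernoulli over each step. The
#' state multipliers are non-decreasing from S0 to S3, which is what makes
#' the process selective for damaged organelles.
#'
#' @param state stress-state label(s) or 0-based code(s).
#' @param daf16 DAF-16 activity in `[0, 1]`.
#' @param drug_mult mitophagy modulation multiplier (see
#'   [mitophagy_modulation()]).
#' @param rates cell rate block.
#' @return per-minute hazard (vectorised).
#' @export
mitophagy_hazard <- function(state, daf16 = 0, drug_mult = 1,
                             rates = default_config()$cell) {
  code <- if (is.character(state)) state_to_code(state) else as.integer(state)
  stopifnot(all(code >= 0 & code <= 3))
  rates$k_mitophagy * rates$state_mult[code + 1L] * drug_mult *
    (1 + rates$d_daf * daf16)
}

#' Sample a cell's compromise threshold
#'
#' One triangular(0.60, 0.625, 0.75) variate, drawn once per cell at
#' creation: the cell enters the compromised state when its fraction of
#' defective mitochondria exceeds this threshold.
#'
#' @param seed stream seed.
#' @return a fraction in `[0.60, 0.75]`.
#' @export
sample_compromise_threshold <- function(seed = 1L) {
  cpp_rtri(1L, 0.60, 0.625, 0.75, seed)
}

#' Compromised/death state machine
#'
#' Pure-rule form of the life-state update used by the engine: a healthy cell
#' becomes compromised when its defective-mitochondria fraction exceeds its
#' sampled threshold; a compromised cell recovers when the fraction falls
#' below the lower bound (0.60, giving hysteresis) and otherwise accrues a
#' death hazard `k_death * (1 + t_compromised / tau_d)` applied as a
#' Bernoulli draw per `dt`. Death is absorbing. The transition guards are
#' mutually exclusive, so a cell cannot oscillate within a single step.
#'
#' @param life current life state label.
#' @param frac_defective fraction of defective (severely damaged)
#'   mitochondria.
#' @param threshold_c the cell's compromise threshold.
#' @param t_compromised minutes already spent compromised.
#' @param dt step in minutes.
#' @param seed stream seed for the death draw.
#' @param rates cell rate block.
#' @return a list with updated `life` and `t_compromised`.
#' @export
check_life_transition <- function(life, frac_defective, threshold_c,
                                  t_compromised = 0, dt = 1, seed = 1L,
                                  rates = default_config()$cell) {
  life <- match.arg(life, life_labels())
  if (life == "dead") return(list(life = "dead",
                                  t_compromised = t_compromised))
  if (life == "healthy") {
    if (frac_defective > threshold_c)
      return(list(life = "compromised", t_compromised = 0))
    return(list(life = "healthy", t_compromised = 0))
  }
  # compromised
  if (frac_defective < rates$recover_frac)
    return(list(life = "healthy", t_compromised = 0))
  t_compromised <- t_compromised + dt
  hz <- rates$k_death * (1 + t_compromised / rates$tau_d)
  p <- 1 - exp(-hz * dt)
  if (cpp_runif(1L, seed) < p)
    return(list(life = "dead", t_compromised = t_compromised))
  list(life = "compromised", t_compromised = t_compromised)
}

# ---------------------------------------------------------------------------
# Triangular distribution (closed forms used throughout the tests)
# ---------------------------------------------------------------------------

#' Triangular distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the triangular distribution with support `[a, b]` and mode `c`.
#' `triangular_sample()` draws via the inverse CDF from the package's own
#' seeded stream (the same sampler the simulation engine uses).
#'
#' @param x,q,p quantiles / probabilities.
#' @param n number of draws.
#' @param a,b lower/upper support bounds (`a <= c <= b`).
#' @param c mode.
#' @param seed stream seed for `triangular_sample()`.
#' @return numeric vector.
#' @name triangular
#' @export
#' @examples
#' ptri(0.65, 0.60, 0.625, 0.75)  # 0.4667
triangular_sample <- function(n, a, c, b, seed = 1L) {
  check_tri(a, c, b)
  if (a == b) return(rep(a, n))
  cpp_rtri(as.integer(n), a, c, b, seed)
}

#' @rdname triangular
#' @export
dtri <- function(x, a, c, b) {
  check_tri(a, c, b)
  out <- numeric(length(x))
  up <- x >= a & x < c
  dn <- x >= c & x <= b
  if (c > a) out[up] <- 2 * (x[up] - a) / ((b - a) * (c - a))
  if (b > c) out[dn] <- 2 * (b - x[dn]) / ((b - a) * (b - c))
  out
}

#' @rdname triangular
#' @export
ptri <- function(q, a, c, b) {
  check_tri(a, c, b)
  out <- numeric(length(q))
  out[q >= b] <- 1
  up <- q > a & q < c
  dn <- q >= c & q < b
  if (c > a) out[up] <- (q[up] - a)^2 / ((b - a) * (c - a))
  if (b > c) out[dn] <- 1 - (b - q[dn])^2 / ((b - a) * (b - c))
  out
}

#' @rdname triangular
#' @export
qtri <- function(p, a, c, b) {
  check_tri(a, c, b)
  stopifnot(all(p >= 0 & p <= 1))
  fc <- if (b > a) (c - a) / (b - a) else 0
  out <- numeric(length(p))
  lo <- p < fc
  out[lo] <- a + sqrt(p[lo] * (b - a) * (c - a))
  out[!lo] <- b - sqrt((1 - p[!lo]) * (b - a) * (b - c))
  out
}

check_tri <- function(a, c, b) {
  if (!(a <= c && c <= b))
    stop("triangular parameters must satisfy a <= c <= b", call. = FALSE)
  invisible(TRUE)
}
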