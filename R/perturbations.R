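#' Pharmacological dosing schemes
#'
#' Describes one dosing window for a virtual compound. The level is 0 outside
#' `[t_start, t_end]`; inside, it resets to `dose` at every `refresh_every`
#' boundary and decays first-order with `decay_halflife` between refreshes
#' (the default, no decay, gives the constant low-level dosing used in the
#' headline experiments: 15 nM rapamycin or 10 nM bafilomycin refreshed every
#' 2500 min, and constant 5 or 100 uM paraquat and 100 uM pterostilbene).
#'
#' @param agent one of `"rapamycin"`, `"bafilomycin"`, `"paraquat"`,
#'   `"pterostilbene"`.
#' @param dose concentration, nM for rapamycin/bafilomycin and uM for
#'   paraquat/pterostilbene.
#' @param t_start,t_end dosing window in minutes (`Inf` = whole run).
#' @param refresh_every refresh interval in minutes (default 2500).
#' @param decay_halflife first-order decay half-life between refreshes in
#'   minutes; `NA` (default) means the level is held constant.
#' @return an object of class `mitosim_perturbation`.
#' @export
#' @examples
#' perturbation("rapamycin", 15)
perturbation <- function(agent, dose, t_start = 0, t_end = Inf,
                         refresh_every = 2500, decay_halflife = NA_real_) {
  agents <- c("rapamycin", "bafilomycin", "paraquat", "pterostilbene")
  agent <- match.arg(agent, agents)
  if (dose < 0) stop("`dose` must be >= 0", call. = FALSE)
  if (refresh_every <= 0) stop("`refresh_every` must be > 0", call. = FALSE)
  if (t_start >= t_end) stop("`t_start` must be < `t_end`", call. = FALSE)
  structure(list(
    agent = agent,
    agent_code = match(agent, agents) - 1L,
    dose = dose,
    dose_unit = if (agent %in% c("rapamycin", "bafilomycin")) "nM" else "uM",
    t_start = t_start, t_end = t_end,
    refresh_every = refresh_every,
    decay_halflife = decay_halflife),
    class = "mitosim_perturbation")
}

#' Momentary drug level under a dosing scheme
#'
#' @param scheme a [perturbation()].
#' @param t time(s) in minutes (vectorised).
#' @return concentration at each `t`, in the scheme's dose unit.
#' @export
#' @examples
#' sch <- perturbation("rapamycin", 15, decay_halflife = 2500)
#' drug_level(sch, c(0, 2499.99, 2500))
drug_level <- function(scheme, t) {
  stopifnot(inherits(scheme, "mitosim_perturbation"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  inside <- t >= scheme$t_start & t < scheme$t_end
  lvl <- numeric(length(t))
  if (is.na(scheme$decay_halflife)) {
    lvl[inside] <- scheme$dose
  } else {
    since <- (t[inside] - scheme$t_start) %% scheme$refresh_every
    lvl[inside] <- scheme$dose * 0.5^(since / scheme$decay_halflife)
  }
  lvl
}

#' Mitophagy modulation by rapamycin and bafilomycin
#'
#' Multiplier applied to the baseline mitophagy hazard:
#' `(1 + E_r * rapa / (EC50_r + rapa)) / (1 + baf / IC50_b)`. Rapamycin
#' induces mitophagy (multiplier > 1), bafilomycin hinders it (< 1), and the
#' multiplier is exactly 1 with neither drug.
#'
#' @param rapa rapamycin concentration (nM).
#' @param baf bafilomycin concentration (nM).
#' @param drugs drug parameter block (defaults from [sim_config()]).
#' @return dimensionless hazard multiplier (vectorised over `rapa`/`baf`).
#' @export
mitophagy_modulation <- function(rapa, baf, drugs = default_config()$drugs) {
  if (any(rapa < 0) || any(baf < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  (1 + drugs$E_r * rapa / (drugs$EC50_r + rapa)) / (1 + baf / drugs$IC50_b)
}

#' Paraquat superoxide boost
#'
#' Linear redox-cycling term added to every organelle's superoxide output.
#'
#' @param conc paraquat concentration (uM).
#' @param drugs drug parameter block.
#' @return additional superoxide production (nM/min per mitochondrion).
#' @export
paraquat_boost <- function(conc, drugs = default_config()$drugs) {
  if (any(conc < 0)) stop("`conc` must be >= 0", call. = FALSE)
  drugs$k_pq * conc
}

#' Pterostilbene effects
#'
#' Saturating (Hill) drives on DAF-16 and SKN-1 activation plus an
#' NAD+-dependent sirtuin multiplier, calibrated so the 100 uM preset lowers
#' aged-state tissue ROS by 20-25% versus control.
#'
#' @param conc pterostilbene concentration (uM).
#' @param drugs drug parameter block.
#' @return a tibble with columns `conc`, `daf16_drive`, `skn1_drive`,
#'   `sirtuin_scale`.
#' @export
pterostilbene_effects <- function(conc, drugs = default_config()$drugs) {
  if (any(conc < 0)) stop("`conc` must be >= 0", call. = FALSE)
  h <- conc / (drugs$pt_K + conc)
  tibble::tibble(
    conc = conc,
    daf16_drive = drugs$pt_daf * h,
    skn1_drive = drugs$pt_skn * h,
    sirtuin_scale = 1 + drugs$pt_sirt * h)
}

#' Genetic ablation schemes
#'
#' `ablation()` describes a fractional reduction of gene expression;
#' `apply_ablation()` maps it onto the configuration's rate blocks:
#' \emph{sod-2} scales the SOD dismutation activity (including its UPRmt- and
#' transcription-factor-driven share) by `1 - fraction`; \emph{daf-16} scales
#' the DAF-16 activation drive (and therefore its mitophagy and antioxidant
#' contributions) by `1 - fraction`; \emph{skn-1} scales the SKN-1 drive
#' likewise. A fraction of 0 is the identity.
#'
#' @param gene one of `"sod-2"`, `"daf-16"`, `"skn-1"`.
#' @param fraction expression reduction in `[0, 1]` (0.9 = 90% ablation).
#' @return `ablation()`: a `mitosim_ablation`; `apply_ablation()`: the
#'   modified config.
#' @export
#' @examples
#' cfg <- apply_ablation(sim_config(), ablation("sod-2", 0.9))
#' cfg$ablations$sod2
ablation <- function(gene, fraction) {
  gene <- match.arg(gene, c("sod-2", "daf-16", "skn-1"))
  if (fraction < 0 || fraction > 1)
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  structure(list(gene = gene, fraction = fraction),
            class = "mitosim_ablation")
}

#' @rdname ablation
#' @param cfg a `mitosim_config`.
#' @param scheme a `mitosim_ablation`.
#' @export
apply_ablation <- function(cfg, scheme) {
  if (!inherits(scheme, "mitosim_ablation"))
    stop("`scheme` must be built with ablation()", call. = FALSE)
  key <- switch(scheme$gene, "sod-2" = "sod2", "daf-16" = "daf16",
                "skn-1" = "skn1")
  cfg$ablations[[key]] <- scheme$fraction
  cfg
}
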