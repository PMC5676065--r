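#' Simulation configuration
#'
#' Builds a fully validated configuration for [run_simulation()]. Every rate
#' constant of the model lives in one of four named blocks (`simulation`,
#' `mitochondrion`, `cell`, `drugs`); pharmacological dosing windows and
#' genetic ablations are attached under `perturbations` and `ablations`.
#' Unsupplied values fall back to the calibrated defaults, which reproduce
#' the control aging timeline (NAD+ decline onset near 7500 min, first
#' compromised cells near 10000 min, ATP saturation near 20000 min, and an
#' aged-state tissue ROS roughly 10-fold the first-day baseline).
#'
#' Units: time in minutes, ROS pools in nM, ATP in mM, NAD+ relative to its
#' initial value, drug doses in nM (rapamycin, bafilomycin) or uM (paraquat,
#' pterostilbene). The simulated environment is isothermal at 20 degrees C;
#' the constant is informational and has no dynamics.
#'
#' @param t_end simulation horizon in minutes (default 30000).
#' @param dt integration step in minutes (default 1).
#' @param n_cells number of cell agents (default 65).
#' @param n_mito_init initial mitochondria per cell (default 50).
#' @param n_record number of evenly spaced output grid points (default 500).
#' @param seed integer master seed; every stochastic draw derives from it.
#' @param mitochondrion,cell,drugs named lists overriding individual rate
#'   constants in the corresponding block (see Details).
#' @param perturbations list of dosing schemes built with [perturbation()].
#' @param ablations list of genetic ablations built with [ablation()].
#'
#' @details
#' `mitochondrion` block: `k_sox` (superoxide per unit respiration flux,
#' nM/min), `w_flux` (share of electron input tied to functional capacity),
#' `leak_gain` (extra superoxide per unit OXPHOS defect), `w_h` (heteroplasmy
#' weight in the defect fraction), `k_atp` (ATP output per functional-capacity
#' unit, mM/min), `k_dmg_F`/`k_rep_F` (ROS-driven damage and
#' chaperone-dependent repair of OXPHOS capacity), `s_upr` (UPRmt suppression
#' of OXPHOS subunit synthesis), `k_dmg_P`/`k_rep_P` (matrix-protein damage
#' and repair), `k_dmg_dna` (ROS-driven mtDNA hit rate per copy),
#' `k_deg_dna`/`k_repl` (mtDNA turnover and homeostatic replication),
#' `adv_mut` (replicative advantage of the damaged class, >= 1),
#' `n_dna_init`/`n_dna_target` (copy numbers), `bands` (stress-state band
#' edges on the defect fraction), `state_fast`/`state_slow` (per-minute
#' hazards of moving toward or away from the defect-determined band).
#'
#' `cell` block: `k_sod`/`k_cat` (dismutation and peroxide clearance),
#' `k_sox_decay` (spontaneous dismutation), `K_g` (NAD+ half-saturation of
#' respiration), `k_import` (ATFS-1 mitochondrial import capacity),
#' `upr_K`/`upr_n` (Hill constants for UPRmt activation by nuclear ATFS-1),
#' `tau_tf` (DAF-16/SKN-1 relaxation time), `ros_K`/`ros_m` (Hill constants
#' of the ROS drive on DAF-16/SKN-1), `a_upr`/`a_daf`/`a_skn` (antioxidant
#' boosts), `c_upr`/`c_daf` (chaperone boosts), `eps_nad` (NADPH floor for
#' clearance), `k_nad_syn`/`k_nad_decay`/`beta_ros`/`ros_floor` (NAD+
#' salvage, consumption and its stress escalation), `k_atp_use` (ATP
#' consumption), `k_biog`/`b_nad`/`mito_cap` (biogenesis and carrying
#' capacity), `k_mitophagy`/`d_daf`/`state_mult` (selective mitophagy),
#' `k_death`/`tau_d`/`recover_frac` (compromised-state death hazard and the
#' recovery bound), `defective_include_s2` (0 counts only severely damaged
#' organelles as defective, 1 also counts significantly stressed ones),
#' `atp_init`/`nad_init` (initial pools).
#'
#' @return an object of class `mitosim_config` (a named list).
#' @seealso [preset_config()], [load_config()], [run_simulation()]
#' @export
#' @examples
#' cfg <- sim_config(t_end = 200, n_cells = 3, n_mito_init = 5, n_record = 5)
#' cfg$simulation$t_end
sim_config <- function(t_end = 30000, dt = 1, n_cells = 65,
                       n_mito_init = 50, n_record = 500, seed = 1L,
                       mitochondrion = list(), cell = list(), drugs = list(),
                       perturbations = list(), ablations = list()) {
  cfg <- default_config()
  cfg$simulation <- utils::modifyList(cfg$simulation, list(
    t_end = t_end, dt = dt, n_cells = n_cells, n_mito_init = n_mito_init,
    n_record = n_record, seed = as.integer(seed)))
  cfg$mitochondrion <- utils::modifyList(cfg$mitochondrion, mitochondrion)
  cfg$cell <- utils::modifyList(cfg$cell, cell)
  cfg$drugs <- utils::modifyList(cfg$drugs, drugs)
  if (length(perturbations) && inherits(perturbations, "mitosim_perturbation"))
    perturbations <- list(perturbations)
  if (length(ablations) && inherits(ablations, "mitosim_ablation"))
    ablations <- list(ablations)
  cfg$perturbations <- perturbations
  for (ab in ablations) cfg <- apply_ablation(cfg, ab)
  validate_config(cfg)
}

#' All-defaults configuration
#'
#' The calibrated default parameterization as a plain config object; the
#' building block behind [sim_config()] and the source of the default rate
#' blocks quoted throughout the documentation.
#'
#' @return a `mitosim_config`.
#' @export
default_config <- function() {
  structure(list(
    simulation = list(
      t_end = 30000, dt = 1, n_cells = 65L, n_mito_init = 50L,
      n_record = 500L, seed = 1L, temperature_C = 20),
    mitochondrion = list(
      k_sox = 3.9e-3, w_flux = 0.3, leak_gain = 15, w_h = 0.5,
      k_atp = 9.4e-4, k_dmg_F = 3e-5, k_rep_F = 3e-3, s_upr = 4,
      k_dmg_P = 2e-5, k_rep_P = 2e-3,
      k_dmg_dna = 3.4e-6, k_deg_dna = 2e-4, k_repl = 0.002, adv_mut = 1.1,
      n_dna_init = 10L, n_dna_target = 10L,
      bands = c(0.30, 0.60, 0.90), state_fast = 0.02, state_slow = 0.002),
    cell = list(
      k_sod = 0.1, k_cat = 0.05, k_sox_decay = 5e-4,
      K_g = 0.5, k_import = 1.18, upr_K = 0.25, upr_n = 4,
      tau_tf = 200, ros_K = 60, ros_m = 2,
      a_upr = 0.15, a_daf = 0.15, a_skn = 0.2, a_cat = 0.1,
      c_upr = 0.2, c_daf = 0.3,
      eps_nad = 0.1, w_sox_dmg = 0.05, sox_dmg_K = 60, k_nad_syn = 4e-4, k_nad_decay = 4e-4, beta_ros = 6,
      beta_upr = 5, ros_floor = 40, k_atp_use = 1 / 60,
      k_biog = 0.025, b_nad = 1, mito_cap = 80,
      k_mitophagy = 1e-4, d_daf = 0.5, u_mitoph = 0,
      state_mult = c(1, 1.5, 3, 6),
      k_death = 1e-4, tau_d = 5000, recover_frac = 0.60,
      defective_include_s2 = 0L, atp_init = 2.7, nad_init = 1),
    drugs = list(
      EC50_r = 5, E_r = 1.5, IC50_b = 20, B_r = 5, k_pq = 1.25e-4,
      pt_K = 30, pt_daf = 0.028, pt_skn = 0.028, pt_sirt = 0.025),
    perturbations = list(),
    ablations = list(sod2 = 0, daf16 = 0, skn1 = 0),
    conversion = list(
      protein_mass_per_worm_ug = 0.681, worm_volume_L = 3.5e-9,
      ros_aged_threshold_nM = 100, ros_fold_increase = 10)),
    class = "mitosim_config")
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant and names the offending key on failure.
#'
#' @param cfg a `mitosim_config` (or plain list with the same structure).
#' @return the validated config, invisibly classed as `mitosim_config`.
#' @export
validate_config <- function(cfg) {
  s <- cfg$simulation
  fail <- function(key, why) {
    stop("invalid config: `", key, "` ", why, call. = FALSE)
  }
  if (!is.numeric(s$t_end) || s$t_end <= 0) fail("t_end", "must be > 0")
  if (!is.numeric(s$dt) || s$dt <= 0) fail("dt", "must be > 0")
  if (s$n_record < 2) fail("n_record", "must be >= 2")
  if (s$n_cells < 1) fail("n_cells", "must be >= 1")
  if (s$n_mito_init < 1) fail("n_mito_init", "must be >= 1")
  if (s$dt > s$t_end / s$n_record)
    fail("dt", paste0("must be <= t_end/n_record = ",
                      format(s$t_end / s$n_record)))
  m <- cfg$mitochondrion
  rate_keys <- c("k_sox", "k_atp", "k_dmg_F", "k_rep_F", "k_dmg_dna",
                 "k_deg_dna", "k_repl", "leak_gain", "s_upr")
  for (k in rate_keys) if (m[[k]] < 0) fail(k, "must be >= 0")
  if (m$adv_mut < 1) fail("adv_mut", "must be >= 1")
  if (m$w_h < 0 || m$w_h > 1) fail("w_h", "must be in [0, 1]")
  if (!all(diff(m$bands) > 0) || length(m$bands) != 3)
    fail("bands", "must be three increasing defect-fraction edges")
  cc <- cfg$cell
  for (k in c("k_sod", "k_cat", "k_nad_syn", "k_nad_decay", "k_atp_use",
              "k_biog", "k_mitophagy", "k_death"))
    if (cc[[k]] < 0) fail(k, "must be >= 0")
  if (length(cc$state_mult) != 4 || any(diff(cc$state_mult) < 0))
    fail("state_mult",
         "must be four non-decreasing multipliers (mitophagy selectivity)")
  if (cc$recover_frac < 0 || cc$recover_frac > 1)
    fail("recover_frac", "must be a fraction")
  for (p in cfg$perturbations) {
    if (!inherits(p, "mitosim_perturbation"))
      fail("perturbations", "entries must be built with perturbation()")
  }
  ab <- cfg$ablations
  for (k in c("sod2", "daf16", "skn1"))
    if (ab[[k]] < 0 || ab[[k]] > 1) fail(k, "ablation fraction not in [0, 1]")
  structure(cfg, class = "mitosim_config")
}

#' @export
print.mitosim_config <- function(x, ...) {
  s <- x$simulation
  cat("<mitosim_config>\n")
  cat(sprintf("  horizon %g min, dt %g min, %d cells x %d mitochondria, %d grid points, seed %d\n",
              s$t_end, s$dt, s$n_cells, s$n_mito_init, s$n_record, s$seed))
  if (length(x$perturbations)) {
    for (p in x$perturbations)
      cat(sprintf("  dosing: %s %g %s [%g, %g] min, refresh %g min\n",
                  p$agent, p$dose, p$dose_unit, p$t_start,
                  min(p$t_end, s$t_end), p$refresh_every))
  }
  ab <- x$ablations
  on <- names(ab)[vapply(ab, function(v) v > 0, logical(1))]
  if (length(on))
    cat("  ablations:",
        paste(sprintf("%s %.0f%%", on, 100 * unlist(ab[on])), collapse = ", "),
        "\n")
  invisible(x)
}

#' Named scenario presets
#'
#' Returns a ready-to-run configuration for each virtual experiment:
#' `control`, `rapamycin15nM`, `bafilomycin10nM` (both refreshed every
#' 2500 min), `pq5uM`, `pq100uM`, `pt100uM` (constant dosing), the 90%
#' ablations `sod2_90`, `daf16_90`, `skn1_90`, the full knockout `skn1_100`,
#' and `sod2_sweep` (a named list of configs at 0/25/50/75/90/100% ablation).
#'
#' @param name preset name (see above).
#' @param seed master seed for the run.
#' @param ... further arguments passed to [sim_config()] (e.g. a shorter
#'   `t_end` or smaller `n_cells` for quick exploration).
#' @return a `mitosim_config`, or a named list of them for `sod2_sweep`.
#' @export
#' @examples
#' preset_config("control", seed = 7, t_end = 1000, n_record = 10)
preset_config <- function(name, seed = 1L, ...) {
  presets <- c("control", "rapamycin15nM", "bafilomycin10nM", "pq5uM",
               "pq100uM", "pt100uM", "sod2_90", "daf16_90", "skn1_90",
               "skn1_100", "sod2_sweep")
  name <- match.arg(name, presets)
  if (name == "sod2_sweep") {
    fr <- c(0, 0.25, 0.5, 0.75, 0.9, 1)
    out <- lapply(fr, function(f)
      sim_config(seed = seed, ablations = list(ablation("sod-2", f)), ...))
    names(out) <- sprintf("sod2_%.0f", 100 * fr)
    return(out)
  }
  args <- switch(name,
    control = list(),
    rapamycin15nM = list(perturbations = list(perturbation("rapamycin", 15))),
    bafilomycin10nM = list(perturbations = list(perturbation("bafilomycin", 10))),
    pq5uM = list(perturbations = list(perturbation("paraquat", 5))),
    pq100uM = list(perturbations = list(perturbation("paraquat", 100))),
    pt100uM = list(perturbations = list(perturbation("pterostilbene", 100))),
    sod2_90 = list(ablations = list(ablation("sod-2", 0.9))),
    daf16_90 = list(ablations = list(ablation("daf-16", 0.9))),
    skn1_90 = list(ablations = list(ablation("skn-1", 0.9))),
    skn1_100 = list(ablations = list(ablation("skn-1", 1))))
  do.call(sim_config, c(args, list(seed = seed), list(...)))
}

#' Read / write configurations as YAML
#'
#' `load_config()` reads a (possibly partial) YAML file, fills defaults, and
#' validates; an empty file yields the all-defaults configuration. Unknown
#' keys produce a warning, not an error. `write_config()` serialises a config
#' so that load -> write -> load round-trips.
#'
#' @param path file path.
#' @return `load_config()`: a `mitosim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  known <- names(cfg)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  for (blk in intersect(names(raw), setdiff(known, "perturbations"))) {
    sub_unknown <- setdiff(names(raw[[blk]]), names(cfg[[blk]]))
    if (length(sub_unknown))
      warning("ignoring unknown keys in `", blk, "`: ",
              paste(sub_unknown, collapse = ", "), call. = FALSE)
    cfg[[blk]] <- utils::modifyList(cfg[[blk]],
                                    raw[[blk]][names(raw[[blk]]) %in%
                                                 names(cfg[[blk]])])
  }
  cfg$simulation$n_cells <- as.integer(cfg$simulation$n_cells)
  cfg$simulation$n_record <- as.integer(cfg$simulation$n_record)
  cfg$simulation$n_mito_init <- as.integer(cfg$simulation$n_mito_init)
  cfg$simulation$seed <- as.integer(cfg$simulation$seed)
  if (!is.null(raw$perturbations)) {
    cfg$perturbations <- lapply(raw$perturbations, function(p)
      perturbation(p$agent, p$dose,
                   t_start = p$t_start %||% 0,
                   t_end = p$t_end %||% Inf,
                   refresh_every = p$refresh_every %||% 2500,
                   decay_halflife = p$decay_halflife %||% NA_real_))
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg a `mitosim_config`.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- unclass(cfg)
  out$perturbations <- lapply(out$perturbations, function(p) {
    p <- unclass(p)
    p$t_end <- if (is.infinite(p$t_end)) .Machine$double.xmax else p$t_end
    p
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Deterministic configuration hash
#'
#' Semantically identical configs (same values, any construction route) hash
#' identically; used in run manifests.
#'
#' @param cfg a `mitosim_config`.
#' @return a character scalar.
#' @export
config_hash <- function(cfg) {
  rlang::hash(normalize_config(cfg))
}

# canonical form: sorted keys, numeric coercion, perturbations as plain lists
normalize_config <- function(cfg) {
  norm <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, norm)
      if (!is.null(names(x))) x <- x[order(names(x))]
      x
    } else if (is.numeric(x)) as.numeric(x) else x
  }
  norm(unclass(cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
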