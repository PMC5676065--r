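#' Run manifest
#'
#' Deterministic metadata for one run: config hash, seed, package version and
#' timestamps. The hash depends only on the config's semantic content.
#'
#' @param config a `mitosim_config`.
#' @param preset optional preset name to record.
#' @return a list of class `mitosim_manifest`.
#' @export
run_manifest <- function(config, preset = NA_character_) {
  structure(list(
    config_hash = config_hash(config),
    seed = config$simulation$seed,
    preset = preset,
    version = as.character(utils::packageVersion("mitosim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "mitosim_manifest")
}

#' Write run outputs
#'
#' Writes `cells.csv` (tidy per-cell rows), `tissue.csv` (alive-cell
#' aggregates), `summary.json` (endpoints: survival curve, time-to-threshold
#' values, final tissue means) and `manifest.json` into `outdir`. Numeric
#' formatting is bit-stable across runs of the same seed (RFC 4180 CSV,
#' UTF-8, `.` decimal).
#'
#' @param result a `mitosim_result`.
#' @param outdir output directory (created if missing).
#' @param manifest optional [run_manifest()]; taken from the result when
#'   omitted.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir, manifest = NULL) {
  stopifnot(inherits(result, "mitosim_result"))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(manifest)) manifest <- result$manifest
  paths <- c(
    cells = file.path(outdir, "cells.csv"),
    tissue = file.path(outdir, "tissue.csv"),
    summary = file.path(outdir, "summary.json"),
    manifest = file.path(outdir, "manifest.json"))
  utils::write.csv(result$cells, paths["cells"], row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(result$tissue, paths["tissue"], row.names = FALSE,
                   fileEncoding = "UTF-8")
  crossings <- time_to_ros_threshold(result)
  sc <- survival_and_state_curves(result)
  summary <- list(
    survival_curve = list(time = sc$time, survival = sc$survival,
                          n_compromised = sc$n_compromised,
                          n_dead = sc$n_dead),
    time_to_ros_threshold = list(
      threshold_nM = result$config$conversion$ros_aged_threshold_nM,
      t_cross = crossings$t_cross,
      n_never_crossed = sum(is.na(crossings$t_cross))),
    end_state = as.list(result$tissue[nrow(result$tissue),
                                      c("ros", "atp", "nad", "mito_count",
                                        "heteroplasmy_pct", "survival")]),
    ros_baseline_nM = ros_baseline(result))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  jsonlite::write_json(unclass(manifest), paths["manifest"],
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(paths)
}

#' Miniature fixtures for testing and examples
#'
#' Deterministic, fast-running inputs: `tiny_population` (3 cells, 5
#' mitochondria, 100 min), `frozen` (every rate zero, so all observables stay
#' constant), and `surrogate_powerlaw` (a closed-form power-law "model" for
#' checking the sensitivity machinery against its analytic answer).
#'
#' @param kind one of `"tiny_population"`, `"frozen"`,
#'   `"surrogate_powerlaw"`.
#' @param seed master seed.
#' @return a `mitosim_config` for the first two kinds; for
#'   `surrogate_powerlaw`, a list with the surrogate function `f(P)`,
#'   its exponent `k`, and coefficient `c0`.
#' @export
#' @examples
#' cfg <- make_fixture("tiny_population", seed = 5)
#' run_simulation(cfg)$tissue
make_fixture <- function(kind, seed = 1L) {
  kind <- match.arg(kind, c("tiny_population", "frozen",
                            "surrogate_powerlaw"))
  if (kind == "tiny_population") {
    return(sim_config(t_end = 100, dt = 1, n_cells = 3, n_mito_init = 5,
                      n_record = 11, seed = seed))
  }
  if (kind == "frozen") {
    zero_m <- list(k_sox = 0, k_dmg_F = 0, k_rep_F = 0, k_dmg_P = 0,
                   k_rep_P = 0, k_dmg_dna = 0, k_deg_dna = 0, k_repl = 0,
                   state_fast = 0, state_slow = 0, k_atp = 0)
    zero_c <- list(k_sod = 0, k_cat = 0, k_sox_decay = 0, k_nad_syn = 0,
                   k_nad_decay = 0, k_atp_use = 0, k_biog = 0,
                   k_mitophagy = 0, k_death = 0)
    return(sim_config(t_end = 100, dt = 1, n_cells = 3, n_mito_init = 5,
                      n_record = 11, seed = seed, mitochondrion = zero_m,
                      cell = zero_c))
  }
  k <- 2
  c0 <- 3.7
  list(f = function(P) c0 * P^k, k = k, c0 = c0)
}
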