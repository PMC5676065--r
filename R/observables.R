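#' Literature unit conversions
#'
#' `atp_mM()` converts a per-worm ATP amount (mol) to a concentration (mM)
#' assuming an average worm body volume of 3.5e-9 L. `o2_per_worm()` converts
#' an oxygen consumption rate per mg protein to a per-worm rate assuming an
#' average protein mass per worm of 0.681 ug. Both are linear and round-trip
#' exactly.
#'
#' @param mol_per_worm ATP per worm (mol), >= 0.
#' @param conversion conversion-constant block (see [sim_config()]).
#' @return `atp_mM()`: mmol/L; `o2_per_worm()`: pmol min^-1 worm^-1.
#' @export
#' @examples
#' atp_mM(3.5e-12)        # 1 mM
#' o2_per_worm(1000)      # 0.681 pmol/min/worm
atp_mM <- function(mol_per_worm,
                   conversion = default_config()$conversion) {
  if (any(mol_per_worm < 0)) stop("amount must be >= 0", call. = FALSE)
  mol_per_worm / conversion$worm_volume_L * 1e3
}

#' @rdname atp_mM
#' @param rate_per_mg_protein O2 consumption (pmol min^-1 mg^-1), >= 0.
#' @export
o2_per_worm <- function(rate_per_mg_protein,
                        conversion = default_config()$conversion) {
  if (any(rate_per_mg_protein < 0)) stop("rate must be >= 0", call. = FALSE)
  rate_per_mg_protein * conversion$protein_mass_per_worm_ug * 1e-3
}

#' Deleterious heteroplasmy percentage
#'
#' `100 * sum(n_mut) / sum(n_wt + n_mut)` over a cell's mitochondria —
#' invariant to how copies are distributed among organelles at fixed pool
#' totals.
#'
#' @param cell a `mitosim_cell`, or a data frame with columns `n_wt`,
#'   `n_mut`; alternatively pass `n_wt` and `n_mut` directly.
#' @param n_wt,n_mut pooled copy counts.
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' heteroplasmy_percent(n_wt = 30, n_mut = 10)  # 25
heteroplasmy_percent <- function(cell = NULL, n_wt = NULL, n_mut = NULL) {
  if (!is.null(cell)) {
    mt <- if (inherits(cell, "mitosim_cell")) cell$mitos else cell
    if (nrow(mt) == 0) stop("cell has no mitochondria", call. = FALSE)
    n_wt <- sum(mt$n_wt); n_mut <- sum(mt$n_mut)
  }
  tot <- sum(n_wt) + sum(n_mut)
  if (tot < 1) stop("total mtDNA must be >= 1", call. = FALSE)
  100 * sum(n_mut) / tot
}

#' First crossing of the aged-ROS threshold
#'
#' Scans a per-cell ROS series for the first grid time at which combined
#' superoxide and peroxide reaches `threshold` (default 100 nM, the 10-fold
#' increase characterising the age-compromised phenotype). Cells that never
#' cross return `NA` and are counted, not dropped.
#'
#' @param trace either a numeric ROS series (with `time`), a `mitosim_result`
#'   (per-cell scan), or a data frame with `time` and `ros` columns.
#' @param time grid times matching a numeric `trace`.
#' @param threshold nM, > 0.
#' @return a single time for a numeric trace; for a `mitosim_result`, a
#'   tibble with columns `cell` and `t_cross` (NA when never crossed).
#' @export
#' @examples
#' time_to_ros_threshold(c(8, 50, 120, 90), time = c(0, 60, 120, 180))
time_to_ros_threshold <- function(trace, time = NULL, threshold = 100) {
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (inherits(trace, "mitosim_result")) {
    out <- dplyr::summarise(
      dplyr::group_by(trace$cells, .data$cell),
      t_cross = first_crossing(.data$ros, .data$time, threshold),
      .groups = "drop")
    return(out)
  }
  if (is.data.frame(trace))
    return(first_crossing(trace$ros, trace$time, threshold))
  first_crossing(trace, time, threshold)
}

first_crossing <- function(ros, time, threshold) {
  i <- which(ros >= threshold)
  if (length(i) == 0) NA_real_ else time[min(i)]
}

#' Survival and life-state curves
#'
#' Viable/compromised/dead counts on the recording grid and the survival
#' fraction `1 - dead / n_cells`, which is non-increasing because death is
#' absorbing.
#'
#' @param traj a `mitosim_result`, or a per-cell tibble with columns `time`,
#'   `cell`, `life`.
#' @return a tibble with columns `time`, `n_healthy`, `n_compromised`,
#'   `n_dead`, `survival`.
#' @export
survival_and_state_curves <- function(traj) {
  cells <- if (inherits(traj, "mitosim_result")) traj$cells else traj
  n_cells <- length(unique(cells$cell))
  dplyr::summarise(
    dplyr::group_by(cells, .data$time),
    n_healthy = sum(.data$life == "healthy"),
    n_compromised = sum(.data$life == "compromised"),
    n_dead = sum(.data$life == "dead"),
    survival = 1 - .data$n_dead / n_cells,
    .groups = "drop")
}

#' Mean cell survival time
#'
#' Restricted mean survival over the simulated horizon: the area under the
#' survival-fraction curve (cells alive at `t_end` contribute the full
#' horizon).
#'
#' @param traj a `mitosim_result`.
#' @return minutes.
#' @export
mean_survival_time <- function(traj) {
  sc <- survival_and_state_curves(traj)
  sum(diff(sc$time) * (utils::head(sc$survival, -1) +
                         utils::tail(sc$survival, -1)) / 2)
}

#' First-day tissue ROS baseline
#'
#' Population-mean combined superoxide and peroxide over the first recorded
#' day (1440 min); the calibrated default configuration puts this near 10 nM
#' so that the 100 nM aged threshold is the canonical 10-fold increase.
#'
#' @param result a `mitosim_result`.
#' @param window minutes counted as the first day.
#' @return nM.
#' @export
ros_baseline <- function(result, window = 1440) {
  t0 <- result$tissue$time <= window
  mean(result$tissue$ros[t0], na.rm = TRUE)
}

#' Onset of a sustained decline
#'
#' Finds the first grid time after which a (seed-mean) trajectory decreases
#' monotonically over a trailing window and loses at least `min_drop` of its
#' initial level across that window. Used to date the onset of the NAD+ and
#' ATP declines.
#'
#' @param time grid times (minutes).
#' @param value trajectory values.
#' @param window minutes over which the decrease must be sustained.
#' @param min_drop minimum fractional drop (relative to the trajectory's
#'   initial value) across the window.
#' @param tol small upward wiggle tolerated per grid step, as a fraction of
#'   the initial value. The window must open with a strict decrease, so a
#'   flat stretch ahead of the decline is not counted as part of it.
#' @return onset time in minutes, or `NA` when no sustained decline exists.
#' @export
decline_onset <- function(time, value, window = 2000, min_drop = 0.05,
                          tol = 1e-4) {
  stopifnot(length(time) == length(value))
  v0 <- value[1]
  k <- max(1L, sum(time <= time[1] + window) - 1L)
  n <- length(value)
  for (i in seq_len(n - k)) {
    seg <- value[i:(i + k)]
    if (seg[2] < seg[1] &&
        all(diff(seg) <= tol * v0) && (seg[1] - seg[k + 1]) >= min_drop * v0)
      return(time[i])
  }
  NA_real_
}

#' Time at which a declining trajectory saturates
#'
#' Dates the end of a decline: the first grid time, at or after the steepest
#' descent, from which the decline rate stays below `frac` of its peak
#' magnitude for a sustained `window`. Used to date the late-life ATP
#' plateau.
#'
#' @param time grid times (minutes).
#' @param value trajectory values.
#' @param frac fraction of the peak decline rate below which the trajectory
#'   counts as saturated.
#' @param window minutes the rate must stay low.
#' @return minutes, or `NA` if the trajectory never settles.
#' @export
saturation_time <- function(time, value, frac = 0.1, window = 2000) {
  stopifnot(length(time) == length(value))
  d <- diff(value) / diff(time)
  peak <- which.min(d)
  if (d[peak] >= 0) return(NA_real_)
  low <- abs(d) < frac * abs(d[peak])
  k <- max(1L, sum(time <= time[1] + window) - 1L)
  for (i in peak:(length(d) - k)) {
    if (all(low[i:(i + k)])) return(time[i])
  }
  NA_real_
}

#' Time at which a trajectory reaches half its total rise
#'
#' Used for the heteroplasmy half-rise comparison between mitophagy
#' perturbations: the first grid time at which the series reaches
#' `start + 0.5 * (max - start)`.
#'
#' @param time grid times.
#' @param value trajectory values.
#' @return minutes, or `NA` for a flat series.
#' @export
half_rise_time <- function(time, value) {
  v0 <- value[1]
  vmax <- max(value, na.rm = TRUE)
  if (!is.finite(vmax) || vmax <= v0) return(NA_real_)
  first_crossing(value, time, v0 + 0.5 * (vmax - v0))
}
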