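#' Run the hierarchical aging simulation
#'
#' Initialises `n_cells` cell agents, each holding `n_mito_init` healthy
#' mitochondria and a compromise threshold sampled from
#' triangular(0.60, 0.625, 0.75), then advances the coupled ODE network and
#' discrete stochastic events in fixed `dt` increments to `t_end`, recording
#' every observable on an evenly spaced grid of `n_record` points. Identical
#' seed and configuration give a bit-identical result; each cell draws from
#' its own stream derived from the master seed, so a cell's trajectory does
#' not depend on how many other cells are simulated after it.
#'
#' @param config a `mitosim_config` from [sim_config()] or [preset_config()].
#' @return an object of class `mitosim_result`: a list with tibbles `cells`
#'   (one row per cell per grid time) and `tissue` (alive-cell aggregates and
#'   life-state counts per grid time), plus `time`, `config`, and a run
#'   `manifest`.
#' @seealso [survival_and_state_curves()], [autoplot.mitosim_result()]
#' @export
#' @examples
#' res <- run_simulation(sim_config(t_end = 500, n_cells = 3,
#'                                  n_mito_init = 5, n_record = 6))
#' res$tissue
run_simulation <- function(config) {
  config <- validate_config(config)
  raw <- cpp_run_simulation(lower_config(config))
  assemble_result(raw, config)
}

# Resolve R-side conveniences (Inf dosing windows, label codes) into the
# plain numeric structure the C++ engine reads.
lower_config <- function(config) {
  cfg <- unclass(config)
  t_end <- cfg$simulation$t_end
  cfg$perturbations <- lapply(cfg$perturbations, function(p) {
    list(agent_code = p$agent_code, dose = p$dose,
         t_start = p$t_start,
         t_end = if (is.infinite(p$t_end)) t_end + 1 else p$t_end,
         refresh_every = p$refresh_every,
         decay_halflife = if (is.na(p$decay_halflife)) -1
                          else p$decay_halflife)
  })
  cfg
}

assemble_result <- function(raw, config) {
  n_record <- length(raw$time)
  n_cells <- ncol(raw$nad)
  time <- raw$time
  count <- raw$mito_count

  frac <- function(s) {
    f <- s / count
    f[count == 0] <- NA_real_
    f
  }
  cells <- tibble::tibble(
    time = rep(time, n_cells),
    cell = rep(seq_len(n_cells), each = n_record),
    sox = as.vector(raw$sox),
    h2o2 = as.vector(raw$h2o2),
    ros = as.vector(raw$sox + raw$h2o2),
    nad = as.vector(raw$nad),
    atp = as.vector(raw$atp),
    resp = as.vector(raw$resp),
    mito_count = as.vector(count),
    n_wt = as.vector(raw$n_wt),
    n_mut = as.vector(raw$n_mut),
    mean_F = as.vector(raw$mean_F),
    upr = as.vector(raw$upr),
    daf16 = as.vector(raw$daf16),
    skn1 = as.vector(raw$skn1),
    atfs1_nuc = as.vector(raw$atfs1),
    s0_frac = as.vector(frac(raw$s0)),
    s1_frac = as.vector(frac(raw$s1)),
    s2_frac = as.vector(frac(raw$s2)),
    s3_frac = as.vector(frac(raw$s3)),
    cum_mitophagy = as.vector(raw$cum_mitophagy),
    cum_biogenesis = as.vector(raw$cum_biogenesis),
    life = life_labels()[as.vector(raw$life) + 1L])

  alive <- raw$life < 2L
  n_alive <- rowSums(alive)
  amean <- function(x) {
    m <- rowSums(x * alive) / n_alive
    m[n_alive == 0] <- NA_real_
    m
  }
  het <- 100 * raw$n_mut / pmax(raw$n_wt + raw$n_mut, 1L)
  tissue <- tibble::tibble(
    time = time,
    ros = amean(raw$sox + raw$h2o2),
    sox = amean(raw$sox),
    h2o2 = amean(raw$h2o2),
    nad = amean(raw$nad),
    atp = amean(raw$atp),
    resp = amean(raw$resp),
    mito_count = amean(count),
    heteroplasmy_pct = amean(het),
    mean_F = amean(raw$mean_F),
    n_healthy = rowSums(raw$life == 0L),
    n_compromised = rowSums(raw$life == 1L),
    n_dead = rowSums(raw$life == 2L),
    survival = 1 - rowSums(raw$life == 2L) / n_cells)

  structure(list(
    time = time,
    cells = cells,
    tissue = tissue,
    config = config,
    manifest = run_manifest(config)),
    class = "mitosim_result")
}

#' Reproducible random-number streams
#'
#' Derives one independent substream seed per cell plus one engine stream
#' from the master seed. The same master seed always yields the same
#' streams, and each cell's draws depend only on its own stream, so stepping
#' cells in any order (or adding more cells) leaves existing per-cell
#' trajectories unchanged.
#'
#' @param seed master seed (integer).
#' @param n_cells number of cells.
#' @return a tibble with columns `stream` (`"engine"`, `"cell_1"`, ...) and
#'   `seed`.
#' @export
rng_streams <- function(seed, n_cells) {
  stopifnot(n_cells >= 1)
  s <- cpp_stream_seeds(seed, as.integer(n_cells) + 1L)
  tibble::tibble(
    stream = c("engine", paste0("cell_", seq_len(n_cells))),
    seed = s)
}

#' @export
print.mitosim_result <- function(x, ...) {
  s <- x$config$simulation
  last <- x$tissue[nrow(x$tissue), ]
  cat("<mitosim_result>\n")
  cat(sprintf("  %d cells to %g min (%d grid points), seed %d\n",
              s$n_cells, s$t_end, s$n_record, s$seed))
  cat(sprintf("  end state: %d healthy / %d compromised / %d dead (survival %.2f)\n",
              last$n_healthy, last$n_compromised, last$n_dead, last$survival))
  if (is.finite(last$ros))
    cat(sprintf("  end tissue means: ROS %.1f nM, ATP %.2f mM, NAD+ %.2f, %.1f mitochondria\n",
                last$ros, last$atp, last$nad, last$mito_count))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' @param x a `mitosim_result`.
#' @param level `"cells"` (default) for per-cell rows or `"tissue"` for
#'   alive-cell aggregates.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mitosim_result <- function(x, level = c("cells", "tissue"), ...) {
  level <- match.arg(level)
  x[[level]]
}

#' One-row summary of a simulation run
#'
#' @param x a `mitosim_result`.
#' @param ... unused.
#' @return a tibble with end-of-run survival, life-state counts, tissue
#'   means, the aged-ROS baseline/fold, and the config hash.
#' @export
glance.mitosim_result <- function(x, ...) {
  last <- x$tissue[nrow(x$tissue), ]
  base <- ros_baseline(x)
  tibble::tibble(
    t_end = max(x$time),
    n_cells = x$config$simulation$n_cells,
    survival = last$survival,
    n_healthy = last$n_healthy,
    n_compromised = last$n_compromised,
    n_dead = last$n_dead,
    end_ros = last$ros,
    end_atp = last$atp,
    end_nad = last$nad,
    end_mito_count = last$mito_count,
    ros_baseline = base,
    peak_ros_fold = max(x$tissue$ros, na.rm = TRUE) / base,
    config_hash = config_hash(x$config))
}
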