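#' Plot tissue-level trajectories
#'
#' Faceted tissue means (ROS, ATP, NAD+, mitochondrial count, heteroplasmy
#' percentage) over simulated time, with the cell life-state composition.
#'
#' @param object a `mitosim_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mitosim_result <- function(object, ...) {
  vars <- c(ros = "tissue ROS (nM)", atp = "ATP (mM)",
            nad = "NAD+ (relative)", mito_count = "mitochondria per cell",
            heteroplasmy_pct = "heteroplasmy (%)",
            survival = "survival fraction")
  long <- tidyr::pivot_longer(
    object$tissue[, c("time", names(vars))],
    -"time", names_to = "variable", values_to = "value")
  long$variable <- factor(vars[long$variable], levels = unname(vars))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = "Tissue-level aging trajectories") +
    ggplot2::theme_minimal()
}

#' Plot single-cell ROS traces
#'
#' One line per cell (the stochastic single-cell picture behind the tissue
#' mean), with the aged-phenotype threshold marked.
#'
#' @param result a `mitosim_result`.
#' @param threshold aged-ROS threshold to mark (nM).
#' @return a ggplot object.
#' @export
plot_cell_ros <- function(result, threshold = 100) {
  ggplot2::ggplot(result$cells,
                  ggplot2::aes(x = .data$time, y = .data$ros,
                               group = .data$cell)) +
    ggplot2::geom_line(alpha = 0.3, color = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "time (min)", y = "single-cell ROS (nM)",
                  title = "Single-cell oxidative burden") +
    ggplot2::theme_minimal()
}

#' Plot stress-state composition
#'
#' Population-mean fractions of the four mitochondrial stress states over
#' time (the mito-phenotyping view).
#'
#' @param result a `mitosim_result`.
#' @return a ggplot object.
#' @export
plot_stress_states <- function(result) {
  cells <- result$cells[result$cells$life != "dead", ]
  long <- tidyr::pivot_longer(
    cells[, c("time", "cell", "s0_frac", "s1_frac", "s2_frac", "s3_frac")],
    tidyr::all_of(c("s0_frac", "s1_frac", "s2_frac", "s3_frac")),
    names_to = "state", values_to = "frac")
  long$state <- factor(long$state,
                       levels = c("s0_frac", "s1_frac", "s2_frac", "s3_frac"),
                       labels = stress_state_labels())
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$time, .data$state),
    frac = mean(.data$frac, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$time, y = .data$frac,
                                    fill = .data$state)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = c("forestgreen", "gold",
                                          "darkorange", "firebrick")) +
    ggplot2::labs(x = "time (min)", y = "fraction of mitochondria",
                  fill = NULL, title = "Mitochondrial stress-state phenotyping") +
    ggplot2::theme_minimal()
}

#' Plot survival and life-state curves
#'
#' @param result a `mitosim_result` (or a list of them, named by arm, for an
#'   overlay).
#' @return a ggplot object.
#' @export
plot_survival <- function(result) {
  if (inherits(result, "mitosim_result")) result <- list(run = result)
  tabs <- dplyr::bind_rows(
    lapply(result, survival_and_state_curves), .id = "arm")
  ggplot2::ggplot(tabs, ggplot2::aes(x = .data$time, y = .data$survival,
                                     color = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "survival fraction", color = NULL,
                  title = "Cell survival") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity table
#'
#' Heatmap of normalized sensitivity coefficients by parameter, response and
#' age point; cells beyond the significance boundary (`|SC| >= 1`) are
#' outlined.
#'
#' @param object a `mitosim_sensitivity` table.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mitosim_sensitivity <- function(object, ...) {
  object$age_lab <- factor(paste0(object$age_min, " min"),
                           levels = paste0(sort(unique(object$age_min)),
                                           " min"))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$response, y = .data$parameter,
                               fill = .data$SC)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = object[which(object$significant), ],
                       color = "black", linewidth = 0.6, fill = NA) +
    ggplot2::facet_wrap(~age_lab) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Normalized sensitivity coefficients") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
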