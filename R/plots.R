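#' Plot a substrate concentration field
#'
#' @param object a [substrate_field()].
#' @param ... unused.
#' @return A ggplot raster of the gold-concentration field with axes in nm.
#' @export
autoplot.substrate_field <- function(object, ...) {
  m <- object$concentration
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    c = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col * object$pixel_size,
                                   y = .data$row * object$pixel_size,
                                   fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "gold",
                                 limits = c(0, 1), name = "gold\nfraction") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = if (!is.na(object$nominal_pore_nm))
                    sprintf("NPG substrate, nominal pore %g nm",
                            object$nominal_pore_nm) else "substrate field") +
    ggplot2::theme_minimal()
}

#' Plot state counts along a trajectory
#'
#' @param object an `mc_trajectory` from [run_to_equilibrium()].
#' @param ... unused.
#' @return A ggplot of integrin state counts versus simulated time.
#' @export
autoplot.mc_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$checkpoints,
                              cols = dplyr::starts_with("n_"),
                              names_to = "state", names_prefix = "n_",
                              values_to = "count")
  long$state <- factor(long$state,
                       levels = c("inactive", "active", "bound", "associated"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step * object$params$dt,
                                     y = .data$count,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "integrins", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a scenario x pore-size sweep
#'
#' Mirrors the standard presentation of the clustering results: one bar per
#' substrate (pore sizes in nm plus the flat gold control), mean +/-
#' standard error over replicates, faceted by scenario.
#'
#' @param object an `npg_sweep` tibble from [sweep_scenarios()].
#' @param metric `"n_clustered"` or `"mean_fa_area_top10"`.
#' @param ... unused.
#' @return A ggplot bar chart.
#' @export
autoplot.npg_sweep <- function(object, metric = c("n_clustered",
                                                  "mean_fa_area_top10"), ...) {
  metric <- match.arg(metric)
  agg <- summarize_sweep(object)
  if (metric == "n_clustered") {
    agg$mean <- agg$n_clustered_mean
    agg$se <- agg$n_clustered_se
    ylab <- "clustered integrins"
  } else {
    agg$mean <- agg$fa_area_mean
    agg$se <- agg$fa_area_se
    ylab <- "mean FA area, top decile (integrins)"
  }
  agg$substrate <- stats::reorder(agg$substrate, agg$pore_nm)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$substrate, y = .data$mean)) +
    ggplot2::geom_col(fill = "goldenrod") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "substrate", y = ylab) +
    ggplot2::theme_minimal()
}
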