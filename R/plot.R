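#' Plot a closed-loop run
#'
#' Time series of the patient output y, reference-model output ym,
#' commanded set-point r, and (optionally) the control signal u in a
#' second panel.
#'
#' @param res A `simulation_result`.
#' @param show_u Include the control-signal panel.
#' @param thin Plot every `thin`-th sample (the 1 ms grid is denser than
#'   any display needs).
#' @return A ggplot object.
#' @export
plot_run <- function(res, show_u = FALSE, thin = 20) {
  stopifnot(inherits(res, "simulation_result"))
  tr <- res$trajectories
  if (nrow(tr) == 0) stop("empty simulation result")
  tr <- tr[seq(1, nrow(tr), by = max(1L, as.integer(thin))), ]
  long <- rbind(
    data.frame(t = tr$t, value = tr$y, signal = "y (patient SpO2)"),
    data.frame(t = tr$t, value = tr$ym, signal = "ym (reference)"),
    data.frame(t = tr$t, value = tr$r, signal = "r (set-point)"))
  if (show_u)
    long <- rbind(long,
                  data.frame(t = tr$t, value = tr$u, signal = "u (control)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$signal,
                                     linetype = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "% SpO2 / % supply",
                  title = res$scenario$name) +
    ggplot2::theme_minimal()
}

#' Plot the fuzzy control surface
#'
#' Heatmap of the inferred adaptation gain m over the (e, de) grid.
#'
#' @param surface Output of [control_surface()].
#' @return A ggplot object.
#' @export
plot_surface <- function(surface) {
  df <- expand.grid(e = surface$e, de = surface$de)
  df$m <- as.vector(surface$m)          # m[i, j]: e index i varies fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e, y = .data$de,
                                   fill = .data$m)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "error e (% SpO2)", y = "error rate de (%/s)",
                  fill = "m") +
    ggplot2::theme_minimal()
}
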