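#' Plot a metagene profile
#'
#' Mean (adjusted) sigma against the offset from the origin summit.
#'
#' @param profiles A [metagene()] profile or a list of them (overlaid, one
#'   line per timepoint).
#' @return A ggplot object.
#' @export
plot_metagene <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (inherits(profiles, "metagene_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(offset_kb = p$offset / 1000, mean_asigma = p$mean_asigma,
               timepoint = factor(attr(p, "timepoint_min")))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = offset_kb,
                                   y = mean_asigma,
                                   colour = timepoint)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from origin summit (kb)",
                  y = "mean adjusted sigma", colour = "t (min)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-origin efficiencies between two samples
#'
#' The classic class-coloured diagonal scatter: efficiency in sample A against
#' sample B, one point per origin.
#'
#' @param correlation A [correlate_catalogs()] summary.
#' @return A ggplot object.
#' @export
plot_origin_correlation <- function(correlation) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  pts <- attr(correlation, "points")
  pts <- pts[!is.na(pts$eff_A) & !is.na(pts$eff_B), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = eff_A, y = eff_B,
                                    colour = class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(CN = "purple3",
                                            intermediate = "grey40",
                                            Oi = "red3")) +
    ggplot2::labs(x = "efficiency, sample A (sigma)",
                  y = "efficiency, sample B (sigma)") +
    ggplot2::theme_minimal()
}
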