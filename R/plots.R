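#' Plot a composite-index trajectory
#'
#' Per-window composite index against window age, the peak (tipping
#' point) highlighted.
#'
#' @param result A `dnb_result` from [dnb_scan()].
#' @param ... Passed to [graphics::plot()].
#' @return `result`, invisibly.
#' @export
plot_ci_trajectory <- function(result, ...) {
  stopifnot(inherits(result, "dnb_result"))
  s <- result$scores
  graphics::plot(s$age_label, s$ci, type = "b", pch = 19,
                 xlab = "window age (years)", ylab = "composite index (CI)",
                 main = sprintf("DNB composite index (peak z = %.2f)", result$z),
                 ...)
  graphics::points(s$age_label[result$tipping_index],
                   s$ci[result$tipping_index], pch = 19, cex = 1.6,
                   col = "red")
  invisible(result)
}

#' Plot a 1-D ordination axis against age
#'
#' @param axis A 1-D `ordination` (see [mds_axis()]).
#' @param ages Ages aligned with the axis samples.
#' @param species Optional species labels for coloring.
#' @param ... Passed to [graphics::plot()].
#' @return `axis`, invisibly.
#' @export
plot_mds_age <- function(axis, ages, species = NULL, ...) {
  stopifnot(inherits(axis, "ordination"))
  col <- if (is.null(species)) 1 else as.integer(factor(species))
  graphics::plot(ages, axis$coordinates[, 1], col = col, pch = 19,
                 xlab = "age (years)", ylab = "first axis", ...)
  if (!is.null(species)) {
    lv <- levels(factor(species))
    graphics::legend("bottomright", legend = lv, col = seq_along(lv), pch = 19)
  }
  invisible(axis)
}
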