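# Heat-map of a connectivity matrix and a distance-decay curve.

#' Plot a connectivity matrix heat map
#'
#' Releases on the y-axis, settlement cells on the x-axis, the diagonal
#' showing self-recruitment, on a log-like colour scale emphasising rare
#' long-distance connections.
#'
#' @param matrix a [ConnectivityMatrix-class].
#' @param main plot title.
#' @return invisibly, the plotted probability matrix
#' @export
plotConnectivity <- function(matrix,
                             main = paste("Connectivity,",
                                          connBehavior(matrix))) {
  p <- connProbabilities(matrix)
  z <- log10(pmax(p, 1e-5))
  cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_len(ncol(p)), seq_len(nrow(p)), t(z[nrow(z):1, ]),
                  col = cols, xlab = "settlement cell",
                  ylab = "release cell", main = main, axes = FALSE)
  graphics::box()
  invisible(p)
}

#' Plot connectivity probability against shoreline distance
#'
#' Off-diagonal probabilities against distance with the fitted
#' exponential decay overlaid.
#'
#' @param matrix a [ConnectivityMatrix-class] or probability matrix.
#' @param distances km matrix aligned with `matrix`.
#' @param ... passed to [graphics::plot()].
#' @return the [distanceDecay()] fit, invisibly
#' @export
plotDistanceDecay <- function(matrix, distances, ...) {
  p <- if (is(matrix, "ConnectivityMatrix")) connProbabilities(matrix)
       else matrix
  off <- row(p) != col(p)
  use <- off & !is.na(p) & p > 0 & is.finite(distances)
  graphics::plot(distances[use], p[use], log = "y",
                 xlab = "shoreline distance (km)",
                 ylab = "connectivity probability", ...)
  fit <- distanceDecay(p, distances)
  xs <- seq(0, max(distances[use]), length.out = 100)
  graphics::lines(xs, fit$a * exp(-fit$b * xs), col = "red", lwd = 2)
  invisible(fit)
}
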