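#' @import methods
NULL

#' Coastal habitat grid
#'
#' A regular lon/lat grid with a land/sea mask and a set of habitat cells:
#' sea cells adjacent to land where larvae can be released and settle.
#' Cells are half-open boxes `[lon, lon + res) x [lat, lat + res)` so any
#' point lies in exactly one cell.
#'
#' @slot lon numeric vector of cell-centre longitudes (degrees, ascending).
#' @slot lat numeric vector of cell-centre latitudes (degrees, ascending).
#' @slot resolution grid spacing in degrees.
#' @slot seaMask logical matrix `[lon, lat]`, `TRUE` for sea.
#' @slot cells data.frame of habitat cells: `cell_id`, `lon`, `lat`
#'   (centroids), `i`, `j` (grid indices).
#'
#' @exportClass HabitatGrid
setClass("HabitatGrid",
  representation(
    lon = "numeric",
    lat = "numeric",
    resolution = "numeric",
    seaMask = "matrix",
    cells = "data.frame"
  )
)

setValidity("HabitatGrid", function(object) {
  msg <- character()
  if (length(object@resolution) != 1L || object@resolution <= 0)
    msg <- c(msg, "resolution must be a single positive number")
  if (!is.logical(object@seaMask))
    msg <- c(msg, "seaMask must be a logical matrix")
  if (nrow(object@seaMask) != length(object@lon) ||
      ncol(object@seaMask) != length(object@lat))
    msg <- c(msg, "seaMask dimensions must match lon/lat")
  cl <- object@cells
  need <- c("cell_id", "lon", "lat", "i", "j")
  if (!all(need %in% names(cl))) {
    msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(cl) > 0) {
    onSea <- object@seaMask[cbind(cl$i, cl$j)]
    if (!all(onSea)) msg <- c(msg, "habitat cells must lie on sea cells")
    if (anyDuplicated(cl$cell_id)) msg <- c(msg, "cell ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Daily two-layer ocean velocity field series
#'
#' Gridded horizontal velocities (m/s) at two depth layers (surface, 0 m;
#' deep, 10 m), one snapshot per day, with a land/sea mask. Velocities are
#' zero on land cells.
#'
#' @slot u,v numeric arrays `[lon, lat, layer, time]` in m/s.
#' @slot lon,lat cell-centre coordinates (degrees).
#' @slot layers numeric depths in metres, e.g. `c(0, 10)`.
#' @slot times numeric day offsets (days since the series origin; snapshot
#'   `k` is valid at `times[k]`, with linear interpolation in between and
#'   clamping outside the span).
#' @slot seaMask logical matrix `[lon, lat]`, `TRUE` for sea.
#'
#' @exportClass VelocityFieldSeries
setClass("VelocityFieldSeries",
  representation(
    u = "array",
    v = "array",
    lon = "numeric",
    lat = "numeric",
    layers = "numeric",
    times = "numeric",
    seaMask = "matrix"
  )
)

setValidity("VelocityFieldSeries", function(object) {
  msg <- character()
  du <- dim(object@u)
  if (length(du) != 4L) msg <- c(msg, "u must be a 4-d array [lon, lat, layer, time]")
  if (!identical(dim(object@u), dim(object@v)))
    msg <- c(msg, "u and v must have identical dimensions")
  if (length(du) == 4L) {
    if (du[1] != length(object@lon) || du[2] != length(object@lat))
      msg <- c(msg, "first two dims must match lon/lat")
    if (du[3] != length(object@layers)) msg <- c(msg, "layer dim mismatch")
    if (du[4] != length(object@times)) msg <- c(msg, "time dim mismatch")
    land <- which(!object@seaMask, arr.ind = TRUE)
    if (nrow(land) > 0 && du[4] > 0) {
      # check first snapshot only (cheap proxy; generators zero all)
      uu <- object@u[, , 1, 1]
      if (any(abs(uu[land]) > 0)) msg <- c(msg, "velocities must be zero on land")
    }
  }
  if (is.unsorted(object@times)) msg <- c(msg, "times must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Cell-by-cell connectivity matrix
#'
#' Paired transport probabilities between habitat cells: entry `(i, j)` is
#' the mean, over particles released from cell `i`, of the fraction of the
#' maximum simulated time steps (PLD days x steps per day) that a particle
#' spends in cell `j`. The diagonal measures retention.
#'
#' @slot probabilities numeric matrix, rows = release cells, cols =
#'   destination cells, entries in `[0, 1]`.
#' @slot year character label ("averaged" for multi-year means).
#' @slot behavior character, one of surface/deep/migration (or "mixed").
#' @slot denominator character, `"all_released"` or `"excluding_lost"`.
#'
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(
    probabilities = "matrix",
    year = "character",
    behavior = "character",
    denominator = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  p <- object@probabilities
  if (nrow(p) != ncol(p)) msg <- c(msg, "probability matrix must be square")
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!object@denominator %in% c("all_released", "excluding_lost"))
    msg <- c(msg, "denominator must be 'all_released' or 'excluding_lost'")
  if (length(msg)) msg else TRUE
})

#' Diploid multilocus genotype table
#'
#' Microsatellite-style codominant genotypes: two integer allele codes per
#' individual and locus, `NA` for missing, with population / year labels.
#'
#' @slot allele1,allele2 integer matrices (individuals x loci); allele codes
#'   are positive integers, `NA` = missing.
#' @slot ind data.frame with one row per individual: `id`, `pop`, `year`.
#' @slot loci character vector of locus names.
#'
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(
    allele1 = "matrix",
    allele2 = "matrix",
    ind = "data.frame",
    loci = "character"
  )
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (!identical(dim(object@allele1), dim(object@allele2)))
    msg <- c(msg, "allele matrices must have identical dimensions")
  if (ncol(object@allele1) != length(object@loci))
    msg <- c(msg, "number of loci must match allele matrix columns")
  if (nrow(object@allele1) != nrow(object@ind))
    msg <- c(msg, "ind table must have one row per individual")
  if (!all(c("id", "pop") %in% names(object@ind)))
    msg <- c(msg, "ind must have columns id and pop")
  a <- c(object@allele1, object@allele2)
  if (any(a[!is.na(a)] < 1)) msg <- c(msg, "allele codes must be positive integers")
  # an allele pair must be jointly observed or jointly missing
  if (any(xor(is.na(object@allele1), is.na(object@allele2))))
    msg <- c(msg, "half-missing genotypes are not allowed (diploid table)")
  if (length(msg)) msg else TRUE
})
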