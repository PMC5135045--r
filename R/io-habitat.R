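# Habitat grid exchange: GeoJSON cell polygons and a flat CSV.

#' Write habitat cells as GeoJSON polygons
#'
#' Each habitat cell becomes a Polygon feature (its grid-cell bounding
#' box) with a `cell_id` property.
#'
#' @param habitat a [HabitatGrid-class].
#' @param path output file path.
#' @return `path`, invisibly
#' @export
writeHabitatGeojson <- function(habitat, path) {
  res <- habitat@resolution
  cl <- habitat@cells
  features <- lapply(seq_len(nrow(cl)), function(k) {
    x0 <- cl$lon[k] - res / 2; x1 <- cl$lon[k] + res / 2
    y0 <- cl$lat[k] - res / 2; y1 <- cl$lat[k] + res / 2
    ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    list(type = "Feature",
         properties = list(cell_id = cl$cell_id[k],
                           lon = cl$lon[k], lat = cl$lat[k]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(resolution = res,
                               lonRange = range(habitat@lon) +
                                 c(-res, res) / 2,
                               latRange = range(habitat@lat) +
                                 c(-res, res) / 2),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read habitat cells as flat CSV
#'
#' Columns `cell_id`, `lon`, `lat`, `i`, `j`.
#'
#' @param habitat a [HabitatGrid-class].
#' @param path file path.
#' @return `path` (write) / data.frame (read)
#' @export
writeHabitatCsv <- function(habitat, path) {
  utils::write.csv(habitat@cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHabitatCsv
#' @export
readHabitatCsv <- function(path) {
  utils::read.csv(path)
}

#' Write particle records to CSV
#'
#' One row per particle: natal cell, release time, fate, settlement cell
#' and age, and the number of recorded steps. Trajectory paths are not
#' included (use the in-memory object for step-count analyses).
#'
#' @param records a `ParticleRecords` object.
#' @param path output file path.
#' @return `path`, invisibly
#' @export
writeParticleCsv <- function(records, path) {
  utils::write.csv(records$table, path, row.names = FALSE)
  invisible(path)
}

#' Write a connectivity matrix to CSV
#'
#' Header row/column are habitat cell ids; a comment-free plain matrix
#' layout readable by any tool.
#'
#' @param matrix a [ConnectivityMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly
#' @export
writeConnectivityCsv <- function(matrix, path) {
  utils::write.csv(connProbabilities(matrix), path, row.names = TRUE)
  invisible(path)
}
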