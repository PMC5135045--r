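# NetCDF exchange of velocity field series (dimensions lon, lat, layer,
# time; variables u, v in m/s; land stored as the fill value).

#' Write a velocity field series to NetCDF
#'
#' @param fields a [VelocityFieldSeries-class].
#' @param path output file path.
#' @return `path`, invisibly
#' @export
writeVelocityNetcdf <- function(fields, path) {
  dimLon <- ncdf4::ncdim_def("lon", "degrees_east", fields@lon)
  dimLat <- ncdf4::ncdim_def("lat", "degrees_north", fields@lat)
  dimLay <- ncdf4::ncdim_def("layer", "meters", fields@layers)
  dimT <- ncdf4::ncdim_def("time", "days", fields@times, unlim = TRUE)
  fill <- 9.969209968386869e36
  varU <- ncdf4::ncvar_def("u", "m s-1", list(dimLon, dimLat, dimLay, dimT),
                           missval = fill, prec = "double")
  varV <- ncdf4::ncvar_def("v", "m s-1", list(dimLon, dimLat, dimLay, dimT),
                           missval = fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(varU, varV))
  on.exit(ncdf4::nc_close(nc))
  u <- fields@u; v <- fields@v
  land <- !fields@seaMask
  if (any(land)) {
    for (l in seq_along(fields@layers)) for (k in seq_along(fields@times)) {
      ul <- u[, , l, k]; ul[land] <- fill; u[, , l, k] <- ul
      vl <- v[, , l, k]; vl[land] <- fill; v[, , l, k] <- vl
    }
  }
  ncdf4::ncvar_put(nc, varU, u)
  ncdf4::ncvar_put(nc, varV, v)
  invisible(path)
}

#' Read a velocity field series from NetCDF
#'
#' Expects dimensions `lon`, `lat`, `layer`, `time` and variables `u`, `v`
#' in m/s; the land mask is derived from the fill value and land
#' velocities are set to zero.
#'
#' @param path NetCDF file path.
#' @return a [VelocityFieldSeries-class]
#' @export
readVelocityNetcdf <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (v in c("u", "v")) {
    if (!v %in% names(nc$var))
      stop("format error: variable '", v, "' missing from ", path)
  }
  for (d in c("lon", "lat", "layer", "time")) {
    if (!d %in% names(nc$dim))
      stop("format error: dimension '", d, "' missing from ", path)
  }
  lon <- nc$dim$lon$vals; lat <- nc$dim$lat$vals
  layers <- nc$dim$layer$vals; times <- nc$dim$time$vals
  u <- ncdf4::ncvar_get(nc, "u", collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, "v", collapse_degen = FALSE)
  dim(u) <- c(length(lon), length(lat), length(layers), length(times))
  dim(v) <- dim(u)
  landNA <- is.na(u[, , 1, 1])
  sea <- !landNA
  u[is.na(u)] <- 0; v[is.na(v)] <- 0
  new("VelocityFieldSeries", u = u, v = v, lon = as.numeric(lon),
      lat = as.numeric(lat), layers = as.numeric(layers),
      times = as.numeric(times), seaMask = sea)
}
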