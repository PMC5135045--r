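# Shared helpers: grid indexing, geodesy constants, seed streams.

# metres per degree of latitude (spherical mean); per degree of longitude
# this is scaled by cos(latitude) at the point of interest.
M_PER_DEG_LAT <- 111194.9

mPerDegLon <- function(lat) M_PER_DEG_LAT * cos(lat * pi / 180)

# Map points to grid cell indices under the half-open convention
# [edge, edge + res). Points outside the grid get NA.
cellIndex <- function(lon, lat, gridLon, gridLat, res) {
  lon0 <- gridLon[1] - res / 2
  lat0 <- gridLat[1] - res / 2
  i <- floor((lon - lon0) / res) + 1L
  j <- floor((lat - lat0) / res) + 1L
  i[i < 1L | i > length(gridLon)] <- NA_integer_
  j[j < 1L | j > length(gridLat)] <- NA_integer_
  list(i = i, j = j)
}

# Habitat cell id at point positions (0 = not in any habitat cell,
# NA = outside grid). `habLookup` is an integer matrix [lon, lat] with the
# habitat cell id or 0.
habitatCellAt <- function(lon, lat, habitat, habLookup) {
  ij <- cellIndex(lon, lat, habitat@lon, habitat@lat, habitat@resolution)
  out <- rep(NA_integer_, length(lon))
  ok <- !is.na(ij$i) & !is.na(ij$j)
  out[ok] <- habLookup[cbind(ij$i[ok], ij$j[ok])]
  out
}

# Integer lookup matrix: habitat cell id per grid cell, 0 elsewhere.
habitatLookup <- function(habitat) {
  lk <- matrix(0L, length(habitat@lon), length(habitat@lat))
  cl <- habitat@cells
  lk[cbind(cl$i, cl$j)] <- cl$cell_id
  lk
}

# Independent RNG substreams derived from one master seed, so that toggling
# one pipeline stage never perturbs another stage's draws. Offsets are
# arbitrary fixed constants kept below 2^31 - max(offset).
stageSeed <- function(seed, stage) {
  offs <- c(ocean = 101L, genotypes = 211L, families = 307L,
            simulate = 401L, popgen = 503L, assignment = 601L,
            parentage = 701L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 2100000000L) + offs[[stage]]
}

# Evaluate an expression under a local RNG state (restores the caller's).
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
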