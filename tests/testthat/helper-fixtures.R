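# Shared fixtures: analytic velocity fields, small domains, toy genotype
# tables. Everything is built in code at test time.

# A velocity series evaluated from analytic functions u(lon, lat, t),
# v(lon, lat, t) in m/s on an all-sea grid (both layers identical unless
# layer-specific functions are given).
analyticFields <- function(ufun, vfun, lonRange = c(-0.1, 0.1),
                           latRange = c(-0.1, 0.1), res = 0.01,
                           times = 0:2, ufunDeep = ufun, vfunDeep = vfun) {
  lon <- seq(lonRange[1], lonRange[2], by = res)
  lat <- seq(latRange[1], latRange[2], by = res)
  nx <- length(lon); ny <- length(lat); nt <- length(times)
  u <- array(0, c(nx, ny, 2, nt)); v <- array(0, c(nx, ny, 2, nt))
  X <- matrix(lon, nx, ny); Y <- matrix(lat, nx, ny, byrow = TRUE)
  for (k in seq_len(nt)) {
    u[, , 1, k] <- ufun(X, Y, times[k]) + 0 * X
    v[, , 1, k] <- vfun(X, Y, times[k]) + 0 * X
    u[, , 2, k] <- ufunDeep(X, Y, times[k]) + 0 * X
    v[, , 2, k] <- vfunDeep(X, Y, times[k]) + 0 * X
  }
  new("VelocityFieldSeries", u = u, v = v, lon = lon, lat = lat,
      layers = c(0, 10), times = as.numeric(times),
      seaMask = matrix(TRUE, nx, ny))
}

# solid-body rotation about (0, 0): dlon/dt = -Om*lat, dlat/dt = Om*lon
# in degrees/day, encoded as m/s so the integrator's unit conversion is
# exercised; period = 1 day for Om = 2*pi
rotationFields <- function(Om = 2 * pi) {
  analyticFields(
    ufun = function(x, y, t) -Om * y * 111194.9 * cos(y * pi / 180) / 86400,
    vfun = function(x, y, t) Om * x * 111194.9 / 86400)
}

# a small meridional-coast domain with nCoast habitat cells (rows beyond
# nCoast are padded as habitat gaps to satisfy the 10 x 10 grid minimum)
coastDomain <- function(nCoast = 20, res = 0.05, gaps = integer(0)) {
  rows <- max(nCoast, 10)
  if (rows > nCoast) gaps <- union(gaps, (nCoast + 1):rows)
  makeDomain(domainSpec(lonRange = c(-10.5, -10.5 + 12 * res),
                        latRange = c(38, 38 + rows * res),
                        resolution = res, habitatGaps = gaps))
}

# uniform-flow series on a coast domain (m/s), zero on land
uniformCoastFields <- function(habitat, u0 = 0, v0 = 0, nDays = 40) {
  nx <- length(habitat@lon); ny <- length(habitat@lat)
  u <- array(u0, c(nx, ny, 2, nDays)); v <- array(v0, c(nx, ny, 2, nDays))
  land <- which(!habitat@seaMask, arr.ind = TRUE)
  for (l in 1:2) for (k in seq_len(nDays)) {
    ul <- u[, , l, k]; ul[land] <- 0; u[, , l, k] <- ul
    vl <- v[, , l, k]; vl[land] <- 0; v[, , l, k] <- vl
  }
  new("VelocityFieldSeries", u = u, v = v, lon = habitat@lon,
      lat = habitat@lat, layers = c(0, 10),
      times = as.numeric(seq_len(nDays) - 1), seaMask = habitat@seaMask)
}

# the hand-worksheet toy table: pop A = {(1,1), (1,2)}, pop B = {(2,2),
# (2,2)}; Weir-Cockerham components a = 0.5, b = 0, c = 0.25 so
# theta = 2/3; Nei-Chesser Hs = 0.25, Ht = 0.5 so Jost D = 2/3
toyTwoPops <- function() {
  genotypeTable(matrix(c(1, 1, 2, 2)), matrix(c(1, 2, 2, 2)),
                pop = c("A", "A", "B", "B"))
}

# two populations fixed for different alleles
fixedTwoPops <- function(n = 10) {
  genotypeTable(matrix(rep(c(1, 2), each = n), ncol = 1),
                matrix(rep(c(1, 2), each = n), ncol = 1),
                pop = rep(c("A", "B"), each = n))
}

# a diverse candidate-parent pool: one panmictic population with
# microsatellite-like allele numbers (for parentage fixtures)
diverseParents <- function(n = 100, nLoci = 12, seed = 5) {
  makeGenotypeDataset(list(popSpec("ARR", n, 1)), nLoci = nLoci,
                      allelesPerLocus = round(seq(9, 41,
                                                  length.out = nLoci)),
                      poolDivergence = 0, seed = seed)$genotypes
}
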