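# Synthetic two-layer daily velocity fields: a coastline-parallel mean flow
# with a seasonal reversal and interannual jitter, plus divergence-free
# mesoscale eddy noise, attenuated in the deeper layer.

#' Specify a synthetic ocean regime
#'
#' Emulates an eastern-boundary shelf circulation with two seasonal
#' phases: an upwelling phase with an alongshore jet that ramps up away
#' from the frictional inner shelf plus surface-trapped offshore Ekman
#' transport, followed (after `seasonReversalDay`) by a weaker
#' coast-trapped counter-current in the opposite direction with onshore
#' relaxation. Mesoscale eddies are a random divergence-free
#' streamfunction field. In the deep (10 m) layer the mean flow and the
#' eddy kinetic energy are attenuated by `depthAttenuation` and the
#' Ekman component by its square.
#'
#' Mean speeds default to the 0.05--0.2 m/s range typical of temperate
#' shelf currents; no site-specific speeds are assumed.
#'
#' @param meanAlongshore surface mean alongshore speed, m/s (>= 0).
#' @param depthAttenuation factor in `[0, 1]` applied to the 10 m layer.
#' @param eddyAmplitude RMS eddy speed at the surface, m/s; the deep layer
#'   receives an independent eddy realization scaled by `depthAttenuation`.
#' @param eddyLengthKm eddy length scale in km.
#' @param eddyPropKmDay propagation speed of eddy patterns in km/day.
#' @param seasonReversalDay day (within the series year) when the
#'   alongshore flow direction flips sign.
#' @param reversalWidthDays width of the smooth (tanh) reversal; 0 gives an
#'   abrupt flip.
#' @param interannualJitter sd (m/s) of a yearly perturbation of the mean
#'   alongshore speed.
#' @param initialDirection +1 for initially northward flow, -1 southward.
#' @param offshoreSurface mean cross-shore (westward, offshore) surface
#'   speed in m/s during the upwelling phase, emulating surface Ekman
#'   transport; it relaxes weakly onshore after the seasonal reversal and,
#'   being surface-trapped, is attenuated with depth by the square of
#'   `depthAttenuation`.
#' @param jetOffshoreKm offshore e-folding scale over which the upwelling
#'   jet ramps up from the frictional inner shelf to full speed.
#' @param counterFraction strength of the post-reversal inner-shelf
#'   counter-current relative to the upwelling jet.
#' @param coastalTrapKm e-folding width of the coast-trapped
#'   counter-current.
#' @return a list of class `OceanRegime`
#' @export
oceanRegime <- function(meanAlongshore = 0.1, depthAttenuation = 0.5,
                        eddyAmplitude = 0.05, eddyLengthKm = 30,
                        seasonReversalDay = 90, reversalWidthDays = 5,
                        interannualJitter = 0.02, initialDirection = -1,
                        offshoreSurface = 0.02, jetOffshoreKm = 15,
                        counterFraction = 0.6, coastalTrapKm = 10,
                        eddyPropKmDay = 5) {
  stopifnot(meanAlongshore >= 0, eddyAmplitude >= 0,
            depthAttenuation >= 0, depthAttenuation <= 1,
            eddyLengthKm > 0, interannualJitter >= 0,
            initialDirection %in% c(-1, 1), offshoreSurface >= 0,
            jetOffshoreKm > 0, counterFraction >= 0, coastalTrapKm > 0)
  structure(list(meanAlongshore = meanAlongshore,
                 offshoreSurface = offshoreSurface,
                 jetOffshoreKm = jetOffshoreKm,
                 counterFraction = counterFraction,
                 coastalTrapKm = coastalTrapKm,
                 eddyPropKmDay = eddyPropKmDay,
                 depthAttenuation = depthAttenuation,
                 eddyAmplitude = eddyAmplitude,
                 eddyLengthKm = eddyLengthKm,
                 seasonReversalDay = seasonReversalDay,
                 reversalWidthDays = reversalWidthDays,
                 interannualJitter = interannualJitter,
                 initialDirection = initialDirection),
            class = "OceanRegime")
}

# Distance from every cell to the nearest land cell, in km, by a two-pass
# chamfer transform (cell metric; adequate for smooth flow profiles).
.distToLandKm <- function(sea, res, midLat) {
  nx <- nrow(sea); ny <- ncol(sea)
  big <- 1e9
  d <- matrix(ifelse(sea, big, 0), nx, ny)
  step <- c(res * mPerDegLon(midLat), res * M_PER_DEG_LAT) / 1000
  diag <- sqrt(sum(step^2))
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i > 1) d[i, j] <- min(d[i, j], d[i - 1, j] + step[1])
    if (j > 1) d[i, j] <- min(d[i, j], d[i, j - 1] + step[2])
    if (i > 1 && j > 1) d[i, j] <- min(d[i, j], d[i - 1, j - 1] + diag)
    if (i < nx && j > 1) d[i, j] <- min(d[i, j], d[i + 1, j - 1] + diag)
  }
  for (j in rev(seq_len(ny))) for (i in rev(seq_len(nx))) {
    if (i < nx) d[i, j] <- min(d[i, j], d[i + 1, j] + step[1])
    if (j < ny) d[i, j] <- min(d[i, j], d[i, j + 1] + step[2])
    if (i < nx && j < ny) d[i, j] <- min(d[i, j], d[i + 1, j + 1] + diag)
    if (i > 1 && j < ny) d[i, j] <- min(d[i, j], d[i - 1, j + 1] + diag)
  }
  d
}

# One divergence-free eddy snapshot on (xKm, yKm) grids from a sum of
# random plane-wave streamfunction modes; returns u, v with RMS speed 1
# over sea (before scaling). Modes evolve smoothly day to day through
# phase rotation, handled by the caller.
.eddyField <- function(xKm, yKm, modes, phase) {
  nx <- length(xKm); ny <- length(yKm)
  u <- matrix(0, nx, ny); v <- matrix(0, nx, ny)
  X <- matrix(xKm, nx, ny); Y <- matrix(yKm, nx, ny, byrow = TRUE)
  for (m in seq_len(nrow(modes))) {
    kx <- modes$kx[m]; ky <- modes$ky[m]
    arg <- 2 * pi * (kx * X + ky * Y) + phase[m]
    # u = -dpsi/dy, v = dpsi/dx for psi = A sin(arg)
    u <- u - modes$amp[m] * 2 * pi * ky * cos(arg)
    v <- v + modes$amp[m] * 2 * pi * kx * cos(arg)
  }
  list(u = u, v = v)
}

#' Generate a daily two-layer velocity field series
#'
#' One (u, v) snapshot per day per layer on the habitat grid. The deep
#' layer is the surface mean flow scaled by `depthAttenuation` plus an
#' independent eddy realization (also attenuated). Velocities are zero on
#' land. Deterministic given `seed`.
#'
#' @param habitat a [HabitatGrid-class] from [makeDomain()].
#' @param regime an `OceanRegime` from [oceanRegime()].
#' @param years number of years to generate.
#' @param daysPerYear days per year (must cover the spawning season plus
#'   the larval duration of any simulation run on the series).
#' @param seed integer seed.
#' @return a [VelocityFieldSeries-class]
#' @export
makeVelocitySeries <- function(habitat, regime, years = 1, daysPerYear = 80,
                               seed = 1) {
  stopifnot(inherits(regime, "OceanRegime"), years >= 1, daysPerYear >= 1)
  withSeed(seed, {
    lon <- habitat@lon; lat <- habitat@lat
    nLon <- length(lon); nLat <- length(lat)
    sea <- habitat@seaMask
    land <- !sea
    nT <- years * daysPerYear
    u <- array(0, c(nLon, nLat, 2, nT))
    v <- array(0, c(nLon, nLat, 2, nT))
    # local planar coordinates in km for the eddy streamfunction
    midLat <- mean(lat)
    xKm <- (lon - lon[1]) * mPerDegLon(midLat) / 1000
    yKm <- (lat - lat[1]) * M_PER_DEG_LAT / 1000
    nModes <- 6L
    distKm <- .distToLandKm(sea, habitat@resolution, midLat)
    # spatial structure of the two seasonal phases
    fJet <- distKm^2 / (distKm^2 + regime$jetOffshoreKm^2)
    fCoast <- exp(-distKm / regime$coastalTrapKm)
    for (y in seq_len(years)) {
      yearMean <- regime$meanAlongshore +
        stats::rnorm(1, 0, regime$interannualJitter)
      yearMean <- max(yearMean, 0)
      # independent eddy mode sets per layer, phases drift over the year
      modes <- lapply(1:2, function(l) {
        ang <- stats::runif(nModes, 0, 2 * pi)
        kmag <- (1 / regime$eddyLengthKm) * stats::runif(nModes, 0.7, 1.3)
        data.frame(kx = kmag * cos(ang), ky = kmag * sin(ang),
                   amp = stats::rexp(nModes, 1))
      })
      phase0 <- lapply(1:2, function(l) stats::runif(nModes, 0, 2 * pi))
      # modes propagate at mesoscale drift speeds (a few km/day) so eddy
      # patterns translate rather than stand still and trap particles
      omega <- lapply(1:2, function(l) {
        ang <- stats::runif(nModes, 0, 2 * pi)
        cx <- regime$eddyPropKmDay * cos(ang)
        cy <- regime$eddyPropKmDay * sin(ang)
        -2 * pi * (modes[[l]]$kx * cx + modes[[l]]$ky * cy)
      })
      eddyAmp <- c(regime$eddyAmplitude,
                   regime$eddyAmplitude * regime$depthAttenuation)
      meanAmp <- c(yearMean, yearMean * regime$depthAttenuation)
      for (d in seq_len(daysPerYear)) {
        tIdx <- (y - 1) * daysPerYear + d
        if (regime$reversalWidthDays > 0) {
          phase <- tanh((regime$seasonReversalDay - d) /
                          regime$reversalWidthDays)
        } else {
          phase <- ifelse(d < regime$seasonReversalDay, 1, -1)
        }
        # weight of the upwelling phase in [0, 1]
        w <- (1 + phase) / 2
        for (l in 1:2) {
          # alongshore: upwelling jet (offshore-intensified) in the
          # initial direction, then a weaker coast-trapped counter-current
          vl <- meanAmp[l] * regime$initialDirection *
            (w * fJet - (1 - w) * regime$counterFraction * fCoast)
          # cross-shore: offshore (westward; land lies east) surface Ekman
          # transport while upwelling, weak onshore relaxation after
          ekman <- regime$offshoreSurface *
            (if (l == 1) 1 else regime$depthAttenuation^2)
          ul <- matrix(-ekman * ifelse(phase > 0, phase, 0.3 * phase),
                       nLon, nLat)
          if (eddyAmp[l] > 0) {
            e <- .eddyField(xKm, yKm, modes[[l]],
                            phase0[[l]] + omega[[l]] * d)
            rms <- sqrt(mean(e$u[sea]^2 + e$v[sea]^2))
            if (rms > 0) {
              ul <- ul + e$u * (eddyAmp[l] / rms)
              vl <- vl + e$v * (eddyAmp[l] / rms)
            }
          }
          ul[land] <- 0; vl[land] <- 0
          u[, , l, tIdx] <- ul
          v[, , l, tIdx] <- vl
        }
      }
    }
    new("VelocityFieldSeries", u = u, v = v, lon = lon, lat = lat,
        layers = c(0, 10), times = seq_len(nT) - 1, seaMask = sea)
  })
}
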