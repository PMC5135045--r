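# Individual-based Lagrangian advection of larval particles: masked
# bilinear interpolation of daily velocity snapshots, classical 4th-order
# Runge-Kutta stepping with CFL-limited substeps inside hourly macro-steps,
# behaviour-dependent depth-layer choice, and competence/settlement rules.

#' Simulation parameters
#'
#' @param pldMax maximum pelagic larval duration in days (default 18).
#' @param competenceDay age (days) from which settlement is possible
#'   (default 10; the age-10.0 boundary already counts as competent).
#' @param stepsPerDay recorded positions per day (default 24, hourly).
#' @param releaseIntervalHours hours between releases; must divide 24
#'   (default 6).
#' @param seasonStartDay first spawning day within each simulated year
#'   (1-based).
#' @param seasonLengthDays length of the spawning season (default 180,
#'   six 30-day months).
#' @param years number of years simulated.
#' @param behavior `"surface"` (0 m throughout), `"deep"` (10 m
#'   throughout) or `"migration"` (0 m before `competenceDay`, 10 m from
#'   then on).
#' @param cflFraction maximum per-substep displacement as a fraction of
#'   the grid cell size, in `(0, 1]`; controls adaptive substepping.
#' @return a list of class `SimulationParams`
#' @export
simParams <- function(pldMax = 18, competenceDay = 10, stepsPerDay = 24,
                      releaseIntervalHours = 6, seasonStartDay = 1,
                      seasonLengthDays = 180, years = 1,
                      behavior = c("surface", "deep", "migration"),
                      cflFraction = 0.5) {
  behavior <- match.arg(behavior)
  stopifnot(competenceDay > 0, competenceDay <= pldMax, stepsPerDay >= 1,
            24 %% releaseIntervalHours == 0, seasonLengthDays >= 1,
            years >= 1, cflFraction > 0, cflFraction <= 1)
  structure(list(pldMax = pldMax, competenceDay = competenceDay,
                 stepsPerDay = as.integer(stepsPerDay),
                 releaseIntervalHours = as.integer(releaseIntervalHours),
                 seasonStartDay = as.integer(seasonStartDay),
                 seasonLengthDays = as.integer(seasonLengthDays),
                 years = as.integer(years), behavior = behavior,
                 cflFraction = cflFraction),
            class = "SimulationParams")
}

# Vectorized masked space-time interpolation. Returns m/s velocities and an
# in-domain flag. Positions outside the grid's outer cell edges are flagged
# (velocities are still evaluated with clamped coordinates so that RK4
# stage points just beyond the edge remain usable).
.velocityAt <- function(fields, lon, lat, time, layer) {
  gl <- fields@lon; ga <- fields@lat
  res <- gl[2] - gl[1]
  nLon <- length(gl); nLat <- length(ga)
  nT <- length(fields@times)
  inDom <- lon >= gl[1] - res / 2 & lon < gl[nLon] + res / 2 &
    lat >= ga[1] - res / 2 & lat < ga[nLat] + res / 2
  fx <- pmin(pmax((lon - gl[1]) / res + 1, 1), nLon)
  fy <- pmin(pmax((lat - ga[1]) / res + 1, 1), nLat)
  i0 <- pmin(floor(fx), max(nLon - 1, 1)); wx <- fx - i0
  j0 <- pmin(floor(fy), max(nLat - 1, 1)); wy <- fy - j0
  tt <- pmin(pmax(time - fields@times[1], 0), max(nT - 1, 0))
  k0 <- pmin(floor(tt) + 1, max(nT - 1, 1)); wt <- pmin(tt - (k0 - 1), 1)
  k1 <- pmin(k0 + 1, nT)
  planeN <- nLon * nLat
  offL <- (layer - 1) * planeN
  off0 <- (k0 - 1) * planeN * length(fields@layers) + offL
  off1 <- (k1 - 1) * planeN * length(fields@layers) + offL
  uacc <- vacc <- wsum <- numeric(length(lon))
  sea <- fields@seaMask
  for (di in 0:1) for (dj in 0:1) {
    ii <- pmin(i0 + di, nLon); jj <- pmin(j0 + dj, nLat)
    w <- (if (di == 0) 1 - wx else wx) * (if (dj == 0) 1 - wy else wy)
    m <- sea[cbind(ii, jj)]
    wm <- w * m
    cellIdx <- ii + (jj - 1) * nLon
    u0 <- fields@u[cellIdx + off0]; u1 <- fields@u[cellIdx + off1]
    v0 <- fields@v[cellIdx + off0]; v1 <- fields@v[cellIdx + off1]
    uacc <- uacc + wm * ((1 - wt) * u0 + wt * u1)
    vacc <- vacc + wm * ((1 - wt) * v0 + wt * v1)
    wsum <- wsum + wm
  }
  ok <- wsum > 0
  u <- ifelse(ok, uacc / ifelse(ok, wsum, 1), 0)
  v <- ifelse(ok, vacc / ifelse(ok, wsum, 1), 0)
  list(u = u, v = v, inDomain = inDom)
}

#' Interpolate the velocity field at arbitrary points
#'
#' Bilinear interpolation in space over the four surrounding grid nodes
#' (land nodes contribute zero velocity, with weights renormalized over
#' sea nodes only) and linear interpolation in time between the two
#' bracketing daily snapshots (clamped outside the series span).
#'
#' @param fields a [VelocityFieldSeries-class].
#' @param lon,lat query positions in degrees (vectorized).
#' @param time query time in days since the series origin.
#' @param layer layer index (1 = surface, 2 = deep), recycled.
#' @return list with `u`, `v` (m/s) and logical `inDomain`; querying a
#'   point outside the grid returns `inDomain = FALSE` (callers mark such
#'   particles lost).
#' @export
interpolateVelocity <- function(fields, lon, lat, time, layer = 1) {
  n <- max(length(lon), length(lat))
  .velocityAt(fields, rep_len(lon, n), rep_len(lat, n),
              rep_len(time, n), rep_len(layer, n))
}

# m/s -> degrees/day at given latitudes
.degPerDay <- function(u, v, lat) {
  list(du = u * 86400 / mPerDegLon(lat),
       dv = v * 86400 / M_PER_DEG_LAT)
}

#' One classical fourth-order Runge-Kutta step
#'
#' Integrates the path equation dx/dt = v(x, t) over `dt` days with the
#' four RK4 stage velocities taken from [interpolateVelocity()], converting
#' m/s to degrees at each stage latitude.
#'
#' @param fields a [VelocityFieldSeries-class].
#' @param lon,lat start positions (degrees, vectorized).
#' @param time start time (days).
#' @param dt step length in days (> 0).
#' @param layer layer index per particle.
#' @return list with `lon`, `lat` (end positions) and logical `inDomain`
#'   (`FALSE` if any stage left the grid).
#' @export
rk4Step <- function(fields, lon, lat, time, dt, layer = 1) {
  stopifnot(dt > 0)
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  layer <- rep_len(layer, n)
  stage <- function(lo, la, tt) {
    vv <- .velocityAt(fields, lo, la, tt, layer)
    d <- .degPerDay(vv$u, vv$v, la)
    list(du = d$du, dv = d$dv, inDomain = vv$inDomain)
  }
  k1 <- stage(lon, lat, time)
  k2 <- stage(lon + dt / 2 * k1$du, lat + dt / 2 * k1$dv, time + dt / 2)
  k3 <- stage(lon + dt / 2 * k2$du, lat + dt / 2 * k2$dv, time + dt / 2)
  k4 <- stage(lon + dt * k3$du, lat + dt * k3$dv, time + dt)
  list(lon = lon + dt / 6 * (k1$du + 2 * k2$du + 2 * k3$du + k4$du),
       lat = lat + dt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv),
       inDomain = k1$inDomain & k2$inDomain & k3$inDomain & k4$inDomain)
}

#' Advance positions by one recording macro-step with adaptive substeps
#'
#' Chains [rk4Step()] substeps whose length is chosen so the estimated
#' displacement per substep does not exceed `cflFraction` times the grid
#' cell size; only the macro-step endpoint is recorded. A substep endpoint
#' falling on a land cell is rejected and the particle holds its position
#' for that substep (no-flux coastline).
#'
#' @param fields a [VelocityFieldSeries-class].
#' @param lon,lat start positions (vectorized).
#' @param time start time (days).
#' @param layer layer index per particle.
#' @param cflFraction CFL fraction in `(0, 1]`.
#' @param stepDays macro-step length in days (default one hour, 1/24).
#' @return list with `lon`, `lat`, `inDomain` and `nSub` (substeps taken).
#' @export
advectHour <- function(fields, lon, lat, time, layer = 1,
                       cflFraction = 0.5, stepDays = 1 / 24) {
  stopifnot(cflFraction > 0, cflFraction <= 1)
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  layer <- rep_len(layer, n)
  res <- fields@lon[2] - fields@lon[1]
  v0 <- .velocityAt(fields, lon, lat, time, layer)
  d0 <- .degPerDay(v0$u, v0$v, lat)
  dispDeg <- sqrt(d0$du^2 + d0$dv^2) * stepDays
  nSub <- pmax(1L, ceiling(dispDeg / (cflFraction * res)))
  outLon <- lon; outLat <- lat
  inDom <- rep(TRUE, n)
  sea <- fields@seaMask
  for (ns in sort(unique(nSub))) {
    sel <- which(nSub == ns)
    dt <- stepDays / ns
    lo <- lon[sel]; la <- lat[sel]
    okAll <- rep(TRUE, length(sel))
    isSea <- function(lonQ, latQ) {
      ij <- cellIndex(lonQ, latQ, fields@lon, fields@lat, res)
      ok <- !is.na(ij$i) & !is.na(ij$j)
      ok[ok] <- sea[cbind(ij$i[ok], ij$j[ok])]
      ok
    }
    for (s in seq_len(ns)) {
      st <- rk4Step(fields, lo, la, time + (s - 1) * dt, dt, layer[sel])
      okAll <- okAll & st$inDomain
      # free-slip coastline: a substep that would beach the particle on a
      # land cell keeps only the along-coast component (try each axis in
      # turn); if both directions hit land the particle holds position
      onSea <- isSea(st$lon, st$lat)
      newLo <- ifelse(onSea, st$lon, lo)
      newLa <- ifelse(onSea, st$lat, la)
      beach <- which(!onSea & st$inDomain)
      if (length(beach)) {
        slideLon <- isSea(st$lon[beach], la[beach])
        newLo[beach[slideLon]] <- st$lon[beach[slideLon]]
        rest <- beach[!slideLon]
        if (length(rest)) {
          slideLat <- isSea(lo[rest], st$lat[rest])
          newLa[rest[slideLat]] <- st$lat[rest[slideLat]]
        }
      }
      # particles whose endpoint left the grid keep the exit position so
      # the caller can flag them lost
      left <- !st$inDomain
      newLo[left] <- st$lon[left]; newLa[left] <- st$lat[left]
      lo <- newLo; la <- newLa
    }
    outLon[sel] <- lo; outLat[sel] <- la
    inDom[sel] <- okAll
  }
  list(lon = outLon, lat = outLat, inDomain = inDom, nSub = nSub)
}

#' Depth layer used by a behaviour at a given age
#'
#' Surface behaviour always uses the 0 m layer, deep behaviour always the
#' 10 m layer, and vertical migration uses the surface for ages strictly
#' below `migrationDay` and the deep layer from that day on (the boundary
#' age belongs to the deep layer).
#'
#' @param behavior `"surface"`, `"deep"` or `"migration"`.
#' @param ageDays particle age in days (vectorized).
#' @param migrationDay day of the downward switch (default 10).
#' @return integer layer index: 1 = surface (0 m), 2 = deep (10 m)
#' @export
behaviorLayer <- function(behavior, ageDays, migrationDay = 10) {
  stopifnot(all(ageDays >= 0))
  switch(behavior,
    surface = rep(1L, length(ageDays)),
    deep = rep(2L, length(ageDays)),
    migration = ifelse(ageDays < migrationDay, 1L, 2L),
    stop("unknown behavior: ", behavior))
}

#' Release schedule
#'
#' Particles are released from every habitat cell at fixed intervals
#' (default every 6 hours: 0h, 6h, 12h, 18h) on each day of the spawning
#' season, each simulated year. The number of events per cell is
#' `seasonLengthDays * (24 / releaseIntervalHours) * years`.
#'
#' @param params a `SimulationParams` from [simParams()].
#' @return data.frame with columns `year`, `day` (day within the season,
#'   1-based) and `hour`
#' @export
releaseSchedule <- function(params) {
  hours <- seq(0, 23, by = params$releaseIntervalHours)
  expand.grid(hour = hours, day = seq_len(params$seasonLengthDays),
              year = seq_len(params$years))[, c("year", "day", "hour")]
}

#' Settlement / death rule for one recorded position
#'
#' A particle settles at the first recorded position at which it is both
#' competent (age at least `competenceDay`) and inside a habitat cell;
#' a particle that reaches `pldMax` days without settling is dead;
#' otherwise nothing happens.
#'
#' @param lon,lat particle position.
#' @param ageDays particle age in days.
#' @param habitat a [HabitatGrid-class].
#' @param params a `SimulationParams`.
#' @return list with `status` (`"none"`, `"settled"` or `"dead"`) and
#'   `cell` (habitat cell id or `NA`)
#' @export
checkSettlement <- function(lon, lat, ageDays, habitat, params) {
  stopifnot(ageDays <= params$pldMax)
  cell <- habitatCellAt(lon, lat, habitat, habitatLookup(habitat))
  if (!is.na(cell) && cell > 0 && ageDays >= params$competenceDay)
    return(list(status = "settled", cell = cell))
  if (ageDays >= params$pldMax) return(list(status = "dead", cell = NA))
  list(status = "none", cell = NA)
}

#' Run the dispersal simulation
#'
#' Releases one particle per habitat cell and release event, advects it
#' with hourly recorded positions under the behaviour's depth layer,
#' applies the settlement rule after every recorded position, and marks
#' particles leaving the domain as lost. Deterministic given `seed`
#' (randomness enters only through optional sub-grid release jitter).
#'
#' @param fields a [VelocityFieldSeries-class] spanning the simulated
#'   season(s) plus `pldMax` days.
#' @param habitat a [HabitatGrid-class] on the same grid.
#' @param params a `SimulationParams`.
#' @param seed integer seed (used only when `releaseJitter = TRUE`).
#' @param releaseJitter if `TRUE`, release positions are drawn uniformly
#'   within the natal cell instead of at its centroid.
#' @param cells optional subset of habitat cell ids to release from.
#' @return an object of class `ParticleRecords`: a list with `table`
#'   (one row per particle: natal cell, release time, fate, settlement
#'   cell/age, steps recorded), `paths` (integer matrix, habitat cell id
#'   occupied at each recorded step, 0 = open water, `NA` = after
#'   termination), and the run `params`.
#' @export
simulateDispersal <- function(fields, habitat, params, seed = 1,
                              releaseJitter = FALSE, cells = NULL) {
  if (!identical(dim(fields@seaMask), dim(habitat@seaMask)))
    stop("velocity fields and habitat are on different grids")
  res <- habitat@resolution
  dpy <- length(fields@times) / params$years
  if (dpy != floor(dpy))
    stop("field series length must be a multiple of the number of years")
  need <- params$seasonStartDay - 1 + params$seasonLengthDays + params$pldMax
  if (dpy < need)
    stop("field series too short: each year needs at least ", need, " days")
  habCells <- habitat@cells
  if (!is.null(cells)) habCells <- habCells[habCells$cell_id %in% cells, ]
  if (nrow(habCells) == 0) stop("no release cells")
  lk <- habitatLookup(habitat)
  sched <- releaseSchedule(params)
  nEv <- nrow(sched); nC <- nrow(habCells)
  nPart <- nEv * nC
  maxSteps <- params$pldMax * params$stepsPerDay
  # particle state
  natal <- rep(habCells$cell_id, times = nEv)
  relLon <- rep(habCells$lon, times = nEv)
  relLat <- rep(habCells$lat, times = nEv)
  relYear <- rep(sched$year, each = nC)
  relDay <- rep(sched$day, each = nC)
  relHour <- rep(sched$hour, each = nC)
  if (releaseJitter) {
    withSeed(seed, {
      relLon <- relLon + (stats::runif(nPart) - 0.5) * res
      relLat <- relLat + (stats::runif(nPart) - 0.5) * res
    })
  }
  t0 <- (relYear - 1) * dpy + (params$seasonStartDay - 1) +
    (relDay - 1) + relHour / 24
  status <- rep(0L, nPart) # 0 unreleased/active, 1 settled, 2 dead, 3 lost
  lon <- relLon; lat <- relLat
  ageSteps <- rep(0L, nPart)
  settleCell <- rep(NA_integer_, nPart)
  settleAge <- rep(NA_real_, nPart)
  paths <- matrix(NA_integer_, nPart, maxSteps)
  stepDays <- 1 / params$stepsPerDay
  # march a global clock in macro-steps; particles are active from their
  # release tick until a terminal status
  tickOf <- as.integer(round(t0 / stepDays))
  active <- rep(FALSE, nPart)
  done <- rep(FALSE, nPart)
  compSteps <- params$competenceDay * params$stepsPerDay
  for (tick in seq(min(tickOf), max(tickOf) + maxSteps - 1)) {
    active[tickOf == tick] <- TRUE
    idx <- which(active)
    if (length(idx) == 0) next
    tNow <- tick * stepDays
    age <- ageSteps[idx] * stepDays
    lay <- behaviorLayer(params$behavior, age,
                         migrationDay = params$competenceDay)
    adv <- advectHour(fields, lon[idx], lat[idx], tNow, lay,
                      cflFraction = params$cflFraction,
                      stepDays = stepDays)
    lon[idx] <- adv$lon; lat[idx] <- adv$lat
    ageSteps[idx] <- ageSteps[idx] + 1L
    stepNo <- ageSteps[idx]
    # lost particles: left the grid during this macro-step
    lost <- !adv$inDomain
    if (any(lost)) {
      li <- idx[lost]
      status[li] <- 3L; active[li] <- FALSE; done[li] <- TRUE
    }
    ok <- idx[!lost]
    if (length(ok)) {
      cellHere <- habitatCellAt(lon[ok], lat[ok], habitat, lk)
      cellHere[is.na(cellHere)] <- 0L
      paths[cbind(ok, ageSteps[ok])] <- cellHere
      canSettle <- ageSteps[ok] >= compSteps & cellHere > 0
      if (any(canSettle)) {
        si <- ok[canSettle]
        status[si] <- 1L
        settleCell[si] <- cellHere[canSettle]
        settleAge[si] <- ageSteps[si] * stepDays
        active[si] <- FALSE; done[si] <- TRUE
      }
      expired <- ageSteps[ok] >= maxSteps & status[ok] == 0L
      if (any(expired)) {
        di <- ok[expired]
        status[di] <- 2L; active[di] <- FALSE; done[di] <- TRUE
      }
    }
  }
  tab <- data.frame(
    particle = seq_len(nPart),
    natal_cell = natal,
    year = relYear, release_day = relDay, release_hour = relHour,
    status = c("active", "settled", "dead", "lost")[status + 1L],
    settlement_cell = settleCell,
    settlement_age = settleAge,
    n_steps = ageSteps,
    final_lon = lon, final_lat = lat)
  structure(list(table = tab, paths = paths, params = params,
                 behavior = params$behavior),
            class = "ParticleRecords")
}

#' @export
print.ParticleRecords <- function(x, ...) {
  cat("ParticleRecords:", nrow(x$table), "particles; behavior =",
      x$behavior, "\n")
  print(table(x$table$status))
  invisible(x)
}
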