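# Advection: interpolation, RK4 integration, adaptive substepping,
# behaviour layers, release schedule, settlement rules, full simulation.

test_that("interpolation reproduces constant and linear fields exactly", {
  fC <- analyticFields(function(x, y, t) 0.3, function(x, y, t) -0.1)
  v <- interpolateVelocity(fC, c(0.013, -0.071), c(0.052, 0.049), 0.4)
  expect_equal(v$u, c(0.3, 0.3))
  expect_equal(v$v, c(-0.1, -0.1))
  expect_true(all(v$inDomain))
  # bilinear is exact on fields linear in lon and lat
  fL <- analyticFields(function(x, y, t) 0.2 * x + 0.1 * y,
                       function(x, y, t) -0.3 * x + 0.05 * y)
  pts <- list(lon = c(0.013, -0.042, 0.088), lat = c(-0.037, 0.011, 0.06))
  v <- interpolateVelocity(fL, pts$lon, pts$lat, 1)
  expect_equal(v$u, 0.2 * pts$lon + 0.1 * pts$lat, tolerance = 1e-12)
  expect_equal(v$v, -0.3 * pts$lon + 0.05 * pts$lat, tolerance = 1e-12)
})

test_that("time interpolation blends the bracketing daily snapshots", {
  f <- analyticFields(function(x, y, t) 0.1 * (1 + t),
                      function(x, y, t) 0, times = 0:3)
  v <- interpolateVelocity(f, 0, 0, 1.25)
  expect_equal(v$u, 0.75 * 0.2 + 0.25 * 0.3)
  # clamped outside the span
  expect_equal(interpolateVelocity(f, 0, 0, -5)$u, 0.1)
  expect_equal(interpolateVelocity(f, 0, 0, 99)$u, 0.4)
})

test_that("points outside the grid are flagged out of domain", {
  f <- analyticFields(function(x, y, t) 0, function(x, y, t) 0)
  expect_false(interpolateVelocity(f, 0.5, 0, 1)$inDomain)
  expect_false(interpolateVelocity(f, 0, -0.2, 1)$inDomain)
})

test_that("masked interpolation renormalizes over sea nodes", {
  f <- analyticFields(function(x, y, t) 0.4, function(x, y, t) 0)
  # make the eastern half land; a point near the boundary must still see
  # the full sea velocity, not a value dragged toward zero
  f@seaMask[f@lon > 0.049, ] <- FALSE
  for (l in 1:2) for (k in 1:3) {
    uu <- f@u[, , l, k]; uu[!f@seaMask] <- 0; f@u[, , l, k] <- uu
  }
  v <- interpolateVelocity(f, 0.048, 0, 1)
  expect_equal(v$u, 0.4)
})

test_that("RK4 is stationary in a zero field", {
  f <- analyticFields(function(x, y, t) 0, function(x, y, t) 0)
  st <- rk4Step(f, 0.02, -0.03, 0.5, 0.1)
  expect_equal(st$lon, 0.02)
  expect_equal(st$lat, -0.03)
})

test_that("RK4 closes a solid-body rotation orbit", {
  f <- rotationFields()
  run <- function(n) {
    p <- c(0.02, 0); dt <- 1 / n
    for (s in seq_len(n)) {
      st <- rk4Step(f, p[1], p[2], (s - 1) * dt, dt)
      p <- c(st$lon, st$lat)
    }
    p
  }
  pEnd <- run(1000)
  err <- sqrt(sum((pEnd - c(0.02, 0))^2))
  expect_lt(err, 1e-3 * 0.02)
})

test_that("halving dt reduces the rotation endpoint error about 16-fold", {
  f <- rotationFields()
  endErr <- function(n) {
    p <- c(0.02, 0); dt <- 1 / n
    for (s in seq_len(n)) {
      st <- rk4Step(f, p[1], p[2], (s - 1) * dt, dt)
      p <- c(st$lon, st$lat)
    }
    sqrt(sum((p - c(0.02, 0))^2))
  }
  ratio <- endErr(64) / endErr(128)
  expect_gte(ratio, 12)
  expect_lte(ratio, 20)
})

test_that("slow flow needs a single substep, fast flow refines", {
  # slow: far below one cell per hour
  fS <- analyticFields(function(x, y, t) 0.05, function(x, y, t) 0)
  a <- advectHour(fS, 0, 0, 1, cflFraction = 0.5)
  expect_equal(a$nSub, 1L)
  # fast: 10 cells per hour at cfl 0.5 needs >= 20 substeps and still
  # matches the straight-line displacement
  res <- 0.01
  cellMh <- res * 111194.9 # metres per cell in latitude
  v10 <- 10 * cellMh / 3600
  fF <- analyticFields(function(x, y, t) 0, function(x, y, t) v10,
                       latRange = c(-0.2, 0.2))
  a <- advectHour(fF, 0, -0.15, 1, cflFraction = 0.5)
  expect_gte(a$nSub, 20L)
  expect_equal(a$lat, -0.15 + 10 * res, tolerance = 1e-6)
  expect_equal(a$lon, 0, tolerance = 1e-9)
})

test_that("hourly chaining matches a fine-step reference trajectory", {
  f <- rotationFields()
  p <- c(0.02, 0)
  for (h in seq_len(12)) { # half a period in hourly macro-steps
    a <- advectHour(f, p[1], p[2], (h - 1) / 24, cflFraction = 0.5)
    p <- c(a$lon, a$lat)
  }
  ref <- c(0.02, 0); dt <- 0.5 / 5000
  for (s in seq_len(5000)) {
    st <- rk4Step(f, ref[1], ref[2], (s - 1) * dt, dt)
    ref <- c(st$lon, st$lat)
  }
  expect_lt(sqrt(sum((p - ref)^2)), 1e-6) # within a metre over half a period
})

test_that("behaviour determines the depth layer, boundary to deep", {
  expect_equal(behaviorLayer("surface", c(0, 5, 17)), rep(1L, 3))
  expect_equal(behaviorLayer("deep", c(0, 5, 17)), rep(2L, 3))
  expect_equal(behaviorLayer("migration", 9.99), 1L)
  expect_equal(behaviorLayer("migration", 10), 2L)
  expect_equal(behaviorLayer("migration", 10.01), 2L)
  expect_error(behaviorLayer("diving", 1), "unknown behavior")
})

test_that("release schedule yields the documented event counts", {
  p <- simParams(seasonLengthDays = 180, releaseIntervalHours = 6,
                 years = 11)
  expect_equal(nrow(releaseSchedule(p)), 7920)
  p1 <- simParams(seasonLengthDays = 1, releaseIntervalHours = 24)
  expect_equal(nrow(releaseSchedule(p1)), 1)
  p2 <- simParams(seasonLengthDays = 30, releaseIntervalHours = 6,
                  years = 2)
  expect_equal(nrow(releaseSchedule(p2)), 240)
  expect_equal(unique(releaseSchedule(p)$hour), c(0, 6, 12, 18))
})

test_that("settlement rule: competence gates habitat contact", {
  h <- coastDomain(10)
  cl <- habitatCells(h)
  p <- simParams()
  inHab <- checkSettlement(cl$lon[3], cl$lat[3], 12, h, p)
  expect_equal(inHab$status, "settled")
  expect_equal(inHab$cell, cl$cell_id[3])
  pre <- checkSettlement(cl$lon[3], cl$lat[3], 5, h, p)
  expect_equal(pre$status, "none")
  openWater <- checkSettlement(cl$lon[3] - 0.3, cl$lat[3], 18, h, p)
  expect_equal(openWater$status, "dead")
})

test_that("zero flow forces natal settlement at the competence age", {
  h <- coastDomain(10)
  f <- uniformCoastFields(h, 0, 0, nDays = 25)
  pars <- simParams(seasonLengthDays = 1, releaseIntervalHours = 6)
  rec <- simulateDispersal(f, h, pars)
  tb <- rec$table
  expect_equal(nrow(tb), 40)
  expect_true(all(tb$status == "settled"))
  expect_true(all(tb$settlement_cell == tb$natal_cell))
  expect_true(all(tb$settlement_age == 10))
})

test_that("uniform downstream flow settles strictly downstream", {
  h <- coastDomain(30)
  f <- uniformCoastFields(h, 0, 0.08, nDays = 40) # northward ~7 km/day
  pars <- simParams(seasonLengthDays = 2, releaseIntervalHours = 12)
  rec <- simulateDispersal(f, h, pars)
  tb <- rec$table
  settled <- tb[tb$status == "settled", ]
  expect_gt(nrow(settled), 0)
  expect_true(all(settled$settlement_cell > settled$natal_cell))
})

test_that("a single release day yields four bounded records per cell", {
  h <- coastDomain(10)
  f <- uniformCoastFields(h, 0, 0.01, nDays = 25)
  pars <- simParams(seasonLengthDays = 1, releaseIntervalHours = 6)
  rec <- simulateDispersal(f, h, pars, cells = habitatCells(h)$cell_id[5])
  expect_equal(nrow(rec$table), 4)
  expect_true(all(rec$table$n_steps <= 18 * 24))
  expect_equal(ncol(rec$paths), 432)
})

test_that("every particle ends in exactly one terminal status", {
  ex <- list(
    simulateDispersal(uniformCoastFields(coastDomain(10), 0, 0.2,
                                         nDays = 25),
                      coastDomain(10),
                      simParams(seasonLengthDays = 1,
                                releaseIntervalHours = 6)),
    simulateDispersal(uniformCoastFields(coastDomain(10), -0.05, 0.1,
                                         nDays = 25),
                      coastDomain(10),
                      simParams(seasonLengthDays = 2,
                                releaseIntervalHours = 12,
                                behavior = "migration")))
  for (rec in ex) {
    expect_true(all(rec$table$status %in% c("settled", "dead", "lost")))
    settled <- rec$table[rec$table$status == "settled", ]
    expect_true(all(settled$settlement_age >= 10 &
                      settled$settlement_age <= 18))
    dead <- rec$table[rec$table$status == "dead", ]
    expect_true(all(is.na(dead$settlement_cell)))
    expect_true(all(dead$n_steps == 432))
  }
})

test_that("recorded positions stay off land under onshore forcing", {
  h <- coastDomain(10)
  f <- uniformCoastFields(h, 0.1, 0.02, nDays = 25) # pushes east into land
  pars <- simParams(seasonLengthDays = 1, releaseIntervalHours = 6)
  rec <- simulateDispersal(f, h, pars)
  tb <- rec$table
  ij <- larvaConn:::cellIndex(tb$final_lon, tb$final_lat, h@lon, h@lat,
                              gridResolution(h))
  # lost particles legitimately end outside the grid; everyone else must
  # be on a sea cell
  ok <- !is.na(ij$i) & !is.na(ij$j)
  expect_true(all(seaMask(h)[cbind(ij$i[ok], ij$j[ok])]))
  # onshore flow with free-slip coast cannot beach particles; they slide
  # along the coast and still settle
  expect_true(all(tb$status %in% c("settled", "dead", "lost")))
})

test_that("simulation is deterministic and jitter respects the seed", {
  h <- coastDomain(10)
  f <- uniformCoastFields(h, -0.01, 0.03, nDays = 25)
  pars <- simParams(seasonLengthDays = 1, releaseIntervalHours = 12)
  r1 <- simulateDispersal(f, h, pars, seed = 3, releaseJitter = TRUE)
  r2 <- simulateDispersal(f, h, pars, seed = 3, releaseJitter = TRUE)
  r3 <- simulateDispersal(f, h, pars, seed = 4, releaseJitter = TRUE)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$paths, r2$paths)
  expect_false(identical(r1$table$final_lon, r3$table$final_lon))
})
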