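# From particle records to connectivity matrices, retention / effective
# settlement, behaviour comparisons, distance-decay fits and focal-region
# source/sink summaries.

#' Build the cell-by-cell connectivity matrix from particle records
#'
#' For each particle the recorded hourly steps whose position falls inside
#' habitat cell `j` are counted and divided by the maximum number of
#' simulated steps (PLD days x steps per day, 432 by default); entry
#' `(i, j)` is the mean of this fraction over all particles released from
#' cell `i`. The release position itself is not a step; recording stops at
#' settlement (first-contact truncation), so every entry lies in `[0, 1]`.
#'
#' @param records a `ParticleRecords` object from [simulateDispersal()].
#' @param habitat the [HabitatGrid-class] the simulation used.
#' @param year optional year to restrict to (default: all records, tagged
#'   with the year set).
#' @param denominator `"all_released"` (default) averages over every
#'   released particle; `"excluding_lost"` drops particles advected out of
#'   the domain from the denominator.
#' @param settledResidence if `TRUE`, a settled particle is additionally
#'   counted as occupying its settlement cell for all remaining steps up
#'   to the PLD (sensitivity variant; default `FALSE`).
#' @return a [ConnectivityMatrix-class]
#' @export
connectivityMatrix <- function(records, habitat, year = NULL,
                               denominator = c("all_released",
                                               "excluding_lost"),
                               settledResidence = FALSE) {
  denominator <- match.arg(denominator)
  tab <- records$table
  paths <- records$paths
  if (!is.null(year)) {
    keep <- tab$year %in% year
    tab <- tab[keep, , drop = FALSE]
    paths <- paths[keep, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("empty record set")
  maxSteps <- records$params$pldMax * records$params$stepsPerDay
  ids <- habitat@cells$cell_id
  nCell <- length(ids)
  idRank <- integer(max(ids)); idRank[ids] <- seq_len(nCell)
  if (denominator == "excluding_lost") {
    keep <- tab$status != "lost"
    tab <- tab[keep, , drop = FALSE]
    paths <- paths[keep, , drop = FALSE]
    if (nrow(tab) == 0) stop("no particles left after excluding lost")
  }
  nRel <- tabulate(idRank[tab$natal_cell], nCell)
  counts <- matrix(0, nCell, nCell)
  hit <- which(!is.na(paths) & paths > 0L, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    i <- idRank[tab$natal_cell[hit[, 1]]]
    j <- idRank[paths[hit]]
    tb <- table(factor(i, levels = seq_len(nCell)),
                factor(j, levels = seq_len(nCell)))
    counts <- counts + unclass(tb)
  }
  if (settledResidence) {
    st <- which(tab$status == "settled")
    if (length(st)) {
      rem <- maxSteps - tab$n_steps[st]
      i <- idRank[tab$natal_cell[st]]
      j <- idRank[tab$settlement_cell[st]]
      for (k in seq_along(st))
        counts[i[k], j[k]] <- counts[i[k], j[k]] + rem[k]
    }
  }
  probs <- counts / (maxSteps * pmax(nRel, 1))
  probs[nRel == 0, ] <- NA_real_
  dimnames(probs) <- list(ids, ids)
  yearTag <- if (is.null(year)) paste(sort(unique(tab$year)), collapse = ",")
             else paste(year, collapse = ",")
  new("ConnectivityMatrix", probabilities = probs,
      year = as.character(yearTag), behavior = records$behavior,
      denominator = denominator)
}

#' Average connectivity matrices over years
#'
#' Element-wise mean of a list of same-shaped matrices (e.g. the annual
#' matrices of one behaviour), tagged `"averaged"`.
#'
#' @param matrices list of [ConnectivityMatrix-class] objects.
#' @return a [ConnectivityMatrix-class]
#' @export
averageMatrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  p0 <- connProbabilities(matrices[[1]])
  for (m in matrices[-1]) {
    if (!identical(dim(connProbabilities(m)), dim(p0)))
      stop("matrices differ in shape")
  }
  acc <- Reduce(`+`, lapply(matrices, connProbabilities))
  new("ConnectivityMatrix", probabilities = acc / length(matrices),
      year = "averaged", behavior = matrices[[1]]@behavior,
      denominator = matrices[[1]]@denominator)
}

#' Per-cell retention, effective settlement and dispersal distances
#'
#' Retention of cell `i` is the fraction of particles released from `i`
#' that settle back into `i`; effective settlement is the fraction that
#' settle anywhere. The dispersal distance of a settled particle is the
#' shoreline (least-cost through sea) distance from its natal to its
#' settlement cell.
#'
#' @param records a `ParticleRecords` object.
#' @param habitat the [HabitatGrid-class].
#' @param coastDistances optional precomputed km matrix from
#'   [shorelineDistanceMatrix()] (computed on the fly if missing).
#' @param denominator as in [connectivityMatrix()].
#' @return list of class `SettlementSummary`: `cells` (per-cell data.frame
#'   with `retention` and `effective_settlement`), `meanKm`, `sdKm`,
#'   `maxKm`, and the settled-particle `distancesKm`.
#' @export
settlementSummary <- function(records, habitat, coastDistances = NULL,
                              denominator = c("all_released",
                                              "excluding_lost")) {
  denominator <- match.arg(denominator)
  tab <- records$table
  if (denominator == "excluding_lost")
    tab <- tab[tab$status != "lost", , drop = FALSE]
  ids <- habitat@cells$cell_id
  nCell <- length(ids)
  idRank <- integer(max(ids)); idRank[ids] <- seq_len(nCell)
  nRel <- tabulate(idRank[tab$natal_cell], nCell)
  settled <- tab[tab$status == "settled", , drop = FALSE]
  nSet <- tabulate(idRank[settled$natal_cell], nCell)
  nRet <- tabulate(idRank[settled$natal_cell[
    settled$natal_cell == settled$settlement_cell]], nCell)
  if (is.null(coastDistances))
    coastDistances <- shorelineDistanceMatrix(habitat)
  dKm <- coastDistances[cbind(idRank[settled$natal_cell],
                              idRank[settled$settlement_cell])]
  cells <- data.frame(cell_id = ids, released = nRel,
                      retention = ifelse(nRel > 0, nRet / nRel, NA),
                      effective_settlement =
                        ifelse(nRel > 0, nSet / nRel, NA))
  structure(list(cells = cells,
                 meanKm = if (length(dKm)) mean(dKm) else NA_real_,
                 sdKm = if (length(dKm) > 1) stats::sd(dKm) else NA_real_,
                 maxKm = if (length(dKm)) max(dKm) else NA_real_,
                 distancesKm = dKm),
            class = "SettlementSummary")
}

#' @export
print.SettlementSummary <- function(x, ...) {
  cat("SettlementSummary:",
      "mean retention", signif(mean(x$cells$retention, na.rm = TRUE), 3),
      "| mean effective settlement",
      signif(mean(x$cells$effective_settlement, na.rm = TRUE), 3),
      "| dispersal", signif(x$meanKm, 4), "+/-", signif(x$sdKm, 4),
      "km (max", signif(x$maxKm, 4), "km)\n")
  invisible(x)
}

#' Kruskal-Wallis test with Nemenyi post-hoc comparisons
#'
#' Compares three or more groups of per-cell probabilities (e.g. retention
#' under the surface/deep/migration behaviours) with the Kruskal-Wallis
#' rank-sum test (tie-corrected H from [stats::kruskal.test()]) followed
#' by all-pairs Nemenyi tests using the chi-square approximation on mean
#' rank differences, which accommodates unequal group sizes.
#'
#' @param valuesByGroup named list of numeric vectors (each length >= 2).
#' @return list with `H`, `df`, `p.value` and the `pairwise` p-value
#'   matrix
#' @export
compareParticleTypes <- function(valuesByGroup) {
  stopifnot(length(valuesByGroup) >= 2)
  if (any(vapply(valuesByGroup, length, 1L) < 2))
    stop("each group needs at least 2 values")
  if (is.null(names(valuesByGroup)))
    names(valuesByGroup) <- paste0("group", seq_along(valuesByGroup))
  x <- unlist(valuesByGroup, use.names = FALSE)
  g <- factor(rep(names(valuesByGroup),
                  vapply(valuesByGroup, length, 1L)),
              levels = names(valuesByGroup))
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  k <- nlevels(g)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  pw <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    stat <- (rbar[a] - rbar[b])^2 /
      (N * (N + 1) / 12 * (1 / n[a] + 1 / n[b]))
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    pw[a, b] <- pw[b, a] <- p
  }
  diag(pw) <- 1
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, pairwise = pw)
}

#' Shoreline (least-cost through sea) distances between habitat cells
#'
#' Builds an 8-connected graph over sea cells with great-circle edge
#' lengths (diagonal steps cost the true diagonal distance, about sqrt(2)
#' times the cell size) and returns shortest-path distances in km between
#' all habitat cells. Disconnected pairs get `Inf`.
#'
#' @param habitat a [HabitatGrid-class].
#' @return symmetric km matrix with habitat cell ids as dimnames
#' @export
shorelineDistanceMatrix <- function(habitat) {
  sea <- habitat@seaMask
  nLon <- nrow(sea); nLat <- ncol(sea)
  idx <- which(sea)
  vid <- integer(nLon * nLat); vid[idx] <- seq_along(idx)
  ii <- (idx - 1) %% nLon + 1
  jj <- (idx - 1) %/% nLon + 1
  lonC <- habitat@lon[ii]; latC <- habitat@lat[jj]
  edges <- NULL; wts <- NULL
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    i2 <- ii + d[1]; j2 <- jj + d[2]
    ok <- i2 >= 1 & i2 <= nLon & j2 >= 1 & j2 <= nLat
    tgt <- (j2[ok] - 1) * nLon + i2[ok]
    okSea <- sea[tgt]
    from <- vid[idx[ok]][okSea]
    to <- vid[tgt][okSea]
    w <- geosphere::distHaversine(
      cbind(lonC[from], latC[from]), cbind(lonC[to], latC[to])) / 1000
    edges <- c(edges, rbind(from, to))
    wts <- c(wts, w)
  }
  g <- igraph::make_graph(edges, directed = FALSE, n = length(idx))
  cl <- habitat@cells
  hv <- vid[(cl$j - 1) * nLon + cl$i]
  D <- igraph::distances(g, v = hv, to = hv, weights = wts)
  dimnames(D) <- list(cl$cell_id, cl$cell_id)
  D
}

#' Shoreline distance between two habitat cells
#'
#' @param habitat a [HabitatGrid-class].
#' @param cellA,cellB habitat cell ids.
#' @return distance in km (`Inf` if the cells are disconnected by land)
#' @export
shorelineDistance <- function(habitat, cellA, cellB) {
  D <- shorelineDistanceMatrix(habitat)
  D[as.character(cellA), as.character(cellB)]
}

#' Fit an exponential distance-decay to connectivity probabilities
#'
#' Fits `P = a * exp(-b * d)` by least squares on the log-transformed
#' positive off-diagonal entries (zeros carry no information about the
#' decay rate on the log scale and are excluded).
#'
#' @param matrix a [ConnectivityMatrix-class] or plain probability matrix.
#' @param distances km matrix aligned with `matrix`.
#' @param weighted if `TRUE`, weight log-scale residuals by `P` (down-
#'   weighting the noisiest small probabilities).
#' @return list with `a`, `b`, `r2` and `n` (entries used)
#' @export
distanceDecay <- function(matrix, distances, weighted = FALSE) {
  p <- if (is(matrix, "ConnectivityMatrix")) connProbabilities(matrix)
       else matrix
  stopifnot(identical(dim(p), dim(distances)))
  off <- row(p) != col(p)
  use <- off & !is.na(p) & p > 0 & is.finite(distances)
  if (sum(use) < 3) stop("need at least 3 positive off-diagonal entries")
  y <- log(p[use]); d <- distances[use]
  fit <- if (weighted) stats::lm(y ~ d, weights = p[use])
         else stats::lm(y ~ d)
  co <- stats::coef(fit)
  list(a = exp(unname(co[1])), b = -unname(co[2]),
       r2 = summary(fit)$r.squared, n = sum(use))
}

#' Source/sink summary for a focal region
#'
#' Aggregates mean pairwise probabilities between a focal cell set (e.g. a
#' marine protected area) and cell sets to its north and south, and forms
#' the directional ratios: south-to-focal over north-to-focal settlement,
#' focal-to-north over focal-to-south export, and local retention within
#' the focal area over import from the south.
#'
#' @param matrix a [ConnectivityMatrix-class] or probability matrix.
#' @param focalCells,northCells,southCells disjoint habitat cell id sets.
#' @return list with `aggregates` (named means), `ratios` (named, `Inf`
#'   with `infinite = TRUE` flag where a denominator is zero)
#' @export
focalRegionSummary <- function(matrix, focalCells, northCells, southCells) {
  if (length(intersect(focalCells, northCells)) ||
      length(intersect(focalCells, southCells)) ||
      length(intersect(northCells, southCells)))
    stop("cell sets must be disjoint")
  p <- if (is(matrix, "ConnectivityMatrix")) connProbabilities(matrix)
       else matrix
  ids <- rownames(p)
  sel <- function(cells) which(ids %in% as.character(cells))
  f <- sel(focalCells); n <- sel(northCells); s <- sel(southCells)
  agg <- c(south_to_focal = mean(p[s, f]),
           north_to_focal = mean(p[n, f]),
           focal_to_north = mean(p[f, n]),
           focal_to_south = mean(p[f, s]),
           focal_to_focal = mean(p[f, f]))
  rat <- function(num, den) if (den == 0) Inf else num / den
  ratios <- c(south_vs_north_settlement =
                rat(agg["south_to_focal"], agg["north_to_focal"]),
              north_vs_south_export =
                rat(agg["focal_to_north"], agg["focal_to_south"]),
              retention_vs_south_import =
                rat(agg["focal_to_focal"], agg["south_to_focal"]))
  names(ratios) <- c("south_vs_north_settlement", "north_vs_south_export",
                     "retention_vs_south_import")
  list(aggregates = agg, ratios = ratios,
       infinite = !is.finite(ratios))
}
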