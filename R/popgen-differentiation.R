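# Population differentiation: Weir-Cockerham theta (F_ST) with permutation
# tests and bootstrap-over-loci confidence intervals, Jost's D with
# null-resampling p-values, Mantel isolation-by-distance, and FDR control.

# Weir-Cockerham (1984) variance components for one locus across r
# populations; returns c(sumA, sumB, sumC) over alleles. Populations with
# no data at the locus are dropped; fewer than 2 informative populations
# gives NAs (the locus is skipped pairwise).
.wcLocus <- function(a1, a2, popf) {
  pops <- levels(popf)
  nI <- h <- list()
  ns <- numeric(0)
  for (p in pops) {
    sel <- popf == p & !is.na(a1)
    if (sum(sel) >= 1) {
      nI[[p]] <- c(a1[sel], a2[sel])
      h[[p]] <- (a1[sel] != a2[sel])
      ns <- c(ns, sum(sel))
    }
  }
  r <- length(ns)
  if (r < 2 || sum(ns) < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  alleles <- sort(unique(unlist(nI)))
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  sumA <- sumB <- sumC <- 0
  for (al in alleles) {
    pk <- vapply(seq_len(r), function(k) mean(nI[[k]] == al), 1)
    # heterozygote frequency for this allele: genotypes with exactly one copy
    hk <- vapply(seq_len(r), function(k) {
      g1 <- nI[[k]][seq_len(ns[k])]
      g2 <- nI[[k]][ns[k] + seq_len(ns[k])]
      mean((g1 == al) != (g2 == al))
    }, 1)
    pbar <- sum(ns * pk) / (r * nbar)
    s2 <- sum(ns * (pk - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * hk) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    sumA <- sumA + a; sumB <- sumB + b; sumC <- sumC + hbar / 2
  }
  c(a = sumA, b = sumB, c = sumC)
}

# components for all loci: 3 x L matrix
.wcAllLoci <- function(gt, popf) {
  vapply(seq_len(nLoci(gt)),
         function(l) .wcLocus(gt@allele1[, l], gt@allele2[, l], popf),
         numeric(3))
}

.thetaFromComp <- function(comp) {
  a <- sum(comp[1, ], na.rm = TRUE)
  tot <- sum(comp, na.rm = TRUE)
  if (tot == 0) return(NA_real_)
  a / tot
}

#' Weir-Cockerham F_ST (theta)
#'
#' Per-locus and multilocus theta as ratios of summed variance components,
#' the pairwise population matrix, a permutation p-value per pair
#' (individuals shuffled across the two populations; one-sided for
#' theta greater than the null), and a bootstrap-over-loci 95% confidence
#' interval for the global estimate.
#'
#' @param gt a [GenotypeTable-class] with at least 2 populations.
#' @param nPerm permutations per pairwise test (0 to skip).
#' @param nBoot bootstrap-over-loci resamples for the global CI (0 to
#'   skip).
#' @param seed integer seed.
#' @return list with `perLocus`, `global`, `globalCI`, `pairwise`
#'   (theta matrix), `pairwiseP`
#' @export
fstWC <- function(gt, nPerm = 0, nBoot = 0, seed = 1) {
  popf <- factor(popLabels(gt))
  if (nlevels(popf) < 2) stop("need at least 2 populations")
  comp <- .wcAllLoci(gt, popf)
  perLocus <- apply(comp, 2, function(x) {
    if (all(is.na(x)) || sum(x, na.rm = TRUE) == 0) NA_real_
    else x[1] / sum(x)
  })
  names(perLocus) <- lociNames(gt)
  global <- .thetaFromComp(comp)
  globalCI <- c(NA_real_, NA_real_)
  pops <- levels(popf)
  k <- length(pops)
  pw <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pwP <- pw
  diag(pw) <- 0
  withSeed(seed, {
    if (nBoot > 0) {
      bt <- vapply(seq_len(nBoot), function(b) {
        sel <- sample.int(ncol(comp), replace = TRUE)
        .thetaFromComp(comp[, sel, drop = FALSE])
      }, 1)
      globalCI <- unname(stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE))
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sel <- popf %in% pops[c(i, j)]
      sub <- subsetInd(gt, sel)
      f2 <- factor(popLabels(sub))
      th <- .thetaFromComp(.wcAllLoci(sub, f2))
      pw[i, j] <- pw[j, i] <- th
      if (nPerm > 0 && !is.na(th)) {
        hits <- 0L
        for (b in seq_len(nPerm)) {
          fp <- factor(sample(as.character(f2)), levels = levels(f2))
          if (.thetaFromComp(.wcAllLoci(sub, fp)) >= th) hits <- hits + 1L
        }
        pwP[i, j] <- pwP[j, i] <- (hits + 1) / (nPerm + 1)
      }
    }
  })
  list(perLocus = perLocus, global = global, globalCI = globalCI,
       pairwise = pw, pairwiseP = pwP)
}

# Jost's D for one locus with Nei-Chesser sample-size-corrected
# heterozygosities; returns NA when fewer than 2 populations have data or
# when Hs = 1.
.jostDLocus <- function(a1, a2, popf) {
  pops <- levels(popf)
  freqs <- list(); ns <- numeric(0); hos <- numeric(0)
  for (p in pops) {
    sel <- popf == p & !is.na(a1)
    if (sum(sel) >= 1) {
      al <- c(a1[sel], a2[sel])
      freqs[[length(freqs) + 1]] <- al
      ns <- c(ns, sum(sel))
      hos <- c(hos, mean(a1[sel] != a2[sel]))
    }
  }
  r <- length(ns)
  if (r < 2) return(NA_real_)
  alleles <- sort(unique(unlist(freqs)))
  P <- t(vapply(freqs, function(al) {
    vapply(alleles, function(x) mean(al == x), 1)
  }, numeric(length(alleles))))
  ntil <- r / sum(1 / ns) # harmonic mean sample size
  Ho <- mean(hos)
  Hs <- ntil / (ntil - 1) * (1 - mean(rowSums(P^2)) - Ho / (2 * ntil))
  pbar <- colMeans(P)
  Ht <- 1 - sum(pbar^2) + Hs / (ntil * r) - Ho / (2 * ntil * r)
  if (1 - Hs <= 0) return(NA_real_)
  (Ht - Hs) / (1 - Hs) * r / (r - 1)
}

.jostDAll <- function(gt, popf) {
  vapply(seq_len(nLoci(gt)),
         function(l) .jostDLocus(gt@allele1[, l], gt@allele2[, l], popf), 1)
}

#' Jost's D differentiation
#'
#' Per-locus D with sample-size-corrected heterozygosities (Nei-Chesser
#' estimators with harmonic-mean sample size and the r/(r-1) correction),
#' averaged over loci; pairwise matrix; and a null-resampling p-value per
#' pair: individuals are resampled with replacement from the pooled pair
#' into groups of the original sizes (panmixia null) and the one-sided
#' exceedance fraction of the mean-over-loci D is reported.
#'
#' Loci where the within-population heterozygosity reaches 1 are excluded
#' with a warning (D undefined there).
#'
#' @param gt a [GenotypeTable-class].
#' @param nBoot null resamples per pairwise p-value (default 1000; 0 to
#'   skip).
#' @param seed integer seed.
#' @return list with `perLocus`, `mean`, `pairwise`, `pairwiseP`
#' @export
jostD <- function(gt, nBoot = 1000, seed = 1) {
  popf <- factor(popLabels(gt))
  if (nlevels(popf) < 2) stop("need at least 2 populations")
  perLocus <- .jostDAll(gt, popf)
  names(perLocus) <- lociNames(gt)
  if (anyNA(perLocus))
    warning("excluding ", sum(is.na(perLocus)),
            " loci with undefined D from the mean")
  pops <- levels(popf)
  k <- length(pops)
  pw <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pwP <- pw
  diag(pw) <- 0
  withSeed(seed, {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sel <- popf %in% pops[c(i, j)]
      sub <- subsetInd(gt, sel)
      f2 <- factor(popLabels(sub))
      dObs <- mean(.jostDAll(sub, f2), na.rm = TRUE)
      pw[i, j] <- pw[j, i] <- dObs
      if (nBoot > 0 && !is.na(dObs)) {
        n <- nInd(sub)
        hits <- 0L
        for (b in seq_len(nBoot)) {
          draw <- sample.int(n, n, replace = TRUE)
          bs <- subsetInd(sub, draw)
          bs@ind$pop <- as.character(f2) # original sizes, pooled draw
          fb <- factor(popLabels(bs))
          if (mean(.jostDAll(bs, fb), na.rm = TRUE) >= dObs)
            hits <- hits + 1L
        }
        pwP[i, j] <- pwP[j, i] <- (hits + 1) / (nBoot + 1)
      }
    }
  })
  list(perLocus = perLocus, mean = mean(perLocus, na.rm = TRUE),
       pairwise = pw, pairwiseP = pwP)
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic
#' differentiation matrix and a geographic (shoreline km) distance matrix,
#' with a one-sided permutation p-value from random row/column
#' permutations (delegated to [vegan::mantel()]).
#'
#' @param genetic,geographic symmetric matrices with matching labels.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `r` and `p`
#' @export
mantelIBD <- function(genetic, geographic, nPerm = 10000, seed = 1) {
  stopifnot(identical(dim(genetic), dim(geographic)))
  gv <- genetic[lower.tri(genetic)]
  if (stats::sd(gv) == 0 || stats::sd(geographic[lower.tri(geographic)]) == 0)
    stop("constant matrix: Mantel r undefined")
  withSeed(seed, {
    # always sample permutations (vegan would otherwise enumerate the
    # full set for small matrices, with different p-value granularity)
    ctrl <- permute::how(nperm = nPerm, minperm = 0)
    mt <- vegan::mantel(stats::as.dist(genetic), stats::as.dist(geographic),
                        method = "pearson", permutations = ctrl)
    list(r = unname(mt$statistic), p = mt$signif)
  })
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values (monotone step-up adjusted p-values)
#' @export
fdrAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
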