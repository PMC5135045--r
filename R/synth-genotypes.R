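# Synthetic microsatellite genotypes: K latent gene pools diverged from a
# common ancestral allele-frequency distribution (Balding-Nichols style),
# mixed into sampled populations by ancestry weights, with Hardy-Weinberg
# sampling of diploids; plus Mendelian families with genotyping error.

#' Specify a sampled population
#'
#' @param name population label.
#' @param n number of diploid individuals (>= 1).
#' @param weights ancestry proportions over the K latent gene pools
#'   (must sum to 1).
#' @param year optional year label.
#' @return a list of class `PopSpec`
#' @export
popSpec <- function(name, n, weights, year = NA) {
  stopifnot(n >= 1, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("ancestry weights must sum to 1")
  structure(list(name = name, n = as.integer(n),
                 weights = as.numeric(weights), year = year),
            class = "PopSpec")
}

#' Packaged calibration population set
#'
#' Seven populations of 30--45 adults strung along a coastline, each a
#' mixture of K = 3 latent gene pools whose weights drift from south to
#' north. With the default pool divergence this yields weak global
#' structure (theta of order 0.02) and microsatellite-like diversity,
#' the regime the rest of the pipeline is exercised against.
#'
#' @param year year label attached to all populations.
#' @param shift optional shift in `[0, 1]` of the ancestry weights toward
#'   the third pool, used to emulate a between-year change in genetic
#'   composition (0 = none).
#' @return list of `PopSpec`
#' @export
demoPopSpecs <- function(year = NA, shift = 0) {
  names <- c("MAR", "PEN", "LIS", "ARR", "SIN", "ALM", "BAR")
  n <- c(38, 39, 40, 45, 30, 35, 42)
  lapply(seq_along(names), function(k) {
    f <- (k - 1) / (length(names) - 1)
    w <- c((1 - f) * 0.7 + 0.1, 0.2, f * 0.7 + 0.1)
    w <- (1 - shift) * w / sum(w) + shift * c(0.1, 0.2, 0.7)
    popSpec(names[k], n[k], w / sum(w), year = year)
  })
}

#' The packaged calibration genotype dataset
#'
#' [makeGenotypeDataset()] applied to [demoPopSpecs()] with a pool
#' divergence of 0.2, calibrated once so that the realized global theta of
#' the admixed populations falls in the weak-structure band (roughly
#' 0.01--0.03) with microsatellite-like diversity.
#'
#' @param seed integer seed.
#' @param year,shift passed to [demoPopSpecs()].
#' @return as [makeGenotypeDataset()]
#' @export
demoGenotypeDataset <- function(seed = 1, year = NA, shift = 0) {
  makeGenotypeDataset(demoPopSpecs(year = year, shift = shift),
                      poolDivergence = 0.2, seed = seed)
}

# Dirichlet draw (rows = draws).
.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Generate a multilocus genotype dataset with known truth
#'
#' Ancestral allele frequencies per locus are drawn from a skewed symmetric
#' Dirichlet (microsatellite-like, expected heterozygosity about 0.7--0.9
#' depending on allele number). Each of K latent pools diverges from the
#' ancestral frequencies following a Balding-Nichols parameterization with
#' divergence `poolDivergence` (the F of the pool relative to the
#' ancestor). Sampled populations mix pools per their ancestry weights.
#'
#' With `mixing = "allele"` every allele is drawn independently from the
#' population's mixed frequencies, so genotypes are in Hardy-Weinberg
#' proportions within populations. With `mixing = "individual"` each
#' individual first draws a pool of origin and then both alleles from that
#' pool: pooling diverged gene pools in one sample produces a Wahlund-type
#' heterozygote deficit (positive F_IS).
#'
#' @param pops list of `PopSpec` from [popSpec()].
#' @param nLoci number of loci (default 12).
#' @param allelesPerLocus integer vector (recycled) of allele counts,
#'   default spanning 9--41.
#' @param poolDivergence Balding-Nichols F of the latent pools.
#' @param mixing `"allele"` (HWE within populations) or `"individual"`
#'   (Wahlund construction).
#' @param dirichletAlpha skew of the ancestral frequency distribution.
#' @param seed integer seed.
#' @return list with `genotypes` (a [GenotypeTable-class]) and `truth`
#'   (pool allele frequencies per locus plus generator settings).
#' @export
makeGenotypeDataset <- function(pops, nLoci = 12,
                                allelesPerLocus = NULL,
                                poolDivergence = 0.05,
                                mixing = c("allele", "individual"),
                                dirichletAlpha = 0.35,
                                seed = 1) {
  mixing <- match.arg(mixing)
  stopifnot(nLoci >= 1)
  if (is.null(allelesPerLocus))
    allelesPerLocus <- round(seq(9, 41, length.out = nLoci))
  allelesPerLocus <- rep_len(as.integer(allelesPerLocus), nLoci)
  if (any(allelesPerLocus < 2)) stop("each locus needs >= 2 alleles")
  K <- length(pops[[1]]$weights)
  for (p in pops) {
    if (length(p$weights) != K) stop("all PopSpecs must use the same K")
  }
  withSeed(seed, {
    poolFreqs <- vector("list", nLoci)
    for (l in seq_len(nLoci)) {
      A <- allelesPerLocus[l]
      anc <- .rdirichlet(1, rep(dirichletAlpha, A))[1, ]
      if (poolDivergence > 0) {
        lam <- (1 - poolDivergence) / poolDivergence
        pf <- t(vapply(seq_len(K),
                       function(k) .rdirichlet(1, anc * lam)[1, ],
                       numeric(A)))
      } else {
        pf <- matrix(anc, K, A, byrow = TRUE)
      }
      poolFreqs[[l]] <- pf
    }
    nTot <- sum(vapply(pops, function(p) p$n, 1L))
    a1 <- matrix(NA_integer_, nTot, nLoci)
    a2 <- matrix(NA_integer_, nTot, nLoci)
    popLab <- character(nTot); yearLab <- rep(NA, nTot)
    row <- 0L
    for (p in pops) {
      idx <- row + seq_len(p$n)
      popLab[idx] <- p$name
      yearLab[idx] <- p$year
      for (l in seq_len(nLoci)) {
        A <- allelesPerLocus[l]
        if (mixing == "allele") {
          mixed <- drop(p$weights %*% poolFreqs[[l]])
          a1[idx, l] <- sample.int(A, p$n, replace = TRUE, prob = mixed)
          a2[idx, l] <- sample.int(A, p$n, replace = TRUE, prob = mixed)
        } else {
          poolOf <- sample.int(K, p$n, replace = TRUE, prob = p$weights)
          for (k in seq_len(K)) {
            sel <- idx[poolOf == k]
            if (length(sel)) {
              a1[sel, l] <- sample.int(A, length(sel), replace = TRUE,
                                       prob = poolFreqs[[l]][k, ])
              a2[sel, l] <- sample.int(A, length(sel), replace = TRUE,
                                       prob = poolFreqs[[l]][k, ])
            }
          }
        }
      }
      row <- row + p$n
    }
    gt <- genotypeTable(a1, a2, pop = popLab, year = yearLab)
    list(genotypes = gt,
         truth = list(poolFreqs = poolFreqs,
                      allelesPerLocus = allelesPerLocus,
                      poolDivergence = poolDivergence,
                      mixing = mixing))
  })
}

#' Generate parent-offspring families with genotyping error
#'
#' Candidate parents are paired at random (disjoint pairs); each pair
#' produces `nOffspringPerPair` offspring receiving one Mendelian allele
#' per parent per locus. Each observed offspring allele then independently
#' drops out (is replaced by its homologue, creating false homozygosity)
#' with probability `dropoutRate`, or is replaced by a random allele from
#' the locus's candidate-parent allele pool with probability `errorRate`.
#'
#' @param parents a [GenotypeTable-class] of candidate parents (no missing
#'   genotypes).
#' @param nPairs number of parent pairs to form.
#' @param nOffspringPerPair offspring per pair.
#' @param dropoutRate,errorRate per-allele rates in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `offspring` (a [GenotypeTable-class], pop label
#'   `"offspring"`) and `truth` (data.frame `offspring`, `parent1`,
#'   `parent2` ids).
#' @export
makeFamilies <- function(parents, nPairs, nOffspringPerPair = 1,
                         dropoutRate = 0.05, errorRate = 0.01, seed = 1) {
  if (dropoutRate < 0 || dropoutRate > 1 || errorRate < 0 || errorRate > 1)
    stop("rates must lie in [0, 1]")
  if (anyNA(alleleMatrix(parents, 1)))
    stop("candidate parents must have complete genotypes")
  nP <- nInd(parents)
  if (2 * nPairs > nP) stop("not enough candidates to form disjoint pairs")
  withSeed(seed, {
    ord <- sample.int(nP, 2 * nPairs)
    p1 <- ord[seq_len(nPairs)]
    p2 <- ord[nPairs + seq_len(nPairs)]
    L <- nLoci(parents)
    nOff <- nPairs * nOffspringPerPair
    o1 <- matrix(NA_integer_, nOff, L)
    o2 <- matrix(NA_integer_, nOff, L)
    truth <- data.frame(offspring = character(nOff),
                        parent1 = character(nOff),
                        parent2 = character(nOff),
                        stringsAsFactors = FALSE)
    A1 <- alleleMatrix(parents, 1); A2 <- alleleMatrix(parents, 2)
    ids <- indTable(parents)$id
    # allele pools per locus for "other" errors
    pools <- lapply(seq_len(L), function(l) unique(c(A1[, l], A2[, l])))
    k <- 0L
    for (f in seq_len(nPairs)) {
      for (o in seq_len(nOffspringPerPair)) {
        k <- k + 1L
        pick1 <- stats::runif(L) < 0.5
        pick2 <- stats::runif(L) < 0.5
        o1[k, ] <- ifelse(pick1, A1[p1[f], ], A2[p1[f], ])
        o2[k, ] <- ifelse(pick2, A1[p2[f], ], A2[p2[f], ])
        truth$offspring[k] <- sprintf("off_%03d", k)
        truth$parent1[k] <- ids[p1[f]]
        truth$parent2[k] <- ids[p2[f]]
      }
    }
    # observation noise, allele-wise
    for (l in seq_len(L)) {
      u1 <- stats::runif(nOff); u2 <- stats::runif(nOff)
      # dropout: the failed allele is replaced by its homologue, creating
      # a false homozygote; if both drop, one of the two true alleles is
      # seen as a homozygote
      t1 <- o1[, l]; t2 <- o2[, l]
      d1 <- u1 < dropoutRate; d2 <- u2 < dropoutRate
      o1[d1, l] <- t2[d1]
      o2[d2, l] <- t1[d2]
      both <- d1 & d2
      if (any(both)) {
        keep <- ifelse(stats::runif(sum(both)) < 0.5, t1[both], t2[both])
        o1[both, l] <- keep; o2[both, l] <- keep
      }
      # other error: random allele from the locus pool
      e1 <- u1 >= dropoutRate & u1 < dropoutRate + errorRate
      e2 <- u2 >= dropoutRate & u2 < dropoutRate + errorRate
      if (any(e1)) o1[e1, l] <- sample(pools[[l]], sum(e1), replace = TRUE)
      if (any(e2)) o2[e2, l] <- sample(pools[[l]], sum(e2), replace = TRUE)
    }
    off <- genotypeTable(o1, o2, pop = "offspring", id = truth$offspring,
                         loci = lociNames(parents))
    list(offspring = off, truth = truth)
  })
}
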