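# Monte-Carlo population assignment (partial exclusion) and error-tolerant
# Mendelian parentage with simulated-null confidence, feeding
# self-recruitment estimates.

# Reference allele frequencies per population and locus, with a floor of
# 1/(2n+1) for alleles unobserved in the reference (so a foreign allele
# excludes softly rather than zeroing the likelihood).
.refFreqs <- function(reference) {
  popf <- factor(popLabels(reference))
  L <- nLoci(reference)
  out <- list()
  for (p in levels(popf)) {
    sel <- popf == p
    fr <- vector("list", L)
    for (l in seq_len(L)) {
      cnt <- .alleleCounts(reference@allele1[sel, l],
                           reference@allele2[sel, l])
      fr[[l]] <- list(freq = cnt / sum(cnt), n2 = sum(cnt))
    }
    out[[p]] <- fr
  }
  out
}

# log10 genotype likelihood of (a1, a2) vectors over loci under one
# population's frequencies; NA loci skipped.
.genoLogLik <- function(a1, a2, popFreq) {
  ll <- 0
  for (l in seq_along(popFreq)) {
    if (is.na(a1[l])) next
    fr <- popFreq[[l]]$freq
    floorP <- 1 / (popFreq[[l]]$n2 + 1)
    p1 <- fr[as.character(a1[l])]; p1 <- if (is.na(p1)) floorP else max(p1, floorP)
    p2 <- fr[as.character(a2[l])]; p2 <- if (is.na(p2)) floorP else max(p2, floorP)
    g <- if (a1[l] == a2[l]) p1 * p2 else 2 * p1 * p2
    ll <- ll + log10(g)
  }
  unname(ll)
}

#' Monte-Carlo population assignment of recruits
#'
#' For each recruit and reference population, the recruit's multilocus
#' genotype likelihood under the population's allele frequencies is ranked
#' within the likelihoods of `nSim` genotypes simulated from those
#' frequencies under Hardy-Weinberg: the assignment probability is the
#' fraction of simulated genotypes with likelihood at or below the
#' recruit's. A recruit is assigned to a population if its probability
#' exceeds `alpha` for exactly one population, classed an immigrant if
#' the probabilities are below `alpha` everywhere, and ambiguous
#' otherwise. Recruits missing more than half their loci are flagged
#' unassignable.
#'
#' @param recruits,reference [GenotypeTable-class] objects sharing loci.
#' @param nSim simulated genotypes per population (default 10000).
#' @param alpha assignment threshold (default 0.05).
#' @param seed integer seed.
#' @return list with `probabilities` (recruits x populations matrix) and
#'   `category` data.frame (`id`, `category`, `pop`)
#' @export
assignmentTest <- function(recruits, reference, nSim = 10000, alpha = 0.05,
                           seed = 1) {
  if (!identical(lociNames(recruits), lociNames(reference)))
    stop("recruits and reference must share the same loci")
  refs <- .refFreqs(reference)
  pops <- names(refs)
  L <- nLoci(recruits)
  nR <- nInd(recruits)
  probs <- matrix(NA_real_, nR, length(pops),
                  dimnames = list(indTable(recruits)$id, pops))
  withSeed(seed, {
    for (p in pops) {
      fr <- refs[[p]]
      # simulate nSim genotypes from this population's frequencies
      simLL <- numeric(nSim)
      for (l in seq_len(L)) {
        f <- fr[[l]]$freq
        if (!length(f)) next
        a <- sample(names(f), nSim, replace = TRUE, prob = f)
        b <- sample(names(f), nSim, replace = TRUE, prob = f)
        pa <- as.numeric(f[a]); pb <- as.numeric(f[b])
        simLL <- simLL + log10(ifelse(a == b, pa * pb, 2 * pa * pb))
      }
      for (i in seq_len(nR)) {
        ll <- .genoLogLik(recruits@allele1[i, ], recruits@allele2[i, ], fr)
        probs[i, p] <- mean(simLL <= ll)
      }
    }
  })
  nMiss <- rowSums(is.na(recruits@allele1))
  category <- character(nR); popOut <- rep(NA_character_, nR)
  for (i in seq_len(nR)) {
    if (nMiss[i] > L / 2) {
      category[i] <- "unassignable"
    } else {
      over <- which(probs[i, ] > alpha)
      if (length(over) == 1) {
        category[i] <- "assigned"; popOut[i] <- pops[over]
      } else if (length(over) == 0) {
        category[i] <- "immigrant"
      } else {
        category[i] <- "ambiguous"
      }
    }
  }
  list(probabilities = probs,
       category = data.frame(id = indTable(recruits)$id,
                             category = category, pop = popOut,
                             stringsAsFactors = FALSE))
}

# Offspring x candidate mismatch counts: a locus mismatches when the
# candidate shares no allele with the offspring (missing loci are skipped).
.mismatchMatrix <- function(offspring, candidates) {
  nO <- nInd(offspring); nC <- nInd(candidates)
  L <- nLoci(offspring)
  mm <- matrix(0L, nO, nC)
  for (l in seq_len(L)) {
    o1 <- offspring@allele1[, l]; o2 <- offspring@allele2[, l]
    c1 <- candidates@allele1[, l]; c2 <- candidates@allele2[, l]
    share <- outer(o1, c1, `==`) | outer(o1, c2, `==`) |
      outer(o2, c1, `==`) | outer(o2, c2, `==`)
    ok <- !is.na(share)
    mis <- !share & ok
    mm <- mm + mis
  }
  mm
}

# Per-locus probability that an unrelated candidate drawn from `freqs`
# shares no allele with the given offspring genotype.
.exclusionProb <- function(o1, o2, freqs) {
  vapply(seq_along(freqs), function(l) {
    if (is.na(o1[l])) return(0)
    f <- freqs[[l]]$freq
    p1 <- f[as.character(o1[l])]; if (is.na(p1)) p1 <- 0
    p2 <- if (o1[l] == o2[l]) 0 else f[as.character(o2[l])]
    if (is.na(p2)) p2 <- 0
    max(1 - as.numeric(p1) - as.numeric(p2), 0)^2
  }, 1)
}

#' Error-tolerant parentage by Mendelian exclusion
#'
#' Screens every offspring-candidate pair by the number of loci at which
#' the candidate shares no allele with the offspring. Pairs with at most
#' `maxMismatch` mismatching loci (default: the 95% binomial quantile of
#' the per-locus incompatibility implied by the genotyping error model,
#' `dropout + error` per allele, so about 95% of true pairs pass the
#' screen by construction) are scored: the pair's
#' confidence is one minus the fraction of `confidenceSim` simulated
#' unrelated candidates, drawn from the candidate allele frequencies under
#' Hardy-Weinberg, that reach as few mismatches with that offspring.
#' Pairs with confidence above `confidenceLevel` are accepted.
#'
#' @param offspring,candidates [GenotypeTable-class] objects sharing loci;
#'   candidate `pop` labels identify the site of origin.
#' @param dropout,errorRate per-allele genotyping error rates used to set
#'   the default mismatch tolerance (defaults 0.05 and 0.01).
#' @param maxMismatch mismatch tolerance override.
#' @param confidenceSim simulated unrelated candidates per offspring.
#' @param confidenceLevel acceptance threshold (default 0.95).
#' @param seed integer seed.
#' @return list of class `ParentageResult`: `pairs` data.frame
#'   (`offspring`, `parent`, `parent_pop`, `mismatches`, `confidence`),
#'   plus the threshold settings
#' @export
parentage <- function(offspring, candidates, dropout = 0.05,
                      errorRate = 0.01, maxMismatch = NULL,
                      confidenceSim = 1000, confidenceLevel = 0.95,
                      seed = 1) {
  if (dropout < 0 || dropout > 1 || errorRate < 0 || errorRate > 1)
    stop("rates must lie in [0, 1]")
  if (!identical(lociNames(offspring), lociNames(candidates)))
    stop("offspring and candidates must share the same loci")
  L <- nLoci(offspring)
  if (is.null(maxMismatch))
    maxMismatch <- stats::qbinom(0.95, L, min(dropout + errorRate, 1))
  empty <- data.frame(offspring = character(0), parent = character(0),
                      parent_pop = character(0), mismatches = integer(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
  if (nInd(candidates) == 0)
    return(structure(list(pairs = empty, maxMismatch = maxMismatch,
                          confidenceLevel = confidenceLevel),
                     class = "ParentageResult"))
  mm <- .mismatchMatrix(offspring, candidates)
  # pooled candidate allele frequencies for the unrelated null
  freqs <- lapply(seq_len(L), function(l) {
    cnt <- .alleleCounts(candidates@allele1[, l], candidates@allele2[, l])
    list(freq = cnt / sum(cnt), n2 = sum(cnt))
  })
  offIds <- indTable(offspring)$id
  candIds <- indTable(candidates)$id
  candPop <- popLabels(candidates)
  hits <- which(mm <= maxMismatch, arr.ind = TRUE)
  pairs <- empty
  if (nrow(hits) > 0) {
    withSeed(seed, {
      # null mismatch-count draws per offspring (shared across its pairs)
      nullLe <- function(oi, k) {
        q <- .exclusionProb(offspring@allele1[oi, ], offspring@allele2[oi, ],
                            freqs)
        draws <- rowSums(matrix(stats::runif(confidenceSim * L), confidenceSim, L) <
                           matrix(q, confidenceSim, L, byrow = TRUE))
        mean(draws <= k)
      }
      conf <- numeric(nrow(hits))
      for (h in seq_len(nrow(hits))) {
        conf[h] <- 1 - nullLe(hits[h, 1], mm[hits[h, 1], hits[h, 2]])
      }
      keep <- conf > confidenceLevel
      pairs <- data.frame(
        offspring = offIds[hits[keep, 1]],
        parent = candIds[hits[keep, 2]],
        parent_pop = candPop[hits[keep, 2]],
        mismatches = mm[hits[keep, , drop = FALSE]],
        confidence = conf[keep],
        stringsAsFactors = FALSE)
    })
  }
  structure(list(pairs = pairs, maxMismatch = maxMismatch,
                 confidenceLevel = confidenceLevel),
            class = "ParentageResult")
}

#' @export
print.ParentageResult <- function(x, ...) {
  cat("ParentageResult:", nrow(x$pairs), "accepted pairs",
      "(mismatch tolerance", x$maxMismatch,
      ", confidence >", x$confidenceLevel, ")\n")
  invisible(x)
}

#' Self-recruitment proportion
#'
#' The proportion of recruits sampled at a focal site that have at least
#' one accepted parent from that same site.
#'
#' @param result a `ParentageResult` from [parentage()].
#' @param recruitIds ids of the recruits sampled at the focal site.
#' @param focalSite site (population) label of the focal site.
#' @return proportion in `[0, 1]`
#' @export
selfRecruitment <- function(result, recruitIds, focalSite) {
  if (length(recruitIds) == 0) stop("no recruits at the focal site")
  pr <- result$pairs
  local <- unique(pr$offspring[pr$parent_pop == focalSite])
  sum(recruitIds %in% local) / length(recruitIds)
}
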