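# Genetic diversity: allele counts, rarefied allelic richness, unbiased
# heterozygosities and the within-population inbreeding coefficient.

# Allele count table for one locus in one set of individuals: named vector
# of gene-copy counts (missing genotypes excluded).
.alleleCounts <- function(a1, a2) {
  a <- c(a1, a2)
  a <- a[!is.na(a)]
  if (!length(a)) return(integer(0))
  table(a)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g`
#' diploid individuals (2g gene copies), by the hypergeometric rarefaction
#' formula: the sum over alleles of one minus the probability that the
#' allele is absent from the subsample.
#'
#' @param counts integer vector of gene-copy counts per allele at one
#'   locus (e.g. from a population sample).
#' @param g number of diploid individuals to rarefy to; `2 * g` must not
#'   exceed the total number of gene copies.
#' @return expected allele count (numeric)
#' @export
allelicRichness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (2 * g > N) stop("cannot rarefy to more gene copies than sampled")
  sum(1 - exp(lchoose(N - counts, 2 * g) - lchoose(N, 2 * g)))
}

# Weir-Cockerham within-population variance components for one population
# at one locus; returns c(sumB, sumC) over alleles (the `a` component is
# zero within a single population).
.wcWithin <- function(a1, a2) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < 2) return(c(b = NA_real_, c = NA_real_))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(c(b = 0, c = 0))
  sumB <- 0; sumC <- 0
  for (al in alleles) {
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    h <- mean((a1 == al) != (a2 == al))
    b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    sumB <- sumB + b
    sumC <- sumC + h / 2
  }
  c(b = sumB, c = sumC)
}

#' Per-population diversity summary
#'
#' Mean number of alleles per locus (A), allelic richness rarefied to `g`
#' individuals, Nei's unbiased expected heterozygosity, observed
#' heterozygosity, and the Weir-Cockerham within-population inbreeding
#' coefficient f (F_IS) as a ratio of variance components summed over loci
#' and alleles, with a one-sided permutation p-value for heterozygote
#' deficit obtained by shuffling alleles among the population's
#' individuals at each locus.
#'
#' Monomorphic loci contribute H = 0 and A = 1 but carry no information
#' about F_IS (zero variance components).
#'
#' @param gt a [GenotypeTable-class].
#' @param pop population label to summarize.
#' @param g rarefaction size in individuals (default: the smallest
#'   per-locus sample size in this population).
#' @param nPerm permutations for the F_IS p-value (0 to skip).
#' @param seed integer seed for the permutations.
#' @return list with `A`, `Arich`, `He`, `Ho`, `Fis`, `FisP`, `n`
#' @export
summarizePopulation <- function(gt, pop, g = NULL, nPerm = 999, seed = 1) {
  sel <- popLabels(gt) == pop
  if (!any(sel)) stop("no such population: ", pop)
  a1 <- gt@allele1[sel, , drop = FALSE]
  a2 <- gt@allele2[sel, , drop = FALSE]
  L <- nLoci(gt)
  nPerLocus <- colSums(!is.na(a1))
  if (is.null(g)) g <- min(nPerLocus)
  if (g > min(nPerLocus))
    stop("g exceeds the smallest per-locus sample size (", min(nPerLocus), ")")
  A <- Ar <- He <- Ho <- numeric(L)
  for (l in seq_len(L)) {
    cnt <- .alleleCounts(a1[, l], a2[, l])
    n <- sum(cnt) / 2
    A[l] <- length(cnt)
    Ar[l] <- allelicRichness(as.integer(cnt), g)
    p <- cnt / sum(cnt)
    He[l] <- if (n > 0) 2 * n / (2 * n - 1) * (1 - sum(p^2)) else NA
    keep <- !is.na(a1[, l])
    Ho[l] <- mean(a1[keep, l] != a2[keep, l])
  }
  fisOf <- function(m1, m2) {
    bc <- rowSums(vapply(seq_len(L),
                         function(l) .wcWithin(m1[, l], m2[, l]),
                         numeric(2)), na.rm = TRUE)
    if (bc[1] + bc[2] <= 0) return(NA_real_)
    unname(1 - bc[2] / (bc[1] + bc[2]))
  }
  fis <- fisOf(a1, a2)
  fisP <- NA_real_
  if (nPerm > 0 && !is.na(fis)) {
    fisP <- withSeed(seed, {
      hits <- 0L
      n <- nrow(a1)
      for (b in seq_len(nPerm)) {
        p1 <- a1; p2 <- a2
        for (l in seq_len(L)) {
          keep <- which(!is.na(a1[, l]))
          al <- sample(c(a1[keep, l], a2[keep, l]))
          p1[keep, l] <- al[seq_along(keep)]
          p2[keep, l] <- al[length(keep) + seq_along(keep)]
        }
        if (fisOf(p1, p2) >= fis) hits <- hits + 1L
      }
      (hits + 1) / (nPerm + 1)
    })
  }
  list(pop = pop, n = sum(sel), A = mean(A), Arich = mean(Ar),
       He = mean(He, na.rm = TRUE), Ho = mean(Ho, na.rm = TRUE),
       Fis = fis, FisP = fisP, g = g)
}
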