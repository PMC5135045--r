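# Accessors and show methods for the core classes.

#' Number of habitat cells
#' @param x a [HabitatGrid-class]
#' @return integer count of habitat cells
#' @export
nCells <- function(x) nrow(x@cells)

#' Habitat cell table
#' @param x a [HabitatGrid-class]
#' @return data.frame with `cell_id`, centroid `lon`/`lat` and grid indices
#' @export
habitatCells <- function(x) x@cells

#' Land/sea mask
#' @param x a [HabitatGrid-class] or [VelocityFieldSeries-class]
#' @return logical matrix `[lon, lat]`, `TRUE` = sea
#' @export
seaMask <- function(x) x@seaMask

#' Grid resolution in degrees
#' @param x a [HabitatGrid-class]
#' @export
gridResolution <- function(x) x@resolution

#' Connectivity probabilities
#' @param x a [ConnectivityMatrix-class]
#' @return numeric matrix of paired probabilities
#' @export
connProbabilities <- function(x) x@probabilities

#' @rdname connProbabilities
#' @export
connYear <- function(x) x@year

#' @rdname connProbabilities
#' @export
connBehavior <- function(x) x@behavior

#' Number of individuals / loci in a genotype table
#' @param x a [GenotypeTable-class]
#' @export
nInd <- function(x) nrow(x@allele1)

#' @rdname nInd
#' @export
nLoci <- function(x) length(x@loci)

#' @rdname nInd
#' @export
lociNames <- function(x) x@loci

#' Population labels, one per individual
#' @param x a [GenotypeTable-class]
#' @export
popLabels <- function(x) as.character(x@ind$pop)

#' Individual metadata table
#' @param x a [GenotypeTable-class]
#' @export
indTable <- function(x) x@ind

#' Allele matrices of a genotype table
#' @param x a [GenotypeTable-class]
#' @param which 1 or 2, which homologue
#' @return integer matrix individuals x loci
#' @export
alleleMatrix <- function(x, which = 1) {
  stopifnot(which %in% c(1, 2))
  if (which == 1) x@allele1 else x@allele2
}

#' Subset a genotype table by individuals
#'
#' @param x a [GenotypeTable-class]
#' @param keep logical or integer index over individuals
#' @return a [GenotypeTable-class]
#' @export
subsetInd <- function(x, keep) {
  new("GenotypeTable",
    allele1 = x@allele1[keep, , drop = FALSE],
    allele2 = x@allele2[keep, , drop = FALSE],
    ind = x@ind[keep, , drop = FALSE],
    loci = x@loci)
}

#' Construct a genotype table
#'
#' @param allele1,allele2 integer matrices (individuals x loci), `NA` missing.
#' @param pop population label per individual.
#' @param id individual ids (default `ind_1..n`).
#' @param year optional year label per individual.
#' @param loci locus names (default `L1..p`).
#' @return a [GenotypeTable-class]
#' @export
genotypeTable <- function(allele1, allele2, pop, id = NULL, year = NA,
                          loci = NULL) {
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"
  n <- nrow(allele1)
  if (is.null(id)) id <- paste0("ind_", seq_len(n))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(allele1)))
  ind <- data.frame(id = as.character(id), pop = as.character(pop),
                    year = rep_len(year, n), stringsAsFactors = FALSE)
  dimnames(allele1) <- dimnames(allele2) <- list(ind$id, loci)
  new("GenotypeTable", allele1 = allele1, allele2 = allele2,
      ind = ind, loci = as.character(loci))
}

setMethod("show", "HabitatGrid", function(object) {
  cat("HabitatGrid:", length(object@lon), "x", length(object@lat),
      "grid at", object@resolution, "deg;",
      sum(object@seaMask), "sea cells;",
      nCells(object), "habitat cells\n")
})

setMethod("show", "VelocityFieldSeries", function(object) {
  d <- dim(object@u)
  cat("VelocityFieldSeries:", d[1], "x", d[2], "grid,",
      d[3], "layers (", paste(object@layers, collapse = "/"), "m ),",
      d[4], "daily snapshots\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", nrow(object@probabilities), "cells; year =",
      object@year, "; behavior =", object@behavior,
      "; denominator =", object@denominator, "\n")
  cat("  mean retention (diagonal):",
      signif(mean(diag(object@probabilities)), 4), "\n")
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nInd(object), "individuals,", nLoci(object),
      "loci,", length(unique(popLabels(object))), "populations\n")
})
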