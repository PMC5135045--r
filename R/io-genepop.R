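# GENEPOP reader/writer: 2- and 3-digit allele dialects, case-insensitive
# "Pop" separators, tolerant of trailing whitespace; 00/000 codes mean
# missing.

#' Write a genotype table in GENEPOP format
#'
#' @param gt a [GenotypeTable-class].
#' @param path output file path.
#' @param digits allele code width, 2 or 3 (default 3).
#' @param title first header line.
#' @return `path`, invisibly
#' @export
writeGenepop <- function(gt, path, digits = 3, title = "larvaConn export") {
  stopifnot(digits %in% c(2, 3))
  if (any(c(gt@allele1, gt@allele2) >= 10^digits, na.rm = TRUE))
    stop("allele codes too large for ", digits, "-digit format")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(lociNames(gt), con)
  fmt <- paste0("%0", digits, "d%0", digits, "d")
  popf <- popLabels(gt)
  for (p in unique(popf)) {
    writeLines("Pop", con)
    for (i in which(popf == p)) {
      a1 <- gt@allele1[i, ]; a2 <- gt@allele2[i, ]
      g <- sprintf(fmt, ifelse(is.na(a1), 0L, a1), ifelse(is.na(a2), 0L, a2))
      writeLines(paste0(indTable(gt)$id[i], " ,  ", paste(g, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a GENEPOP file
#'
#' Population labels are taken from the id of each block's last individual
#' (the GENEPOP convention) unless ids are unique, in which case blocks
#' are labelled `pop1..k`. The allele-code width (2 or 3 digits) is
#' auto-detected from the genotype field length.
#'
#' @param path GENEPOP file path.
#' @return a [GenotypeTable-class]
#' @export
readGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  if (length(lines) < 3) stop("parse error: file too short")
  isPop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  firstPop <- which(isPop)[1]
  if (is.na(firstPop)) stop("parse error: no Pop separator found")
  lociLines <- lines[2:(firstPop - 1)]
  # loci may be one per line or comma-separated on one line
  loci <- trimws(unlist(strsplit(lociLines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  popIdx <- which(isPop)
  a1 <- NULL; a2 <- NULL; ids <- character(0); pops <- character(0)
  popNo <- 0L
  for (p in seq_along(popIdx)) {
    from <- popIdx[p] + 1L
    to <- if (p < length(popIdx)) popIdx[p + 1L] - 1L else length(lines)
    b <- if (from > to) integer(0) else seq(from, to)
    b <- b[nzchar(trimws(lines[b]))]
    popNo <- popNo + 1L
    if (length(b) == 0) stop("parse error: empty Pop block ", popNo)
    for (ln in b) {
      parts <- strsplit(lines[ln], ",")[[1]]
      if (length(parts) < 2)
        stop("parse error at line ", ln, ": missing ',' id separator")
      id <- trimws(parts[1])
      gfields <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                          "\\s+")[[1]]
      if (length(gfields) != L)
        stop("parse error at line ", ln, ": expected ", L,
             " genotypes, found ", length(gfields))
      w <- nchar(gfields[1])
      if (!w %in% c(4, 6) || any(nchar(gfields) != w))
        stop("parse error at line ", ln, ": ragged genotype codes")
      d <- w / 2
      x1 <- as.integer(substr(gfields, 1, d))
      x2 <- as.integer(substr(gfields, d + 1, w))
      x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
      # a half-missing genotype is treated as fully missing
      miss <- is.na(x1) | is.na(x2)
      x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
      a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
      ids <- c(ids, id)
      pops <- c(pops, paste0("pop", popNo))
    }
  }
  genotypeTable(a1, a2, pop = pops, id = ids, loci = loci)
}
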