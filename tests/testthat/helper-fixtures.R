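# Fixture builders and independent oracles shared across test files.

# GenotypeMatrix from a plain dosage matrix (variants x samples).
makeGm <- function(calls, chrom = "chr1", pos = NULL, ref = "A", alt = "G") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(pos)) pos <- seq_len(nrow(calls)) * 100L
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("P%02d", seq_len(ncol(calls)))
  GenotypeMatrix(calls, data.frame(
    chrom = chrom, pos = pos, vid = sprintf("v%03d", seq_len(nrow(calls))),
    ref = ref, alt = alt, stringsAsFactors = FALSE))
}

# Cross manifest over samples of a GenotypeMatrix; detects defaults to TRUE.
makeCrosses <- function(founders, references, qtlName = "qtl1",
                        detects = TRUE) {
  n <- length(founders)
  cm <- data.frame(cross_id = sprintf("c%02d", seq_len(n)),
                   founder_id = founders, reference_id = references,
                   stringsAsFactors = FALSE)
  cm$detects <- lapply(rep_len(detects, n), function(d)
    stats::setNames(d, qtlName))
  cm
}

# Random dosage matrix with missingness and optional hets.
randomGm <- function(nVar, nSam, missRate = 0.1, hetRate = 0) {
  calls <- matrix(sample(c(0L, 2L), nVar * nSam, replace = TRUE), nVar, nSam)
  if (hetRate > 0)
    calls[runif(nVar * nSam) < hetRate] <- 1L
  if (missRate > 0)
    calls[runif(nVar * nSam) < missRate] <- NA_integer_
  makeGm(calls)
}

# Independent nested-loop recount of the Ho index (no vectorisation shared
# with the implementation).
hoOracle <- function(gm, crosses, qtlName, missingPolicy = "adjust",
                     hetPolicy = "uninformative") {
  calls <- dosages(gm)
  det <- vapply(crosses$detects, function(d) isTRUE(d[[qtlName]]),
                logical(1))
  crosses <- crosses[det, , drop = FALSE]
  ho <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    nPoly <- 0L; nInf <- 0L
    for (cc in seq_len(nrow(crosses))) {
      f <- calls[i, crosses$founder_id[cc]]
      r <- calls[i, crosses$reference_id[cc]]
      usable <- !is.na(f) && !is.na(r)
      if (usable && hetPolicy == "uninformative")
        usable <- f != 1L && r != 1L
      if (usable) {
        nInf <- nInf + 1L
        if (f != r) nPoly <- nPoly + 1L
      }
    }
    ho[i] <- if (missingPolicy == "adjust") {
      if (nInf > 0) nPoly / nInf else NA_real_
    } else nPoly / nrow(crosses)
  }
  ho
}

# Normal-equations least squares with classic t-test, the oracle for
# assocScan on small instances.
normalEqOracle <- function(X, y) {
  XtX <- t(X) %*% X
  betas <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% betas
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- betas / se
  list(beta = betas[2], se = se[2], stat = tval[2],
       p = 2 * pt(-abs(tval[2]), df))
}

# Mean pairwise difference at one site by full pair enumeration.
sitePiOracle <- function(altCount, refCount) {
  haps <- c(rep(1L, altCount), rep(0L, refCount))
  n <- length(haps)
  if (n < 2) return(NA_real_)
  tot <- 0L; npair <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + (haps[i] != haps[j])
    npair <- npair + 1L
  }
  tot / npair
}

# Average pairwise difference per bp over a window by brute force, handling
# per-site missingness pairwise (inbred coding, hets dropped).
windowPiOracle <- function(calls, span) {
  ns <- ncol(calls)
  total <- 0
  for (v in seq_len(nrow(calls))) {
    haps <- calls[v, ]
    haps[haps == 1L] <- NA_integer_
    ok <- which(!is.na(haps))
    if (length(ok) < 2) next
    diffs <- 0L; npair <- 0L
    for (i in seq_along(ok)[-length(ok)]) for (j in (i + 1):length(ok)) {
      diffs <- diffs + (haps[ok[i]] != haps[ok[j]])
      npair <- npair + 1L
    }
    total <- total + diffs / npair
  }
  unname(total / span)
}

# Write a small VCF literal for reader tests.
writeVcfText <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcfHeader <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
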