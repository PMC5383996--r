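# Run code with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Allele frequencies in the phenotype tails
#'
#' Splits the panel into a high tail and a low tail of `ceiling(f * n)`
#' samples each by extreme trait performance (ties broken by stable input
#' order) and reports, per variant, the alternate-allele frequency among
#' non-missing calls in each tail. These are the `p_H` and `p_L` driving the
#' tail-selection power estimator.
#'
#' @param samples sample table (data.frame with `sample_id`, `phenotype`,
#'   `subpopulation`); samples with missing phenotype are excluded.
#' @param gm a [GenotypeMatrix-class]
#' @param tailFraction tail size as a fraction of usable samples (default
#'   0.05, the cutoff retained after comparing 0.05/0.10/0.15).
#' @param group optional subpopulation label; the panel is restricted to that
#'   subgroup before tail selection.
#' @return data.frame per variant: `vid`, `p_H`, `p_L`, `n_H`, `n_L`
#'   (non-missing tail calls); frequencies `NA` where a tail has no calls
#' @export
tailAlleleFreqs <- function(samples, gm, tailFraction = 0.05, group = NULL) {
  stopifnot(tailFraction > 0, tailFraction < 0.5)
  if (!is.null(group)) {
    if (!group %in% samples$subpopulation)
      stop("unknown subpopulation '", group, "'")
    samples <- samples[!is.na(samples$subpopulation) &
                         samples$subpopulation == group, , drop = FALSE]
  }
  samples <- samples[!is.na(samples$phenotype) &
                       samples$sample_id %in% sampleIds(gm), , drop = FALSE]
  n <- nrow(samples)
  size <- ceiling(tailFraction * n)
  if (size < 1 || n < 2 * size)
    stop("not enough phenotyped samples (", n, ") for two tails of ", size)
  ordHigh <- order(-samples$phenotype)   # stable for ties
  ordLow <- order(samples$phenotype)
  highIds <- samples$sample_id[ordHigh[seq_len(size)]]
  lowIds <- samples$sample_id[ordLow[seq_len(size)]]
  freq <- function(ids) {
    calls <- dosages(gm)[, ids, drop = FALSE]
    nm <- rowSums(!is.na(calls))
    f <- rowSums(calls, na.rm = TRUE) / (2 * nm)
    f[nm == 0] <- NA_real_
    list(f = unname(f), n = unname(nm))
  }
  fh <- freq(highIds); fl <- freq(lowIds)
  data.frame(vid = variantIds(gm), p_H = fh$f, p_L = fl$f,
             n_H = fh$n, n_L = fl$n, stringsAsFactors = FALSE)
}

#' Tail-selection power of the Ho scan
#'
#' The probability that a randomly drawn high-tail x low-tail parent pair is
#' polymorphic at a SNP with tail allele frequencies `pH` and `pL`:
#' `pH * (1 - pL) + (1 - pH) * pL`. It is 1 exactly when the tails are fixed
#' for opposite alleles and 0 when both tails are fixed for the same allele.
#'
#' @param pH,pL allele frequencies in the high and low tails, in `[0, 1]`;
#'   vectors recycle.
#' @return numeric vector of power values in `[0, 1]`
#' @export
tailPower <- function(pH, pL) {
  if (any(pH < 0 | pH > 1 | pL < 0 | pL > 1, na.rm = TRUE))
    stop("tail allele frequencies must lie in [0, 1]")
  pH * (1 - pL) + (1 - pH) * pL
}

#' MAF versus tail power across the panel
#'
#' For each variant and each requested group (the full panel and/or
#' subpopulations), reports the panel MAF alongside the tail-selection power,
#' sorted by MAF within group — the design curve showing how minor allele
#' frequency limits the chance that extreme-phenotype parents segregate at a
#' SNP. A Spearman rank correlation between MAF and power per group is
#' attached as attribute `"trend"`.
#'
#' @param samples sample table
#' @param gm a [GenotypeMatrix-class]
#' @param tailFraction tail size fraction (default 0.05)
#' @param groups character vector of group labels; `"full"` means the whole
#'   panel, any other value a subpopulation. Default: full panel plus every
#'   subpopulation present.
#' @return data.frame: `vid`, `group`, `maf`, `p_H`, `p_L`, `power`, sorted
#'   by MAF within group; attribute `"trend"` holds per-group rank
#'   correlations
#' @export
mafPowerSweep <- function(samples, gm, tailFraction = 0.05, groups = NULL) {
  if (is.null(groups))
    groups <- c("full",
                sort(unique(stats::na.omit(samples$subpopulation))))
  maf <- minorAlleleFreq(gm)
  out <- lapply(groups, function(g) {
    tf <- tailAlleleFreqs(samples, gm, tailFraction,
                          group = if (g == "full") NULL else g)
    data.frame(vid = tf$vid, group = g, maf = maf,
               p_H = tf$p_H, p_L = tf$p_L,
               power = tailPower(tf$p_H, tf$p_L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$group, groups), out$maf), , drop = FALSE]
  rownames(out) <- NULL
  trend <- vapply(groups, function(g) {
    d <- out[out$group == g & !is.na(out$power) & !is.na(out$maf), ]
    if (nrow(d) < 3) return(NA_real_)
    stats::cor(d$maf, d$power, method = "spearman")
  }, numeric(1))
  attr(out, "trend") <- trend
  out
}

#' Monte-Carlo power of detecting the functional variant with N crosses
#'
#' Splits the panel into group A (homozygous alternate at the functional
#' variant) and group a (homozygous reference; heterozygotes belong to
#' neither), then repeatedly draws N parents from each group, pairs them into
#' N crosses all flagged as detecting the QTL, computes the Ho index over the
#' region variants, and scores a replicate as a success only when the set of
#' variants attaining the maximum Ho is exactly the functional variant — any
#' tie with a non-functional variant is a failure. Power is the success
#' fraction over `reps` replicates.
#'
#' @param gm a [GenotypeMatrix-class]
#' @param functionalVid id of the functional variant (must be in `gm`)
#' @param region optional `"chrom:start-end"` string or data.frame row; `NULL`
#'   scans all variants in `gm`.
#' @param N number of crosses per replicate
#' @param reps Monte-Carlo replicates (default 1000)
#' @param seed RNG seed; the result is reproducible from it
#' @param replace draw parents with replacement (`TRUE`) or without (the
#'   default: an accession is used as at most one parent per replicate)
#' @return one-row data.frame: `N`, `reps`, `successes`, `power`
#' @export
crossNumberPower <- function(gm, functionalVid, region = NULL, N,
                             reps = 1000L, seed = NULL, replace = FALSE) {
  if (!is.null(region)) {
    r <- if (is.character(region)) parseRegion(region) else
      list(chrom = region$chrom[1], start = region$start[1],
           end = region$end[1])
    gm <- subsetRegion(gm, r$chrom, r$start, r$end)
  }
  fi <- match(functionalVid, variantIds(gm))
  if (is.na(fi))
    stop("functional variant '", functionalVid, "' not in region")
  calls <- dosages(gm)
  fdose <- calls[fi, ]
  grpA <- which(!is.na(fdose) & fdose == 2L)
  grpa <- which(!is.na(fdose) & fdose == 0L)
  if (!replace && (length(grpA) < N || length(grpa) < N))
    stop("group sizes (A = ", length(grpA), ", a = ", length(grpa),
         ") must both be >= N = ", N, " for sampling without replacement")
  if (length(grpA) < 1 || length(grpa) < 1)
    stop("both functional-allele groups must be non-empty")

  successes <- .withSeed(seed, {
    s <- 0L
    for (r in seq_len(reps)) {
      ia <- sample(grpA, N, replace = replace)
      ib <- sample(grpa, N, replace = replace)
      fd <- calls[, ia, drop = FALSE]
      rf <- calls[, ib, drop = FALSE]
      usable <- !is.na(fd) & !is.na(rf) & fd != 1L & rf != 1L
      nInf <- rowSums(usable)
      ho <- rowSums(usable & fd != rf) / nInf
      ho[nInf == 0] <- NA_real_
      mx <- max(ho, na.rm = TRUE)
      if (!is.na(ho[fi]) && ho[fi] == mx &&
          sum(ho == mx, na.rm = TRUE) == 1L)
        s <- s + 1L
    }
    s
  })
  data.frame(N = N, reps = reps, successes = successes,
             power = successes / reps)
}

#' Power curve over a range of cross numbers
#'
#' Runs [crossNumberPower()] for each N in `NValues`, deriving a per-N
#' substream from the base seed so the curve is reproducible and entries are
#' independent. The smallest N reaching power >= `powerGoal` is attached as
#' attribute `"N_required"` (`NA` if never reached).
#'
#' @inheritParams crossNumberPower
#' @param NValues cross numbers to evaluate (default 2 to 50)
#' @param powerGoal design goal for the reported required N (default 0.95)
#' @return data.frame with one row per N: `N`, `reps`, `successes`, `power`
#' @export
crossNumberCurve <- function(gm, functionalVid, region = NULL,
                             NValues = 2:50, reps = 1000L, seed = NULL,
                             replace = FALSE, powerGoal = 0.95) {
  rows <- lapply(seq_along(NValues), function(j) {
    sub <- if (is.null(seed)) NULL else (as.integer(seed) + 7919L * j) %%
      2147483647L
    crossNumberPower(gm, functionalVid, region, NValues[j], reps,
                     seed = sub, replace = replace)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  hit <- which(out$power >= powerGoal)
  attr(out, "N_required") <- if (length(hit)) out$N[min(hit)] else NA_integer_
  out
}
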