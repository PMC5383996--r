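#' Population-structure covariates by principal components
#'
#' Computes per-sample principal-component scores from the dosage matrix to
#' use as structure (Q) covariates in the structure-corrected association
#' model. Missing dosages are mean-imputed per variant and each variant is
#' centered; scores are deterministic up to component sign, which is fixed by
#' making the largest-magnitude loading of each component positive.
#'
#' @param gm a [GenotypeMatrix-class] with at least two polymorphic variants.
#' @param k number of components; must be below `min(n_samples, n_variants)`.
#'   Defaults to 3, a common choice for structured crop panels.
#' @return data.frame with column `sample_id` and columns `PC1..PCk`
#' @export
computePcaCovariates <- function(gm, k = 3L) {
  n <- nSamples(gm); m <- nVariants(gm)
  if (k >= min(n, m))
    stop("k = ", k, " must be smaller than min(n_samples, n_variants) = ",
         min(n, m))
  calls <- dosages(gm)
  mu <- rowMeans(calls, na.rm = TRUE)
  poly <- which(!is.na(mu) & apply(calls, 1, stats::var, na.rm = TRUE) > 0)
  if (length(poly) < 2) stop("need at least 2 polymorphic variants for PCA")
  X <- calls[poly, , drop = FALSE]
  mu <- mu[poly]
  X[is.na(X)] <- mu[row(X)[is.na(X)]]
  X <- X - mu                     # center per variant
  pc <- stats::prcomp(t(X), center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {        # fix sign: largest-|loading| positive
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  out <- data.frame(sample_id = sampleIds(gm), scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("sample_id", paste0("PC", seq_len(k)))
  out
}

#' Per-variant association scan in a candidate region
#'
#' Fits, per variant, `trait = intercept + beta * dosage` (naive LM) or
#' `trait = intercept + beta * dosage + sum_j gamma_j Q_j` (GLM with
#' structure covariates) by least squares, with a two-sided t test on `beta`
#' at `n_used - (2 + k)` degrees of freedom. Samples with missing phenotype,
#' or missing genotype at a given variant, are dropped for that variant only
#' (per-variant complete cases).
#'
#' @param y named numeric phenotype vector (names = sample ids), or a sample
#'   table from [readSampleTable()].
#' @param gm a [GenotypeMatrix-class]
#' @param Q optional structure covariates: a data.frame with `sample_id` plus
#'   numeric columns (as from [computePcaCovariates()]), or a numeric matrix
#'   with rownames. Required for `model = "GLM_Q"`; a zero-column Q reduces
#'   to the naive model.
#' @param model `"LM"` (naive) or `"GLM_Q"`.
#' @return data.frame per variant: `vid`, `chrom`, `pos`, `model`, `n_used`,
#'   `beta`, `se`, `stat`, `p`, `neglog10p`. Monomorphic variants and fits
#'   without positive degrees of freedom yield `NA` statistics.
#' @export
assocScan <- function(y, gm, Q = NULL, model = c("LM", "GLM_Q")) {
  model <- match.arg(model)
  if (is.data.frame(y)) {
    yy <- y$phenotype; names(yy) <- y$sample_id; y <- yy
  }
  ids <- sampleIds(gm)
  if (is.null(names(y))) {
    if (length(y) != length(ids))
      stop("unnamed phenotype vector must match sample count")
    names(y) <- ids
  }
  y <- y[ids]

  Qm <- NULL
  if (model == "GLM_Q") {
    if (is.null(Q)) stop("model GLM_Q requires structure covariates Q")
    if (is.data.frame(Q)) {
      rn <- Q$sample_id
      Qm <- as.matrix(Q[setdiff(names(Q), "sample_id")])
      rownames(Qm) <- rn
    } else {
      Qm <- as.matrix(Q)
    }
    if (ncol(Qm) > 0) {
      Qm <- Qm[ids, , drop = FALSE]
      if (any(!is.finite(Qm))) stop("non-finite values in Q covariates")
      if (qr(cbind(1, Qm))$rank < ncol(Qm) + 1)
        stop("collinear Q columns: covariate matrix is rank deficient")
    }
  }
  k <- if (is.null(Qm)) 0L else ncol(Qm)

  calls <- dosages(gm)
  m <- nVariants(gm)
  beta <- se <- stat <- p <- rep(NA_real_, m)
  nUsed <- integer(m)
  dfWarn <- FALSE
  for (i in seq_len(m)) {
    g <- calls[i, ]
    use <- !is.na(g) & !is.na(y)
    nUsed[i] <- sum(use)
    df <- nUsed[i] - (2L + k)
    if (nUsed[i] < 2L || stats::var(g[use]) == 0) next  # monomorphic: NA
    if (df <= 0L) { dfWarn <- TRUE; next }
    X <- cbind(1, g[use])
    if (k > 0) X <- cbind(X, Qm[use, , drop = FALSE])
    fit <- stats::lm.fit(X, y[use])
    if (fit$rank < ncol(X)) next   # dosage collinear with covariates
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df
    XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                 drop = FALSE])
    j2 <- which(fit$qr$pivot == 2L)  # dosage column after any pivoting
    beta[i] <- fit$coefficients[2]
    se[i] <- sqrt(sigma2 * XtXinv[j2, j2])
    if (se[i] == 0) {              # perfect fit: residual variance 0
      stat[i] <- Inf * sign(beta[i]); p[i] <- .Machine$double.xmin
    } else {
      stat[i] <- beta[i] / se[i]
      p[i] <- 2 * stats::pt(-abs(stat[i]), df)
      p[i] <- max(p[i], .Machine$double.xmin)  # keep p in (0, 1]
    }
  }
  if (dfWarn)
    warning("some variants had non-positive degrees of freedom; ",
            "results recorded as NA")
  v <- variantInfo(gm)
  data.frame(vid = v$vid, chrom = v$chrom, pos = v$pos, model = model,
             n_used = nUsed, beta = beta, se = se, stat = stat, p = p,
             neglog10p = -log10(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Bonferroni-corrected genome-wide significance threshold
#'
#' The cutoff on the -log10(p) scale for family-wise error `alpha` over
#' `nTests` SNPs: `-log10(alpha / nTests)`. With alpha 0.05 and the
#' 3.6-million-SNP scale of a resequenced rice panel this is about 7.9.
#'
#' @param alpha family-wise error rate, in (0, 1); default 0.05.
#' @param nTests number of tests (SNPs), at least 1.
#' @return list with `alpha`, `n_tests`, `neglog10_threshold`
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  list(alpha = alpha, n_tests = nTests,
       neglog10_threshold = -log10(alpha / nTests))
}
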