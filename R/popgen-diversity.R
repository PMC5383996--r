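#' Per-site nucleotide diversity with missing-data sample-size correction
#'
#' The unbiased average pairwise difference at a biallelic site with
#' `altCount` alternate and `refCount` reference haplotypes among the
#' non-missing calls: `2 * alt * ref / (n_s * (n_s - 1))` with
#' `n_s = alt + ref`. Missing data enter through `n_s`, the per-site
#' population-size adjustment. Sites with fewer than two non-missing
#' haplotypes are undefined (`NA`, counted but contributing 0 to windows).
#'
#' @param altCount,refCount non-negative haplotype counts; vectors recycle.
#' @return numeric vector of per-site pi values
#' @export
sitePi <- function(altCount, refCount) {
  if (any(altCount < 0 | refCount < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  ns <- altCount + refCount
  out <- ifelse(ns >= 2, 2 * altCount * refCount / (ns * (ns - 1)),
                NA_real_)
  as.numeric(out)
}

# Haplotype counts per variant under inbred coding: dosage 2 -> one alt
# haplotype, 0 -> one ref; hets are excluded unless includeHet, in which case
# an het accession contributes one of each.
.hapCounts <- function(calls, includeHet = FALSE) {
  alt <- rowSums(calls == 2L, na.rm = TRUE)
  ref <- rowSums(calls == 0L, na.rm = TRUE)
  if (includeHet) {
    h <- rowSums(calls == 1L, na.rm = TRUE)
    alt <- alt + h; ref <- ref + h
  }
  list(alt = alt, ref = ref)
}

#' Windowed nucleotide diversity per group
#'
#' Sums per-site pi over non-overlapping windows tiling the region from its
#' start in steps of `windowSpan` (default 10 kb) and divides by the window
#' span in bp, giving pi per base pair with invariant sites implicitly zero.
#' Each inbred accession contributes one haplotype (dosage 2 -> alternate,
#' 0 -> reference); heterozygous calls are excluded unless `includeHet`.
#' Missing calls reduce the per-site sample size (see [sitePi()]).
#'
#' @param gm a [GenotypeMatrix-class]
#' @param samples sample table with `sample_id` and `subpopulation`
#' @param groups character vector of subpopulation labels to report; use
#'   `"full"` for all samples. Default: every subpopulation present.
#' @param windowSpan window width in bp (default 10000)
#' @param region `"chrom:start-end"` string or data.frame row; `NULL` spans
#'   the observed variant range of the (single) chromosome in `gm`.
#' @param partialExact divide a short terminal window by its actual span
#'   instead of the full `windowSpan` (default `FALSE`)
#' @param includeHet count heterozygous accessions as one haplotype of each
#'   allele (default `FALSE`)
#' @return data.frame: `group`, `chrom`, `window_start`, `window_end`,
#'   `n_sites` (polymorphic sites with defined pi in the window),
#'   `pi_per_bp`
#' @export
windowedPi <- function(gm, samples, groups = NULL, windowSpan = 10000L,
                       region = NULL, partialExact = FALSE,
                       includeHet = FALSE) {
  stopifnot(windowSpan >= 1)
  if (is.null(groups))
    groups <- sort(unique(stats::na.omit(samples$subpopulation)))
  if (is.null(region)) {
    v <- variantInfo(gm)
    if (length(unique(v$chrom)) != 1)
      stop("supply a region when the matrix spans several chromosomes")
    region <- list(chrom = v$chrom[1], start = min(v$pos), end = max(v$pos))
  } else if (is.character(region)) {
    region <- parseRegion(region)
  } else {
    region <- list(chrom = region$chrom[1], start = region$start[1],
                   end = region$end[1])
  }
  gm <- subsetRegion(gm, region$chrom, region$start, region$end)
  pos <- variantInfo(gm)$pos
  starts <- seq.int(region$start, region$end, by = windowSpan)
  ends <- pmin(starts + windowSpan - 1L, region$end)

  out <- lapply(groups, function(g) {
    ids <- if (g == "full") samples$sample_id else
      samples$sample_id[!is.na(samples$subpopulation) &
                          samples$subpopulation == g]
    ids <- intersect(ids, sampleIds(gm))
    if (length(ids) == 0) stop("no genotyped samples in group '", g, "'")
    hc <- .hapCounts(dosages(gm)[, ids, drop = FALSE], includeHet)
    pi <- sitePi(hc$alt, hc$ref)
    win <- findInterval(pos, starts)
    sums <- vapply(seq_along(starts), function(w) {
      p <- pi[win == w]
      c(sum(p, na.rm = TRUE), sum(!is.na(p) & p > 0))
    }, numeric(2))
    span <- if (partialExact) (ends - starts + 1) else windowSpan
    data.frame(group = g, chrom = region$chrom, window_start = starts,
               window_end = ends, n_sites = as.integer(sums[2, ]),
               pi_per_bp = sums[1, ] / span, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gene-versus-flank diversity contrast
#'
#' Length-weighted mean pi over windows intersecting a gene interval versus
#' windows intersecting its flanks (`flankSpan` bp on each side), per group.
#' A ratio well below 1 in one group is the footprint expected of a selective
#' sweep around the gene in that group.
#'
#' @param piWindows output of [windowedPi()]
#' @param geneInterval list or one-row data.frame with `chrom`, `start`,
#'   `end` (1-based inclusive)
#' @param flankSpan flank width in bp on each side (default 20000)
#' @return data.frame per group: `group`, `pi_gene`, `pi_flank`, `ratio`
#'   (`NA` when `pi_flank` is 0)
#' @export
flankContrast <- function(piWindows, geneInterval, flankSpan = 20000L) {
  gi <- list(chrom = geneInterval$chrom[1],
             start = as.numeric(geneInterval$start[1]),
             end = as.numeric(geneInterval$end[1]))
  pw <- piWindows[piWindows$chrom == gi$chrom, , drop = FALSE]
  if (nrow(pw) == 0 || min(pw$window_start) > gi$start ||
      max(pw$window_end) < gi$end)
    stop("computed windows do not cover the gene interval")
  ov <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1) + 1)
  wg <- ov(pw$window_start, pw$window_end, gi$start, gi$end)
  wf <- ov(pw$window_start, pw$window_end, gi$start - flankSpan,
           gi$start - 1) +
    ov(pw$window_start, pw$window_end, gi$end + 1, gi$end + flankSpan)
  out <- lapply(unique(pw$group), function(g) {
    sel <- pw$group == g
    piG <- sum(pw$pi_per_bp[sel] * wg[sel]) / sum(wg[sel])
    piF <- if (sum(wf[sel]) > 0)
      sum(pw$pi_per_bp[sel] * wf[sel]) / sum(wf[sel]) else NA_real_
    data.frame(group = g, pi_gene = piG, pi_flank = piF,
               ratio = ifelse(!is.na(piF) && piF > 0, piG / piF, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
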