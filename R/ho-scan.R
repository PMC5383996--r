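#' Classify a founder/reference parent pair at one variant
#'
#' A cross is "heterozygous" at a SNP when its two inbred parents carry
#' different homozygous alleles, so the F1 would be heterozygous there.
#' Residual heterozygous parent calls violate the inbred-line assumption and
#' are uninformative under the default policy; the lenient policy compares
#' dosages directly (a het parent against a homozygote counts as polymorphic,
#' two equal hets as monomorphic). Any missing call is uninformative.
#'
#' @param founder,reference dosage codes (0/1/2/NA); vectors recycle.
#' @param hetPolicy `"uninformative"` (default) or `"lenient"`.
#' @return character vector in `{"POLYMORPHIC", "MONOMORPHIC", "UNINFORMATIVE"}`
#' @export
parentsDiffer <- function(founder, reference,
                          hetPolicy = c("uninformative", "lenient")) {
  hetPolicy <- match.arg(hetPolicy)
  n <- max(length(founder), length(reference))
  founder <- rep_len(founder, n)
  reference <- rep_len(reference, n)
  out <- rep("UNINFORMATIVE", n)
  usable <- !is.na(founder) & !is.na(reference)
  if (hetPolicy == "uninformative")
    usable <- usable & founder != 1L & reference != 1L
  out[usable & founder != reference] <- "POLYMORPHIC"
  out[usable & founder == reference] <- "MONOMORPHIC"
  out
}

#' Compute the Ho index across a region
#'
#' For each variant in the region, the Ho (observed heterozygosity per locus)
#' index is the fraction of crosses detecting the target QTL whose two
#' parents carry different alleles. At the causal variant every detecting
#' cross segregates, so Ho = 1; at loci unlinked to the trait the expectation
#' is about 0.5. Crosses not flagged as detecting `qtlName` are ignored
#' entirely.
#'
#' Missing parent calls make a cross uninformative at that variant. Under the
#' default `"adjust"` policy uninformative crosses drop out of both numerator
#' and denominator (Ho = n_polymorphic / n_informative, undefined when no
#' cross is informative); under `"strict"` the denominator stays the number
#' of detecting crosses (Ho = n_polymorphic / n_detecting), the literal
#' definition. All three counts are reported so either ratio can be
#' recomputed.
#'
#' @param gm a [GenotypeMatrix-class] holding at least the parent samples.
#' @param crosses cross manifest (data.frame with `cross_id`, `founder_id`,
#'   `reference_id`, `detects` list column), as from [readCrossManifest()] or
#'   [simulateCrosses()].
#' @param qtlName name of the target QTL in each cross's `detects` map.
#' @param region optional region: a `"chrom:start-end"` string or a one-row
#'   data.frame with `chrom`, `start`, `end` (e.g. a [readQtlIntervals()]
#'   row). `NULL` uses all variants in `gm`.
#' @param missingPolicy `"adjust"` (default) or `"strict"`.
#' @param hetPolicy passed to [parentsDiffer()].
#' @return data.frame (one row per region variant, genomic order) with
#'   columns `vid`, `chrom`, `pos`, `n_detecting`, `n_informative`,
#'   `n_polymorphic`, `ho` (`NA` where undefined under `"adjust"`).
#' @export
hoIndex <- function(gm, crosses, qtlName, region = NULL,
                    missingPolicy = c("adjust", "strict"),
                    hetPolicy = c("uninformative", "lenient")) {
  missingPolicy <- match.arg(missingPolicy)
  hetPolicy <- match.arg(hetPolicy)
  validateCrossManifest(crosses, gm)
  det <- vapply(crosses$detects, function(d) isTRUE(d[[qtlName]]), logical(1))
  if (!any(det))
    stop("no cross in the manifest detects QTL '", qtlName, "'")
  crosses <- crosses[det, , drop = FALSE]
  if (!is.null(region)) {
    r <- if (is.character(region)) parseRegion(region) else
      list(chrom = region$chrom[1], start = region$start[1],
           end = region$end[1])
    gm <- subsetRegion(gm, r$chrom, r$start, r$end)
  }
  if (nVariants(gm) == 0)
    stop("no variants in the requested region")

  calls <- dosages(gm)
  fd <- calls[, crosses$founder_id, drop = FALSE]
  rf <- calls[, crosses$reference_id, drop = FALSE]
  usable <- !is.na(fd) & !is.na(rf)
  if (hetPolicy == "uninformative") usable <- usable & fd != 1L & rf != 1L
  poly <- usable & fd != rf
  nInf <- rowSums(usable)
  nPoly <- rowSums(poly)
  nDet <- nrow(crosses)
  ho <- if (missingPolicy == "adjust") {
    ifelse(nInf > 0, nPoly / nInf, NA_real_)
  } else nPoly / nDet
  v <- variantInfo(gm)
  data.frame(vid = v$vid, chrom = v$chrom, pos = v$pos,
             n_detecting = nDet, n_informative = as.integer(nInf),
             n_polymorphic = as.integer(nPoly), ho = unname(ho),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Smooth a Ho profile with a moving window over consecutive SNPs
#'
#' Averages the raw Ho index over a moving window of `window` consecutive
#' SNPs, shifting one SNP at a time; a smoothed series of `m - window + 1`
#' values for `m` defined Ho values. Variants whose Ho is undefined are
#' skipped, so windows span consecutive *defined* values. Each smoothed value
#' is reported both at the window's leading variant and at the midpoint of
#' the window's first and last positions (`smoothed_pos`). Smoothing is for
#' display; candidate calling uses the raw index.
#'
#' @param profile a Ho profile from [hoIndex()]
#' @param window number of consecutive SNPs to average (default 2)
#' @return `profile` with added columns `ho_smoothed` and `smoothed_pos`
#'   (`NA` at series edges and undefined variants)
#' @export
smoothHo <- function(profile, window = 2L) {
  stopifnot(window >= 1)
  profile$ho_smoothed <- NA_real_
  profile$smoothed_pos <- NA_real_
  def <- which(!is.na(profile$ho))
  m <- length(def)
  if (m < window) {
    warning("fewer defined Ho values (", m, ") than window (", window,
            "); smoothed series is empty")
    return(profile)
  }
  for (j in seq_len(m - window + 1L)) {
    idx <- def[j:(j + window - 1L)]
    profile$ho_smoothed[def[j]] <- mean(profile$ho[idx])
    profile$smoothed_pos[def[j]] <-
      (profile$pos[idx[1]] + profile$pos[idx[window]]) / 2
  }
  profile
}

#' Call candidate clusters of high-Ho variants
#'
#' Finds maximal runs of consecutive region variants whose raw Ho index is at
#' least `hoMin` (within `tol`, guarding float storage of exact rationals).
#' Runs shorter than `minCluster` are discarded. Variants with undefined Ho
#' break runs and never join a cluster.
#'
#' @param profile a Ho profile from [hoIndex()]
#' @param hoMin minimum Ho to enter a cluster (default 1, the causal-variant
#'   expectation)
#' @param tol numeric tolerance on the threshold
#' @param minCluster minimum cluster size to report
#' @return data.frame, one row per cluster in genomic order: `cluster`,
#'   `chrom`, `first_pos`, `last_pos`, `size`, `max_ho`, `vids`
#'   (comma-separated member ids)
#' @export
callCandidates <- function(profile, hoMin = 1.0, tol = 1e-9, minCluster = 1L) {
  hit <- !is.na(profile$ho) & profile$ho >= hoMin - tol
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minCluster
  out <- lapply(which(keep), function(k) {
    idx <- starts[k]:ends[k]
    data.frame(chrom = profile$chrom[idx[1]],
               first_pos = profile$pos[idx[1]],
               last_pos = profile$pos[idx[length(idx)]],
               size = length(idx),
               max_ho = max(profile$ho[idx]),
               vids = paste(profile$vid[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), first_pos = integer(),
               last_pos = integer(), size = integer(), max_ho = numeric(),
               vids = character(), stringsAsFactors = FALSE)
  out <- out[order(out$first_pos), , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Assign candidate SNPs to gene features
#'
#' Classifies each candidate SNP against a GFF3 annotation: overlapping a CDS
#' -> `CDS`; a UTR -> `UTR`; inside a gene body but neither -> `intron`;
#' within `promoterUpstream` bp upstream of a gene start (strand-aware:
#' upstream of the start on `+`, of the end on `-`) -> `promoter`; otherwise
#' `intergenic` with the distance to the nearest gene.
#'
#' @param candidates data.frame with columns `vid`, `chrom`, `pos` (e.g. the
#'   members of a cluster from [callCandidates()], or a Ho profile subset).
#' @param gff3Path GFF3 annotation file.
#' @param promoterUpstream promoter window in bp upstream of the gene start
#'   (default 2000; the conventional promoter span, configurable).
#' @return data.frame: `vid`, `gene_id`, `feature_class`,
#'   `distance_to_feature` (0 for overlaps; bp to the gene start for
#'   promoters; bp to the nearest gene for intergenic SNPs)
#' @export
annotateCandidates <- function(candidates, gff3Path,
                               promoterUpstream = 2000L) {
  ann <- rtracklayer::import(gff3Path, format = "gff3")
  snps <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(candidates$pos, candidates$pos))
  genes <- ann[ann$type == "gene"]
  if (length(genes) == 0)
    stop("GFF3 contains no gene features")
  geneIds <- .featureGeneId(genes)
  res <- data.frame(vid = candidates$vid, gene_id = NA_character_,
                    feature_class = "intergenic",
                    distance_to_feature = NA_real_,
                    stringsAsFactors = FALSE)

  firstHit <- function(feats) {
    if (length(feats) == 0) return(rep(NA_integer_, length(snps)))
    GenomicRanges::findOverlaps(snps, feats, select = "first")
  }
  utr <- ann[ann$type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")]
  prom <- GenomicRanges::trim(
    GenomicRanges::promoters(genes, upstream = promoterUpstream,
                             downstream = 0))
  gstart <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                   GenomicRanges::end(genes), GenomicRanges::start(genes))

  # precedence: CDS > UTR > intron (gene body) > promoter > intergenic
  layers <- list(
    CDS = list(hits = firstHit(ann[ann$type == "CDS"]),
               ids = .featureGeneId(ann[ann$type == "CDS"])),
    UTR = list(hits = firstHit(utr), ids = .featureGeneId(utr)),
    intron = list(hits = firstHit(genes), ids = geneIds),
    promoter = list(hits = firstHit(prom), ids = geneIds))
  for (klass in names(layers)) {
    h <- layers[[klass]]$hits
    sel <- is.na(res$gene_id) & !is.na(h)
    if (!any(sel)) next
    res$gene_id[sel] <- layers[[klass]]$ids[h[sel]]
    res$feature_class[sel] <- klass
    res$distance_to_feature[sel] <-
      if (klass == "promoter") abs(candidates$pos[sel] - gstart[h[sel]]) else 0
  }

  inter <- which(res$feature_class == "intergenic")
  if (length(inter)) {
    near <- GenomicRanges::distanceToNearest(snps[inter], genes)
    res$gene_id[inter][S4Vectors::queryHits(near)] <-
      geneIds[S4Vectors::subjectHits(near)]
    res$distance_to_feature[inter][S4Vectors::queryHits(near)] <-
      S4Vectors::mcols(near)$distance
  }
  res
}

.featureGeneId <- function(gr) {
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  if ("Parent" %in% names(md)) {
    par <- vapply(md$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, "")
    id <- ifelse(is.na(id) | gr$type != "gene", par, id)
  }
  sub("^(gene:|transcript:)", "", id)
}

#' Intersect association signal with the Ho scan
#'
#' The fine-mapping step: candidate causal variants are those that are both
#' significantly associated with the trait in the candidate region and have a
#' Ho index of (at least) `hoMin` across the QTL-detecting crosses. Results
#' are ranked by Ho (descending), then p-value (ascending), then position.
#'
#' @param assoc association results from [assocScan()]
#' @param profile Ho profile from [hoIndex()] over the same variants
#' @param sigThreshold significance cutoff on the -log10(p) scale (e.g. from
#'   [bonferroniThreshold()])
#' @param hoMin minimum Ho index (default 1)
#' @return ranked data.frame with columns `vid`, `chrom`, `pos`, `ho`,
#'   `beta`, `p`, `neglog10p`
#' @export
holamapScan <- function(assoc, profile, sigThreshold, hoMin = 1.0) {
  if (nrow(assoc) != nrow(profile) || !all(assoc$vid == profile$vid)) {
    off <- union(setdiff(assoc$vid, profile$vid),
                 setdiff(profile$vid, assoc$vid))
    stop("association and Ho profile index different variants: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  keep <- !is.na(assoc$neglog10p) & assoc$neglog10p >= sigThreshold &
    !is.na(profile$ho) & profile$ho >= hoMin - 1e-9
  out <- data.frame(vid = profile$vid, chrom = profile$chrom,
                    pos = profile$pos, ho = profile$ho, beta = assoc$beta,
                    p = assoc$p, neglog10p = assoc$neglog10p,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$ho, out$p, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
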