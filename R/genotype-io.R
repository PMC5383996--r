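#' Read genotypes from a VCF file
#'
#' Reads the GT field of a VCF (v4.x) into a [GenotypeMatrix-class]. Diploid
#' genotypes map to allele dosage (`0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2,
#' `./.` -> missing); haploid calls map `0` -> 0 and `1` -> 2 (an inbred
#' accession carries one haplotype). Phased separators are accepted.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `"chrom:start-end"` restriction, 1-based inclusive.
#' @param splitMultiallelic if `FALSE` (default) a record with more than one
#'   alternate allele is an error naming its position; if `TRUE` each
#'   alternate allele becomes its own biallelic record and genotypes carrying
#'   a different alternate are set missing.
#' @return a `GenotypeMatrix`
#' @export
readGenotypeVcf <- function(path, region = NULL, splitMultiallelic = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(GenotypeMatrix(matrix(integer(), 0, 0), .emptyVariants()))
  if (ncol(vcf@gt) < 2 ||
      !"GT" %in% strsplit(vcf@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]])
    stop("VCF has no GT field in FORMAT; cannot derive dosages")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && !splitMultiallelic)
    stop("multi-allelic record(s) at ",
         paste(sprintf("%s:%s", fix$CHROM[multi], fix$POS[multi]),
               collapse = ", "),
         "; rerun with splitMultiallelic = TRUE or normalize upstream")

  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    rows[[r]] <- lapply(seq_along(alts), function(a) {
      list(chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
           vid = .variantId(fix$ID[r], fix$CHROM[r], fix$POS[r],
                            if (length(alts) > 1) a else 0L),
           ref = fix$REF[r], alt = alts[a],
           dose = .gtToDosage(gt[r, ], a))
    })
  }
  rows <- unlist(rows, recursive = FALSE)
  calls <- do.call(rbind, lapply(rows, `[[`, "dose"))
  colnames(calls) <- colnames(gt)
  variants <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 0L, "pos"),
    vid = vapply(rows, `[[`, "", "vid"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(calls, variants)
  if (!is.null(region)) {
    r <- parseRegion(region)
    gm <- subsetRegion(gm, r$chrom, r$start, r$end)
  }
  gm
}

.emptyVariants <- function() {
  data.frame(chrom = character(), pos = integer(), vid = character(),
             ref = character(), alt = character(), stringsAsFactors = FALSE)
}

.variantId <- function(id, chrom, pos, altIndex = 0L) {
  base <- if (is.na(id) || id == ".") sprintf("%s_%s", chrom, pos) else id
  if (altIndex > 0L) sprintf("%s_alt%d", base, altIndex) else base
}

# Map GT strings to dosage of alternate allele `altIndex`; genotypes carrying
# a different alternate allele become NA (relevant only when splitting).
.gtToDosage <- function(gts, altIndex = 1L) {
  alleles <- strsplit(gts, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == "." | is.na(a))) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (any(is.na(ai))) return(NA_integer_)
    if (any(ai != 0L & ai != altIndex)) return(NA_integer_)
    n <- sum(ai == altIndex)
    if (length(ai) == 1L) n * 2L else n  # haploid 0 -> 0, 1 -> 2
  }, integer(1))
}

#' Write a GenotypeMatrix as a minimal VCF v4.2
#'
#' Emits a plain-text VCF carrying only the GT field; dosages map back to
#' `0/0`, `0/1`, `1/1` and `./.` so that [readGenotypeVcf()] reproduces the
#' dosage matrix bit-exactly.
#'
#' @param x a `GenotypeMatrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeGenotypeVcf <- function(x, path) {
  stopifnot(methods::is(x, "GenotypeMatrix"))
  v <- variantInfo(x)
  gtCodes <- c("0/0", "0/1", "1/1")
  calls <- dosages(x)
  gt <- matrix("./.", nrow(calls), ncol(calls))
  ok <- !is.na(calls)
  gt[ok] <- gtCodes[calls[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIds(x)), collapse = "\t"))
  body <- if (nrow(v)) {
    paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Minor allele frequency per variant
#'
#' Computed from allele counts over non-missing calls only: with `k` alternate
#' alleles among `2n` non-missing haploid equivalents, MAF is
#' `min(k, 2n - k) / (2n)`. Variants with no non-missing call get `NA`.
#'
#' @param x a `GenotypeMatrix`
#' @return numeric vector, one MAF per variant
#' @export
minorAlleleFreq <- function(x) {
  calls <- dosages(x)
  nonmiss <- rowSums(!is.na(calls))
  altCount <- rowSums(calls, na.rm = TRUE)
  tot <- 2 * nonmiss
  maf <- pmin(altCount, tot - altCount) / tot
  maf[nonmiss == 0] <- NA_real_
  unname(maf)
}

#' Filter variants on missing rate and minor allele frequency
#'
#' Retains variants whose missing fraction is at most `maxMissing` and whose
#' MAF (over non-missing calls) is at least `minMaf`; both bounds are
#' inclusive. Variant order is preserved and the operation is idempotent.
#'
#' @param x a `GenotypeMatrix`
#' @param maxMissing maximum tolerated missing-call fraction, in `[0, 1)`.
#' @param minMaf minimum minor allele frequency, in `[0, 0.5]`.
#' @return the filtered `GenotypeMatrix`
#' @export
filterVariants <- function(x, maxMissing = 0.30, minMaf = 0.05) {
  stopifnot(maxMissing >= 0, maxMissing < 1, minMaf >= 0, minMaf <= 0.5)
  if (nVariants(x) == 0) return(x)
  calls <- dosages(x)
  missFrac <- rowMeans(is.na(calls))
  maf <- minorAlleleFreq(x)
  keep <- missFrac <= maxMissing & !is.na(maf) & maf >= minMaf
  x[which(keep), ]
}

#' Read a sample metadata table
#'
#' Tab-separated with header `sample_id`, `phenotype`, `subpopulation`.
#' Missing phenotype or subpopulation is the token `NA`; such samples are
#' kept but excluded downstream from association and tail selection.
#'
#' @param path TSV file
#' @return data.frame with the three columns, phenotype numeric
#' @export
readSampleTable <- function(path) {
  st <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("sample_id", "phenotype", "subpopulation")
  if (!all(need %in% names(st)))
    stop("samples table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(st$sample_id))
    stop("duplicate sample_id in ", path)
  st$phenotype <- as.numeric(st$phenotype)
  if (any(!is.finite(st$phenotype) & !is.na(st$phenotype)))
    stop("non-finite phenotype values in ", path)
  st$subpopulation <- as.character(st$subpopulation)
  st[need]
}

#' Read a cross manifest
#'
#' Tab-separated with header `cross_id`, `founder_id`, `reference_id`,
#' `detects`; the detects column holds semicolon-separated `qtlname=0|1`
#' pairs. When `gm` is supplied every parent id is checked against the
#' genotype samples.
#'
#' @param path TSV file
#' @param gm optional `GenotypeMatrix` to validate parent ids against
#' @return data.frame with columns `cross_id`, `founder_id`, `reference_id`
#'   and a `detects` list column of named logical vectors
#' @export
readCrossManifest <- function(path, gm = NULL) {
  cm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("cross_id", "founder_id", "reference_id", "detects")
  if (!all(need %in% names(cm)))
    stop("cross manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(cm$cross_id)) stop("duplicate cross_id in ", path)
  if (any(cm$founder_id == cm$reference_id))
    stop("founder_id equals reference_id for cross(es) ",
         paste(cm$cross_id[cm$founder_id == cm$reference_id], collapse = ", "))
  cm$detects <- lapply(cm$detects, .parseDetects)
  validateCrossManifest(cm, gm)
  cm
}

.parseDetects <- function(s) {
  pairs <- strsplit(trimws(strsplit(s, ";", fixed = TRUE)[[1]]), "=",
                    fixed = TRUE)
  bad <- vapply(pairs, length, 0L) != 2
  if (any(bad)) stop("malformed detects entry: '", s, "'")
  val <- vapply(pairs, function(p) p[2] == "1", logical(1))
  names(val) <- vapply(pairs, `[[`, "", 1)
  val
}

#' Check a cross manifest against genotype samples
#'
#' @param crosses manifest as from [readCrossManifest()]
#' @param gm a `GenotypeMatrix`, or `NULL` to skip the check
#' @return `crosses`, invisibly; errors name any unknown parent id
#' @export
validateCrossManifest <- function(crosses, gm = NULL) {
  if (!is.null(gm)) {
    ids <- unique(c(crosses$founder_id, crosses$reference_id))
    unknown <- setdiff(ids, sampleIds(gm))
    if (length(unknown))
      stop("cross manifest names sample(s) absent from genotypes: ",
           paste(unknown, collapse = ", "))
  }
  invisible(crosses)
}

#' Read a QTL interval table
#'
#' Tab-separated with header `qtl_name`, `chrom`, `start_1based`,
#' `end_1based`; coordinates 1-based and inclusive.
#'
#' @param path TSV file
#' @return data.frame with columns `qtl_name`, `chrom`, `start`, `end`
#' @export
readQtlIntervals <- function(path) {
  qt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("qtl_name", "chrom", "start_1based", "end_1based")
  if (!all(need %in% names(qt)))
    stop("QTL table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(qt$qtl_name)) stop("duplicate qtl_name in ", path)
  out <- data.frame(qtl_name = qt$qtl_name, chrom = qt$chrom,
                    start = as.integer(qt$start_1based),
                    end = as.integer(qt$end_1based),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("QTL interval with start > end")
  out
}
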