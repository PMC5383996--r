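#' GenotypeMatrix: variants-by-samples dosage calls
#'
#' The substrate of every computation in the package: a matrix of diploid
#' allele dosages (0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternate, `NA` = missing) with one row per biallelic variant and one
#' column per accession, plus a variant table giving chromosome, 1-based
#' position, identifier and the two alleles.
#'
#' @slot calls integer matrix, variants x samples, values in \{0, 1, 2, NA\};
#'   rownames are variant ids, colnames are sample ids.
#' @slot variants data.frame with columns `chrom`, `pos` (1-based), `vid`,
#'   `ref`, `alt`; one row per row of `calls`, positions sorted
#'   (non-decreasing) within each chromosome — records produced by splitting
#'   a multi-allelic site legitimately share a position.
#'
#' @examples
#' gm <- GenotypeMatrix(
#'   calls = matrix(c(0L, 2L, 1L, 0L, 2L, NA), nrow = 2,
#'                  dimnames = list(c("s1", "s2"), c("A", "B", "C"))),
#'   variants = data.frame(chrom = "chr1", pos = c(100L, 250L),
#'                         vid = c("s1", "s2"), ref = "A", alt = "G"))
#' gm
#' dosages(gm)
#' @aliases GenotypeMatrix-class
#' @export GenotypeMatrix
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         representation(calls = "matrix", variants = "data.frame"))

.DOSAGE_CODES <- c(0L, 1L, 2L)

setValidity("GenotypeMatrix", function(object) {
  v <- object@variants
  calls <- object@calls
  msgs <- character()
  need <- c("chrom", "pos", "vid", "ref", "alt")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns", paste(need, collapse = ", ")))
  if (nrow(v) != nrow(calls))
    msgs <- c(msgs, "nrow(variants) must equal nrow(calls)")
  if (!is.integer(calls) && !all(is.na(calls)))
    msgs <- c(msgs, "calls must be an integer matrix")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% .DOSAGE_CODES))
    msgs <- c(msgs, "calls must be 0, 1, 2 or NA")
  if (any(v$pos < 1L)) msgs <- c(msgs, "positions must be >= 1")
  if (any(v$ref == v$alt)) msgs <- c(msgs, "ref and alt alleles must differ")
  if (anyDuplicated(v$vid)) msgs <- c(msgs, "variant ids must be unique")
  if (!is.null(colnames(calls)) && anyDuplicated(colnames(calls)))
    msgs <- c(msgs, "sample ids must be unique")
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    # non-decreasing: split multi-allelic records legitimately share a position
    if (any(diff(p) < 0)) {
      msgs <- c(msgs, sprintf("positions not sorted on %s", ch))
      break
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of dosages (variants x samples); rownames are
#'   taken as variant ids if `variants$vid` is absent.
#' @param variants data.frame with columns `chrom`, `pos`, `vid`, `ref`, `alt`.
#' @return A validated [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, variants) {
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  if (is.null(rownames(calls))) rownames(calls) <- variants$vid
  methods::new("GenotypeMatrix", calls = calls, variants = variants)
}

#' @rdname GenotypeMatrix
#' @param object,x a `GenotypeMatrix`
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@calls)

#' @rdname GenotypeMatrix
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeMatrix
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @rdname GenotypeMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x@calls))

#' @rdname GenotypeMatrix
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname GenotypeMatrix
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x) x@variants$vid)

#' @rdname GenotypeMatrix
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname GenotypeMatrix
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x@calls))

#' @rdname GenotypeMatrix
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) ncol(x@calls))

#' @describeIn GenotypeMatrix subset by variant (i) and/or sample (j);
#'   indices, logicals or names.
#' @param i,j variant and sample subscripts
#' @param ... ignored
#' @param drop ignored (always `FALSE`)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  if (is.character(i)) i <- match(i, x@variants$vid)
  GenotypeMatrix(x@calls[i, j, drop = FALSE], x@variants[i, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@variants
  cat(sprintf("GenotypeMatrix: %d variants x %d samples\n",
              nrow(v), ncol(object@calls)))
  if (nrow(v)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(v$chrom), collapse = ", ")))
    nmiss <- sum(is.na(object@calls))
    cat(sprintf("  missing calls: %d (%.1f%%)\n", nmiss,
                100 * nmiss / length(object@calls)))
  }
  invisible(object)
})

#' Restrict a GenotypeMatrix to a genomic region
#'
#' Coordinates are 1-based and inclusive on both ends, matching VCF.
#'
#' @param x a `GenotypeMatrix`
#' @param chrom chromosome name
#' @param start,end 1-based inclusive bounds
#' @return the `GenotypeMatrix` restricted to variants inside the region
#' @export
subsetRegion <- function(x, chrom, start = 1L, end = .Machine$integer.max) {
  stopifnot(methods::is(x, "GenotypeMatrix"), start <= end)
  v <- x@variants
  keep <- v$chrom == chrom & v$pos >= start & v$pos <= end
  x[which(keep), ]
}

#' Parse a "chrom:start-end" region string
#'
#' @param region string like `"chr3:100-200"`; commas in numbers are allowed.
#' @return list with elements `chrom`, `start`, `end` (1-based inclusive)
#' @export
parseRegion <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4)
    stop("cannot parse region '", region, "'; expected chrom:start-end")
  list(chrom = m[2],
       start = as.integer(gsub(",", "", m[3])),
       end = as.integer(gsub(",", "", m[4])))
}
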