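#' Simulate a structured inbred diversity panel
#'
#' Generates a panel with the statistical structure the Ho scan assumes: two
#' or more subpopulations whose background allele frequencies diverge around
#' a shared ancestral frequency (a Balding-Nichols-style model, one
#' divergence parameter), inbred genotypes (dosage 0 or 2), one biallelic
#' causal SNP of configurable frequency and effect, and a phenotype that is
#' causal effect + subpopulation shift + Gaussian noise. The causal SNP's
#' frequency is held equal across subpopulations so the requested MAF is
#' realized up to binomial noise; divergence applies to background SNPs,
#' which is what creates structure confounding.
#'
#' @param nSamples number of accessions (default 500)
#' @param nSnps number of SNPs in the region (default 200)
#' @param nSubpops number of subpopulations (default 2)
#' @param divergence Balding-Nichols divergence of subpopulation frequencies
#'   from the ancestral frequency, in (0, 1) (default 0.15, within the range
#'   seen between domesticated rice subspecies)
#' @param causalMaf requested causal-allele frequency (default 0.3)
#' @param beta causal effect in trait units per alternate allele carried by
#'   an inbred accession, i.e. the hom-alt vs hom-ref phenotype gap
#'   (default 1.5)
#' @param subpopEffect phenotype shift per subpopulation step (default 1.0)
#' @param residualSd residual phenotype standard deviation (default 1.0)
#' @param missingRate per-call missing probability (default 0)
#' @param hetRate per-call residual-heterozygosity probability (default 0)
#' @param chrom chromosome name (default "chr1")
#' @param regionStart position of the first SNP (default 100000)
#' @param spacing distance between consecutive SNPs in bp (default 500)
#' @param causalIndex index of the causal SNP (default the middle SNP)
#' @param ldCopies number of SNPs adjacent to the causal one carrying its
#'   exact genotype column (perfect linkage; default 0). Exercises cluster
#'   calling; no recombination model is implied.
#' @param sweep optional list `(start, end, factor, group)` suppressing
#'   diversity in one subpopulation: within `start..end` the subpopulation
#'   `group`'s per-site heterozygosity is scaled by `factor`
#' @param seed RNG seed; the same seed reproduces the panel bit-exactly
#' @return list with elements `gm` ([GenotypeMatrix-class]), `samples`
#'   (sample table), `truth` (list recording the causal variant, effect
#'   sizes, realized MAF and heritability, subpopulation means, sweep and
#'   seed)
#' @export
simulatePanel <- function(nSamples = 500L, nSnps = 200L, nSubpops = 2L,
                          divergence = 0.15, causalMaf = 0.3, beta = 1.5,
                          subpopEffect = 1.0, residualSd = 1.0,
                          missingRate = 0, hetRate = 0, chrom = "chr1",
                          regionStart = 100000L, spacing = 500L,
                          causalIndex = NULL, ldCopies = 0L, sweep = NULL,
                          seed = NULL) {
  stopifnot(nSamples >= 2, nSnps >= 1, nSubpops >= 1,
            divergence > 0, divergence < 1,
            causalMaf > 0, causalMaf < 1, residualSd >= 0,
            missingRate >= 0, missingRate < 1, hetRate >= 0, hetRate < 1)
  if (causalMaf * nSamples < 1)
    stop("causalMaf ", causalMaf, " infeasible at nSamples = ", nSamples)
  if (is.null(causalIndex)) causalIndex <- max(1L, nSnps %/% 2L)
  stopifnot(causalIndex >= 1, causalIndex <= nSnps)

  .withSeed(seed, {
    subpop <- rep_len(seq_len(nSubpops), nSamples)
    subpop <- sort(subpop)
    pos <- regionStart + (seq_len(nSnps) - 1L) * as.integer(spacing)

    # ancestral frequencies; Balding-Nichols draw per subpopulation
    anc <- stats::runif(nSnps, 0.05, 0.95)
    anc[causalIndex] <- causalMaf
    a <- anc * (1 - divergence) / divergence
    b <- (1 - anc) * (1 - divergence) / divergence
    freq <- matrix(stats::rbeta(nSnps * nSubpops, a, b), nSnps, nSubpops)
    freq[causalIndex, ] <- causalMaf   # no divergence at the causal SNP

    if (!is.null(sweep)) {
      inSweep <- pos >= sweep$start & pos <= sweep$end
      g <- if (is.null(sweep$group)) 1L else sweep$group
      p <- freq[inSweep, g]
      hz <- sweep$factor * 2 * p * (1 - p)    # target heterozygosity
      pLow <- (1 - sqrt(pmax(0, 1 - 2 * hz))) / 2
      freq[inSweep, g] <- ifelse(p <= 0.5, pLow, 1 - pLow)
    }

    calls <- matrix(0L, nSnps, nSamples)
    for (j in seq_len(nSubpops)) {
      cols <- which(subpop == j)
      calls[, cols] <- 2L * stats::rbinom(nSnps * length(cols), 1L,
                                          freq[, j])
    }
    if (ldCopies > 0) {
      nbr <- setdiff(causalIndex + seq(-ldCopies, ldCopies), causalIndex)
      nbr <- nbr[nbr >= 1 & nbr <= nSnps]
      calls[nbr, ] <- rep(calls[causalIndex, ], each = length(nbr))
    }
    if (hetRate > 0) {
      het <- stats::runif(length(calls)) < hetRate
      calls[het] <- 1L
    }
    causalDose <- calls[causalIndex, ]   # phenotype uses pre-missing truth
    if (missingRate > 0)
      calls[stats::runif(length(calls)) < missingRate] <- NA_integer_

    gvalue <- beta * causalDose / 2
    svalue <- subpopEffect * (subpop - 1)
    phen <- gvalue + svalue + stats::rnorm(nSamples, 0, residualSd)

    sampleId <- sprintf("S%04d", seq_len(nSamples))
    vid <- sprintf("%s_%d", chrom, pos)
    colnames(calls) <- sampleId
    gm <- GenotypeMatrix(
      calls,
      data.frame(chrom = chrom, pos = pos, vid = vid, ref = "A", alt = "G",
                 stringsAsFactors = FALSE))
    samples <- data.frame(sample_id = sampleId, phenotype = phen,
                          subpopulation = paste0("pop", subpop),
                          stringsAsFactors = FALSE)
    mafBySub <- vapply(seq_len(nSubpops), function(j)
      mean(causalDose[subpop == j]) / 2, numeric(1))
    truth <- list(
      causal_vid = vid[causalIndex], causal_pos = pos[causalIndex],
      causal_index = causalIndex, beta = beta,
      causal_maf = min(mean(causalDose) / 2, 1 - mean(causalDose) / 2),
      causal_maf_by_subpop = mafBySub,
      subpop_means = subpopEffect * (seq_len(nSubpops) - 1),
      residual_sd = residualSd,
      heritability = if (stats::var(phen) > 0)
        stats::var(gvalue) / stats::var(phen) else NA_real_,
      region = list(chrom = chrom, start = min(pos), end = max(pos)),
      sweep = sweep, seed = seed)
    list(gm = gm, samples = samples, truth = truth)
  })
}

#' Simulate extreme-phenotype crosses from a panel
#'
#' Emulates the breeding design behind the Ho scan: founder parents are drawn
#' from the high-phenotype tail and crossed to reference parents from the
#' low tail. A cross is flagged as detecting the causal QTL exactly when its
#' two parents carry different homozygous alleles at the causal SNP (a cross
#' monomorphic there cannot map the QTL); full linkage mapping is not
#' simulated.
#'
#' @param panel output of [simulatePanel()]
#' @param nCrosses number of crosses (default 4)
#' @param tailFraction phenotype tail from which parents are drawn (default
#'   0.05; widened to `nCrosses` samples when the tail is smaller)
#' @param qtlName name for the simulated QTL (default "simQTL")
#' @param seed RNG seed for parent sampling and pairing
#' @return list with `crosses` (manifest data.frame with `cross_id`,
#'   `founder_id`, `reference_id`, `detects` list column) and `qtl` (one-row
#'   interval table covering the simulated region)
#' @export
simulateCrosses <- function(panel, nCrosses = 4L, tailFraction = 0.05,
                            qtlName = "simQTL", seed = NULL) {
  samples <- panel$samples
  ok <- !is.na(samples$phenotype)
  n <- sum(ok)
  size <- max(ceiling(tailFraction * n), nCrosses)
  if (2 * size > n)
    stop("nCrosses = ", nCrosses, " exceeds tail capacity at n = ", n)
  ordHigh <- order(-samples$phenotype[ok])
  ordLow <- order(samples$phenotype[ok])
  ids <- samples$sample_id[ok]
  .withSeed(seed, {
    founders <- sample(ids[ordHigh[seq_len(size)]], nCrosses)
    references <- sample(ids[ordLow[seq_len(size)]], nCrosses)
    cd <- dosages(panel$gm)[panel$truth$causal_index, ]
    status <- parentsDiffer(cd[founders], cd[references])
    crosses <- data.frame(
      cross_id = sprintf("cross%02d", seq_len(nCrosses)),
      founder_id = founders, reference_id = references,
      stringsAsFactors = FALSE)
    crosses$detects <- lapply(status == "POLYMORPHIC", function(d)
      stats::setNames(d, qtlName))
    qtl <- data.frame(qtl_name = qtlName,
                      chrom = panel$truth$region$chrom,
                      start = panel$truth$region$start,
                      end = panel$truth$region$end,
                      stringsAsFactors = FALSE)
    list(crosses = crosses, qtl = qtl)
  })
}

#' Mean Ho index at unlinked loci under repeated cross draws
#'
#' Simulates SNPs unlinked to the trait: at each locus every parent is an
#' independent homozygote with alternate-allele frequency `freq`. For each
#' replicate draw, `nCrosses` founder/reference pairs are formed and the Ho
#' index computed per SNP; the grand mean over SNPs and replicates estimates
#' the unlinked expectation: a random parent pair is polymorphic with
#' probability `2 * freq * (1 - freq)`, which is 0.5 at `freq = 0.5`.
#'
#' @param nSnps SNPs per replicate (default 1000)
#' @param nCrosses crosses per replicate (default 4)
#' @param reps replicate draws (default 100)
#' @param freq parental alternate-allele frequency (default 0.5)
#' @param seed RNG seed
#' @return list with `mean_ho` (grand mean), `rep_means` (per replicate),
#'   `n_snps`, `n_crosses`, `reps`
#' @export
simulateUnlinkedHo <- function(nSnps = 1000L, nCrosses = 4L, reps = 100L,
                               freq = 0.5, seed = NULL) {
  stopifnot(freq >= 0, freq <= 1)
  .withSeed(seed, {
    repMeans <- vapply(seq_len(reps), function(r) {
      fd <- matrix(2L * stats::rbinom(nSnps * nCrosses, 1L, freq),
                   nSnps, nCrosses)
      rf <- matrix(2L * stats::rbinom(nSnps * nCrosses, 1L, freq),
                   nSnps, nCrosses)
      mean(rowMeans(fd != rf))
    }, numeric(1))
    list(mean_ho = mean(repMeans), rep_means = repMeans,
         n_snps = nSnps, n_crosses = nCrosses, reps = reps)
  })
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Emits the standard file set consumed by the readers: `panel.vcf`,
#' `samples.tsv`, `crosses.tsv`, `qtl.tsv` and `truth.json`. Reading the VCF
#' back reproduces the dosage matrix bit-exactly.
#'
#' @param panel output of [simulatePanel()]
#' @param crosses optional output of [simulateCrosses()]
#' @param outDir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
writeFixture <- function(panel, crosses = NULL, outDir) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  paths <- c(vcf = file.path(outDir, "panel.vcf"),
             samples = file.path(outDir, "samples.tsv"),
             truth = file.path(outDir, "truth.json"))
  writeGenotypeVcf(panel$gm, paths[["vcf"]])
  utils::write.table(panel$samples, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(panel$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(crosses)) {
    paths[["crosses"]] <- file.path(outDir, "crosses.tsv")
    paths[["qtl"]] <- file.path(outDir, "qtl.tsv")
    cm <- crosses$crosses
    cm$detects <- vapply(cm$detects, function(d)
      paste(sprintf("%s=%d", names(d), as.integer(d)), collapse = ";"), "")
    utils::write.table(cm, paths[["crosses"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    qt <- data.frame(qtl_name = crosses$qtl$qtl_name,
                     chrom = crosses$qtl$chrom,
                     start_1based = crosses$qtl$start,
                     end_1based = crosses$qtl$end)
    utils::write.table(qt, paths[["qtl"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
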