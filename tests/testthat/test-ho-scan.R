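test_that("parent-pair classification follows the het and missing policies", {
  expect_equal(parentsDiffer(0L, 2L), "POLYMORPHIC")
  expect_equal(parentsDiffer(2L, 2L), "MONOMORPHIC")
  expect_equal(parentsDiffer(0L, 0L), "MONOMORPHIC")
  expect_equal(parentsDiffer(1L, 0L), "UNINFORMATIVE")  # het, default policy
  expect_equal(parentsDiffer(NA_integer_, 2L), "UNINFORMATIVE")
  expect_equal(parentsDiffer(1L, 0L, hetPolicy = "lenient"), "POLYMORPHIC")
  expect_equal(parentsDiffer(1L, 1L, hetPolicy = "lenient"), "MONOMORPHIC")
  # vectorised over pairs
  expect_equal(parentsDiffer(c(0L, 2L, 1L), c(2L, 2L, 0L)),
               c("POLYMORPHIC", "MONOMORPHIC", "UNINFORMATIVE"))
})

# 4 crosses over 8 parents; rows: causal-like (all polymorphic), monomorphic,
# half polymorphic, and one with a missing founder call.
.hoFixture <- function() {
  #           F1  F2  F3  F4  R1  R2  R3  R4
  calls <- rbind(
    c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L),   # ho = 1
    c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),   # ho = 0
    c(2L, 2L, 0L, 0L, 0L, 0L, 0L, 0L),   # ho = 0.5
    c(NA, 2L, 2L, 2L, 0L, 0L, 0L, 0L))   # 3/3 adjust, 3/4 strict
  colnames(calls) <- c(paste0("F", 1:4), paste0("R", 1:4))
  list(gm = makeGm(calls),
       crosses = makeCrosses(paste0("F", 1:4), paste0("R", 1:4)))
}

test_that("Ho index matches its definition under both missing policies", {
  fx <- .hoFixture()
  prof <- hoIndex(fx$gm, fx$crosses, "qtl1")
  expect_equal(prof$ho, c(1, 0, 0.5, 1))
  expect_equal(prof$n_detecting, rep(4L, 4))
  expect_equal(prof$n_informative, c(4L, 4L, 4L, 3L))
  expect_equal(prof$n_polymorphic, c(4L, 0L, 2L, 3L))
  strict <- hoIndex(fx$gm, fx$crosses, "qtl1", missingPolicy = "strict")
  expect_equal(strict$ho, c(1, 0, 0.5, 0.75))
})

test_that("crosses not detecting the QTL are ignored; none detecting errors", {
  fx <- .hoFixture()
  cr <- fx$crosses
  cr$detects[[4]] <- c(qtl1 = FALSE)
  prof <- hoIndex(fx$gm, cr, "qtl1")
  dropped <- hoIndex(fx$gm, cr[1:3, ], "qtl1")
  expect_identical(prof, dropped)
  cr$detects <- lapply(cr$detects, function(d) c(qtl1 = FALSE))
  expect_error(hoIndex(fx$gm, cr, "qtl1"), "no cross")
})

test_that("Ho equals a nested-loop recount on random instances", {
  set.seed(31)
  for (rep in 1:15) {
    nc <- sample(2:8, 1)
    gm <- randomGm(sample(10:50, 1), 2 * nc, missRate = 0.15,
                   hetRate = 0.1)
    ids <- sampleIds(gm)
    cr <- makeCrosses(ids[seq_len(nc)], ids[nc + seq_len(nc)],
                      detects = sample(c(TRUE, TRUE, FALSE), nc,
                                       replace = TRUE))
    if (!any(vapply(cr$detects, `[[`, TRUE, 1))) next
    for (pol in c("adjust", "strict")) {
      prof <- hoIndex(gm, cr, "qtl1", missingPolicy = pol)
      expect_equal(prof$ho, hoOracle(gm, cr, "qtl1", missingPolicy = pol))
    }
  }
})

test_that("Ho is invariant to cross order and to all-missing crosses", {
  fx <- .hoFixture()
  prof <- hoIndex(fx$gm, fx$crosses, "qtl1")
  perm <- hoIndex(fx$gm, fx$crosses[c(3, 1, 4, 2), ], "qtl1")
  expect_equal(prof$ho, perm$ho)
  # add a cross whose parents are missing at every variant
  calls <- cbind(dosages(fx$gm), F9 = NA_integer_, R9 = NA_integer_)
  gm2 <- makeGm(calls)
  cr2 <- rbind(fx$crosses, makeCrosses("F9", "R9"))
  expect_equal(hoIndex(gm2, cr2, "qtl1")$ho, prof$ho)
})

test_that("region restriction and undefined Ho handling work", {
  fx <- .hoFixture()
  prof <- hoIndex(fx$gm, fx$crosses, "qtl1", region = "chr1:200-300")
  expect_equal(prof$pos, c(200L, 300L))
  # all parents missing at one variant -> undefined under adjust
  calls <- dosages(fx$gm)
  calls[2, ] <- NA_integer_
  prof2 <- hoIndex(makeGm(calls), fx$crosses, "qtl1")
  expect_true(is.na(prof2$ho[2]))
  expect_error(hoIndex(fx$gm, fx$crosses, "qtl1", region = "chr9:1-10"),
               "no variants")
})

test_that("moving-window smoothing averages consecutive defined values", {
  prof <- data.frame(vid = paste0("v", 1:3), chrom = "chr1",
                     pos = c(100L, 200L, 300L), ho = c(1, 0, 1))
  sm <- smoothHo(prof, window = 2)
  expect_equal(sm$ho_smoothed, c(0.5, 0.5, NA))
  expect_equal(sm$smoothed_pos, c(150, 250, NA))
  # window 1 is the identity
  expect_equal(smoothHo(prof, window = 1)$ho_smoothed, prof$ho)
  # undefined values are skipped: window spans defined neighbours
  prof$ho <- c(1, NA, 1)
  sm <- smoothHo(prof, window = 2)
  expect_equal(sm$ho_smoothed, c(1, NA, NA))
  expect_equal(sm$smoothed_pos, c(200, NA, NA))  # midpoint of 100 and 300
  # fewer defined values than the window warns and leaves the series empty
  prof$ho <- c(1, NA, NA)
  expect_warning(sm <- smoothHo(prof, window = 2), "fewer")
  expect_true(all(is.na(sm$ho_smoothed)))
})

test_that("candidate clusters are maximal runs of Ho >= threshold", {
  prof <- data.frame(vid = sprintf("v%d", 1:7), chrom = "chr3",
                     pos = 100L * (1:7),
                     ho = c(0.5, 1, 1, 1, 1, 1, 0.25))
  cl <- callCandidates(prof)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 5L)
  expect_equal(cl$vids, "v2,v3,v4,v5,v6")
  expect_equal(cl$first_pos, 200L)
  expect_equal(cl$last_pos, 600L)
  # all below threshold -> empty
  prof$ho <- rep(0.9, 7)
  expect_equal(nrow(callCandidates(prof)), 0L)
  # runs broken by a low value -> two singletons
  prof3 <- data.frame(vid = c("a", "b", "c"), chrom = "chr1",
                      pos = c(1L, 2L, 3L), ho = c(1, 0, 1))
  cl3 <- callCandidates(prof3)
  expect_equal(cl3$vids, c("a", "c"))
  expect_equal(callCandidates(prof3, minCluster = 2)$size, integer(0))
  # float-storage tolerance: a value within 1e-9 of 1 still qualifies
  prof3$ho <- c(1 - 1e-12, 0, 1)
  expect_equal(nrow(callCandidates(prof3)), 2L)
})

test_that("candidate SNPs are assigned to gene features with precedence", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr3", "test", "gene", "10000", "12000", ".", "+", ".",
          "ID=geneA", sep = "\t"),
    paste("chr3", "test", "mRNA", "10000", "12000", ".", "+", ".",
          "ID=mrnaA;Parent=geneA", sep = "\t"),
    paste("chr3", "test", "five_prime_UTR", "10000", "10099", ".", "+", ".",
          "Parent=mrnaA", sep = "\t"),
    paste("chr3", "test", "CDS", "10100", "11000", ".", "+", ".",
          "Parent=mrnaA", sep = "\t"),
    paste("chr3", "test", "gene", "30000", "31000", ".", "-", ".",
          "ID=geneB", sep = "\t")), gff)
  snps <- data.frame(
    vid = c("prom", "cds", "utr", "intron", "inter", "promB"),
    chrom = "chr3",
    pos = c(9500L, 10500L, 10050L, 11500L, 21500L, 31400L))
  ann <- annotateCandidates(snps, gff)
  expect_equal(ann$feature_class,
               c("promoter", "CDS", "UTR", "intron", "intergenic",
                 "promoter"))
  expect_equal(ann$gene_id[1], "geneA")
  expect_equal(ann$distance_to_feature[1], 500)   # bp upstream of gene start
  # minus-strand promoter sits upstream of the gene end
  expect_equal(ann$gene_id[6], "geneB")
  expect_equal(ann$distance_to_feature[6], 400)
  # intergenic distance matches a brute-force nearest-gene scan
  expect_equal(ann$distance_to_feature[5],
               min(abs(21500 - c(10000, 12000, 30000, 31000))) - 1)
  # beyond the promoter window -> intergenic
  far <- annotateCandidates(
    data.frame(vid = "far", chrom = "chr3", pos = 7000L), gff)
  expect_equal(far$feature_class, "intergenic")
})

test_that("scan intersection keeps significant Ho-1 variants, ranked", {
  prof <- data.frame(vid = c("a", "b", "c", "d"), chrom = "chr1",
                     pos = 1:4 * 100L, ho = c(1, 1, 0.5, 1))
  assoc <- data.frame(vid = c("a", "b", "c", "d"),
                      beta = c(1, 2, 3, 4),
                      p = c(1e-6, 1e-9, 1e-12, 0.5),
                      neglog10p = c(6, 9, 12, log10(2)))
  hits <- holamapScan(assoc, prof, sigThreshold = 3)
  # d: Ho 1 but not significant; c: significant but Ho 0.5
  expect_equal(hits$vid, c("b", "a"))   # equal Ho, smaller p first
  expect_error(holamapScan(assoc[c(1, 3, 2, 4), ], prof, 3), "different")
})
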