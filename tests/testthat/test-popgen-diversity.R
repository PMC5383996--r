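test_that("per-site pi follows the unbiased pairwise estimator", {
  expect_equal(sitePi(1, 1), 1.0)
  expect_equal(sitePi(0, 5), 0)
  expect_equal(sitePi(2, 2), 2 * 4 / (4 * 3))
  expect_equal(sitePi(2, 1), 2 * 2 / (3 * 2))   # one sample missing
  expect_equal(sitePi(2, 2), sitePi(2, 1))      # the example coincidence
  expect_true(is.na(sitePi(1, 0)))              # n_s < 2 undefined
  expect_error(sitePi(-1, 3), "non-negative")
})

test_that("per-site pi equals full pair enumeration for all n_s <= 30", {
  for (ns in 2:30) {
    for (alt in 0:ns) {
      expect_equal(sitePi(alt, ns - alt), sitePiOracle(alt, ns - alt))
    }
  }
})

test_that("windowed pi tiles the region and matches the brute-force oracle", {
  # two accessions differing at exactly one site in a 10-kb window
  calls <- matrix(c(2L, 0L), 1, 2)
  gm <- makeGm(calls, pos = 5000L)
  samples <- data.frame(sample_id = sampleIds(gm), phenotype = 0,
                        subpopulation = "g")
  pw <- windowedPi(gm, samples, groups = "g",
                   region = "chr1:1-10000")
  expect_equal(pw$pi_per_bp, 1e-4)
  expect_equal(pw$window_start, 1L)
  expect_equal(pw$window_end, 10000L)

  # random 5-sample fixture vs pairwise-difference oracle, two windows
  set.seed(61)
  gm <- randomGm(40, 5, missRate = 0.2)
  v <- variantInfo(gm)   # positions 100..4000
  samples <- data.frame(sample_id = sampleIds(gm), phenotype = 0,
                        subpopulation = "g")
  pw <- windowedPi(gm, samples, groups = "g", windowSpan = 2000L,
                   region = "chr1:1-4000")
  expect_equal(nrow(pw), 2L)
  calls <- dosages(gm)
  w1 <- v$pos <= 2000
  expect_equal(pw$pi_per_bp[1], windowPiOracle(calls[w1, ], 2000))
  expect_equal(pw$pi_per_bp[2], windowPiOracle(calls[!w1, ], 2000))

  # a window with no variants reports zero
  pw0 <- windowedPi(gm, samples, groups = "g", windowSpan = 2000L,
                    region = "chr1:1-8000")
  expect_equal(pw0$pi_per_bp[3:4], c(0, 0))
  expect_equal(pw0$n_sites[3:4], c(0L, 0L))
})

test_that("windowed pi is invariant to sample order, region splits and allele swap", {
  set.seed(62)
  gm <- randomGm(60, 8, missRate = 0.15)
  samples <- data.frame(sample_id = sampleIds(gm), phenotype = 0,
                        subpopulation = "g")
  pw <- windowedPi(gm, samples, groups = "g", windowSpan = 1000L,
                   region = "chr1:1-6000")
  # sample order
  perm <- sample(nSamples(gm))
  pwPerm <- windowedPi(gm[, perm], samples, groups = "g",
                       windowSpan = 1000L, region = "chr1:1-6000")
  expect_equal(pw$pi_per_bp, pwPerm$pi_per_bp)
  # split the region, concatenate windows
  pwA <- windowedPi(gm, samples, groups = "g", windowSpan = 1000L,
                    region = "chr1:1-3000")
  pwB <- windowedPi(gm, samples, groups = "g", windowSpan = 1000L,
                    region = "chr1:3001-6000")
  expect_equal(pw$pi_per_bp, c(pwA$pi_per_bp, pwB$pi_per_bp))
  # global ref<->alt swap
  swapped <- dosages(gm)
  swapped[] <- 2L - swapped
  pwSwap <- windowedPi(makeGm(swapped), samples, groups = "g",
                       windowSpan = 1000L, region = "chr1:1-6000")
  expect_equal(pw$pi_per_bp, pwSwap$pi_per_bp)
})

test_that("flank contrast is a length-weighted window average", {
  pw <- data.frame(group = "g", chrom = "chr1",
                   window_start = seq(1L, 50001L, by = 10000L),
                   window_end = seq(10000L, 60000L, by = 10000L),
                   n_sites = 1L,
                   pi_per_bp = c(0.004, 0.004, 0.001, 0.001, 0.004, 0.004))
  gene <- list(chrom = "chr1", start = 20001L, end = 40000L)
  fc <- flankContrast(pw, gene, flankSpan = 20000L)
  expect_equal(fc$pi_gene, 0.001)
  expect_equal(fc$pi_flank, 0.004)
  expect_equal(fc$ratio, 0.25)
  # uniform diversity -> ratio 1
  pw$pi_per_bp <- 0.002
  expect_equal(flankContrast(pw, gene, flankSpan = 20000L)$ratio, 1)
  # gene outside the computed windows errors
  expect_error(flankContrast(pw, list(chrom = "chr1", start = 90000L,
                                      end = 95000L)), "cover")
})

test_that("a simulated sweep suppresses diversity in the swept group only", {
  panel <- simulatePanel(
    nSamples = 400, nSnps = 960, beta = 0, subpopEffect = 0,
    divergence = 0.1, spacing = 125L, regionStart = 1L,
    sweep = list(start = 40001L, end = 80000L, factor = 0.2, group = 1),
    seed = 63)
  pw <- windowedPi(panel$gm, panel$samples, groups = c("pop1", "pop2"),
                   windowSpan = 10000L, region = "chr1:1-120000")
  fc1 <- flankContrast(pw[pw$group == "pop1", ],
                       list(chrom = "chr1", start = 40001L, end = 80000L))
  fc2 <- flankContrast(pw[pw$group == "pop2", ],
                       list(chrom = "chr1", start = 40001L, end = 80000L))
  expect_gt(fc2$ratio, 0.7)            # unswept group keeps flat diversity
  # swept group reduced by the configured factor, within 20% relative
  expect_lt(abs(fc1$ratio - 0.2), 0.2 * 0.2)
})

test_that("heterozygote handling and unknown groups behave as documented", {
  calls <- matrix(c(2L, 0L, 1L), 1, 3)
  gm <- makeGm(calls, pos = 500L)
  samples <- data.frame(sample_id = sampleIds(gm), phenotype = 0,
                        subpopulation = "g")
  # het excluded by default: counts (1, 1)
  pw <- windowedPi(gm, samples, groups = "g", windowSpan = 1000L,
                   region = "chr1:1-1000")
  expect_equal(pw$pi_per_bp, sitePi(1, 1) / 1000)
  # het contributes one haplotype of each allele when included
  pwHet <- windowedPi(gm, samples, groups = "g", windowSpan = 1000L,
                      region = "chr1:1-1000", includeHet = TRUE)
  expect_equal(pwHet$pi_per_bp, sitePi(2, 2) / 1000)
  expect_error(windowedPi(gm, samples, groups = "nope"), "nope")
})
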