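test_that("the generator is deterministic and respects its design", {
  d <- smallDesign()
  s1 <- simulateCohort(d, seed = 5)
  s2 <- simulateCohort(d, seed = 5)
  expect_identical(tableValues(s1$microbes), tableValues(s2$microbes))
  expect_identical(tableValues(s1$metabolites), tableValues(s2$metabolites))
  expect_identical(s1$metadata, s2$metadata)

  s3 <- simulateCohort(d, seed = 6)
  expect_false(identical(tableValues(s1$microbes),
                         tableValues(s3$microbes)))

  n <- 3 * 4 * length(d@timepoints)
  expect_equal(dim(s1$microbes), c(n, 60L))
  expect_equal(dim(s1$metabolites), c(n, 80L))
  expect_identical(sort(unique(s1$metadata$group)),
                   sort(c("RC-Air", "HFHC-Air", "HFHC-IHC")))
  # opposing families are disjoint and planted pairs lie outside them
  tr <- s1$truth
  expect_length(intersect(tr@differentialMicrobes$numerator,
                          tr@differentialMicrobes$denominator), 0)
  expect_length(intersect(tr@plantedPairs$microbe,
                          unlist(tr@differentialMicrobes)), 0)

  expect_error(simulateCohort(cohortDesign(micePerGroup = 1)), "mice")
  expect_error(simulateCohort(cohortDesign(timepoints = c(12, 11))),
               "increasing")
})

test_that("rclr statistics are insensitive to a tenfold depth change", {
  d1 <- smallDesign()
  d10 <- smallDesign(depthMean = 30000)
  s1 <- simulateCohort(d1, seed = 8)
  s10 <- simulateCohort(d10, seed = 8)
  lrOf <- function(s) {
    lr <- featureSetLogRatio(s$microbes,
                             s$truth@differentialMicrobes$numerator,
                             s$truth@differentialMicrobes$denominator)
    ratioValues(lr)
  }
  v1 <- lrOf(s1); v10 <- lrOf(s10)
  shared <- intersect(names(v1), names(v10))
  expect_gt(cor(v1[shared], v10[shared]), 0.95)
  expect_lt(abs(mean(v1[shared]) - mean(v10[shared])), 0.15)
})

test_that("stronger latent factors strengthen the cross-omic log-ratio correlation", {
  # effectSize = 0 isolates the shared-factor channel: the family and
  # metabolite-class ratios then correlate only through latent axis 1
  rOf <- function(latentSD, seed) {
    s <- simulateCohort(smallDesign(latentSD = latentSD, effectSize = 0),
                        seed = seed)
    fam <- featureSetLogRatio(s$microbes,
                              s$truth@differentialMicrobes$denominator,
                              s$truth@differentialMicrobes$numerator)
    met <- featureSetLogRatio(s$metabolites,
                              s$truth@metaboliteSets$hfhcIhc,
                              s$truth@metaboliteSets$rc)
    logratioRegression(fam, met)$r
  }
  rs <- vapply(c(0.05, 0.3, 1), function(sd)
    mean(vapply(1:15, function(s) rOf(sd, 300 + s), numeric(1))), numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("effect_size = 0 removes group information (null calibration)", {
  rej <- vapply(1:40, function(s) {
    sim <- simulateCohort(smallDesign(effectSize = 0,
                                      timepoints = seq(10, 16, by = 2)),
                          seed = 400 + s)
    mic <- suppressMessages(rarefy(sim$microbes, depth = 2000,
                                   seed = s))
    ord <- rpca(mic, rank = 2, maxIter = 60)
    meta <- sim$metadata[match(sampleIDs(mic), sim$metadata$sample_id), ]
    pv <- permanova(ord$distances, meta$group, permutations = 99, seed = s)
    pv$p.value <= 0.05
  }, logical(1))
  # binomial 95% band around 0.05 for 40 replicates
  expect_lte(sum(rej), qbinom(0.975, 40, 0.05) + 1)
})

test_that("large effects make the family ratio significant at study end", {
  hits <- vapply(1:25, function(s) {
    sim <- simulateCohort(smallDesign(micePerGroup = 8), seed = 500 + s)
    tr <- sim$truth
    lr <- featureSetLogRatio(sim$microbes, tr@differentialMicrobes$numerator,
                             tr@differentialMicrobes$denominator)
    meta <- sim$metadata
    lastAges <- tail(sort(unique(meta$host_age)), 2)
    keep <- names(ratioValues(lr)) %in%
      meta$sample_id[meta$host_age %in% lastAges]
    v <- ratioValues(lr)[keep]
    g <- meta$group[match(names(v), meta$sample_id)]
    res <- pairwiseMannWhitney(v, g)
    row <- res$group1 == "HFHC-IHC" & res$group2 == "RC-Air"
    res$p_adj[row] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fixtures round-trip and record the planted truth", {
  dirp <- file.path(tempdir(), "cohort-fixture")
  sim <- simulateCohort(smallDesign(), seed = 3)
  writeFixture(sim, dirp)
  mic <- readFeatureTable(file.path(dirp, "microbes.tsv"))
  expect_identical(tableValues(mic), tableValues(sim$microbes))
  met <- readFeatureTable(file.path(dirp, "metabolites.tsv"),
                          kind = "intensities")
  expect_equal(tableValues(met), tableValues(sim$metabolites),
               tolerance = 1e-3)
  meta <- readSampleMetadata(file.path(dirp, "metadata.tsv"))
  expect_identical(meta$sample_id, sim$metadata$sample_id)

  tr <- readTruth(file.path(dirp, "truth.json"))
  expect_identical(tr@differentialMicrobes$numerator,
                   sim$truth@differentialMicrobes$numerator)
  expect_identical(tr@plantedPairs$metabolite,
                   sim$truth@plantedPairs$metabolite)
  expect_equal(tr@latentFactors, sim$truth@latentFactors,
               tolerance = 1e-5)
})
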