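test_that("TSV feature tables parse, reject bad input, and round-trip", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t5\t0", "s2\t2\t7", "s3\t0\t1"), tf)
  ft <- readFeatureTable(tf, orientation = "samples")
  expect_s4_class(ft, "FeatureTable")
  expect_equal(dim(ft), c(3L, 2L))
  expect_equal(unname(tableValues(ft)),
               matrix(c(5, 0, 2, 7, 0, 1), nrow = 3, byrow = TRUE))

  writeLines(c("sample_id\tf1\tf2", "s1\t5\t-1"), tf)
  expect_error(readFeatureTable(tf, orientation = "samples"), "negative value")

  writeLines(c("sample_id\tf1\tf2", "s1\t5\t2", "s2\t3"), tf)
  expect_error(readFeatureTable(tf, orientation = "samples"), "TSV")

  writeLines(c("sample_id\tf1\tf2", "s1\t5\t1", "s1\t2\t7", "s3\t1\t1"), tf)
  expect_error(readFeatureTable(tf, orientation = "samples"), "duplicated")

  # bit-stable round trip for counts, both orientations
  ft <- randomCounts(seed = 5)
  for (o in c("samples", "features")) {
    writeFeatureTable(ft, tf, orientation = o)
    back <- readFeatureTable(tf, orientation = o)
    expect_identical(tableValues(back), tableValues(ft))
  }
})

test_that("BIOM round trip is value-stable", {
  ft <- randomCounts(n = 6, p = 5, seed = 9)
  tf <- tempfile(fileext = ".biom")
  writeFeatureTable(ft, tf, format = "biom")
  back <- readFeatureTable(tf, format = "biom")
  expect_equal(tableValues(back)[sampleIDs(ft), featureIDs(ft)],
               tableValues(ft))
})

test_that("alignTables restricts to shared samples in t1 order", {
  ft <- randomCounts(n = 6, p = 4, seed = 2)
  meta <- data.frame(sample_id = sampleIDs(ft),
                     host_subject_id = rep(c("m1", "m2"), 3),
                     host_age = rep(10:12, each = 2),
                     diet = "RC", exposure = "Air",
                     stringsAsFactors = FALSE)
  # t2 with shuffled sample order is reordered to match t1
  perm <- c(4, 2, 6, 1, 3, 5)
  t2 <- ft[perm, ]
  al <- alignTables(ft, t2, meta)
  expect_identical(sampleIDs(al$t1), sampleIDs(ft))
  expect_identical(sampleIDs(al$t2), sampleIDs(ft))
  expect_identical(al$meta$sample_id, sampleIDs(ft))
  expect_identical(tableValues(al$t2), tableValues(ft))

  # fewer than 3 shared samples errors
  t3 <- ft[1:2, ]
  expect_error(alignTables(t3, ft[3:6, ], meta), ">= 3 shared")
})

test_that("rarefaction hits depth exactly, drops shallow samples, and is unbiased", {
  m <- rbind(s1 = c(600, 300, 100), s2 = c(50, 30, 20), s3 = c(500, 400, 100))
  colnames(m) <- paste0("f", 1:3)
  ft <- FeatureTable(m, "counts")
  suppressMessages(r <- rarefy(ft, depth = 150, seed = 1))
  expect_equal(unname(rowSums(tableValues(r))), c(150, 150))
  expect_identical(droppedSamples(r), "s2")
  expect_identical(featureIDs(r), featureIDs(ft))

  # a sample already at depth is returned unchanged
  exact <- FeatureTable(rbind(s1 = c(f1 = 60, f2 = 40)), "counts")
  expect_equal(tableValues(rarefy(exact, depth = 100, seed = 1)),
               tableValues(exact))

  expect_error(rarefy(ft, depth = 0), "positive")
  expect_error(rarefy(FeatureTable(m, "intensities"), 100), "counts")

  # expectation: mean rarefied count tracks depth * proportion
  tot <- c(600, 300, 100)
  draws <- vapply(1:1000, function(s)
    tableValues(rarefy(ft[1, ], depth = 100, seed = s))[1, 1], numeric(1))
  p <- tot[1] / sum(tot)
  se <- sqrt(100 * p * (1 - p) * (sum(tot) - 100) / (sum(tot) - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - 100 * p), 3 * se)

  # reproducible under a fixed seed
  expect_identical(tableValues(rarefy(ft, depth = 100, seed = 7)),
                   tableValues(rarefy(ft, depth = 100, seed = 7)))
})

test_that("metadata validation derives and checks the group label", {
  meta <- data.frame(sample_id = c("a", "b"), host_subject_id = c("m1", "m2"),
                     host_age = c(10, 11), diet = c("RC", "HFHC"),
                     exposure = c("Air", "IHC"), stringsAsFactors = FALSE)
  out <- validateSampleMetadata(meta)
  expect_identical(out$group, c("RC-Air", "HFHC-IHC"))
  meta$group <- c("RC-Air", "HFHC-Air")
  expect_error(validateSampleMetadata(meta), "inconsistent")
  meta$group <- NULL
  meta$diet[1] <- "keto"
  expect_error(validateSampleMetadata(meta), "diet")
})
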