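test_that("shift augmentation hits the target size and the shift bound", {
  tr <- extractSample(refTable(), "ct_d4")
  ds <- augmentShift(tr, augmentationConfig(nTotal = 4000, maxShift = 30,
                                            seed = 1))
  expect_identical(nrow(ds@features), 4000L)
  expect_setequal(unique(ds@labels), unique(peakLabels(tr)))
  ## every instance lies within maxShift (per axis) of a source peak
  ## carrying the same label -- brute-force scan
  X <- peakFeatures(tr); lab <- peakLabels(tr)
  ok <- vapply(seq_len(nrow(ds@features)), function(i) {
    src <- X[lab == ds@labels[i], , drop = FALSE]
    any(abs(src[, 1] - ds@features[i, 1]) <= 30 + 1e-9 &
        abs(src[, 2] - ds@features[i, 2]) <= 30 + 1e-9)
  }, TRUE)
  expect_true(all(ok))
  ## class balance: equalized counts
  counts <- table(ds@labels)
  expect_lte(max(counts) / min(counts), 1.1)
})

test_that("zero shift reproduces source peaks exactly", {
  ps <- separableProblem(seed = 3)$train
  ds <- augmentShift(ps, augmentationConfig(nTotal = 50, maxShift = 0,
                                            seed = 2))
  X <- peakFeatures(ps); lab <- peakLabels(ps)
  for (i in seq_len(nrow(ds@features))) {
    src <- X[lab == ds@labels[i], , drop = FALSE]
    expect_true(any(src[, 1] == ds@features[i, 1] &
                    src[, 2] == ds@features[i, 2]))
  }
})

test_that("one-peak augmentation stays bounded and sized", {
  ds <- augmentShift(onePeakSet(), augmentationConfig(nTotal = 10))
  expect_identical(nrow(ds@features), 10L)
  expect_true(all(abs(ds@features[, 1] - 1000) <= 30))
  expect_true(all(abs(ds@features[, 2] - 800) <= 30))
  expect_error(augmentShift(new("PeakSet", sample = "e",
                                peaks = data.frame(metabolite = character(),
                                                   f2 = numeric(),
                                                   f1 = numeric())),
                            augmentationConfig()), "empty")
})

test_that("augmentation is deterministic under a fixed seed", {
  tr <- extractSample(refTable(), "ct_d4")
  cfg <- augmentationConfig(nTotal = 500, seed = 11)
  expect_identical(augmentShift(tr, cfg), augmentShift(tr, cfg))
  expect_identical(augmentNoise(tr, 5, cfg), augmentNoise(tr, 5, cfg))
  expect_false(identical(
    augmentShift(tr, cfg)@features,
    augmentShift(tr, augmentationConfig(nTotal = 500, seed = 12))@features))
})

test_that("noise augmentation matches its nominal distribution", {
  ## sigma = 0: exact copies
  tr <- separableProblem(seed = 5)$train
  ds0 <- augmentNoise(tr, 5, augmentationConfig(noiseSigma = 0))
  expect_identical(nrow(ds0@features), 5L * nPeaks(tr))
  expect_true(all(ds0@features ==
                  peakFeatures(tr)[rep(seq_len(nPeaks(tr)), each = 5), ]))
  ## counts: 69 source peaks x 10
  ct <- extractSample(refTable(), "ct_d4")
  expect_identical(nrow(augmentNoise(ct, 10)@features), 690L)
  ## Monte-Carlo: per-axis sample sd close to the nominal sigma
  ds <- augmentNoise(onePeakSet(f2 = 3000, f1 = 3000), 10000,
                     augmentationConfig(noiseSigma = 10, seed = 1))
  expect_lt(abs(sd(ds@features[, 1] - 3000) - 10), 0.3)
  expect_lt(abs(sd(ds@features[, 2] - 3000) - 10), 0.3)
})

test_that("generated features never leave the spectral window", {
  edge <- onePeakSet(f2 = 10, f1 = spectralWidthHz() - 10)
  ds <- augmentShift(edge, augmentationConfig(nTotal = 500, seed = 4))
  expect_true(all(ds@features >= 0 & ds@features <= spectralWidthHz()))
  dn <- augmentNoise(edge, 500, augmentationConfig(noiseSigma = 20,
                                                   seed = 4))
  expect_true(all(dn@features >= 0 & dn@features <= spectralWidthHz()))
})

test_that("synthetic tables respect class structure and separation", {
  syn <- makeSyntheticTable(5, 2, 3, minSeparation = 200, seed = 7)
  novel <- grepl("^novel", peakLabels(syn$test))
  expect_identical(sum(novel), 6L)                # 2 novel classes x 3
  expect_false(any(grepl("^novel", peakLabels(syn$train))))
  ## single class, single peak, no separation constraint
  tiny <- makeSyntheticTable(1, 0, 1, minSeparation = 0, seed = 1)
  expect_identical(nPeaks(tiny$train), 1L)
  expect_identical(nPeaks(tiny$test), 1L)
  ## exhaustive pairwise check of center separation
  syn3 <- makeSyntheticTable(10, 3, 2, minSeparation = 150, seed = 3)
  d <- as.matrix(dist(syn3$centers))
  expect_true(all(d[upper.tri(d)] >= 150))
  ## determinism
  expect_identical(makeSyntheticTable(4, 2, 2, 300, seed = 9),
                   makeSyntheticTable(4, 2, 2, 300, seed = 9))
  ## geometric infeasibility
  expect_error(makeSyntheticTable(300, 0, 1, minSeparation = 2000,
                                  seed = 1),
               "infeasibility")
})

test_that("datasets serialize with a provenance column", {
  ds <- augmentShift(onePeakSet(), augmentationConfig(nTotal = 5))
  df <- as.data.frame(ds)
  expect_identical(names(df),
                   c("metabolite", "f2_hz", "f1_hz", "provenance"))
  expect_true(all(df$provenance == "train"))
})
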