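test_that("kernel matrix matches the closed-form rbf and is symmetric", {
  cfg <- kernelConfig(sigma = 5)
  expect_equal(kernelMatrix(matrix(c(1, 2), 1), matrix(c(1, 2), 1), cfg),
               matrix(1))
  X <- cbind(c(0, 3, 10), c(0, 4, 2))
  K <- kernelMatrix(X, X, cfg)
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_true(all(eigen(K, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  ## two points at distance 5, sigma 5 -> exp(-25 / 50)
  expect_equal(K[1, 2], exp(-25 / (2 * 25)))
  expect_error(kernelMatrix(X, cbind(1, 2, 3), cfg), "dimensionality")
})

test_that("kernel matrix agrees with an independent implementation", {
  skip_if_not_installed("kernlab")
  set.seed(1)
  X <- matrix(runif(40, 0, 100), ncol = 2)
  sigma <- 12
  ours <- kernelMatrix(X, X, kernelConfig(sigma = sigma))
  ref <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = 1 / (2 * sigma^2)),
                               X)
  expect_equal(ours, unclass(ref), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("KNFST collapses separable classes onto distinct targets", {
  syn <- separableProblem(nKnown = 3, minSep = 500, seed = 1)
  m <- fitKNFST(syn$augmented)
  expect_identical(length(classLabels(m)), 3L)
  expect_lte(ncol(m@targets), 3L)
  ## within-class projected spread far below the between-target spread
  expect_lt(m@nullRatio, 1e-6)
  ## training instances score ~0 against their own class
  D <- knfstDistances(m, syn$augmented@features)
  own <- D[cbind(seq_len(nrow(D)),
                 match(syn$augmented@labels, classLabels(m)))]
  spread <- min(dist(t(m@targets)))
  expect_lt(max(own), 1e-4 * spread)
  ## targets pairwise distinct
  expect_gt(min(dist(t(m@targets))), 0)
})

test_that("two single-instance classes give a one-dimensional projection", {
  ds <- new("PeakDataset",
            features = rbind(c(1000, 1000), c(2000, 2500)),
            labels = c("a", "b"), provenance = "train")
  m <- fitKNFST(ds, kernelConfig(sigma = 300))
  expect_identical(ncol(m@coef), 1L)
  expect_identical(ncol(m@targets), 2L)
  expect_gt(dist(t(m@targets))[1], 0)
})

test_that("single-class training is rejected with an explanation", {
  ds <- new("PeakDataset", features = rbind(c(1, 2), c(3, 4)),
            labels = c("a", "a"), provenance = "train")
  expect_error(fitKNFST(ds), "at least 2 classes")
})

test_that("fitting the reference sample yields 24 targets in <= 23 dims", {
  tr <- extractSample(refTable(), "ct_d4")
  ds <- augmentShift(tr, augmentationConfig(nTotal = 720, seed = 2))
  m <- fitKNFST(ds)
  expect_identical(ncol(m@targets), 24L)
  expect_lte(ncol(m@coef), 23L)
  ## an isolated metabolite perturbed by 5 Hz is still recognized
  nad <- peakFeatures(tr)[peakLabels(tr) == "NAD+", , drop = FALSE]
  expect_identical(classifyPeaks(m, nad + 5), "NAD+")
})

test_that("distances are invariant to instance order and class names", {
  syn <- separableProblem(nKnown = 4, minSep = 400, seed = 6, nTotal = 200)
  ds <- syn$augmented
  q <- matrix(runif(20, 500, 6000), ncol = 2)
  m1 <- fitKNFST(ds)
  set.seed(99); perm <- sample(nrow(ds@features))
  ds2 <- new("PeakDataset", features = ds@features[perm, ],
             labels = ds@labels[perm], provenance = "train")
  m2 <- fitKNFST(ds2)
  expect_lt(max(abs(knfstDistances(m1, q) - knfstDistances(m2, q))), 1e-8)
  ## relabeling classes permutes columns but not the distances
  ds3 <- ds
  ds3@labels <- paste0("zz_", ds@labels)
  m3 <- fitKNFST(ds3)
  expect_lt(max(abs(unname(knfstDistances(m1, q)) -
                    unname(knfstDistances(m3, q)))), 1e-8)
})

test_that("novel synthetic classes score above known validation scores", {
  for (seed in 1:5) {
    syn <- makeSyntheticTable(6, 2, 2, minSeparation = 250, seed = seed,
                              multipletSpread = 0)
    ds <- augmentShift(syn$train, augmentationConfig(nTotal = 360,
                                                     seed = seed))
    m <- fitKNFST(ds)
    val <- augmentNoise(syn$train, 20,
                        augmentationConfig(noiseSigma = 10, seed = seed))
    valScores <- noveltyScores(m, val@features)
    novelX <- peakFeatures(syn$test)[grepl("^novel",
                                           peakLabels(syn$test)), ,
                                     drop = FALSE]
    expect_gt(min(noveltyScores(m, novelX)),
              quantile(valScores, 0.99))
  }
})
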