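test_that("min-error threshold scans midpoints exhaustively", {
  thr <- selectThreshold(c(1, 2, 3), c(10, 11), direction = "greater")
  expect_equal(thr@value, 6.5)
  expect_identical(thr@provenance$validationError, 0)
  ## interleaved scores: one validation error is unavoidable
  thr2 <- selectThreshold(c(1, 3), c(2), direction = "greater")
  expect_identical(thr2@provenance$validationError, 1)
  ## independent oracle: enumerate every real threshold on a fine grid
  ## and confirm no candidate beats the returned validation error
  known <- c(0.5, 1.9, 2.2, 4.0); pnov <- c(1.5, 3.0, 6.0)
  thr3 <- selectThreshold(known, pnov, direction = "greater")
  gridErr <- vapply(seq(0, 7, by = 0.01), function(t)
    sum(known > t) + sum(pnov <= t), 0)
  expect_identical(thr3@provenance$validationError, min(gridErr))
  ## density direction flips the sides
  thr4 <- selectThreshold(c(10, 11), c(1, 2), direction = "less")
  expect_identical(thr4@provenance$validationError, 0)
  expect_true(thr4@value > 2 && thr4@value < 10)
})

test_that("quantile strategy covers the no-pseudo-novel case", {
  thr <- selectThreshold(c(1, 2, 3), direction = "greater",
                         strategy = "quantile", q = 100)
  expect_equal(thr@value, 3)
  thrd <- selectThreshold(c(5, 6, 7), direction = "less",
                          strategy = "quantile", q = 0)
  expect_equal(thrd@value, 5)
  expect_error(selectThreshold(numeric(0), direction = "greater"),
               "non-empty")
})

test_that("open-set predictions split by the threshold", {
  syn <- separableProblem(nKnown = 4, nNovel = 2, minSep = 400, seed = 2,
                          nTotal = 200)
  m <- fitKNFST(syn$augmented)
  val <- augmentNoise(syn$train, 10, augmentationConfig(noiseSigma = 10,
                                                        seed = 2))
  thr <- selectThreshold(noveltyScores(m, val@features),
                         direction = "greater", strategy = "quantile",
                         q = 100)
  ## a training peak replayed as test keeps its own label
  p <- predictOpenSet(m, thr, syn$train)
  expect_identical(p@results$predicted, peakLabels(syn$train))
  expect_false(any(p@results$novel))
  ## direction mismatch is refused
  bad <- new("NoveltyThreshold", value = 1, direction = "less",
             provenance = list())
  expect_error(predictOpenSet(m, bad, syn$train), "direction")
})

test_that("error metrics reproduce the printed-table arithmetic", {
  known <- c("A", "B")
  cases <- list(list(Fn = 0, Fp = 0, Fe = 2, Nn = 16, N = 76, tot = 2.6),
                list(Fn = 0, Fp = 0, Fe = 3, Nn = 16, N = 83, tot = 3.6),
                list(Fn = 0, Fp = 0, Fe = 1, Nn = 16, N = 83, tot = 1.2),
                list(Fn = 0, Fp = 0, Fe = 1, Nn = 6, N = 58, tot = 1.7),
                list(Fn = 0, Fp = 0, Fe = 0, Nn = 16, N = 76, tot = 0))
  for (cs in cases) {
    m <- computeMetrics(predFromCounts(cs$Fn, cs$Fp, cs$Fe, cs$Nn, cs$N),
                        known)
    expect_equal(m@totalError, cs$tot)
    expect_equal(m@fnr, 0)
    expect_equal(m@fpr, 0)
  }
  ## nonzero rates follow the defining ratios
  m <- computeMetrics(predFromCounts(Fn = 2, Fp = 3, Fe = 1, Nn = 16,
                                     N = 76), known)
  expect_equal(m@fnr, round(100 * 2 / 16, 1))
  expect_equal(m@fpr, 5.0)  # 100 * 3 / 60
  expect_equal(m@totalError, 7.9)  # 100 * 6 / 76 = 7.89 -> 7.9
})

test_that("rates recomputed from the confusion matrix agree exactly", {
  set.seed(31)
  for (rep in 1:5) {
    Nn <- sample(3:10, 1); N <- Nn + sample(20:40, 1)
    Fn <- sample(0:Nn, 1)
    Fe <- sample(0:3, 1); Fp <- sample(0:3, 1)
    p <- predFromCounts(Fn, Fp, Fe, Nn, N)
    known <- c("A", "B")
    m <- computeMetrics(p, known)
    cm <- confusionMatrix(p, known)
    novelRows <- !(rownames(cm) %in% known)
    classCols <- setdiff(colnames(cm), "NOVEL")
    FnCm <- sum(cm[novelRows, classCols, drop = FALSE])
    FpCm <- sum(cm[!novelRows, "NOVEL"])
    kn <- cm[!novelRows, classCols, drop = FALSE]
    FeCm <- sum(kn) - sum(kn[cbind(rownames(kn), rownames(kn))])
    expect_identical(c(m@Fn, m@Fp, m@Fe),
                     as.numeric(c(FnCm, FpCm, FeCm)))
    expect_equal(m@fnr, round(100 * FnCm / Nn + 1e-12, 1))
    expect_equal(m@totalError,
                 round(100 * (FnCm + FpCm + FeCm) / N + 1e-12, 1))
    ## conservation: missed novel + detected novel = Nn; grand total = N
    expect_equal(m@Fn + sum(cm[novelRows, "NOVEL"]), Nn)
    expect_identical(sum(cm), as.integer(N))
  }
})

test_that("degenerate test sets report guarded rates", {
  p <- predFromCounts(Fn = 0, Fp = 1, Fe = 0, Nn = 0, N = 10)
  m <- computeMetrics(p, c("A", "B"))
  expect_true(m@degenerate)
  expect_identical(m@fnr, 0)
})

test_that("raising a distance threshold trades false positives for misses", {
  set.seed(17)
  truth <- c(rep("A", 30), rep("Z", 10))
  score <- c(rgamma(30, 2, 2), rgamma(10, 2, 2) + 2)
  prevFn <- 0; prevFp <- Inf
  for (th in seq(0, 6, by = 0.25)) {
    novel <- score > th
    pred <- ifelse(novel, NA, "A")
    p <- new("OpenSetPrediction",
             results = data.frame(truth = truth, predicted = pred,
                                  novel = novel, score = score),
             classifier = "knfst", sample = "s")
    m <- computeMetrics(p, "A")
    expect_gte(m@Fn, prevFn)
    expect_lte(m@Fp, prevFp)
    prevFn <- m@Fn; prevFp <- m@Fp
  }
})

test_that("confusion matrices are diagonal under perfect prediction", {
  p <- predFromCounts(Fn = 0, Fp = 0, Fe = 0, Nn = 4, N = 14)
  cm <- confusionMatrix(p, c("A", "B"))
  expect_identical(sum(cm["A", "A"]), 10L)
  expect_identical(sum(cm["ZNOVEL", "NOVEL"]), 4L)
  expect_identical(sum(cm) - cm["A", "A"] - cm["ZNOVEL", "NOVEL"], 0L)
  ## row sums equal true-label counts
  expect_identical(unname(rowSums(cm)), c(10, 4))
})

test_that("novelty score plots are written for full and empty test sets", {
  syn <- separableProblem(nKnown = 3, nNovel = 1, minSep = 400, seed = 4,
                          nTotal = 150)
  m <- fitKNFST(syn$augmented)
  thr <- selectThreshold(noveltyScores(m, syn$augmented@features),
                         direction = "greater", strategy = "quantile",
                         q = 100)
  p <- predictOpenSet(m, thr, syn$test)
  f <- withr::local_tempfile(fileext = ".png")
  plotNoveltyScores(p, noveltyScores(m, syn$augmented@features), thr, f,
                    classLabels(m))
  expect_true(file.exists(f) && file.size(f) > 0)
  ## degenerate: empty test set still yields a figure
  empty <- new("OpenSetPrediction",
               results = data.frame(truth = character(),
                                    predicted = character(),
                                    novel = logical(), score = numeric()),
               classifier = "knfst", sample = "none")
  f2 <- withr::local_tempfile(fileext = ".png")
  plotNoveltyScores(empty, noveltyScores(m, syn$augmented@features), thr,
                    f2, classLabels(m))
  expect_true(file.exists(f2) && file.size(f2) > 0)
})
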