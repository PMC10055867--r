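## round half away from zero to `digits` decimals (printed-table convention;
## base round() rounds half to even)
.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Select a novelty threshold from validation scores
#'
#' Strategy `"min-error"` scans every midpoint of the sorted pooled scores
#' and returns the threshold minimizing the validation error: the number of
#' known validation instances falling on the novel side plus the number of
#' pseudo-novel scores falling on the known side. Ties are broken toward
#' the first (smallest) candidate. Strategy `"quantile"` needs no
#' pseudo-novel scores and returns the q-th percentile of the known scores
#' (defaults: q = 99 for distance scores, q = 1 for density scores).
#'
#' @param knownScores Scores of known validation instances.
#' @param pseudoNovelScores Scores of pseudo-novel instances (required for
#'   `"min-error"`; when `NULL` the quantile strategy is used).
#' @param direction `"greater"` if larger scores mean novel (distances),
#'   `"less"` if smaller scores mean novel (densities).
#' @param strategy `"min-error"` or `"quantile"`.
#' @param q Percentile for the quantile strategy (0-100).
#' @return A [NoveltyThreshold-class]; its provenance records the strategy
#'   and the achieved validation error.
#' @export
#' @examples
#' selectThreshold(c(1, 2, 3), c(10, 11), direction = "greater")
selectThreshold <- function(knownScores, pseudoNovelScores = NULL,
                            direction = c("greater", "less"),
                            strategy = c("min-error", "quantile"),
                            q = NULL) {
  direction <- match.arg(direction)
  strategy <- match.arg(strategy)
  if (!length(knownScores)) stop("knownScores must be non-empty")
  if (is.null(pseudoNovelScores) || !length(pseudoNovelScores))
    strategy <- "quantile"
  if (strategy == "quantile") {
    if (is.null(q)) q <- if (direction == "greater") 99 else 1
    value <- unname(stats::quantile(knownScores, q / 100, type = 7))
    prov <- list(strategy = "quantile", q = q,
                 nKnown = length(knownScores))
  } else {
    pooled <- sort(c(knownScores, pseudoNovelScores))
    cand <- unique((pooled[-length(pooled)] + pooled[-1]) / 2)
    err <- vapply(cand, function(th) {
      if (direction == "greater")
        sum(knownScores > th) + sum(pseudoNovelScores <= th)
      else
        sum(knownScores < th) + sum(pseudoNovelScores >= th)
    }, 0)
    i <- which.min(err)
    value <- cand[i]
    prov <- list(strategy = "min-error", validationError = err[i],
                 nKnown = length(knownScores),
                 nPseudoNovel = length(pseudoNovelScores))
  }
  new("NoveltyThreshold", value = value, direction = direction,
      provenance = prov)
}

#' Open-set prediction of a test peak set
#'
#' Scores every test peak under the fitted classifier and applies the
#' novelty threshold: peaks whose score lies on the novel side are flagged
#' `NOVEL` (no class label); the rest receive the classifier's predicted
#' metabolite.
#'
#' @param model A fitted [KNFSTModel-class] or [KDEModel-class].
#' @param threshold A [NoveltyThreshold-class] whose direction matches the
#'   model type (`"greater"` for KNFST distances, `"less"` for KDE
#'   densities).
#' @param test A [PeakSet-class].
#' @return An [OpenSetPrediction-class].
#' @export
#' @examples
#' syn <- makeSyntheticTable(4, 1, 2, minSeparation = 400, seed = 2)
#' tr <- augmentShift(syn$train, augmentationConfig(nTotal = 400))
#' m <- fitKNFST(tr)
#' val <- augmentNoise(syn$train, nPerPeak = 10)
#' thr <- selectThreshold(noveltyScores(m, val@features),
#'                        direction = "greater", strategy = "quantile",
#'                        q = 100)
#' predictOpenSet(m, thr, syn$test)
predictOpenSet <- function(model, threshold, test) {
  stopifnot(is(threshold, "NoveltyThreshold"), is(test, "PeakSet"))
  expected <- if (is(model, "KNFSTModel")) "greater"
              else if (is(model, "KDEModel")) "less"
              else stop("unsupported model type")
  if (threshold@direction != expected)
    stop("threshold direction '", threshold@direction,
         "' does not match the classifier (expected '", expected, "')")
  x <- peakFeatures(test)
  score <- noveltyScores(model, x)
  pred <- classifyPeaks(model, x)
  novel <- if (expected == "greater") score > threshold@value
           else score < threshold@value
  pred[novel] <- NA_character_
  new("OpenSetPrediction",
      results = data.frame(truth = peakLabels(test), predicted = pred,
                           novel = novel, score = score,
                           stringsAsFactors = FALSE),
      classifier = if (expected == "greater") "knfst" else "kde",
      sample = sampleName(test))
}

#' Open-set error metrics
#'
#' Computes the open-set error counts of a prediction against the training
#' label set and the three percentage rates
#' `fnr = 100 Fn / Nn`, `fpr = 100 Fp / (N - Nn)`,
#' `totalError = 100 (Fn + Fe + Fp) / N`, rounded to one decimal (half away
#' from zero, the printed-table convention).
#'
#' @param pred An [OpenSetPrediction-class].
#' @param knownLabels The training class labels (instances with other truth
#'   labels are the novel ones).
#' @return A [NoveltyMetrics-class]. When a test set contains no novel
#'   instance (or only novel instances) the undefined rate is reported as 0
#'   and the `degenerate` slot is set.
#' @export
#' @examples
#' df <- data.frame(truth = c("A", "A", "B", "Z"),
#'                  predicted = c("A", "B", "B", NA),
#'                  novel = c(FALSE, FALSE, FALSE, TRUE),
#'                  score = c(0, 0, 0, 9))
#' p <- new("OpenSetPrediction", results = df, classifier = "knfst",
#'          sample = "demo")
#' computeMetrics(p, knownLabels = c("A", "B"))
computeMetrics <- function(pred, knownLabels) {
  stopifnot(is(pred, "OpenSetPrediction"))
  df <- pred@results
  novelTrue <- !(df$truth %in% knownLabels)
  N <- as.numeric(nrow(df))
  Nn <- as.numeric(sum(novelTrue))
  Fn <- as.numeric(sum(novelTrue & !df$novel))
  Fp <- as.numeric(sum(!novelTrue & df$novel))
  Fe <- as.numeric(sum(!novelTrue & !df$novel & df$predicted != df$truth,
                       na.rm = TRUE))
  degenerate <- Nn == 0L || Nn == N
  fnr <- if (Nn > 0) .roundHalfUp(100 * Fn / Nn) else 0
  fpr <- if (N - Nn > 0) .roundHalfUp(100 * Fp / (N - Nn)) else 0
  new("NoveltyMetrics", Fn = Fn, Fp = Fp, Fe = Fe, Nn = Nn, N = N,
      fnr = fnr, fpr = fpr,
      totalError = .roundHalfUp(100 * (Fn + Fe + Fp) / N),
      degenerate = degenerate)
}

setMethod("show", "NoveltyMetrics", function(object) {
  cat(sprintf(
    "NoveltyMetrics: N=%d (novel %d) | Fn=%d Fp=%d Fe=%d\n",
    object@N, object@Nn, object@Fn, object@Fp, object@Fe))
  cat(sprintf(
    "false negative rate %.1f%% | false positive rate %.1f%% | total error %.1f%%\n",
    object@fnr, object@fpr, object@totalError))
  if (object@degenerate)
    cat("(degenerate: no novel or no known instances; affected rate = 0)\n")
})

#' Open-set confusion matrix
#'
#' Rows are true metabolite labels (including those novel to the training
#' set), columns the predicted labels plus a final `NOVEL` column. Row sums
#' equal the per-label test counts.
#'
#' @param pred An [OpenSetPrediction-class].
#' @param knownLabels Optional training label set fixing the column order;
#'   defaults to the labels observed in the predictions.
#' @return An integer matrix with dimnames.
#' @export
confusionMatrix <- function(pred, knownLabels = NULL) {
  stopifnot(is(pred, "OpenSetPrediction"))
  df <- pred@results
  if (is.null(knownLabels))
    knownLabels <- sort(unique(df$predicted[!is.na(df$predicted)]))
  cols <- c(sort(unique(knownLabels)), "NOVEL")
  rows <- sort(unique(df$truth))
  predlab <- ifelse(df$novel, "NOVEL", df$predicted)
  m <- matrix(0L, length(rows), length(cols),
              dimnames = list(truth = rows, predicted = cols))
  for (i in seq_len(nrow(df)))
    m[df$truth[i], predlab[i]] <- m[df$truth[i], predlab[i]] + 1L
  m
}

#' Plot novelty scores with the decision threshold
#'
#' Scatter of novelty scores in five groups: known training instances,
#' correctly classified known test instances, misclassified known test
#' instances, detected novel instances, and missed novel instances, with a
#' horizontal line at the threshold. Density scores (direction `"less"`)
#' are drawn on a log10 axis.
#'
#' @param pred An [OpenSetPrediction-class].
#' @param trainingScores Novelty scores of (a subsample of) the training
#'   instances under the same model.
#' @param threshold The [NoveltyThreshold-class] used for `pred`.
#' @param path Output image file (`.png` or `.svg`).
#' @param knownLabels Training class labels (to tell truly novel test
#'   instances apart).
#' @return `path`, invisibly.
#' @export
plotNoveltyScores <- function(pred, trainingScores, threshold, path,
                              knownLabels) {
  stopifnot(is(pred, "OpenSetPrediction"),
            is(threshold, "NoveltyThreshold"))
  df <- pred@results
  novelTrue <- !(df$truth %in% knownLabels)
  grp <- ifelse(novelTrue,
                ifelse(df$novel, "novel detected", "novel missed"),
                ifelse(df$novel, "known misclassified",
                       ifelse(df$predicted == df$truth, "known test correct",
                              "known misclassified")))
  tf <- function(s) if (threshold@direction == "less")
    log10(pmax(s, 1e-300)) else s
  groups <- list("known train" = tf(trainingScores))
  for (g in c("known test correct", "known misclassified",
              "novel detected", "novel missed"))
    groups[[g]] <- tf(df$score[grp == g])
  cols <- c("known train" = "steelblue",
            "known test correct" = "forestgreen",
            "known misclassified" = "black",
            "novel detected" = "red", "novel missed" = "magenta")
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 7, height = 5)
  else grDevices::png(path, width = 900, height = 640)
  on.exit(grDevices::dev.off())
  ylim <- range(unlist(groups), tf(threshold@value), finite = TRUE)
  graphics::plot(NA, xlim = c(0.5, length(groups) + 0.5), ylim = ylim,
                 xaxt = "n", xlab = "",
                 ylab = if (threshold@direction == "less")
                   "log10 max class density" else "min target distance",
                 main = sprintf("Novelty scores: %s, %s",
                                pred@classifier, pred@sample))
  graphics::axis(1, at = seq_along(groups), labels = names(groups),
                 las = 2, cex.axis = 0.8)
  for (i in seq_along(groups)) {
    y <- groups[[i]]
    if (length(y))
      graphics::points(stats::runif(length(y), i - 0.2, i + 0.2), y,
                       col = cols[[names(groups)[i]]], pch = 19,
                       cex = 0.6)
  }
  graphics::abline(h = tf(threshold@value), lty = 2)
  invisible(path)
}
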