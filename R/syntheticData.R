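#' Construct an AugmentationConfig
#'
#' @param nTotal Target training-set size (default 4000 instances).
#' @param maxShift Per-axis bound on the uniform frequency shift in Hz
#'   (default 30): augmentation emulates the chemical-shift drift of peaks
#'   between samples by shifting each source peak left/right and up/down by
#'   at most this much.
#' @param noiseSigma Standard deviation (Hz) of the Gaussian perturbation
#'   generating the validation set (default 10).
#' @param perClassCap Multiplets retained per metabolite and augmentation
#'   round; metabolites with more multiplets are under-sampled to this many
#'   (default 2), mitigating class imbalance from unequal multiplet counts.
#' @param seed RNG seed.
#' @return An [AugmentationConfig-class].
#' @export
#' @examples
#' augmentationConfig(nTotal = 1000, seed = 7)
augmentationConfig <- function(nTotal = 4000, maxShift = 30,
                               noiseSigma = 10, perClassCap = 2, seed = 1) {
  new("AugmentationConfig", nTotal = nTotal, maxShift = maxShift,
      noiseSigma = noiseSigma, perClassCap = perClassCap, seed = seed)
}

## draw n per-axis shifts for source points, resampling any draw that
## would leave the spectral window (avoids density pile-up at the edges)
.shiftWithin <- function(src, draw) {
  out <- draw(nrow(src))
  bad <- which(out[, 1] < 0 | out[, 1] > .SPECTRAL_WIDTH_HZ |
               out[, 2] < 0 | out[, 2] > .SPECTRAL_WIDTH_HZ)
  guard <- 0L
  while (length(bad)) {
    out[bad, ] <- draw(length(bad), bad)
    bad <- bad[out[bad, 1] < 0 | out[bad, 1] > .SPECTRAL_WIDTH_HZ |
               out[bad, 2] < 0 | out[bad, 2] > .SPECTRAL_WIDTH_HZ]
    guard <- guard + 1L
    if (guard > 1000L)
      stop("cannot keep perturbed peaks inside the spectral window")
  }
  out
}

#' Shift-augmented training set from a labeled peak set
#'
#' Creates the training data for the classifiers by replicating each
#' metabolite's cross peaks with independent uniform per-axis frequency
#' shifts of at most `maxShift` Hz, emulating the chemical-shift drift
#' observed between samples. Class sizes are equalized: the target size is
#' split evenly over the metabolites (round-robin in sorted label order,
#' the remainder going to the first labels), and metabolites with more than
#' `perClassCap` multiplets contribute a fresh random subset of
#' `perClassCap` multiplets in each augmentation round (under-sampling, so
#' many-multiplet metabolites do not dominate their class). Samples falling
#' outside the spectral window are redrawn, never clipped.
#'
#' @param peaks A [PeakSet-class] (the reference sample).
#' @param config An [AugmentationConfig-class]; `config@seed` makes the
#'   output deterministic.
#' @return A [PeakDataset-class] with provenance `"train"` and exactly
#'   `nTotal` instances.
#' @export
#' @examples
#' tab <- loadReferenceTable()
#' train <- augmentShift(extractSample(tab, "ct_d4"),
#'                       augmentationConfig(nTotal = 240, seed = 1))
#' table(train@labels)
augmentShift <- function(peaks, config = augmentationConfig()) {
  stopifnot(is(peaks, "PeakSet"), is(config, "AugmentationConfig"))
  validObject(config)
  if (nPeaks(peaks) == 0L) stop("cannot augment an empty peak set")
  set.seed(config@seed)
  labs <- sort(unique(peakLabels(peaks)))
  C <- length(labs)
  counts <- rep(floor(config@nTotal / C), C)
  extra <- config@nTotal - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  X <- peakFeatures(peaks)
  out <- vector("list", C)
  for (k in seq_len(C)) {
    src <- X[peakLabels(peaks) == labs[k], , drop = FALSE]
    m <- nrow(src)
    rows <- integer(0)
    while (length(rows) < counts[k]) {
      idx <- seq_len(m)
      if (m > config@perClassCap) idx <- sample(idx, config@perClassCap)
      rows <- c(rows, idx)
    }
    rows <- rows[seq_len(counts[k])]
    base <- src[rows, , drop = FALSE]
    out[[k]] <- .shiftWithin(base, function(n, which = seq_len(nrow(base))) {
      base[which, , drop = FALSE] +
        matrix(stats::runif(2 * n, -config@maxShift, config@maxShift),
               ncol = 2)
    })
  }
  feat <- do.call(rbind, out)
  colnames(feat) <- c("f2", "f1")
  new("PeakDataset", features = feat, labels = rep(labs, counts),
      provenance = "train")
}

#' Noise-perturbed validation set from a labeled peak set
#'
#' Each source cross peak yields `nPerPeak` copies perturbed by independent
#' Gaussian noise (standard deviation `config@noiseSigma` Hz on each axis).
#' The resulting set is used to calibrate the novelty threshold: its scores
#' describe how a known, slightly drifted peak scores under the trained
#' model. Out-of-window draws are resampled.
#'
#' @param peaks A [PeakSet-class].
#' @param nPerPeak Number of perturbed copies per source peak.
#' @param config An [AugmentationConfig-class] (uses `noiseSigma`, `seed`).
#' @return A [PeakDataset-class] with provenance `"validation"`.
#' @export
#' @examples
#' tab <- loadReferenceTable()
#' val <- augmentNoise(extractSample(tab, "ct_d4"), nPerPeak = 10)
#' nrow(val@features)  # 69 peaks x 10
augmentNoise <- function(peaks, nPerPeak = 20,
                         config = augmentationConfig()) {
  stopifnot(is(peaks, "PeakSet"), is(config, "AugmentationConfig"))
  validObject(config)
  if (nPeaks(peaks) == 0L) stop("cannot augment an empty peak set")
  set.seed(config@seed)
  X <- peakFeatures(peaks)
  base <- X[rep(seq_len(nrow(X)), each = nPerPeak), , drop = FALSE]
  feat <- .shiftWithin(base, function(n, which = seq_len(nrow(base))) {
    base[which, , drop = FALSE] +
      matrix(stats::rnorm(2 * n, 0, config@noiseSigma), ncol = 2)
  })
  colnames(feat) <- c("f2", "f1")
  new("PeakDataset", features = feat,
      labels = rep(peakLabels(peaks), each = nPerPeak),
      provenance = "validation")
}

#' Fully synthetic train/test peak tables
#'
#' Generates a benchmark problem shaped like the reference experiment:
#' known classes whose multiplets appear in both the train and the test set
#' (reappearing in the test set with a small frequency shift), plus novel
#' classes appearing only in the test set. Class centers are drawn
#' uniformly in the spectral window under a minimum pairwise separation
#' (rejection sampling), multiplets scatter around their center, and test
#' copies of known peaks drift by a bounded uniform shift.
#'
#' @param nKnownClasses,nNovelClasses Number of known / novel classes.
#' @param peaksPerClass Multiplets per class.
#' @param minSeparation Minimum pairwise distance between class centers in
#'   Hz (0 disables the constraint).
#' @param seed RNG seed.
#' @param multipletSpread Uniform per-axis scatter of a class's multiplets
#'   around its center, Hz (default 20).
#' @param testShift Uniform per-axis drift of known peaks in the test set,
#'   Hz (default 10).
#' @param margin Distance kept between class centers and the window edge
#'   (default 150 Hz) so that augmented copies stay inside the window.
#' @return A list with [PeakSet-class] elements `train` (known classes
#'   only, labels `class_01`, ...) and `test` (shifted known peaks plus
#'   novel classes labeled `novel_01`, ...), and `centers`, the matrix of
#'   class centers (rows named by label).
#' @export
#' @examples
#' syn <- makeSyntheticTable(5, 2, 3, minSeparation = 200, seed = 7)
#' nPeaks(syn$test)
makeSyntheticTable <- function(nKnownClasses, nNovelClasses = 0,
                               peaksPerClass = 2, minSeparation = 150,
                               seed = 1, multipletSpread = 20,
                               testShift = 10, margin = 150) {
  stopifnot(minSeparation >= 0, nKnownClasses >= 1, peaksPerClass >= 1)
  set.seed(seed)
  C <- nKnownClasses + nNovelClasses
  lo <- margin
  hi <- .SPECTRAL_WIDTH_HZ - margin
  centers <- matrix(NA_real_, 0, 2)
  attempts <- 0L
  while (nrow(centers) < C) {
    cand <- stats::runif(2, lo, hi)
    ok <- !nrow(centers) || all(sqrt(colSums((t(centers) - cand)^2)) >=
                                minSeparation)
    if (ok) centers <- rbind(centers, cand)
    attempts <- attempts + 1L
    if (attempts > 10000L * C)
      stop("geometric infeasibility: cannot place ", C, " class centers ",
           minSeparation, " Hz apart in the spectral window")
  }
  labs <- c(sprintf("class_%02d", seq_len(nKnownClasses)),
            if (nNovelClasses > 0) sprintf("novel_%02d",
                                           seq_len(nNovelClasses)))
  mkpeaks <- function(idx) {
    do.call(rbind, lapply(idx, function(k) {
      mult <- matrix(stats::runif(2 * peaksPerClass, -multipletSpread,
                                  multipletSpread), ncol = 2)
      data.frame(metabolite = labs[k],
                 f2 = centers[k, 1] + mult[, 1],
                 f1 = centers[k, 2] + mult[, 2],
                 stringsAsFactors = FALSE)
    }))
  }
  trainPeaks <- mkpeaks(seq_len(nKnownClasses))
  testKnown <- trainPeaks
  n <- nrow(testKnown)
  testKnown$f2 <- testKnown$f2 + stats::runif(n, -testShift, testShift)
  testKnown$f1 <- testKnown$f1 + stats::runif(n, -testShift, testShift)
  testPeaks <- rbind(testKnown,
                     if (nNovelClasses > 0)
                       mkpeaks(nKnownClasses + seq_len(nNovelClasses)))
  dimnames(centers) <- list(labs, c("f2", "f1"))
  list(train = new("PeakSet", sample = "synthetic_train",
                   peaks = trainPeaks),
       test = new("PeakSet", sample = "synthetic_test", peaks = testPeaks),
       centers = centers)
}

#' Coerce a PeakDataset to a data.frame
#'
#' @param x A [PeakDataset-class].
#' @param ... Ignored.
#' @return A `data.frame` with columns `metabolite`, `f2_hz`, `f1_hz`,
#'   `provenance` (the peak-set CSV dialect plus a provenance column).
#' @export
as.data.frame.PeakDataset <- function(x, ...) {
  data.frame(metabolite = x@labels, f2_hz = x@features[, 1],
             f1_hz = x@features[, 2], provenance = x@provenance,
             stringsAsFactors = FALSE)
}

setMethod("show", "PeakDataset", function(object) {
  cat("PeakDataset (", object@provenance, "): ", nrow(object@features),
      " instances, ", length(unique(object@labels)), " classes\n", sep = "")
})

#' @rdname PeakSet-accessors
#' @export
setMethod("peakFeatures", "PeakDataset", function(x) x@features)

#' @rdname PeakSet-accessors
#' @export
setMethod("peakLabels", "PeakDataset", function(x) x@labels)
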