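#' @import methods
NULL

## Spectral window of the reference experiments: 12.00 ppm at 600.13 MHz.
.SPECTROMETER_MHZ <- 600.13
.SPECTRAL_WIDTH_PPM <- 12
.SPECTRAL_WIDTH_HZ <- .SPECTRAL_WIDTH_PPM * .SPECTROMETER_MHZ  # 7201.56 Hz

#' Spectral window in Hz
#'
#' Width of the acquisition window of the bundled reference experiments
#' (12.00 ppm in both dimensions at 600.13 MHz). All cross-peak frequencies
#' handled by the package are expected to lie in `[0, spectralWidthHz()]`.
#'
#' @return A single number, 7201.56 (Hz).
#' @export
#' @examples
#' spectralWidthHz()
spectralWidthHz <- function() .SPECTRAL_WIDTH_HZ

#' PeakTable: a multi-sample reference cross-peak table
#'
#' Mirrors the layout of the bundled reference table: one row per cross peak
#' (a metabolite multiplet), with an (F2, F1) frequency pair in Hz for each
#' sample, or `NA` where the peak is not present ("NP") in that sample, plus
#' a standard (F2, F1) pair.
#'
#' @slot rows A `data.frame` with a `metabolite` column and, per sample,
#'   `<sample>_f2` / `<sample>_f1` numeric columns (NA = peak absent), plus
#'   `std_f2` / `std_f1`.
#' @slot samples Character vector of sample identifiers (column prefixes).
#'
#' @seealso [loadReferenceTable()], [extractSample()]
#' @export
setClass("PeakTable",
         representation(rows = "data.frame", samples = "character"))

setValidity("PeakTable", function(object) {
  df <- object@rows
  msg <- character(0)
  if (!"metabolite" %in% names(df))
    msg <- c(msg, "rows must have a 'metabolite' column")
  else if (any(!nzchar(df$metabolite)))
    msg <- c(msg, "metabolite labels must be non-empty")
  for (s in object@samples) {
    c2 <- paste0(s, "_f2"); c1 <- paste0(s, "_f1")
    if (!all(c(c2, c1) %in% names(df))) {
      msg <- c(msg, sprintf("missing frequency columns for sample '%s'", s))
      next
    }
    if (any(is.na(df[[c2]]) != is.na(df[[c1]])))
      msg <- c(msg, sprintf(
        "sample '%s' has half-specified entries (one of F2/F1 missing)", s))
  }
  if (all(c("std_f2", "std_f1") %in% names(df))) {
    if (any(is.na(df$std_f2)) || any(is.na(df$std_f1)))
      msg <- c(msg, "every row must have a standard (F2, F1) pair")
  } else msg <- c(msg, "rows must have std_f2/std_f1 columns")
  if (length(msg)) msg else TRUE
})

#' PeakSet: labeled cross peaks of one sample
#'
#' A set of assigned TOCSY cross peaks from a single sample. Each peak is an
#' (F2, F1) coordinate in Hz together with its metabolite label; multiplets
#' of one metabolite are separate peaks carrying the same label.
#'
#' @slot sample Sample identifier (length-1 character).
#' @slot peaks A `data.frame` with columns `metabolite` (character),
#'   `f2`, `f1` (numeric, Hz).
#'
#' @seealso [extractSample()], [readPeakSet()], [peakFeatures()]
#' @export
setClass("PeakSet",
         representation(sample = "character", peaks = "data.frame"))

setValidity("PeakSet", function(object) {
  msg <- character(0)
  if (length(object@sample) != 1L)
    msg <- c(msg, "sample must be a single identifier")
  df <- object@peaks
  need <- c("metabolite", "f2", "f1")
  if (!all(need %in% names(df)))
    return("peaks must have columns metabolite, f2, f1")
  if (any(is.na(df$f2)) || any(is.na(df$f1)))
    msg <- c(msg, "peaks must not contain missing frequencies")
  else if (any(df$f2 < 0 | df$f2 > .SPECTRAL_WIDTH_HZ |
               df$f1 < 0 | df$f1 > .SPECTRAL_WIDTH_HZ))
    msg <- c(msg, sprintf("frequencies must lie within [0, %.2f] Hz",
                          .SPECTRAL_WIDTH_HZ))
  if (any(!nzchar(df$metabolite)))
    msg <- c(msg, "metabolite labels must be non-empty")
  if (length(msg)) msg else TRUE
})

#' PeakDataset: a labeled feature matrix
#'
#' The feature representation consumed by the classifiers: an n x 2 matrix
#' of (F2, F1) frequencies in Hz, one metabolite label per row, and a
#' provenance tag recording which stage generated the data.
#'
#' @slot features Numeric matrix, n x 2, columns `f2` and `f1` (Hz).
#' @slot labels Character vector of metabolite labels, length n.
#' @slot provenance One of `"train"`, `"validation"`, `"test"`.
#'
#' @seealso [augmentShift()], [augmentNoise()]
#' @export
setClass("PeakDataset",
         representation(features = "matrix", labels = "character",
                        provenance = "character"))

setValidity("PeakDataset", function(object) {
  msg <- character(0)
  if (ncol(object@features) != 2L)
    msg <- c(msg, "features must have exactly two columns (f2, f1)")
  if (nrow(object@features) != length(object@labels))
    msg <- c(msg, "row count of features must equal number of labels")
  if (!object@provenance %in% c("train", "validation", "test"))
    msg <- c(msg, "provenance must be one of train/validation/test")
  if (any(object@features < 0 | object@features > .SPECTRAL_WIDTH_HZ))
    msg <- c(msg, "features must lie within the spectral window")
  if (length(msg)) msg else TRUE
})

#' AugmentationConfig: parameters of the data-augmentation stage
#'
#' @slot nTotal Target size of the augmented training set (default 4000).
#' @slot maxShift Per-axis bound on the uniform frequency shift, Hz
#'   (default 30).
#' @slot noiseSigma Standard deviation of the Gaussian perturbation used
#'   for the validation set, Hz (default 10).
#' @slot perClassCap Maximum number of multiplets a metabolite contributes
#'   per augmentation round; metabolites with more multiplets are
#'   under-sampled to this many (default 2).
#' @slot seed RNG seed making the augmentation reproducible.
#' @export
setClass("AugmentationConfig",
         representation(nTotal = "numeric", maxShift = "numeric",
                        noiseSigma = "numeric", perClassCap = "numeric",
                        seed = "numeric"),
         prototype(nTotal = 4000, maxShift = 30, noiseSigma = 10,
                   perClassCap = 2, seed = 1))

setValidity("AugmentationConfig", function(object) {
  msg <- character(0)
  if (object@nTotal <= 0) msg <- c(msg, "nTotal must be positive")
  if (object@maxShift < 0) msg <- c(msg, "maxShift must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@perClassCap < 1) msg <- c(msg, "perClassCap must be >= 1")
  if (length(msg)) msg else TRUE
})

#' KernelConfig: kernel used by the KNFST classifier
#'
#' @slot family `"rbf"`, `"polynomial"` or `"linear"`.
#' @slot sigma RBF bandwidth in Hz; `NA` selects it automatically as the
#'   median nonzero within-class pairwise distance of the training set
#'   (falling back to the global median when no class has two points).
#' @slot degree Polynomial degree (>= 1), used by the polynomial family.
#' @slot standardize Whether to standardize the two frequency axes before
#'   kernel evaluation. Off by default: both axes are in Hz and share units.
#' @export
setClass("KernelConfig",
         representation(family = "character", sigma = "numeric",
                        degree = "numeric", standardize = "logical"),
         prototype(family = "rbf", sigma = NA_real_, degree = 2,
                   standardize = FALSE))

setValidity("KernelConfig", function(object) {
  msg <- character(0)
  if (!object@family %in% c("rbf", "polynomial", "linear"))
    msg <- c(msg, "family must be rbf, polynomial or linear")
  if (object@family == "rbf" && !is.na(object@sigma) && object@sigma <= 0)
    msg <- c(msg, "rbf sigma must be > 0")
  if (object@family == "polynomial" && object@degree < 1)
    msg <- c(msg, "polynomial degree must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ParzenConfig: Parzen-window density estimator settings
#'
#' @slot h Bandwidth in Hz; `NA` selects it by maximizing the leave-one-out
#'   log-density of the training set over a logarithmic grid.
#' @slot d Feature-space dimension (2 for (F2, F1) features).
#' @export
setClass("ParzenConfig",
         representation(h = "numeric", d = "numeric"),
         prototype(h = NA_real_, d = 2))

setValidity("ParzenConfig", function(object) {
  msg <- character(0)
  if (!is.na(object@h) && object@h <= 0) msg <- c(msg, "h must be > 0")
  if (object@d < 1) msg <- c(msg, "d must be >= 1")
  if (length(msg)) msg else TRUE
})

#' KNFSTModel: fitted kernel null-space projection
#'
#' State of a fitted Kernel Null Foley-Sammon Transform: the training
#' features (needed for kernel evaluation at prediction time), the
#' projection coefficients, and one target point per class, the common image
#' of that class's training instances under the null projection.
#'
#' @slot X Training feature matrix (n x 2).
#' @slot labels Training labels (length n).
#' @slot classLabels Sorted unique class labels (length C).
#' @slot coef Projection coefficient matrix (n x d, d <= C - 1): a test
#'   point's projection is `t(coef)` applied to the doubly centered kernel
#'   column of the point.
#' @slot rowMeansK Row means of the training kernel matrix (centering term).
#' @slot grandMeanK Grand mean of the training kernel matrix.
#' @slot targets d x C matrix of per-class target points.
#' @slot kernel The [KernelConfig-class] used (with the realized sigma).
#' @slot center,scale Axis centering/scaling applied before kernel
#'   evaluation (identity unless standardization was requested).
#' @slot nullRatio Achieved ratio of the largest projected within-class
#'   scatter eigenvalue to the largest projected between-class scatter
#'   eigenvalue; ~0 when an exact null space exists, larger when classes
#'   overlap and the null-space conditions only hold approximately.
#' @slot tol Relative eigenvalue tolerance used for the null-space
#'   extraction.
#' @seealso [fitKNFST()], [knfstDistances()]
#' @export
setClass("KNFSTModel",
         representation(X = "matrix", labels = "character",
                        classLabels = "character", coef = "matrix",
                        rowMeansK = "numeric", grandMeanK = "numeric",
                        targets = "matrix",
                        kernel = "KernelConfig", center = "numeric",
                        scale = "numeric", nullRatio = "numeric",
                        tol = "numeric"))

setValidity("KNFSTModel", function(object) {
  msg <- character(0)
  C <- length(object@classLabels)
  if (ncol(object@targets) != C)
    msg <- c(msg, "one target point per class is required")
  if (nrow(object@coef) != nrow(object@X))
    msg <- c(msg, "coefficient rows must match training instances")
  if (ncol(object@coef) > max(C - 1, 1))
    msg <- c(msg, "projection dimensionality must be <= C - 1")
  if (length(msg)) msg else TRUE
})

#' KDEModel: per-class Parzen-window density model
#'
#' @slot pointsByClass Named list of per-class training feature matrices.
#' @slot classLabels Sorted unique class labels.
#' @slot config The [ParzenConfig-class] used (with the realized bandwidth).
#' @seealso [fitKDE()], [kdeScores()]
#' @export
setClass("KDEModel",
         representation(pointsByClass = "list", classLabels = "character",
                        config = "ParzenConfig"))

setValidity("KDEModel", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@pointsByClass)),
                 sort(object@classLabels)))
    msg <- c(msg, "class set must equal the training label set")
  if (any(vapply(object@pointsByClass, nrow, 0L) < 1L))
    msg <- c(msg, "every class needs at least one training point")
  if (length(msg)) msg else TRUE
})

#' NoveltyThreshold: decision threshold on classifier scores
#'
#' @slot value The threshold.
#' @slot direction `"greater"` (novel when the score exceeds the threshold;
#'   KNFST distances) or `"less"` (novel when the score falls below it;
#'   KDE densities).
#' @slot provenance List recording the selection strategy and a summary of
#'   the validation scores it was derived from.
#' @seealso [selectThreshold()]
#' @export
setClass("NoveltyThreshold",
         representation(value = "numeric", direction = "character",
                        provenance = "list"))

setValidity("NoveltyThreshold", function(object) {
  msg <- character(0)
  if (!is.finite(object@value)) msg <- c(msg, "threshold must be finite")
  if (!object@direction %in% c("greater", "less"))
    msg <- c(msg, "direction must be 'greater' or 'less'")
  if (length(msg)) msg else TRUE
})

#' OpenSetPrediction: per-instance open-set decisions
#'
#' @slot results A `data.frame` with one row per test peak: `truth` (the
#'   annotated metabolite), `predicted` (a class label, or `NA` when the
#'   instance was flagged novel), `novel` (logical flag) and `score` (the
#'   novelty score: minimum projection distance for KNFST, maximum
#'   class-conditional density for KDE).
#' @slot classifier `"knfst"` or `"kde"`.
#' @slot sample Identifier of the test sample.
#' @seealso [predictOpenSet()], [computeMetrics()]
#' @export
setClass("OpenSetPrediction",
         representation(results = "data.frame", classifier = "character",
                        sample = "character"))

setValidity("OpenSetPrediction", function(object) {
  df <- object@results
  need <- c("truth", "predicted", "novel", "score")
  if (!all(need %in% names(df)))
    return("results needs columns truth, predicted, novel, score")
  if (any(df$novel & !is.na(df$predicted)))
    return("a NOVEL flag and a class label are mutually exclusive")
  if (any(!df$novel & is.na(df$predicted)))
    return("non-novel instances must carry a predicted label")
  TRUE
})

#' NoveltyMetrics: open-set error counts and rates
#'
#' Counts and percentage rates of the three open-set error modes: `Fn`
#' novel instances classified as known, `Fp` known instances flagged novel,
#' `Fe` misclassifications within the known classes. Rates are
#' `fnr = 100 Fn / Nn`, `fpr = 100 Fp / (N - Nn)` and
#' `totalError = 100 (Fn + Fe + Fp) / N`.
#'
#' @slot Fn,Fp,Fe Error counts (see above).
#' @slot Nn Number of novel instances in the test set.
#' @slot N Total number of test instances.
#' @slot fnr,fpr,totalError Percentage rates.
#' @slot degenerate TRUE when `Nn = 0` (or `N = Nn`) forced a rate to be
#'   reported as 0 to avoid division by zero.
#' @seealso [computeMetrics()]
#' @export
setClass("NoveltyMetrics",
         representation(Fn = "numeric", Fp = "numeric", Fe = "numeric",
                        Nn = "numeric", N = "numeric", fnr = "numeric",
                        fpr = "numeric", totalError = "numeric",
                        degenerate = "logical"))

setValidity("NoveltyMetrics", function(object) {
  msg <- character(0)
  if (object@Fn < 0 || object@Fn > object@Nn)
    msg <- c(msg, "Fn must satisfy 0 <= Fn <= Nn")
  if (object@Fp + object@Fe < 0 ||
      object@Fp + object@Fe > object@N - object@Nn)
    msg <- c(msg, "Fp + Fe must satisfy 0 <= Fp + Fe <= N - Nn")
  if (length(msg)) msg else TRUE
})

#' ExperimentConfig: settings of the full profiling experiment
#'
#' @slot reference Sample used to build the training model (default
#'   `"ct_d4"`).
#' @slot testSamples Samples evaluated against the training model.
#' @slot augmentation An [AugmentationConfig-class].
#' @slot kernel A [KernelConfig-class] for KNFST.
#' @slot parzen A [ParzenConfig-class] for KDE.
#' @slot thresholdStrategy `"min-error"` or `"quantile"`.
#' @slot validationPerPeak Validation instances generated per training peak.
#' @slot pseudoNovelSeed Seed for the pseudo-novel validation scores.
#' @slot outDir Output directory for artifacts (`NA` = write nothing).
#' @seealso [runExperiment()]
#' @export
setClass("ExperimentConfig",
         representation(reference = "character", testSamples = "character",
                        augmentation = "AugmentationConfig",
                        kernel = "KernelConfig", parzen = "ParzenConfig",
                        thresholdStrategy = "character",
                        validationPerPeak = "numeric",
                        pseudoNovelSeed = "numeric", outDir = "character"),
         prototype(reference = "ct_d4",
                   testSamples = c("ct_d14", "at_d14", "os_d14"),
                   thresholdStrategy = "min-error", validationPerPeak = 20,
                   pseudoNovelSeed = 1, outDir = NA_character_))

setValidity("ExperimentConfig", function(object) {
  msg <- character(0)
  if (object@reference %in% object@testSamples)
    msg <- c(msg, "the reference sample must not be a test sample")
  if (!object@thresholdStrategy %in% c("min-error", "quantile"))
    msg <- c(msg, "thresholdStrategy must be 'min-error' or 'quantile'")
  if (object@validationPerPeak < 1)
    msg <- c(msg, "validationPerPeak must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ExperimentReport: results of one full experiment
#'
#' @slot metrics Named list of [NoveltyMetrics-class], one per
#'   (sample x classifier) pair, names `<sample>.<classifier>`.
#' @slot predictions Named list of [OpenSetPrediction-class], same names.
#' @slot thresholds Named list of [NoveltyThreshold-class] per classifier.
#' @slot config The [ExperimentConfig-class] that produced the report.
#' @slot seeds Named numeric vector recording every seed used.
#' @slot artifacts Named character vector of files written (possibly empty).
#' @export
setClass("ExperimentReport",
         representation(metrics = "list", predictions = "list",
                        thresholds = "list", config = "ExperimentConfig",
                        seeds = "numeric", artifacts = "character"))
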