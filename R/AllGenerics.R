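#' @rdname PeakSet-accessors
#' @export
setGeneric("peakFeatures", function(x) standardGeneric("peakFeatures"))

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakLabels", function(x) standardGeneric("peakLabels"))

#' @rdname PeakSet-accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname PeakSet-accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' Accessors for peak containers
#'
#' `peakFeatures()` returns the n x 2 matrix of (F2, F1) frequencies in Hz;
#' `peakLabels()` the metabolite labels; `sampleName()` the sample
#' identifier; `nPeaks()` the number of cross peaks; `peakSamples()` the
#' sample identifiers of a [PeakTable-class].
#'
#' @param x A [PeakSet-class], [PeakDataset-class] or [PeakTable-class].
#' @return See description.
#' @name PeakSet-accessors
#' @aliases peakFeatures peakLabels sampleName nPeaks peakSamples
#' @examples
#' tab <- loadReferenceTable()
#' ps <- extractSample(tab, "ct_d4")
#' nPeaks(ps)
#' head(peakFeatures(ps))
NULL

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakSamples", function(x) standardGeneric("peakSamples"))

#' Novelty scores of test points under a fitted classifier
#'
#' For a [KNFSTModel-class] the score of a point is the minimum Euclidean
#' distance between its null-space projection and the class target points
#' (novel instances score high). For a [KDEModel-class] it is the maximum
#' class-conditional Parzen density (novel instances score low).
#'
#' @param model A fitted classifier model.
#' @param x Feature matrix (n x 2, Hz) or a [PeakSet-class].
#' @return Numeric vector of novelty scores, one per row of `x`.
#' @seealso [knfstDistances()], [kdeScores()], [predictOpenSet()]
#' @export
setGeneric("noveltyScores", function(model, x) standardGeneric("noveltyScores"))

#' Closed-set class predictions of a fitted classifier
#'
#' @param model A fitted [KNFSTModel-class] or [KDEModel-class].
#' @param x Feature matrix (n x 2, Hz) or a [PeakSet-class].
#' @return Character vector of predicted class labels (no novelty logic;
#'   see [predictOpenSet()] for thresholded open-set prediction).
#' @export
setGeneric("classifyPeaks", function(model, x) standardGeneric("classifyPeaks"))

#' @rdname modelAccessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Accessors for fitted models
#'
#' `classLabels()` returns the class labels a model was trained on;
#' `bandwidth()` the realized kernel bandwidth (KNFST rbf sigma, or the
#' Parzen window width h).
#'
#' @param x A fitted model.
#' @return Character vector of labels, or a single numeric bandwidth (Hz).
#' @name modelAccessors
#' @aliases classLabels bandwidth
NULL

#' @rdname modelAccessors
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))
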