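#' Fit a Kernel Null Foley-Sammon Transform
#'
#' Learns the kernel-space projection with zero within-class scatter and
#' positive between-class scatter: every training class collapses onto a
#' single target point, and the discriminative information lives entirely
#' in the between-target geometry. Classification of a test point is by the
#' nearest target; its minimum target distance is the novelty score.
#'
#' The null space is extracted in three steps: (i) an orthonormal basis of
#' the span of the centered kernel feature map, discarding kernel
#' eigenvalue directions below `tol` x the largest (this absorbs
#' near-duplicate augmented instances); (ii) the null space of the
#' within-class scatter inside that basis; (iii) a between-class scatter
#' rotation keeping at most C - 1 informative directions. When classes
#' overlap so strongly that no exact null direction survives inside the
#' retained basis, the C - 1 smallest within-scatter directions are used
#' instead and the achieved within/between eigenvalue ratio is recorded in
#' the model's `nullRatio` slot (0 means the null-space conditions hold
#' exactly).
#'
#' @param train A [PeakDataset-class] (or [PeakSet-class]) with at least
#'   two classes.
#' @param config A [KernelConfig-class]; an `NA` rbf sigma is resolved to
#'   the median nonzero within-class pairwise distance.
#' @param tol Relative eigenvalue tolerance for basis and null-space
#'   extraction.
#' @return A [KNFSTModel-class].
#' @references Bodesheim, Freytag, Rodner, Kemmler, Denzler (2013),
#'   "Kernel Null Space Methods for Novelty Detection", CVPR.
#' @export
#' @examples
#' syn <- makeSyntheticTable(3, 0, 2, minSeparation = 500, seed = 1)
#' m <- fitKNFST(syn$train)
#' m
fitKNFST <- function(train, config = kernelConfig(), tol = 1e-12) {
  if (is(train, "PeakSet"))
    train <- new("PeakDataset", features = peakFeatures(train),
                 labels = peakLabels(train), provenance = "train")
  stopifnot(is(train, "PeakDataset"), is(config, "KernelConfig"))
  X <- train@features
  labels <- train@labels
  labs <- sort(unique(labels))
  C <- length(labs)
  if (C < 2L)
    stop("KNFST requires at least 2 classes: a null direction of the ",
         "within-class scatter with positive between-class scatter does ",
         "not exist for a single class")
  center <- c(0, 0); scl <- c(1, 1)
  if (config@standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scl, "/")
  }
  if (config@family == "rbf" && is.na(config@sigma))
    config@sigma <- .withinClassSigma(X, labels)
  n <- nrow(X)
  K <- kernelMatrix(X, X, config)
  rm_ <- rowMeans(K)
  Kc <- K - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(K)
  Kc <- (Kc + t(Kc)) / 2
  e <- eigen(Kc, symmetric = TRUE)
  keep <- which(e$values > tol * max(e$values, 0))
  if (!length(keep))
    stop("centered kernel matrix has numerical rank zero; ",
         "degenerate training set")
  B <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), length(keep))
  ## coordinates of the centered samples in the orthonormal basis:
  ## B' Kc = Lambda^{1/2} U', computed directly from the factorization
  TT <- sqrt(e$values[keep]) * t(e$vectors[, keep, drop = FALSE])
  M <- matrix(vapply(labs, function(l)
    rowMeans(TT[, labels == l, drop = FALSE]), numeric(nrow(TT))),
    nrow = nrow(TT))
  Tw <- TT - M[, match(labels, labs), drop = FALSE]
  Sw <- tcrossprod(Tw)
  es <- eigen(Sw, symmetric = TRUE)
  swmax <- max(es$values, 0)
  nullIdx <- which(es$values < 1e-8 * swmax)
  exactNull <- length(nullIdx) >= C - 1L
  if (!exactNull)                               # overlapping classes:
    nullIdx <- utils::tail(seq_along(es$values), C - 1L)
  Nb <- es$vectors[, nullIdx, drop = FALSE]
  Mn <- crossprod(Nb, M)                       # class means in null coords
  Mc <- Mn - rowMeans(Mn)
  eb <- eigen(tcrossprod(Mc), symmetric = TRUE)
  keepb <- which(eb$values > tol * max(eb$values, 0))
  keepb <- keepb[seq_len(min(length(keepb), C - 1L))]
  if (!length(keepb))
    stop("between-class scatter vanishes in the null space; degenerate ",
         "classes: ", paste(labs, collapse = ", "))
  W <- eb$vectors[, keepb, drop = FALSE]
  A <- B %*% Nb %*% W                          # n x d coefficients
  model <- new("KNFSTModel", X = X, labels = labels, classLabels = labs,
               coef = A, rowMeansK = rm_, grandMeanK = mean(K),
               targets = matrix(0, ncol(A), C,
                                dimnames = list(NULL, labs)),
               kernel = config, center = center, scale = scl,
               nullRatio = 0, tol = tol)
  Z <- .knfstProject(model, X, raw = TRUE)
  targets <- vapply(labs, function(l)
    rowMeans(Z[, labels == l, drop = FALSE]), numeric(nrow(Z)))
  targets <- matrix(targets, nrow = nrow(Z), dimnames = list(NULL, labs))
  ## achieved conditions: largest within-scatter eigenvalue relative to
  ## the largest between-target scatter eigenvalue
  Zw <- Z - targets[, match(labels, labs), drop = FALSE]
  wEig <- max(eigen(tcrossprod(Zw), symmetric = TRUE,
                    only.values = TRUE)$values, 0)
  Tc <- targets - rowMeans(targets)
  bEig <- max(eigen(tcrossprod(Tc), symmetric = TRUE,
                    only.values = TRUE)$values)
  model@targets <- targets
  model@nullRatio <- wEig / bEig
  validObject(model)
  model
}

## projection of (already scaled when raw=TRUE) feature rows; d x m.
## the kernel column of each point is doubly centered exactly as the
## training kernel was, so training projections live in the same
## coordinates in which the null space was extracted
.knfstProject <- function(model, Xnew, raw = FALSE) {
  if (!raw && model@kernel@standardize)
    Xnew <- sweep(sweep(Xnew, 2, model@center), 2, model@scale, "/")
  Kn <- kernelMatrix(model@X, Xnew, model@kernel)
  Kc <- Kn - model@rowMeansK -
    rep(colMeans(Kn), each = nrow(Kn)) + model@grandMeanK
  crossprod(model@coef, Kc)
}

#' Null-space projection of test points
#'
#' Maps feature rows into the learned null-space coordinates (the space in
#' which every training class collapses onto its target point).
#'
#' @param model A fitted [KNFSTModel-class].
#' @param x Feature matrix (m x 2, Hz) or a [PeakSet-class].
#' @return An m x d matrix of projected coordinates, d <= C - 1.
#' @export
#' @examples
#' syn <- makeSyntheticTable(3, 0, 2, minSeparation = 500, seed = 1)
#' m <- fitKNFST(syn$train)
#' knfstProject(m, peakFeatures(syn$train))
knfstProject <- function(model, x) {
  stopifnot(is(model, "KNFSTModel"))
  if (is(x, "PeakSet")) x <- peakFeatures(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  t(.knfstProject(model, x))
}

#' Distances of test points to the KNFST class targets
#'
#' Projects each test point into the learned null space and returns its
#' Euclidean distance to every class target. The predicted class is the
#' nearest target; the minimum distance is the novelty score (training
#' instances of a known class sit at distance ~0 from their target).
#'
#' @param model A fitted [KNFSTModel-class].
#' @param x Feature matrix (m x 2, Hz), a single `c(f2, f1)` vector, or a
#'   [PeakSet-class].
#' @return An m x C matrix of nonnegative distances (columns = classes).
#' @export
#' @examples
#' syn <- makeSyntheticTable(3, 1, 2, minSeparation = 500, seed = 1)
#' m <- fitKNFST(syn$train)
#' D <- knfstDistances(m, peakFeatures(syn$test))
#' colnames(D)[apply(D, 1, which.min)]
knfstDistances <- function(model, x) {
  stopifnot(is(model, "KNFSTModel"))
  if (is(x, "PeakSet")) x <- peakFeatures(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  Z <- .knfstProject(model, x)
  D2 <- outer(colSums(Z^2), colSums(model@targets^2), "+") -
    2 * crossprod(Z, model@targets)
  D <- sqrt(pmax(D2, 0))
  dimnames(D) <- list(NULL, model@classLabels)
  D
}

#' @rdname noveltyScores
#' @export
setMethod("noveltyScores", "KNFSTModel", function(model, x) {
  apply(knfstDistances(model, x), 1, min)
})

#' @rdname classifyPeaks
#' @export
setMethod("classifyPeaks", "KNFSTModel", function(model, x) {
  D <- knfstDistances(model, x)
  ## ties broken toward the lowest class index in sorted label order
  model@classLabels[apply(D, 1, which.min)]
})

#' @rdname modelAccessors
#' @export
setMethod("classLabels", "KNFSTModel", function(x) x@classLabels)

#' @rdname modelAccessors
#' @export
setMethod("bandwidth", "KNFSTModel", function(x) x@kernel@sigma)

setMethod("show", "KNFSTModel", function(object) {
  cat("KNFSTModel:", length(object@classLabels), "classes,",
      nrow(object@X), "training instances\n")
  cat(sprintf("kernel: %s (sigma = %.3g), projection dimension %d\n",
              object@kernel@family, object@kernel@sigma,
              ncol(object@coef)))
  cat(sprintf("within/between scatter ratio: %.3g%s\n", object@nullRatio,
              if (object@nullRatio < 1e-8) " (exact null space)" else
                " (approximate null space; overlapping classes)"))
})
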