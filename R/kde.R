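#' Construct a ParzenConfig
#'
#' @param h Parzen-window bandwidth in Hz; `NA` (default) selects it at fit
#'   time by maximizing the leave-one-out log-density of the training set
#'   over a logarithmic grid.
#' @param d Feature dimension (2).
#' @return A [ParzenConfig-class].
#' @export
#' @examples
#' parzenConfig(h = 12)
parzenConfig <- function(h = NA_real_, d = 2) {
  new("ParzenConfig", h = h, d = d)
}

#' Parzen-window density estimate
#'
#' Evaluates the Parzen estimator
#' `p(x) = (1/N) sum_i (1/h^d) k((x - x_i)/h)` with the standard
#' d-variate Gaussian profile `k(u) = (2 pi)^(-d/2) exp(-||u||^2 / 2)`.
#' At `d = 2` the density contributed by a single point at its own
#' location is `1 / (2 pi h^2)`.
#'
#' @param points N x d matrix of training points of one class.
#' @param x Query point(s): a length-d vector or an m x d matrix.
#' @param config A [ParzenConfig-class] with a resolved bandwidth.
#' @return Numeric vector of nonnegative density values, one per query.
#' @export
#' @examples
#' parzenDensity(matrix(c(100, 200), 1), c(100, 200),
#'               parzenConfig(h = 10))  # 1 / (2 pi 100)
parzenDensity <- function(points, x, config = parzenConfig(h = 10)) {
  stopifnot(is(config, "ParzenConfig"))
  if (is.na(config@h) || config@h <= 0)
    stop("parzenDensity needs a positive bandwidth h")
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  if (is.null(dim(x))) x <- matrix(x, ncol = ncol(points))
  if (ncol(x) != ncol(points))
    stop("query dimension does not match the point set")
  d <- config@d
  D2 <- .pairwiseSq(x, points)
  rowMeans(exp(-D2 / (2 * config@h^2))) / ((2 * pi)^(d / 2) * config@h^d)
}

#' Leave-one-out bandwidth selection
#'
#' Maximizes the mean leave-one-out log-density of the training points over
#' a logarithmic bandwidth grid; large training sets are thinned to
#' `maxPoints` deterministic points before the O(n^2) scan.
#'
#' @param X Training feature matrix.
#' @param grid Candidate bandwidths in Hz.
#' @param maxPoints Subsample cap for the pairwise computation.
#' @return The selected bandwidth (Hz).
#' @export
looBandwidth <- function(X, grid = exp(seq(log(2), log(200),
                                           length.out = 15)),
                         maxPoints = 1500L) {
  X <- as.matrix(X)
  if (nrow(X) > maxPoints)
    X <- X[seq(1L, nrow(X), length.out = maxPoints), , drop = FALSE]
  n <- nrow(X)
  if (n < 2L) return(grid[1])
  D2 <- as.matrix(stats::dist(X))^2
  score <- vapply(grid, function(h) {
    L <- exp(-D2 / (2 * h^2))
    diag(L) <- 0
    mean(log(pmax(rowSums(L) / (n - 1) / (2 * pi * h^2), 1e-300)))
  }, 0)
  grid[which.max(score)]
}

#' Fit a Parzen-window (KDE) classifier
#'
#' Partitions the training instances by metabolite label and stores them as
#' per-class Parzen density estimators sharing one global bandwidth.
#' Classification is by the largest class-conditional density; the largest
#' density also serves as the novelty score (novel peaks fall in
#' low-density regions of every class). No class priors are applied: the
#' augmentation balances class sizes by construction.
#'
#' @param train A [PeakDataset-class] or [PeakSet-class].
#' @param config A [ParzenConfig-class]; an `NA` bandwidth is resolved by
#'   [looBandwidth()].
#' @return A [KDEModel-class]. Unlike KNFST, a single-class training set is
#'   valid.
#' @export
#' @examples
#' syn <- makeSyntheticTable(3, 0, 2, minSeparation = 500, seed = 1)
#' fitKDE(syn$train, parzenConfig(h = 15))
fitKDE <- function(train, config = parzenConfig()) {
  if (is(train, "PeakSet"))
    train <- new("PeakDataset", features = peakFeatures(train),
                 labels = peakLabels(train), provenance = "train")
  stopifnot(is(train, "PeakDataset"), is(config, "ParzenConfig"))
  if (nrow(train@features) == 0L) stop("empty training set")
  if (is.na(config@h))
    config@h <- looBandwidth(train@features)
  labs <- sort(unique(train@labels))
  pts <- lapply(labs, function(l)
    train@features[train@labels == l, , drop = FALSE])
  names(pts) <- labs
  new("KDEModel", pointsByClass = pts, classLabels = labs, config = config)
}

#' Class-conditional Parzen densities of test points
#'
#' @param model A fitted [KDEModel-class].
#' @param x Feature matrix (m x 2, Hz), a single `c(f2, f1)` vector, or a
#'   [PeakSet-class].
#' @return An m x C matrix of class-conditional densities. The predicted
#'   label is the argmax column (ties broken toward the lowest class index
#'   in sorted label order); the row maximum is the novelty score.
#' @export
#' @examples
#' syn <- makeSyntheticTable(3, 1, 2, minSeparation = 500, seed = 1)
#' m <- fitKDE(syn$train, parzenConfig(h = 15))
#' S <- kdeScores(m, peakFeatures(syn$test))
#' colnames(S)[apply(S, 1, which.max)]
kdeScores <- function(model, x) {
  stopifnot(is(model, "KDEModel"))
  if (is(x, "PeakSet")) x <- peakFeatures(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  S <- vapply(model@classLabels, function(l)
    parzenDensity(model@pointsByClass[[l]], x, model@config),
    numeric(nrow(x)))
  S <- matrix(S, nrow = nrow(x),
              dimnames = list(NULL, model@classLabels))
  S
}

#' @rdname noveltyScores
#' @export
setMethod("noveltyScores", "KDEModel", function(model, x) {
  apply(kdeScores(model, x), 1, max)
})

#' @rdname classifyPeaks
#' @export
setMethod("classifyPeaks", "KDEModel", function(model, x) {
  S <- kdeScores(model, x)
  model@classLabels[apply(S, 1, which.max)]
})

#' @rdname modelAccessors
#' @export
setMethod("classLabels", "KDEModel", function(x) x@classLabels)

#' @rdname modelAccessors
#' @export
setMethod("bandwidth", "KDEModel", function(x) x@config@h)

setMethod("show", "KDEModel", function(object) {
  cat("KDEModel:", length(object@classLabels), "classes,",
      sum(vapply(object@pointsByClass, nrow, 0L)),
      "training instances\n")
  cat(sprintf("Parzen window: Gaussian, h = %.3g Hz\n", object@config@h))
})
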