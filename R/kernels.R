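#' Construct a KernelConfig
#'
#' @param family Kernel family: `"rbf"` (default), `"polynomial"` or
#'   `"linear"`.
#' @param sigma RBF bandwidth in Hz; `NA` (default) selects the median
#'   nonzero within-class pairwise distance of the training set at fit
#'   time. That scale resolves the structure the classifier must separate
#'   (class clouds a few tens of Hz wide); a global median pairwise
#'   distance would be dominated by the window size and oversmooth.
#' @param degree Polynomial degree.
#' @param standardize Standardize the frequency axes before kernel
#'   evaluation (off by default; both axes share units).
#' @return A [KernelConfig-class].
#' @export
#' @examples
#' kernelConfig(sigma = 60)
kernelConfig <- function(family = "rbf", sigma = NA_real_, degree = 2,
                         standardize = FALSE) {
  new("KernelConfig", family = family, sigma = sigma, degree = degree,
      standardize = standardize)
}

## squared Euclidean distances, accumulated per dimension: with only two
## feature columns this is as fast as the Gram-matrix identity and avoids
## its catastrophic cancellation at O(10^3) Hz coordinates
.pairwiseSq <- function(X, Y) {
  D2 <- 0
  for (j in seq_len(ncol(X)))
    D2 <- D2 + outer(X[, j], Y[, j], "-")^2
  D2
}

#' Kernel matrix between two feature tables
#'
#' Evaluates `k(x_i, y_j)` for all pairs of rows. For the rbf family
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`; polynomial is
#' `(1 + <x, y> / s)^degree` with `s` the mean squared norm scale; linear
#' is the plain inner product.
#'
#' @param X,Y Numeric feature matrices with the same number of columns.
#' @param config A [KernelConfig-class]; for the rbf family `sigma` must be
#'   resolved (not `NA`).
#' @return The `nrow(X)` x `nrow(Y)` kernel matrix; symmetric positive
#'   semidefinite (up to numerical tolerance) when `X` and `Y` coincide.
#' @export
#' @examples
#' X <- cbind(c(0, 3), c(0, 4))
#' kernelMatrix(X, X, kernelConfig(sigma = 5))
kernelMatrix <- function(X, Y, config = kernelConfig(sigma = 30)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("feature dimensionality of X and Y must match")
  switch(config@family,
         rbf = {
           if (is.na(config@sigma))
             stop("rbf sigma is unresolved; fit selects it or set it in ",
                  "kernelConfig()")
           exp(-.pairwiseSq(X, Y) / (2 * config@sigma^2))
         },
         polynomial = {
           s <- mean(c(rowSums(X^2), rowSums(Y^2)))
           if (s == 0) s <- 1
           (1 + tcrossprod(X, Y) / s)^config@degree
         },
         linear = tcrossprod(X, Y))
}

## median nonzero within-class pairwise distance; global median fallback
## when no class has two distinct points
.withinClassSigma <- function(X, labels, maxPer = 200L) {
  ds <- unlist(lapply(split(seq_along(labels), labels), function(i) {
    if (length(i) < 2L) return(NULL)
    if (length(i) > maxPer) i <- i[seq(1L, length(i), length.out = maxPer)]
    d <- stats::dist(X[i, , drop = FALSE])
    d[d > 0]
  }))
  if (length(ds)) return(stats::median(ds))
  d <- stats::dist(X[seq(1L, nrow(X),
                         length.out = min(nrow(X), 1000L)), , drop = FALSE])
  d <- d[d > 0]
  if (!length(d)) stop("cannot select a kernel bandwidth: ",
                       "all training points coincide")
  stats::median(d)
}
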