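## shared helpers: small deterministic problems used across test files

refTable <- function() loadReferenceTable()

## a well-separated synthetic problem plus an augmented training set
separableProblem <- function(nKnown = 3, nNovel = 0, peaksPerClass = 2,
                             minSep = 500, seed = 1, nTotal = 300) {
  syn <- makeSyntheticTable(nKnown, nNovel, peaksPerClass,
                            minSeparation = minSep, seed = seed)
  syn$augmented <- augmentShift(syn$train,
                                augmentationConfig(nTotal = nTotal,
                                                   seed = seed))
  syn
}

## peak set with a single peak (edge cases)
onePeakSet <- function(f2 = 1000, f1 = 800, label = "X") {
  new("PeakSet", sample = "one",
      peaks = data.frame(metabolite = label, f2 = f2, f1 = f1,
                         stringsAsFactors = FALSE))
}

## brute-force Parzen density: naive double loop, the independent oracle
naiveParzen <- function(points, x, h, d = 2) {
  vapply(seq_len(nrow(x)), function(i) {
    s <- 0
    for (j in seq_len(nrow(points))) {
      u <- (x[i, ] - points[j, ]) / h
      s <- s + exp(-sum(u^2) / 2) / (2 * pi)^(d / 2)
    }
    s / (nrow(points) * h^d)
  }, 0)
}

## open-set prediction assembled by hand from counts (for metric tests)
predFromCounts <- function(Fn, Fp, Fe, Nn, N, knownLabels = c("A", "B")) {
  stopifnot(Fn <= Nn, Fp + Fe <= N - Nn)
  nKnown <- N - Nn
  truth <- c(rep("A", nKnown), rep("ZNOVEL", Nn))
  predicted <- rep("A", N)
  novel <- rep(FALSE, N)
  if (Fe > 0) predicted[seq_len(Fe)] <- "B"            # within-known errors
  if (Fp > 0) novel[Fe + seq_len(Fp)] <- TRUE          # known -> novel
  if (Nn > 0) novel[nKnown + seq_len(Nn)] <- TRUE      # novel detected...
  if (Fn > 0) novel[nKnown + seq_len(Fn)] <- FALSE     # ...except Fn missed
  predicted[novel] <- NA_character_
  new("OpenSetPrediction",
      results = data.frame(truth = truth, predicted = predicted,
                           novel = novel, score = seq_len(N),
                           stringsAsFactors = FALSE),
      classifier = "knfst", sample = "synthetic")
}
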