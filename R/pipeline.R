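#' Construct an ExperimentConfig
#'
#' Settings of the full profiling experiment: a training model is built
#' from the reference sample by shift augmentation, both classifiers are
#' fitted, novelty thresholds are selected on a noise-perturbed validation
#' set, and every test sample is evaluated openly against the model.
#'
#' @param reference Reference sample identifier (default `"ct_d4"`).
#' @param testSamples Test sample identifiers.
#' @param augmentation An [AugmentationConfig-class]; its seed drives the
#'   augmentation and validation draws.
#' @param kernel A [KernelConfig-class] for KNFST.
#' @param parzen A [ParzenConfig-class] for KDE.
#' @param thresholdStrategy `"min-error"` (default; pseudo-novel scores
#'   are drawn uniformly over the spectral window) or `"quantile"`.
#' @param validationPerPeak Validation copies per training peak.
#' @param pseudoNovelSeed Seed of the pseudo-novel draw.
#' @param outDir Directory for artifacts (`NA`: keep everything in
#'   memory).
#' @return An [ExperimentConfig-class].
#' @export
#' @examples
#' experimentConfig(augmentation = augmentationConfig(seed = 3))
experimentConfig <- function(reference = "ct_d4",
                             testSamples = c("ct_d14", "at_d14", "os_d14"),
                             augmentation = augmentationConfig(),
                             kernel = kernelConfig(),
                             parzen = parzenConfig(),
                             thresholdStrategy = "min-error",
                             validationPerPeak = 20,
                             pseudoNovelSeed = 1,
                             outDir = NA_character_) {
  new("ExperimentConfig", reference = reference, testSamples = testSamples,
      augmentation = augmentation, kernel = kernel, parzen = parzen,
      thresholdStrategy = thresholdStrategy,
      validationPerPeak = validationPerPeak,
      pseudoNovelSeed = pseudoNovelSeed, outDir = outDir)
}

## uniform pseudo-novel points over the spectral window
.pseudoNovel <- function(n, seed) {
  set.seed(seed)
  matrix(stats::runif(2 * n, 0, .SPECTRAL_WIDTH_HZ), ncol = 2,
         dimnames = list(NULL, c("f2", "f1")))
}

#' Run the full open-set profiling experiment
#'
#' Executes the complete pipeline for both classifiers: augment the
#' reference sample into the training set, fit, select the novelty
#' threshold on the validation set (with pseudo-novel scores under the
#' `"min-error"` strategy), predict every test sample openly, and compute
#' the error metrics. Fully deterministic given the seeds in `config`.
#'
#' @param config An [ExperimentConfig-class].
#' @param table A [PeakTable-class] (defaults to the bundled reference
#'   table).
#' @return An [ExperimentReport-class].
#' @export
#' @examples
#' \donttest{
#' rep <- runExperiment(experimentConfig(
#'   augmentation = augmentationConfig(nTotal = 500, seed = 1)))
#' rep@metrics[["ct_d14.knfst"]]
#' }
runExperiment <- function(config = experimentConfig(),
                          table = loadReferenceTable()) {
  stopifnot(is(config, "ExperimentConfig"), is(table, "PeakTable"))
  validObject(config)
  bad <- setdiff(c(config@reference, config@testSamples),
                 peakSamples(table))
  if (length(bad))
    stop("sample(s) not present in the peak table: ",
         paste(bad, collapse = ", "))
  refPeaks <- extractSample(table, config@reference)
  augSeed <- config@augmentation@seed
  valSeed <- augSeed + 100003
  seeds <- c(augmentation = augSeed, validation = valSeed,
             pseudoNovel = config@pseudoNovelSeed)

  train <- augmentShift(refPeaks, config@augmentation)
  valCfg <- config@augmentation
  valCfg@seed <- valSeed
  val <- augmentNoise(refPeaks, config@validationPerPeak, valCfg)

  knfst <- fitKNFST(train, config@kernel)
  kde <- fitKDE(train, config@parzen)
  knownLabels <- classLabels(knfst)

  pn <- if (config@thresholdStrategy == "min-error")
    .pseudoNovel(nrow(val@features), config@pseudoNovelSeed) else NULL
  thresholds <- list(
    knfst = selectThreshold(noveltyScores(knfst, val@features),
                            if (!is.null(pn)) noveltyScores(knfst, pn),
                            direction = "greater",
                            strategy = config@thresholdStrategy),
    kde = selectThreshold(noveltyScores(kde, val@features),
                          if (!is.null(pn)) noveltyScores(kde, pn),
                          direction = "less",
                          strategy = config@thresholdStrategy))

  metrics <- list(); predictions <- list(); artifacts <- character(0)
  outDir <- config@outDir
  writeOut <- !is.na(outDir)
  if (writeOut) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  models <- list(knfst = knfst, kde = kde)
  for (s in config@testSamples) {
    testSet <- extractSample(table, s)
    for (clf in names(models)) {
      key <- paste(s, clf, sep = ".")
      p <- predictOpenSet(models[[clf]], thresholds[[clf]], testSet)
      predictions[[key]] <- p
      metrics[[key]] <- computeMetrics(p, knownLabels)
      if (writeOut) {
        cm <- confusionMatrix(p, knownLabels)
        cmPath <- file.path(outDir,
                            sprintf("confusion_%s_%s.csv", s, clf))
        utils::write.csv(cm, cmPath)
        idx <- seq(1L, nrow(train@features), length.out = 500L)
        plotPath <- file.path(outDir, sprintf("scores_%s_%s.png", s, clf))
        plotNoveltyScores(p, noveltyScores(models[[clf]],
                                           train@features[idx, ]),
                          thresholds[[clf]], plotPath, knownLabels)
        artifacts <- c(artifacts, cmPath, plotPath)
      }
    }
  }
  report <- new("ExperimentReport", metrics = metrics,
                predictions = predictions, thresholds = thresholds,
                config = config, seeds = seeds, artifacts = artifacts)
  if (writeOut) {
    jsonPath <- file.path(outDir, "metrics.json")
    writeMetricsJSON(report, jsonPath)
    csvPath <- file.path(outDir, "table2.csv")
    utils::write.csv(metricsTable(report), csvPath)
    logPath <- file.path(outDir, "run.log")
    writeLines(c(sprintf("reference: %s", config@reference),
                 sprintf("test samples: %s",
                         paste(config@testSamples, collapse = ", ")),
                 sprintf("nTotal=%d maxShift=%g noiseSigma=%g cap=%d",
                         config@augmentation@nTotal,
                         config@augmentation@maxShift,
                         config@augmentation@noiseSigma,
                         config@augmentation@perClassCap),
                 sprintf("knfst sigma=%.6g  kde h=%.6g",
                         bandwidth(knfst), bandwidth(kde)),
                 sprintf("seeds: %s",
                         paste(names(seeds), seeds, sep = "=",
                               collapse = " "))), logPath)
    report@artifacts <- c(report@artifacts, jsonPath, csvPath, logPath)
  }
  report
}

#' Metrics of a report as a data.frame / JSON
#'
#' `metricsTable()` arranges the three rates as rows and the
#' (sample x classifier) pairs as columns, the layout of a performance
#' summary table. `writeMetricsJSON()` serializes all counts and rates to
#' a JSON file (deterministic bytes for identical reports).
#'
#' @param report An [ExperimentReport-class].
#' @return `metricsTable()` a `data.frame`; `writeMetricsJSON()` the path,
#'   invisibly.
#' @export
metricsTable <- function(report) {
  stopifnot(is(report, "ExperimentReport"))
  cells <- names(report@metrics)
  out <- vapply(cells, function(k) {
    m <- report@metrics[[k]]
    c(m@fnr, m@fpr, m@totalError)
  }, numeric(3))
  df <- as.data.frame(out)
  rownames(df) <- c("falseNegativeRate", "falsePositiveRate", "totalError")
  df
}

#' @rdname metricsTable
#' @param path Output file for the JSON serialization.
#' @export
writeMetricsJSON <- function(report, path) {
  stopifnot(is(report, "ExperimentReport"))
  out <- lapply(report@metrics, function(m)
    list(Fn = m@Fn, Fp = m@Fp, Fe = m@Fe, Nn = m@Nn, N = m@N,
         fnr = m@fnr, fpr = m@fpr, totalError = m@totalError))
  out$seeds <- as.list(report@seeds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Multi-seed aggregation of the experiment
#'
#' Reruns [runExperiment()] over `nSeeds` augmentation seeds (1..nSeeds)
#' and aggregates each (sample x classifier) cell: median and range of the
#' total error, and the median false negative/positive rates. When a
#' `reference` matrix of total-error percentages is supplied, each cell's
#' median is additionally compared against it with a tolerance of one
#' misclassified instance (100/N percentage points).
#'
#' @param config An [ExperimentConfig-class] (its augmentation seed is
#'   overridden per run).
#' @param nSeeds Number of augmentation seeds (>= 1).
#' @param table A [PeakTable-class].
#' @param reference Optional named numeric vector of reference total-error
#'   percentages (names `<sample>.<classifier>`).
#' @return A `data.frame` with one row per cell: median/min/max total
#'   error, median fnr and fpr, N, and (when `reference` is given) the
#'   reference value and a within-tolerance flag.
#' @export
#' @examples
#' \donttest{
#' cfg <- experimentConfig(augmentation = augmentationConfig(nTotal = 500))
#' reproduceTable2(cfg, nSeeds = 2)
#' }
reproduceTable2 <- function(config = experimentConfig(), nSeeds = 5,
                            table = loadReferenceTable(),
                            reference = NULL) {
  stopifnot(nSeeds >= 1)
  runs <- lapply(seq_len(nSeeds), function(s) {
    cfg <- config
    cfg@augmentation@seed <- s
    cfg@pseudoNovelSeed <- s
    cfg@outDir <- NA_character_
    runExperiment(cfg, table)
  })
  cells <- names(runs[[1]]@metrics)
  rows <- lapply(cells, function(k) {
    tot <- vapply(runs, function(r) r@metrics[[k]]@totalError, 0)
    data.frame(cell = k,
               medianTotalError = stats::median(tot),
               minTotalError = min(tot), maxTotalError = max(tot),
               medianFnr = stats::median(
                 vapply(runs, function(r) r@metrics[[k]]@fnr, 0)),
               medianFpr = stats::median(
                 vapply(runs, function(r) r@metrics[[k]]@fpr, 0)),
               N = runs[[1]]@metrics[[k]]@N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    out$reference <- reference[out$cell]
    out$withinTolerance <- abs(out$medianTotalError - out$reference) <=
      100 / out$N + 1e-9
  }
  out
}
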