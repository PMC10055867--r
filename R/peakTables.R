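#' Load the bundled reference cross-peak table
#'
#' Reads the packaged multi-sample TOCSY cross-peak table of intracellular
#' metabolites detected in adipose-tissue-derived human mesenchymal stem
#' cells: 85 cross peaks over 32 metabolites, with (F2, F1) frequencies in
#' Hz (600.13 MHz spectrometer) for the four samples `ct_d4`, `ct_d14`,
#' `at_d14`, `os_d14` and a standard frequency pair per row. Absent peaks
#' ("NP", a metabolite disappearing during cultivation or differentiation)
#' are represented as `NA` pairs.
#'
#' @param path Path to a table in the same TSV dialect; defaults to the
#'   bundled fixture.
#' @return A [PeakTable-class].
#' @export
#' @examples
#' tab <- loadReferenceTable()
#' tab
loadReferenceTable <- function(path = system.file("extdata",
                                                  "table1_tocsy_hmsc.tsv",
                                                  package = "TOCSYprofiler")) {
  if (!nzchar(path) || !file.exists(path))
    stop("reference table fixture not found: '", path, "'")
  df <- utils::read.delim(path, na.strings = "NP", check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  samples <- unique(sub("_f[12]$", "",
                        grep("_f[12]$", names(df), value = TRUE)))
  samples <- setdiff(samples, "std")
  freqcols <- grep("_f[12]$", names(df), value = TRUE)
  for (cc in freqcols) {
    bad <- which(!is.na(df[[cc]]) & is.na(suppressWarnings(
      as.numeric(df[[cc]]))))
    if (length(bad))
      stop("malformed reference table: non-numeric frequency in column '",
           cc, "', row ", bad[1])
    df[[cc]] <- as.numeric(df[[cc]])
  }
  new("PeakTable", rows = df, samples = samples)
}

#' @rdname PeakSet-accessors
#' @export
setMethod("peakSamples", "PeakTable", function(x) x@samples)

#' @rdname PeakSet-accessors
#' @export
setMethod("nPeaks", "PeakTable", function(x) nrow(x@rows))

setMethod("show", "PeakTable", function(object) {
  cat("PeakTable with", nrow(object@rows), "cross peaks,",
      length(unique(object@rows$metabolite)), "metabolites\n")
  cat("samples:", paste(object@samples, collapse = ", "), "\n")
  counts <- vapply(object@samples, function(s)
    sum(!is.na(object@rows[[paste0(s, "_f2")]])), 0L)
  cat("peaks per sample:",
      paste(sprintf("%s=%d", object@samples, counts), collapse = ", "), "\n")
})

#' Extract one sample's peaks from a reference table
#'
#' Returns the cross peaks that are present (not "NP") in the requested
#' sample, in table order, as a labeled peak set.
#'
#' @param table A [PeakTable-class].
#' @param sample One of `peakSamples(table)`.
#' @return A [PeakSet-class].
#' @export
#' @examples
#' tab <- loadReferenceTable()
#' extractSample(tab, "ct_d4")
extractSample <- function(table, sample) {
  stopifnot(is(table, "PeakTable"))
  if (!sample %in% table@samples)
    stop("unknown sample '", sample, "'; valid samples: ",
         paste(table@samples, collapse = ", "))
  f2 <- table@rows[[paste0(sample, "_f2")]]
  keep <- !is.na(f2)
  new("PeakSet", sample = sample,
      peaks = data.frame(metabolite = table@rows$metabolite[keep],
                         f2 = f2[keep],
                         f1 = table@rows[[paste0(sample, "_f1")]][keep],
                         stringsAsFactors = FALSE))
}

#' @rdname PeakSet-accessors
#' @export
setMethod("peakFeatures", "PeakSet", function(x) {
  m <- as.matrix(x@peaks[, c("f2", "f1")])
  rownames(m) <- NULL
  m
})

#' @rdname PeakSet-accessors
#' @export
setMethod("peakLabels", "PeakSet", function(x) x@peaks$metabolite)

#' @rdname PeakSet-accessors
#' @export
setMethod("sampleName", "PeakSet", function(x) x@sample)

#' @rdname PeakSet-accessors
#' @export
setMethod("nPeaks", "PeakSet", function(x) nrow(x@peaks))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet '", object@sample, "': ", nrow(object@peaks), " peaks, ",
      length(unique(object@peaks$metabolite)), " metabolites\n", sep = "")
  if (nrow(object@peaks))
    print(utils::head(object@peaks, 4))
})

#' Metabolite labels novel to a test sample
#'
#' Labels present in the test peak set but absent from the training peak
#' set; these are the metabolites a trained model has never seen and should
#' flag as novel.
#'
#' @param train,test [PeakSet-class] objects.
#' @return Character vector of novel labels (sorted).
#' @export
#' @examples
#' tab <- loadReferenceTable()
#' novelLabels(extractSample(tab, "ct_d4"), extractSample(tab, "os_d14"))
novelLabels <- function(train, test) {
  stopifnot(is(train, "PeakSet"), is(test, "PeakSet"))
  sort(setdiff(unique(test@peaks$metabolite),
               unique(train@peaks$metabolite)))
}

#' Convert between Hz and ppm
#'
#' Chemical-shift unit conversion at a given spectrometer frequency:
#' `ppm = Hz / MHz`.
#'
#' @param f Frequency in Hz (`hzToPpm`) or chemical shift in ppm
#'   (`ppmToHz`).
#' @param spectrometerMHz Spectrometer frequency in MHz (default 600.13).
#' @return Numeric vector of the converted values.
#' @export
#' @examples
#' hzToPpm(7201.56)  # 12 ppm: the spectral width
hzToPpm <- function(f, spectrometerMHz = .SPECTROMETER_MHZ) {
  if (any(spectrometerMHz <= 0))
    stop("spectrometer frequency must be positive")
  f / spectrometerMHz
}

#' @rdname hzToPpm
#' @export
ppmToHz <- function(f, spectrometerMHz = .SPECTROMETER_MHZ) {
  if (any(spectrometerMHz <= 0))
    stop("spectrometer frequency must be positive")
  f * spectrometerMHz
}

#' Read and write labeled peak sets
#'
#' `readPeakSet()` reads a labeled peak set from a delimited file. The
#' `csv`/`tsv` dialects expect a header `metabolite,f2_hz,f1_hz` (UTF-8,
#' "." decimal separator) and round-trip with `writePeakSet()` bit-exactly.
#' The read-only `topspin` dialect parses peak lists exported from
#' acquisition software: comment lines start with `#`, data columns are
#' peak number, F2, F1 and (ignored) intensity; frequencies may be in ppm
#' (default, converted to Hz) or already in Hz.
#'
#' @param path File to read or write.
#' @param dialect `"csv"`, `"tsv"` or (read-only) `"topspin"`.
#' @param sample Sample identifier to attach to the peaks read.
#' @param topspinUnits `"ppm"` or `"hz"`: units of a topspin list.
#' @param spectrometerMHz Spectrometer frequency for ppm conversion.
#' @return `readPeakSet()` a [PeakSet-class]; `writePeakSet()` the path,
#'   invisibly.
#' @export
#' @examples
#' tab <- loadReferenceTable()
#' f <- tempfile(fileext = ".csv")
#' writePeakSet(extractSample(tab, "ct_d4"), f)
#' readPeakSet(f, sample = "ct_d4")
readPeakSet <- function(path, dialect = c("csv", "tsv", "topspin"),
                        sample = "unknown", topspinUnits = c("ppm", "hz"),
                        spectrometerMHz = .SPECTROMETER_MHZ) {
  dialect <- match.arg(dialect)
  if (dialect == "topspin")
    return(.readTopspin(path, sample, match.arg(topspinUnits),
                        spectrometerMHz))
  sep <- if (dialect == "csv") "," else "\t"
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  need <- c("metabolite", "f2_hz", "f1_hz")
  if (!all(need %in% hdr))
    stop("peak-set file '", path, "' is missing columns: ",
         paste(setdiff(need, hdr), collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = rep("character", length(hdr)))
  for (cc in c("f2_hz", "f1_hz")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & nzchar(df[[cc]]))
    if (length(bad) || anyNA(v))
      stop("non-numeric frequency in '", path, "', line ",
           (if (length(bad)) bad[1] else which(is.na(v))[1]) + 1L)
    df[[cc]] <- v
  }
  new("PeakSet", sample = sample,
      peaks = data.frame(metabolite = df$metabolite, f2 = df$f2_hz,
                         f1 = df$f1_hz, stringsAsFactors = FALSE))
}

.readTopspin <- function(path, sample, units, spectrometerMHz) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("topspin peak list '", path, "' has no data rows")
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 3)
      stop("topspin peak list '", path, "': too few columns on line ", i)
    v <- suppressWarnings(as.numeric(fields[2:3]))
    if (anyNA(v))
      stop("topspin peak list '", path,
           "': non-numeric frequency on line ", i)
    v
  })
  f <- do.call(rbind, parsed)
  if (units == "ppm") f <- f * spectrometerMHz
  new("PeakSet", sample = sample,
      peaks = data.frame(metabolite = sprintf("peak_%d", seq_along(rows)),
                         f2 = f[, 1], f1 = f[, 2],
                         stringsAsFactors = FALSE))
}

#' @rdname readPeakSet
#' @param x A [PeakSet-class] to write.
#' @export
writePeakSet <- function(x, path, dialect = c("csv", "tsv")) {
  stopifnot(is(x, "PeakSet"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  ## %.17g preserves doubles exactly, so write -> read is an identity
  lines <- c(paste(c("metabolite", "f2_hz", "f1_hz"), collapse = sep),
             sprintf(paste0("%s", sep, "%.17g", sep, "%.17g"),
                     x@peaks$metabolite, x@peaks$f2, x@peaks$f1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
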