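# Plain-text input format and result writers.
#
# An input file is a set of "Key: value" lines (keys case-sensitive,
# whitespace around ":" and between values flexible, blank lines and lines
# starting with "#" ignored):
#
#   FragmentName: TryptophanProtonated
#   FragmentFormula: C11H13N2O2
#   CanAcquireLabel: C11H13N2O2
#   MIDm: 0.88885 0.106829 0.004322
#   LabeledElement: C
#   TracerEnrichment: 1
#   LabelEnrichment: 1
#   HighRes: N O H

.REQUIRED_KEYS <- c("FragmentName", "FragmentFormula", "CanAcquireLabel",
                    "MIDm", "LabeledElement", "TracerEnrichment",
                    "LabelEnrichment", "HighRes")

.parseKeyLines <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  out <- lapply(idx, function(i) {
    line <- lines[i]
    if (!grepl(":", line, fixed = TRUE))
      stop("line ", i, ": expected 'Key: value', got '", trimws(line), "'")
    pos <- regexpr(":", line, fixed = TRUE)
    list(key = trimws(substr(line, 1L, pos - 1L)),
         value = trimws(substr(line, pos + 1L, nchar(line))),
         line = i)
  })
  out
}

.splitValues <- function(value) strsplit(trimws(value), "[ \t]+")[[1]]

.numericValue <- function(value, key, line) {
  v <- suppressWarnings(as.numeric(value))
  if (any(is.na(v)))
    stop("line ", line, ", key ", key, ": '", paste(value, collapse = " "),
         "' is not numeric")
  v
}

.specFromPairs <- function(pairs, table, context = "input") {
  keys <- vapply(pairs, `[[`, "", "key")
  for (k in .REQUIRED_KEYS) {
    n <- sum(keys == k)
    if (n == 0L) stop(context, ": missing required key '", k, "'")
    if (n > 1L) stop(context, ": key '", k, "' appears ", n, " times")
  }
  unknown <- setdiff(keys, .REQUIRED_KEYS)
  if (length(unknown))
    stop(context, ": unrecognized key(s): ", paste(unknown, collapse = ", "))
  get <- function(k) pairs[[which(keys == k)]]
  wrap <- function(k, expr) {
    p <- get(k)
    tryCatch(expr(p), error = function(e)
      stop("line ", p$line, ", key ", k, ": ", conditionMessage(e),
           call. = FALSE))
  }
  mid <- wrap("MIDm", function(p) {
    v <- .numericValue(.splitValues(p$value), "MIDm", p$line)
    if (length(v) == 0L) stop("no values given")
    if (any(v < 0)) stop("MIDm values must be >= 0")
    v
  })
  tracerE <- wrap("TracerEnrichment", function(p)
    .checkEnrichmentFraction(.numericValue(p$value, "TracerEnrichment", p$line),
                             "TracerEnrichment"))
  labelE <- wrap("LabelEnrichment", function(p)
    .checkEnrichmentFraction(.numericValue(p$value, "LabelEnrichment", p$line),
                             "LabelEnrichment"))
  highRes <- .splitValues(get("HighRes")$value)
  wrap("HighRes", function(p) {
    if (length(highRes) == 0L) stop("no value given")
    invisible(NULL)
  })
  wrap("FragmentFormula", function(p) FragmentSpec(
    name = get("FragmentName")$value,
    formula = get("FragmentFormula")$value,
    canAcquireLabel = get("CanAcquireLabel")$value,
    measuredMID = mid,
    labeledElement = get("LabeledElement")$value,
    tracerEnrichment = tracerE, labelEnrichment = labelE,
    highRes = highRes, table = table))
}

#' Read a fragment specification from a plain-text input file
#'
#' Parses the key:value format shown above into a validated
#' [FragmentSpec-class]. Key order is not significant; blank lines and
#' `#`-comment lines are ignored. Errors name the offending line and key.
#'
#' @param path path to the input file.
#' @param table an [AbundanceTable-class].
#' @return a `FragmentSpec`.
#' @seealso [readFragments()] for multi-record files, [writeFragment()]
#' @export
readFragment <- function(path, table = defaultAbundanceTable()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  pairs <- .parseKeyLines(readLines(path, warn = FALSE))
  if (length(pairs) == 0L) stop(path, ": no key:value lines found")
  .specFromPairs(pairs, table, context = path)
}

#' Read several fragment records from one file
#'
#' A multi-record file concatenates complete key blocks; a new record starts
#' at each `FragmentName:` line. Each record must carry all eight keys.
#'
#' @inheritParams readFragment
#' @return list of [FragmentSpec-class] objects.
#' @export
readFragments <- function(path, table = defaultAbundanceTable()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  pairs <- .parseKeyLines(readLines(path, warn = FALSE))
  if (length(pairs) == 0L) stop(path, ": no key:value lines found")
  starts <- which(vapply(pairs, `[[`, "", "key") == "FragmentName")
  if (length(starts) == 0L) stop(path, ": no FragmentName key found")
  ends <- c(starts[-1L] - 1L, length(pairs))
  lapply(seq_along(starts), function(i) {
    .specFromPairs(pairs[starts[i]:ends[i]], table,
                   context = sprintf("%s (record %d)", path, i)) })
}

#' Write a fragment specification as an input file
#'
#' Serializes a [FragmentSpec-class] back into the key:value text format, so
#' that [readFragment()] on the result reproduces an identical spec.
#'
#' @param spec a `FragmentSpec`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
writeFragment <- function(spec, path) {
  stopifnot(methods::is(spec, "FragmentSpec"))
  hr <- highResElements(spec)
  lines <- c(
    paste("FragmentName:", fragmentName(spec)),
    paste("FragmentFormula:", .formatFormula(fragmentFormula(spec))),
    paste("CanAcquireLabel:", .formatFormula(canAcquireLabel(spec))),
    paste("MIDm:", paste(format(measuredMID(spec), digits = 15,
                                scientific = FALSE, trim = TRUE),
                         collapse = " ")),
    paste("LabeledElement:", labeledElement(spec)),
    paste("TracerEnrichment:", format(tracerEnrichment(spec), digits = 15)),
    paste("LabelEnrichment:", format(labelEnrichment(spec), digits = 15)),
    paste("HighRes:", if (length(hr)) paste(hr, collapse = " ") else "none"))
  writeLines(lines, path)
  invisible(path)
}

#' Run a correction from a spec or an input-file path
#'
#' Convenience front end used by the command-line script: accepts either a
#' [FragmentSpec-class] or the path of an input file, runs [correctMID()],
#' prints the text report (unless `quiet = TRUE`) and returns the full
#' [CorrectionResult-class] so pipelines can consume the corrected MID and
#' SSE programmatically.
#'
#' @param x a `FragmentSpec` or an input-file path.
#' @param table an [AbundanceTable-class].
#' @param quiet suppress the printed report.
#' @return a `CorrectionResult`, invisibly.
#' @export
runCorrection <- function(x, table = defaultAbundanceTable(), quiet = FALSE) {
  spec <- if (methods::is(x, "FragmentSpec")) x
          else if (is.character(x) && length(x) == 1L) readFragment(x, table)
          else stop("x must be a FragmentSpec or an input-file path")
  res <- correctMID(spec, table)
  if (!quiet) cat(formatResultText(res), sep = "\n")
  invisible(res)
}

#' Format a correction result as the plain-text report
#'
#' @param result a [CorrectionResult-class].
#' @return character vector of report lines.
#' @export
formatResultText <- function(result) {
  c(paste("FragmentName:", fragmentName(result)),
    paste("CorrectedMID:",
          paste(formatC(unname(correctedMID(result)), format = "f",
                        digits = 6), collapse = " ")),
    paste("SSE:", format(sse(result), digits = 6)),
    if (length(correctionWarnings(result)))
      paste("Warning:", correctionWarnings(result)))
}

#' Write a correction result to a file
#'
#' `format = "text"` mirrors the console report (name, corrected MID to six
#' decimals, SSE, warnings). `format = "csv"` writes one row per label count
#' with columns `label_count`, `corrected_fraction` and `warning` (set to
#' `"negative"` on rows whose corrected component is negative). Negative
#' components appear verbatim in both formats. Full precision is available
#' from the returned [CorrectionResult-class] object itself.
#'
#' @param result a `CorrectionResult`.
#' @param path destination file path.
#' @param format `"text"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeResult <- function(result, path, format = c("text", "csv")) {
  stopifnot(methods::is(result, "CorrectionResult"))
  format <- match.arg(format)
  if (format == "text") {
    writeLines(formatResultText(result), path)
  } else {
    x <- unname(correctedMID(result))
    df <- data.frame(label_count = seq_along(x) - 1L,
                     corrected_fraction = x,
                     warning = ifelse(x < 0, "negative", ""))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
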