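.asCounts <- function(x, what, table) {
  if (is.character(x)) return(parseFormula(x, table))
  if (!is.numeric(x) || is.null(names(x)))
    stop(what, " must be a formula string or a named count vector")
  storage.mode(x) <- "integer"
  x
}

.resolveHighRes <- function(highRes, formulaElements, labeledElement, table) {
  if (is.null(highRes) || length(highRes) == 0L) return(character(0))
  stopifnot(is.character(highRes))
  if (length(highRes) == 1L && tolower(highRes) == "none") return(character(0))
  if (length(highRes) == 1L && tolower(highRes) == "all")
    return(setdiff(formulaElements, labeledElement))
  unknown <- setdiff(highRes, elementSymbols(table))
  if (length(unknown))
    stop("unknown element(s) in HighRes: ", paste(unknown, collapse = ", "))
  if (labeledElement %in% highRes)
    stop("the labeled element ", labeledElement, " cannot be declared ",
         "high-resolution: its heavy isotopes are what is being traced")
  unique(highRes)
}

.checkEnrichmentFraction <- function(value, key) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value))
    stop(key, " must be a single number")
  if (value > 1)
    stop(key, " = ", value, " is greater than 1; enrichments are fractions ",
         "in [0, 1] - if you have a percentage, divide by 100")
  if (value < 0) stop(key, " must be >= 0")
  value
}

#' Create a fragment specification
#'
#' The constructor for [FragmentSpec-class]. Formulas may be given as strings
#' (parsed with [parseFormula()]) or as named count vectors. `highRes` may be
#' a vector of element symbols, or the sentinels `"all"` (every non-tracer
#' element is resolved) or `"none"`.
#'
#' @param name fragment name.
#' @param formula chemical formula of the measured fragment.
#' @param canAcquireLabel formula of the atoms that can acquire label from
#'   the tracer; defaults to `formula`. For derivatized fragments, exclude
#'   the derivatization-reagent atoms here. Only the count of the tracer
#'   element is used.
#' @param measuredMID numeric vector of measured relative abundances.
#' @param labeledElement element symbol of the tracer label, e.g. `"C"`.
#' @param tracerEnrichment tracer purity `P`, fraction in `[0, 1]`.
#' @param labelEnrichment atom enrichment `E`, fraction in `[0, 1]`.
#' @param highRes high-resolution element set (symbols, `"all"` or `"none"`).
#' @param table an [AbundanceTable-class].
#' @return a validated `FragmentSpec`.
#' @examples
#' FragmentSpec("TryptophanProtonated", "C11H13N2O2",
#'              measuredMID = c(0.88885, 0.106829, 0.004322),
#'              labeledElement = "C", highRes = c("N", "O", "H"))
#' @export
FragmentSpec <- function(name, formula, canAcquireLabel = formula, measuredMID,
                         labeledElement, tracerEnrichment = 1,
                         labelEnrichment = 1, highRes = "none",
                         table = defaultAbundanceTable()) {
  counts <- .asCounts(formula, "formula", table)
  can <- .asCounts(canAcquireLabel, "canAcquireLabel", table)
  .checkEnrichmentFraction(tracerEnrichment, "TracerEnrichment")
  .checkEnrichmentFraction(labelEnrichment, "LabelEnrichment")
  hr <- .resolveHighRes(highRes, names(counts), labeledElement, table)
  methods::new("FragmentSpec",
    name = as.character(name), formula = counts, canAcquireLabel = can,
    labeledElement = labeledElement,
    tracerEnrichment = as.numeric(tracerEnrichment),
    labelEnrichment = as.numeric(labelEnrichment),
    highRes = hr, measuredMID = as.numeric(measuredMID))
}

#' @rdname FragmentSpec
#' @param x a `FragmentSpec`.
#' @export
setMethod("fragmentName", "FragmentSpec", function(x) x@name)

#' @rdname FragmentSpec
#' @export
setMethod("fragmentFormula", "FragmentSpec", function(x) x@formula)

#' @rdname FragmentSpec
#' @export
setMethod("canAcquireLabel", "FragmentSpec", function(x) x@canAcquireLabel)

#' @rdname FragmentSpec
#' @export
setMethod("labeledElement", "FragmentSpec", function(x) x@labeledElement)

#' @rdname FragmentSpec
#' @export
setMethod("tracerEnrichment", "FragmentSpec", function(x) x@tracerEnrichment)

#' @rdname FragmentSpec
#' @export
setMethod("labelEnrichment", "FragmentSpec", function(x) x@labelEnrichment)

#' @rdname FragmentSpec
#' @export
setMethod("highResElements", "FragmentSpec", function(x) x@highRes)

#' @rdname FragmentSpec
#' @export
setMethod("measuredMID", "FragmentSpec", function(x) x@measuredMID)

#' @rdname FragmentSpec
#' @param value replacement measured MID.
#' @export
setMethod("measuredMID<-", "FragmentSpec", function(x, value) {
  x@measuredMID <- as.numeric(value)
  methods::validObject(x)
  x
})

#' @rdname FragmentSpec
#' @details `nLabel()` is the number of tracer-element atoms that can acquire
#'   label; the corrected MID has `nLabel + 1` components (label counts
#'   `0:nLabel`). Tracer-element atoms in the formula beyond this count (e.g.
#'   derivatization-reagent carbons) always carry the natural IMD.
#' @export
setMethod("nLabel", "FragmentSpec", function(x) {
  el <- x@labeledElement
  if (el %in% names(x@canAcquireLabel)) unname(x@canAcquireLabel[[el]]) else 0L
})

.formatFormula <- function(counts) {
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

setMethod("show", "FragmentSpec", function(object) {
  cat("FragmentSpec:", object@name, "\n")
  cat("  formula:         ", .formatFormula(object@formula), "\n")
  cat("  can acquire label:", .formatFormula(object@canAcquireLabel), "\n")
  cat("  labeled element: ", object@labeledElement,
      sprintf(" (n_label = %d)", nLabel(object)), "\n", sep = "")
  cat("  purity * enrichment:",
      object@tracerEnrichment * object@labelEnrichment, "\n")
  cat("  high-res elements:",
      if (length(object@highRes)) paste(object@highRes, collapse = " ")
      else "(none)", "\n")
  cat("  measured MID:    ",
      paste(formatC(object@measuredMID, format = "f", digits = 6),
            collapse = " "), "\n")
})
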