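# Correction-matrix assembly and the least-squares deconvolution itself.

#' Effective per-element IMDs under the declared mass resolution
#'
#' High-resolution instruments resolve mass shifts caused by heavy isotopes
#' of the declared elements from shifts caused by the tracer element; the
#' measured MID then only counts tracer-element isotopes. That is modeled by
#' collapsing each resolved element's IMD to 100% nominal mass (`c(1)`).
#' All other elements keep their natural IMDs. The labeled element is never
#' collapsed; its per-column labeled-atom IMD is handled separately by
#' [componentMID()].
#'
#' @param spec a [FragmentSpec-class].
#' @param table an [AbundanceTable-class].
#' @return named list mapping each formula element to its effective IMD.
#' @export
effectiveIMDMap <- function(spec, table = defaultAbundanceTable()) {
  stopifnot(methods::is(spec, "FragmentSpec"))
  hr <- highResElements(spec)
  if (labeledElement(spec) %in% hr)
    stop("the labeled element cannot be high-resolution")
  els <- names(fragmentFormula(spec))
  out <- lapply(els, function(el) {
    if (el %in% hr && el != labeledElement(spec)) 1 else naturalIMD(el, table)
  })
  names(out) <- els
  out
}

#' Theoretical MID of the fragment with k guaranteed labeled atoms
#'
#' Column k of the correction matrix: the MID of the fragment in which
#' exactly `k` tracer-element atoms are tracer-derived labels (carrying the
#' purity/enrichment-adjusted labeled-atom IMD of [labeledIMD()]) while the
#' remaining tracer-element atoms - including any that cannot acquire label,
#' such as derivatization-reagent atoms - carry the natural IMD, and every
#' other element carries its resolution-effective IMD. The full support is
#' kept; no truncation.
#'
#' @inheritParams effectiveIMDMap
#' @param k number of guaranteed tracer-derived labeled atoms,
#'   `0 <= k <= nLabel(spec)`.
#' @return numeric MID vector.
#' @export
componentMID <- function(spec, k, table = defaultAbundanceTable()) {
  stopifnot(methods::is(spec, "FragmentSpec"))
  n <- nLabel(spec)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
      k < 0 || k > n)
    stop("k must be an integer in [0, ", n, "]")
  k <- as.integer(k)
  emap <- effectiveIMDMap(spec, table)
  el <- labeledElement(spec)
  lab <- labeledIMD(el, tracerEnrichment(spec), labelEnrichment(spec), table)
  counts <- fragmentFormula(spec)
  out <- imdPower(lab, k)
  out <- convolveIMD(out, imdPower(emap[[el]], counts[[el]] - k))
  for (e in setdiff(names(counts), el))
    out <- convolveIMD(out, imdPower(emap[[e]], counts[[e]]))
  out
}

#' Assemble the correction matrix
#'
#' Column `k` (for `k = 0 ... nLabel`) is [componentMID()] of the fragment
#' with `k` guaranteed labels. The row count is the larger of the measured
#' MID length and the longest theoretical support; shorter columns are
#' zero-padded, so over the full support every column sums to one.
#'
#' @inheritParams effectiveIMDMap
#' @return numeric matrix with rows `m0, m1, ...` and columns `k0 ... kn`.
#' @examples
#' spec <- FragmentSpec("serine", "C3H7NO3", measuredMID = rep(1 / 6, 6),
#'                      labeledElement = "C")
#' dim(buildCorrectionMatrix(spec)) # full support x 4 label counts
#' @export
buildCorrectionMatrix <- function(spec, table = defaultAbundanceTable()) {
  stopifnot(methods::is(spec, "FragmentSpec"))
  n <- nLabel(spec)
  cols <- lapply(0:n, function(k) componentMID(spec, k, table))
  R <- max(length(measuredMID(spec)), max(lengths(cols)))
  CM <- vapply(cols, function(v) c(v, numeric(R - length(v))), numeric(R))
  dimnames(CM) <- list(paste0("m", seq_len(R) - 1L), paste0("k", 0:n))
  CM
}

#' Correct a measured MID for natural isotope abundance, purity and enrichment
#'
#' Solves the linear model `measured = CM %*% corrected` for the corrected
#' MID by the Moore-Penrose pseudoinverse, i.e. the minimum-norm
#' least-squares solution - the same contract whether the system is square,
#' over- or under-determined. The measured MID is renormalized (with a
#' warning) if its sum deviates from one by more than `1e-3`, and
#' zero-padded to the matrix row count when it reports fewer mass-shift bins
#' than the theoretical support. Negative corrected components are retained
#' and flagged, never clipped: zeroing them would break the property that
#' the corrected components sum to the measured total.
#'
#' @inheritParams effectiveIMDMap
#' @return a [CorrectionResult-class].
#' @examples
#' spec <- FragmentSpec("TryptophanProtonated", "C11H13N2O2",
#'                      measuredMID = c(0.88885, 0.106829, 0.004322),
#'                      labeledElement = "C", highRes = c("N", "O", "H"))
#' res <- correctMID(spec)
#' correctedMID(res)[1] # m+0 near unity for an unlabeled sample
#' @export
correctMID <- function(spec, table = defaultAbundanceTable()) {
  stopifnot(methods::is(spec, "FragmentSpec"))
  warns <- character(0)
  m <- measuredMID(spec)
  if (all(m == 0)) stop("measured MID is all zero; nothing to correct")
  s <- sum(m)
  if (abs(s - 1) > 1e-3) {
    m <- m / s
    warns <- c(warns, sprintf(
      "measured MID summed to %.6g (off by more than 1e-3); renormalized to 1", s))
  }
  CM <- buildCorrectionMatrix(spec, table)
  R <- nrow(CM)
  K <- ncol(CM)
  if (length(m) < R) {
    padMass <- sum(CM[(length(m) + 1L):R, , drop = FALSE]) / K
    warns <- c(warns, sprintf(
      paste0("measured MID has %d bins but the theoretical support has %d; ",
             "padded with zeros (mean theoretical column mass in padded rows: %.3g)"),
      length(m), R, padMass))
    m <- c(m, numeric(R - length(m)))
  }
  rk <- qr(CM)$rank
  if (rk < K)
    warns <- c(warns, sprintf(
      "correction matrix has rank %d < %d columns; minimum-norm solution returned",
      rk, K))
  x <- drop(MASS::ginv(CM) %*% m)
  fitted <- drop(CM %*% x)
  resid <- m - fitted
  if (any(x < 0))
    warns <- c(warns, sprintf(
      "negative corrected component(s) at label count(s) %s; retained, not clipped",
      paste(which(x < 0) - 1L, collapse = ", ")))
  methods::new("CorrectionResult",
    correctedMID = stats::setNames(x, paste0("m", 0:(K - 1L))),
    residuals = stats::setNames(resid, rownames(CM)),
    sse = sum(resid^2), correctionMatrix = CM, warnings = warns, spec = spec)
}

#' Accessors for CorrectionResult
#'
#' `correctedMID()` returns the corrected MID (one component per label
#' count), `sse()` the sum of squared residuals, `correctionMatrix()` the
#' matrix used, `correctionWarnings()` the diagnostics raised during the
#' fit, and `residuals()` the per-bin residual vector.
#'
#' @param x,object a [CorrectionResult-class].
#' @name CorrectionResult-accessors
NULL

#' @rdname CorrectionResult-accessors
#' @export
setMethod("correctedMID", "CorrectionResult", function(x) x@correctedMID)

#' @rdname CorrectionResult-accessors
#' @export
setMethod("sse", "CorrectionResult", function(x) x@sse)

#' @rdname CorrectionResult-accessors
#' @export
setMethod("correctionMatrix", "CorrectionResult", function(x) x@correctionMatrix)

#' @rdname CorrectionResult-accessors
#' @export
setMethod("correctionWarnings", "CorrectionResult", function(x) x@warnings)

#' @rdname CorrectionResult-accessors
#' @export
setMethod("residuals", "CorrectionResult", function(object) object@residuals)

#' @rdname CorrectionResult-accessors
#' @export
setMethod("fragmentName", "CorrectionResult", function(x) x@spec@name)

setMethod("show", "CorrectionResult", function(object) {
  cat(formatResultText(object), sep = "\n")
})
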