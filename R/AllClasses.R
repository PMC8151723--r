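#' @import methods
NULL

#' Natural isotope abundance table
#'
#' Holds one isotope mass distribution (IMD) per element: a numeric vector of
#' relative abundances indexed by integer mass shift above the nominal
#' (lightest-isotope) mass, summing to one. The package ships a pinned table
#' (see [defaultAbundanceTable()]) so results are bit-stable across releases of
#' upstream compilations.
#'
#' @slot imds named list of numeric abundance vectors, one per element symbol.
#'
#' @seealso [loadAbundanceTable()], [naturalIMD()]
#' @export
setClass("AbundanceTable", slots = c(imds = "list"))

.REQUIRED_ELEMENTS <- c("C", "H", "N", "O", "S", "Si", "P")

setValidity("AbundanceTable", function(object) {
  imds <- object@imds
  if (is.null(names(imds)) || any(!nzchar(names(imds))) || anyDuplicated(names(imds)))
    return("imds must be a uniquely named list of element symbols")
  missing <- setdiff(.REQUIRED_ELEMENTS, names(imds))
  if (length(missing))
    return(paste0("table must cover at least C, H, N, O, S, Si, P; missing: ",
                  paste(missing, collapse = ", ")))
  for (el in names(imds)) {
    w <- imds[[el]]
    if (!is.numeric(w) || length(w) < 1L || any(!is.finite(w)) || any(w < 0))
      return(sprintf("IMD for %s must be non-empty, finite and non-negative", el))
    if (abs(sum(w) - 1) > 1e-9)
      return(sprintf("IMD for %s sums to %.12g, not 1", el, sum(w)))
  }
  TRUE
})

#' Fragment specification for one correction task
#'
#' Bundles everything needed to correct one measured mass isotopologue
#' distribution: the fragment's chemical formula, which of its atoms can
#' acquire label from the tracer, the tracer element, tracer purity and
#' atom enrichment, the set of elements whose heavy-isotope mass shifts are
#' resolved from the tracer's (high-resolution mode), and the measured MID.
#'
#' Construct with [FragmentSpec()]; slots are reached through accessors
#' ([fragmentFormula()], [measuredMID()], [nLabel()], ...), never directly.
#'
#' @slot name fragment name.
#' @slot formula named integer vector of element counts (the fragment formula).
#' @slot canAcquireLabel named integer vector; the subset of atoms that can
#'   acquire label from the tracer (derivatization-reagent atoms excluded).
#' @slot labeledElement single element symbol of the tracer label.
#' @slot tracerEnrichment fraction in `[0, 1]`: purity of the tracer species.
#' @slot labelEnrichment fraction in `[0, 1]`: heavy-isotope enrichment at
#'   labeled atom positions of the tracer.
#' @slot highRes character vector of element symbols resolved from the tracer
#'   element (possibly empty).
#' @slot measuredMID numeric vector of measured relative abundances, index i
#'   corresponding to i mass units above monoisotopic mass.
#'
#' @export
setClass("FragmentSpec",
  slots = c(
    name            = "character",
    formula         = "integer",
    canAcquireLabel = "integer",
    labeledElement  = "character",
    tracerEnrichment = "numeric",
    labelEnrichment = "numeric",
    highRes         = "character",
    measuredMID     = "numeric"
  )
)

.checkCounts <- function(x, what) {
  if (length(x) < 1L) return(sprintf("%s must contain at least one element", what))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    return(sprintf("%s must be a named count vector", what))
  if (anyDuplicated(names(x)))
    return(sprintf("%s has duplicate element symbols", what))
  if (any(is.na(x)) || any(x < 1L))
    return(sprintf("%s counts must all be >= 1", what))
  NULL
}

setValidity("FragmentSpec", function(object) {
  msg <- .checkCounts(object@formula, "formula")
  if (!is.null(msg)) return(msg)
  msg <- .checkCounts(object@canAcquireLabel, "canAcquireLabel")
  if (!is.null(msg)) return(msg)
  if (length(object@name) != 1L) return("name must be a single string")
  if (length(object@labeledElement) != 1L || !nzchar(object@labeledElement))
    return("labeledElement must be a single element symbol")
  if (!object@labeledElement %in% names(object@formula))
    return(sprintf("labeled element %s not present in the fragment formula",
                   object@labeledElement))
  extra <- setdiff(names(object@canAcquireLabel), names(object@formula))
  if (length(extra))
    return(paste0("canAcquireLabel contains elements absent from the formula: ",
                  paste(extra, collapse = ", ")))
  over <- object@canAcquireLabel > object@formula[names(object@canAcquireLabel)]
  if (any(over))
    return(paste0("canAcquireLabel exceeds the formula count for: ",
                  paste(names(object@canAcquireLabel)[over], collapse = ", ")))
  for (fld in c("tracerEnrichment", "labelEnrichment")) {
    v <- slot(object, fld)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single fraction in [0, 1]", fld))
  }
  if (object@labeledElement %in% object@highRes)
    return("the labeled element cannot be listed in highRes")
  if (length(object@measuredMID) < 1L)
    return("measuredMID must be non-empty")
  if (any(!is.finite(object@measuredMID)) || any(object@measuredMID < 0))
    return("measuredMID entries must be finite and >= 0")
  TRUE
})

#' Result of a natural-abundance correction
#'
#' Returned by [correctMID()] and [runCorrection()]. The corrected MID has one
#' component per possible tracer-label count (0 to `nLabel(spec)`); negative
#' components, which can arise from measurement imperfection, are retained
#' verbatim and flagged in the warnings rather than clipped, so the
#' distribution keeps summing to the measured total.
#'
#' @slot correctedMID numeric vector, names `m0`, `m1`, ...: fraction of
#'   fragment molecules carrying that many tracer-derived labeled atoms.
#' @slot residuals numeric vector: padded measured MID minus the correction
#'   matrix applied to the corrected MID.
#' @slot sse sum of squared residuals.
#' @slot correctionMatrix the matrix used for the fit (rows = mass-shift bins,
#'   columns = label counts).
#' @slot warnings character vector of diagnostics raised during correction.
#' @slot spec the [FragmentSpec-class] that was corrected.
#'
#' @export
setClass("CorrectionResult",
  slots = c(
    correctedMID     = "numeric",
    residuals        = "numeric",
    sse              = "numeric",
    correctionMatrix = "matrix",
    warnings         = "character",
    spec             = "FragmentSpec"
  )
)

setValidity("CorrectionResult", function(object) {
  if (length(object@sse) != 1L || !is.finite(object@sse) || object@sse < 0)
    return("sse must be a single non-negative number")
  if (abs(object@sse - sum(object@residuals^2)) > 1e-12 * max(1, object@sse))
    return("sse does not equal the squared norm of the residuals")
  if (length(object@correctedMID) != ncol(object@correctionMatrix))
    return("corrected MID length must equal the correction matrix column count")
  if (length(object@residuals) != nrow(object@correctionMatrix))
    return("residual length must equal the correction matrix row count")
  TRUE
})
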