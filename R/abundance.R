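.abundanceCache <- new.env(parent = emptyenv())

#' Load an isotope abundance table from a delimited text file
#'
#' The file is tab- (or whitespace-) delimited with a header and three
#' columns: `element` (symbol), `mass_shift` (integer mass units above
#' nominal mass) and `abundance` (relative abundance). Shifts absent from the
#' file (e.g. the +3 bin of sulfur) are filled with zero, so the length of
#' each element's distribution is its largest naturally occurring shift plus
#' one. Every element's abundances must sum to one within `1e-9`.
#'
#' @param path path to the delimited abundance file.
#' @return an [AbundanceTable-class] object.
#' @seealso [defaultAbundanceTable()]
#' @export
loadAbundanceTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "mass_shift", "abundance")
  if (!all(need %in% names(df)))
    stop("abundance file must have columns: ", paste(need, collapse = ", "))
  imds <- lapply(split(df, df$element), function(d) {
    w <- numeric(max(d$mass_shift) + 1L)
    w[d$mass_shift + 1L] <- d$abundance
    w
  })
  methods::new("AbundanceTable", imds = imds)
}

#' The pinned natural-isotope abundance table
#'
#' Returns the table shipped with the package
#' (`inst/extdata/isotope_abundances.tsv`), transcribed from the IUPAC/CRC
#' representative isotopic compositions (e.g. carbon-13 at 0.0107) and pinned
#' so that corrections are reproducible regardless of upstream revisions of
#' the compilation. Covers C, H, N, O, S, Si and P. The table is parsed once
#' per session and cached.
#'
#' @return an [AbundanceTable-class] object.
#' @examples
#' naturalIMD("C", defaultAbundanceTable())
#' @export
defaultAbundanceTable <- function() {
  if (is.null(.abundanceCache$default)) {
    path <- system.file("extdata", "isotope_abundances.tsv",
                        package = "midcorrect", mustWork = TRUE)
    .abundanceCache$default <- loadAbundanceTable(path)
  }
  .abundanceCache$default
}

#' @rdname AbundanceTable-accessors
#' @param x an `AbundanceTable`.
#' @export
setMethod("elementSymbols", "AbundanceTable", function(x) names(x@imds))

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable with", length(object@imds), "elements:",
      paste(names(object@imds), collapse = ", "), "\n")
})

#' Parse a chemical formula into element counts
#'
#' Accepts plain element+count tokens (an uppercase letter, an optional
#' lowercase letter, an optional positive integer count; a missing count
#' means 1), e.g. `"C11H13N2O2"`. Repeated tokens accumulate. Parentheses,
#' hydrates and charges are not supported.
#'
#' @param formula a single formula string.
#' @param table abundance table used to validate element symbols.
#' @return named integer vector of atom counts.
#' @examples
#' parseFormula("C3H7NO3")
#' @export
parseFormula <- function(formula, table = defaultAbundanceTable()) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("formula must be a single character string")
  if (!nzchar(formula)) stop("formula is empty")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(formula))
    stop("formula '", formula, "' contains characters outside the ",
         "element+count grammar")
  counts <- integer(0)
  known <- elementSymbols(table)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% known)
      stop("unknown element '", sym, "' in formula token '", tok, "'")
    if (is.na(n) || n < 1L)
      stop("zero or invalid count in formula token '", tok, "'")
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  counts
}

#' Natural isotope mass distribution of an element
#'
#' @param element element symbol, e.g. `"C"`.
#' @param table an [AbundanceTable-class].
#' @return numeric vector of relative abundances; index i is the abundance at
#'   i mass units above nominal mass.
#' @examples
#' naturalIMD("N") # ~ c(0.99636, 0.00364)
#' @export
naturalIMD <- function(element, table = defaultAbundanceTable()) {
  stopifnot(is.character(element), length(element) == 1L)
  if (!element %in% elementSymbols(table))
    stop("element '", element, "' not found in the abundance table")
  table@imds[[element]]
}

#' Isotope mass distribution of a labeled atom under tracer purity and enrichment
#'
#' A tracer-derived labeled atom is fully enriched one mass unit above
#' nominal mass only for a perfectly pure, perfectly enriched tracer. For
#' tracer purity `P` and atom enrichment `E` the labeled-atom IMD is the
#' mixture
#' \deqn{P E \, \delta_{m+1} + (1 - P E) \, \mathrm{IMD}_{nat}}
#' i.e. with probability `P*E` the atom is the heavy isotope, otherwise it
#' behaves like a natural atom of the element. Only the product `P*E` enters,
#' so the two factors are not separately identifiable.
#'
#' @param element element symbol of the tracer label.
#' @param purity tracer purity `P`, fraction in `[0, 1]`.
#' @param enrichment labeled-atom enrichment `E`, fraction in `[0, 1]`.
#' @param table an [AbundanceTable-class].
#' @return numeric abundance vector of length `max(2, length(naturalIMD))`,
#'   summing to one.
#' @examples
#' labeledIMD("C", 1, 1)        # all mass at m+1
#' labeledIMD("C", 0.5, 0.95)   # 47.5% heavy, 52.5% natural carbon
#' @export
labeledIMD <- function(element, purity = 1, enrichment = 1,
                       table = defaultAbundanceTable()) {
  for (v in list(purity = purity, enrichment = enrichment)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("purity and enrichment must be single fractions in [0, 1]",
           if (is.numeric(v) && length(v) == 1L && is.finite(v) && v > 1)
             " (a value > 1 looks like a percentage: divide by 100)" else "")
  }
  nat <- naturalIMD(element, table)
  pe <- purity * enrichment
  out <- numeric(max(2L, length(nat)))
  out[seq_along(nat)] <- (1 - pe) * nat
  out[2L] <- out[2L] + pe
  out
}
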