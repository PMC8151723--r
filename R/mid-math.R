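# Polynomial arithmetic on isotope distributions. An IMD/MID is treated as
# the coefficient vector of a polynomial in the mass-shift variable; the MID
# of a molecule is the product of its atoms' IMD polynomials.

#' Convolve two isotope distributions
#'
#' The distribution of the summed mass shift of two independent atoms (or
#' sub-molecules) is the polynomial product of their distributions: terms
#' with the same collective mass are grouped, so
#' `out[k] = sum_i a[i] * b[k - i]`.
#'
#' @param a,b numeric abundance vectors (index = mass shift above nominal).
#' @return numeric vector of length `length(a) + length(b) - 1`.
#' @examples
#' convolveIMD(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
#' @export
convolveIMD <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) == 0L || length(b) == 0L)
    stop("both distributions must be non-empty numeric vectors")
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' n-fold self-convolution of an isotope distribution
#'
#' The mass-shift distribution of `n` identical independent atoms, computed
#' by binary exponentiation of the convolution product. `n = 0` returns the
#' identity distribution `c(1)` (the empty product).
#'
#' @param a numeric abundance vector.
#' @param n non-negative integer number of atoms.
#' @return numeric vector of length `n * (length(a) - 1) + 1`.
#' @examples
#' imdPower(c(0, 1), 3) # pure m+1 atom, three copies: all mass at m+3
#' @export
imdPower <- function(a, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("n must be a single non-negative integer")
  if (!is.numeric(a) || length(a) == 0L)
    stop("distribution must be a non-empty numeric vector")
  out <- 1
  base <- a
  n <- as.integer(n)
  while (n > 0L) {
    if (n %% 2L == 1L) out <- convolveIMD(out, base)
    n <- n %/% 2L
    if (n > 0L) base <- convolveIMD(base, base)
  }
  out
}

#' Theoretical mass isotopologue distribution of a formula
#'
#' Multiplies the per-element IMDs together as polynomials, one factor per
#' atom: for counts `{C:3, H:7, N:1, O:3}` this is
#' `IMD_C^3 * IMD_H^7 * IMD_N * IMD_O^3`. No truncation is applied; the full
#' support is carried so the result sums to the product of the input sums
#' (one, when all inputs are normalized).
#'
#' @param counts named integer vector of atom counts (see [parseFormula()]).
#' @param imdMap named list mapping each element of `counts` to its IMD.
#' @return numeric MID vector over the full theoretical support.
#' @examples
#' formulaMID(parseFormula("C2"), list(C = naturalIMD("C")))
#' @export
formulaMID <- function(counts, imdMap) {
  if (length(counts) == 0L) stop("counts must contain at least one element")
  missing <- setdiff(names(counts), names(imdMap))
  if (length(missing))
    stop("no IMD supplied for element(s): ", paste(missing, collapse = ", "))
  out <- 1
  for (el in names(counts))
    out <- convolveIMD(out, imdPower(imdMap[[el]], counts[[el]]))
  out
}

#' Brute-force MID by exhaustive isotope enumeration (test oracle)
#'
#' Enumerates every per-atom isotope assignment, multiplying per-atom
#' abundances and accumulating the product into the bin of the summed mass
#' shift. Mathematically identical to [formulaMID()] but computed by
#' combinatorial enumeration rather than polynomial expansion, so it serves
#' as an independent cross-check. Guarded to at most 12 atoms.
#'
#' @inheritParams formulaMID
#' @return numeric MID vector.
#' @export
bruteForceMID <- function(counts, imdMap) {
  if (length(counts) == 0L) stop("counts must contain at least one element")
  atoms <- rep(names(counts), times = counts)
  if (length(atoms) > 12L)
    stop("brute-force enumeration is limited to 12 atoms (got ",
         length(atoms), ")")
  missing <- setdiff(names(counts), names(imdMap))
  if (length(missing))
    stop("no IMD supplied for element(s): ", paste(missing, collapse = ", "))
  shiftChoices <- lapply(atoms, function(el) seq_along(imdMap[[el]]) - 1L)
  grid <- do.call(expand.grid, c(shiftChoices, KEEP.OUT.ATTRS = FALSE))
  prob <- rep(1, nrow(grid))
  for (j in seq_along(atoms))
    prob <- prob * imdMap[[atoms[j]]][grid[[j]] + 1L]
  total <- as.integer(rowSums(grid))
  out <- numeric(max(total) + 1L)
  for (r in seq_along(prob)) out[total[r] + 1L] <- out[total[r] + 1L] + prob[r]
  out
}
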