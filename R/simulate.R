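# Forward simulator: fragments and measured MIDs with known ground truth,
# for validating correction accuracy without any external data.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate a random fragment specification
#'
#' Draws a deterministic-in-seed fragment over the elements C, H, N, O, S
#' and Si with carbon as the tracer element: at least one carbon atom, other
#' elements included at random, total atom count at most `maxAtoms`, and a
#' random number (at least one) of the carbons able to acquire label. The
#' measured MID is a placeholder (`c(1)`); fill it with [forwardMeasure()]
#' via `measuredMID<-`.
#'
#' @param seed integer seed; the same seed always yields the same fragment.
#' @param maxAtoms maximum total atom count (>= 2).
#' @return a [FragmentSpec-class] with placeholder measured MID.
#' @export
randomFragment <- function(seed, maxAtoms = 20L) {
  stopifnot(maxAtoms >= 2)
  .withSeed(seed, {
    nC <- sample.int(min(maxAtoms - 1L, 8L), 1L)
    budget <- maxAtoms - nC
    counts <- c(C = nC)
    for (el in c("H", "N", "O", "S", "Si")) {
      if (budget <= 0L) break
      if (stats::runif(1) < 0.5) {
        n <- sample.int(min(budget, 4L), 1L)
        counts[el] <- n
        budget <- budget - n
      }
    }
    can <- sample.int(nC, 1L)
    FragmentSpec(
      name = sprintf("synthetic_seed%d", as.integer(seed)),
      formula = counts, canAcquireLabel = c(C = can), measuredMID = 1,
      labeledElement = "C", tracerEnrichment = 1, labelEnrichment = 1,
      highRes = "none")
  })
}

#' Forward-simulate a measured MID from known label fractions
#'
#' Runs the correction model forward: weights the correction-matrix columns
#' by the true label-count fractions (`CM %*% w`), then optionally applies
#' independent multiplicative lognormal noise with coefficient of variation
#' `noiseCV` to each isotopologue and renormalizes to sum one. MID
#' components are relative peak areas, which motivates the multiplicative
#' noise model. With `noiseCV = 0` the forward model is exact and
#' [correctMID()] recovers `trueWeights` to numerical precision.
#'
#' @param spec a [FragmentSpec-class] (its measured MID is ignored).
#' @param trueWeights non-negative vector of length `nLabel(spec) + 1`
#'   summing to one: the true fraction of molecules with each label count.
#' @param noiseCV coefficient of variation of the lognormal noise (>= 0).
#' @param seed integer seed for the noise draw; ignored when `noiseCV = 0`.
#' @param table an [AbundanceTable-class].
#' @return numeric measured-MID vector over the full theoretical support.
#' @export
forwardMeasure <- function(spec, trueWeights, noiseCV = 0, seed = NULL,
                           table = defaultAbundanceTable()) {
  stopifnot(methods::is(spec, "FragmentSpec"))
  K <- nLabel(spec) + 1L
  if (length(trueWeights) != K)
    stop("trueWeights must have length nLabel + 1 = ", K)
  if (any(trueWeights < 0) || abs(sum(trueWeights) - 1) > 1e-8)
    stop("trueWeights must be non-negative and sum to 1")
  if (!is.numeric(noiseCV) || length(noiseCV) != 1L || noiseCV < 0)
    stop("noiseCV must be a single non-negative number")
  probe <- spec
  measuredMID(probe) <- 1  # row count driven by the theoretical support
  CM <- buildCorrectionMatrix(probe, table)
  y <- drop(CM %*% trueWeights)
  if (noiseCV > 0) {
    sdlog <- sqrt(log1p(noiseCV^2))
    fac <- .withSeed(seed,
      stats::rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    y <- y * fac
    y <- y / sum(y)
  }
  unname(y)
}
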