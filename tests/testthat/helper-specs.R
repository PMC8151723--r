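# Shared fixtures, all built in code.

tab <- defaultAbundanceTable()

# Unlabeled protonated tryptophan measured on a high-resolution instrument
# in a 13C tracing experiment (carbon shifts resolved from N, O and H).
tryptophanSpec <- function() {
  FragmentSpec("TryptophanProtonated", "C11H13N2O2",
               measuredMID = c(0.88885, 0.106829, 0.004322),
               labeledElement = "C", tracerEnrichment = 1,
               labelEnrichment = 1, highRes = c("N", "O", "H"))
}

serineSpec <- function(mid = rep(1 / 6, 6), ...) {
  FragmentSpec("Serine", "C3H7NO3", measuredMID = mid,
               labeledElement = "C", ...)
}

tryptophanInputLines <- function() c(
  "FragmentName: TryptophanProtonated",
  "",
  "FragmentFormula: C11H13N2O2",
  "",
  "CanAcquireLabel: C11H13N2O2",
  "",
  "MIDm: 0.88885 0.106829 0.004322",
  "",
  "LabeledElement: C",
  "",
  "TracerEnrichment: 1",
  "",
  "LabelEnrichment: 1",
  "",
  "HighRes: N O H")

writeTryptophanInput <- function(path = tempfile(fileext = ".txt")) {
  writeLines(tryptophanInputLines(), path)
  path
}

# All element-count compositions over `elements` with 1..maxAtoms atoms.
allSmallFormulas <- function(maxAtoms, elements = c("C", "H", "N", "O")) {
  grids <- do.call(expand.grid, rep(list(0:maxAtoms), length(elements)))
  names(grids) <- elements
  keep <- rowSums(grids) >= 1 & rowSums(grids) <= maxAtoms
  grids <- grids[keep, , drop = FALSE]
  lapply(seq_len(nrow(grids)), function(i) {
    row <- unlist(grids[i, ])
    counts <- row[row > 0]
    storage.mode(counts) <- "integer"
    counts
  })
}
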