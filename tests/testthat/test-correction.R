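test_that("FragmentSpec validates its invariants", {
  expect_error(FragmentSpec("x", "C3H7NO3", canAcquireLabel = "C4",
                            measuredMID = c(1, 0), labeledElement = "C"),
               "exceeds")
  expect_error(FragmentSpec("x", "C3H7NO3", measuredMID = c(1, 0),
                            labeledElement = "C", highRes = c("C", "N")),
               "labeled element")
  expect_error(FragmentSpec("x", "C3H7NO3", measuredMID = c(1, -0.1),
                            labeledElement = "C"), ">= 0")
  expect_error(FragmentSpec("x", "C3H7NO3", measuredMID = c(1, 0),
                            labeledElement = "C", tracerEnrichment = 50),
               "divide by 100")
  expect_error(FragmentSpec("x", "H2O", measuredMID = 1,
                            labeledElement = "C"), "not present")
})

test_that("high-resolution elements collapse to pure nominal mass", {
  trp <- tryptophanSpec()
  emap <- effectiveIMDMap(trp, tab)
  expect_equal(emap$N, 1)
  expect_equal(emap$O, 1)
  expect_equal(emap$H, 1)
  expect_equal(emap$C, naturalIMD("C", tab))

  lowres <- serineSpec()
  emap2 <- effectiveIMDMap(lowres, tab)
  for (el in names(fragmentFormula(lowres)))
    expect_equal(emap2[[el]], naturalIMD(el, tab))

  allhr <- FragmentSpec("x", "C3H7NO3", measuredMID = rep(0.25, 4),
                        labeledElement = "C", highRes = "all")
  emap3 <- effectiveIMDMap(allhr, tab)
  expect_equal(emap3$C, naturalIMD("C", tab))
  for (el in c("H", "N", "O")) expect_equal(emap3[[el]], 1)
})

test_that("component MIDs place k guaranteed labels on natural backgrounds", {
  natMap <- setNames(lapply(elementSymbols(tab), naturalIMD, table = tab),
                     elementSymbols(tab))
  ser <- serineSpec()
  # k = 0: simply the natural-abundance MID of serine
  expect_equal(componentMID(ser, 0, tab),
               formulaMID(fragmentFormula(ser), natMap), tolerance = 1e-14)
  # k = 1: one carbon replaced by the pure m+1 label
  labMap <- natMap
  k1 <- convolveIMD(c(0, 1),
                    formulaMID(c(C = 2L, H = 7L, N = 1L, O = 3L), natMap))
  expect_equal(componentMID(ser, 1, tab), k1, tolerance = 1e-14)
  # all-high-res, k = n_label: unit mass at shift n_label
  allhr <- FragmentSpec("x", "C2H4", measuredMID = c(1, 0, 0),
                        labeledElement = "C", highRes = "all")
  cm <- componentMID(allhr, 2, tab)
  expect_equal(which(cm == max(cm)) - 1L, 2L)
  expect_equal(max(cm), 1)
  expect_error(componentMID(ser, 4, tab), "\\[0, 3\\]")
})

test_that("tracer atoms outside CanAcquireLabel keep the natural IMD", {
  # a derivatized fragment: 2 of 5 carbons come from the reagent
  spec <- FragmentSpec("deriv", "C5H10", canAcquireLabel = "C3H10",
                       measuredMID = rep(1 / 6, 6), labeledElement = "C")
  expect_equal(nLabel(spec), 3L)
  natMap <- setNames(lapply(elementSymbols(tab), naturalIMD, table = tab),
                     elementSymbols(tab))
  k3 <- componentMID(spec, 3, tab)
  manual <- convolveIMD(imdPower(c(0, 1), 3),
                        formulaMID(c(C = 2L, H = 10L), natMap))
  expect_equal(k3, manual, tolerance = 1e-14)
})

test_that("the correction matrix has one column per possible label count", {
  ser <- serineSpec()
  CM <- buildCorrectionMatrix(ser, tab)
  expect_equal(ncol(CM), 4L)   # 3 labelable carbons + 1
  expect_gte(nrow(CM), 6L)     # at least the measured bins
  expect_true(all(CM >= 0))
  expect_equal(unname(colSums(CM)), rep(1, 4), tolerance = 1e-9)

  # one labelable atom of a monoisotopic element, all-high-res, pure label:
  # both columns are delta distributions, so the matrix is the 2x2 identity
  idspec <- FragmentSpec("id", "PH3", canAcquireLabel = "P",
                         measuredMID = c(0.7, 0.3), labeledElement = "P",
                         highRes = "all")
  expect_equal(unname(buildCorrectionMatrix(idspec, tab)), diag(2),
               tolerance = 1e-12)
})

test_that("correction matrix columns stay normalized across random fragments", {
  for (seed in 1:20) {
    fr <- randomFragment(seed, maxAtoms = 40)
    CM <- buildCorrectionMatrix(fr, tab)
    expect_equal(unname(colSums(CM)), rep(1, ncol(CM)), tolerance = 1e-9)
  }
})

test_that("a measurement equal to one matrix column is recovered exactly", {
  ser <- serineSpec()
  CM <- buildCorrectionMatrix(ser, tab)
  measuredMID(ser) <- CM[, 1]
  res <- correctMID(ser, tab)
  expect_equal(unname(correctedMID(res)), c(1, 0, 0, 0), tolerance = 1e-10)
  expect_lt(sse(res), 1e-20)
})

test_that("forward-model round trips recover the mixing weights", {
  set.seed(99)
  for (i in 1:20) {
    fr <- randomFragment(i, maxAtoms = 25)
    K <- nLabel(fr) + 1L
    w <- rexp(K); w <- w / sum(w)
    measuredMID(fr) <- forwardMeasure(fr, w, table = tab)
    res <- correctMID(fr, tab)
    expect_lt(max(abs(unname(correctedMID(res)) - w)), 1e-8)
    expect_lt(sse(res), 1e-16)
    # idempotence: feeding the fitted measurement back returns the same MID
    measuredMID(fr) <- drop(correctionMatrix(res) %*% correctedMID(res))
    res2 <- correctMID(fr, tab)
    expect_equal(unname(correctedMID(res2)), unname(correctedMID(res)),
                 tolerance = 1e-8)
  }
})

test_that("the corrected components sum to the measured total", {
  trp <- tryptophanSpec()
  res <- correctMID(trp, tab)
  expect_equal(sum(correctedMID(res)), sum(measuredMID(trp)),
               tolerance = 1e-6)
  expect_equal(sse(res), sum(residuals(res)^2), tolerance = 1e-15)
})

test_that("short measured MIDs are zero-padded with a warning, not truncated", {
  trp <- tryptophanSpec()
  res <- correctMID(trp, tab)
  expect_equal(nrow(correctionMatrix(res)), 12L) # C11 support
  expect_length(residuals(res), 12L)
  expect_true(any(grepl("padded", correctionWarnings(res))))
})

test_that("negative corrected components are reported verbatim, never clipped", {
  # a measurement with too little m+1 mass forces a negative component
  ser <- serineSpec(mid = c(0.999, 0.001))
  res <- correctMID(ser, tab)
  expect_true(any(correctedMID(res) < 0))
  expect_true(any(grepl("negative", correctionWarnings(res))))
  # with unit column sums: sum(corrected) + sum(residuals) = sum(measured)
  expect_equal(sum(correctedMID(res)) + sum(residuals(res)), 1,
               tolerance = 1e-10)
})

test_that("off-normalized measurements are renormalized with a warning", {
  ser <- serineSpec(mid = c(1.8, 0.2))
  res <- correctMID(ser, tab)
  expect_true(any(grepl("renormalized", correctionWarnings(res))))
  expect_equal(sum(correctedMID(res)) + sum(residuals(res)), 1,
               tolerance = 1e-10)
  # the tryptophan input sums to 1.000001: within tolerance, not renormalized
  res2 <- correctMID(tryptophanSpec(), tab)
  expect_false(any(grepl("renormalized", correctionWarnings(res2))))
  expect_error(correctMID(serineSpec(mid = c(0, 0, 0)), tab), "all zero")
})

test_that("declaring every non-tracer element high-res equals dropping them", {
  set.seed(7)
  for (i in 1:5) {
    fr <- randomFragment(i + 100, maxAtoms = 20)
    K <- nLabel(fr) + 1L
    w <- rexp(K); w <- w / sum(w)
    full <- FragmentSpec(fragmentName(fr), fragmentFormula(fr),
                         canAcquireLabel = canAcquireLabel(fr),
                         measuredMID = 1, labeledElement = "C",
                         highRes = "all")
    measuredMID(full) <- forwardMeasure(full, w, table = tab)
    nC <- fragmentFormula(fr)[["C"]]
    reduced <- FragmentSpec(fragmentName(fr), c(C = nC),
                            canAcquireLabel = canAcquireLabel(fr),
                            measuredMID = measuredMID(full),
                            labeledElement = "C")
    rFull <- correctMID(full, tab)
    rRed <- correctMID(reduced, tab)
    expect_equal(unname(correctedMID(rFull)), unname(correctedMID(rRed)),
                 tolerance = 1e-10)
  }
})

test_that("purity and enrichment enter the correction only via their product", {
  ser <- serineSpec(mid = c(0.5, 0.2, 0.2, 0.1))
  a <- correctMID(FragmentSpec("s", "C3H7NO3", measuredMID = measuredMID(ser),
                               labeledElement = "C", tracerEnrichment = 0.5,
                               labelEnrichment = 0.95), tab)
  b <- correctMID(FragmentSpec("s", "C3H7NO3", measuredMID = measuredMID(ser),
                               labeledElement = "C", tracerEnrichment = 0.95,
                               labelEnrichment = 0.5), tab)
  expect_equal(correctedMID(a), correctedMID(b), tolerance = 1e-12)
})
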