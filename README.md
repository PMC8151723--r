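# midcorrect

Natural isotope abundance correction for stable-isotope tracing mass
spectrometry.

## The problem

In a stable-isotope tracing experiment, cells are fed a tracer nutrient
(e.g. [U-¹³C₆]glucose) and the heavy label propagates into downstream
metabolites. The readout is the **mass isotopologue distribution (MID)** of
each measured metabolite fragment: the fraction of molecules at 0, 1, 2, ...
mass units above the monoisotopic mass. Interpreting label incorporation —
whether by manual inspection or by metabolic flux analysis — requires first
removing the contribution of *naturally occurring* heavy isotopes (¹³C, ²H,
¹⁵N, ¹⁷O/¹⁸O, ...), which shift mass without saying anything about pathway
use, as well as the effects of tracer impurity and sub-unity atom
enrichment.

`midcorrect` performs that correction for low- and high-mass-resolution
data, with a programmatic S4 API, a plain-text input format, and
command-line entry points, so it slots into processing pipelines.

## The model

Write the measured MID as a weighted sum of theoretical component MIDs,
one per possible tracer-label count. For a fragment whose labelable
tracer-element atoms number *n*:

```
S_m = CM · S_c
```

where `S_m` is the measured MID, `S_c` (length *n* + 1) is the corrected
MID — the fraction of molecules carrying exactly *k* tracer-derived labeled
atoms — and `CM` is the **correction matrix** whose column *k* is the
theoretical MID of the fragment with *k* guaranteed labels and natural
isotope incorporation everywhere else. The corrected MID is the
minimum-norm least-squares solution via the Moore–Penrose pseudoinverse:

```
S_c = CM⁺ · S_m
```

Each column is computed by polynomial expansion: every atom's isotope mass
distribution (IMD) is a polynomial in the mass-shift variable and the
fragment MID is their product, e.g. for serine
`MID(C3H7NO3) = IMD_C³ · IMD_H⁷ · IMD_N · IMD_O³`. A tracer-derived labeled
atom with tracer purity *P* and atom enrichment *E* carries the mixture IMD
`P·E·δ(m+1) + (1 − P·E)·IMD_natural`. On high-resolution instruments, mass
shifts from heavy isotopes of declared elements are resolved from the
tracer element's; those elements' IMDs collapse to 100% nominal mass.

Negative corrected components (from measurement imperfection) are reported
as computed, never clipped — zeroing them would destroy the property that
the corrected MID sums to the measured total. Residuals and their sum of
squares (SSE) are returned with every fit.

## Worked example

Unlabeled protonated tryptophan measured on a high-resolution instrument in
a ¹³C tracer experiment. Input file `trp.txt`:

```
FragmentName: TryptophanProtonated
FragmentFormula: C11H13N2O2
CanAcquireLabel: C11H13N2O2
MIDm: 0.88885 0.106829 0.004322
LabeledElement: C
TracerEnrichment: 1
LabelEnrichment: 1
HighRes: N O H
```

```r
library(midcorrect)
res <- runCorrection("trp.txt")
```

prints

```
FragmentName: TryptophanProtonated
CorrectedMID: 1.000508 0.001202 -0.001667 -0.000048 0.000006 -0.000000 0.000000 -0.000000 0.000000 -0.000000 -0.000000 0.000000
SSE: 6.01994e-30
Warning: measured MID has 3 bins but the theoretical support has 12; padded with zeros (mean theoretical column mass in padded rows: 0.758)
Warning: negative corrected component(s) at label count(s) 2, 3, 5, 7, 9, 10; retained, not clipped
```

The corrected MID has 12 components (label counts 0–11 for the 11 carbons).
The m+0 component is near unity, as it must be for a sample never exposed
to tracer: the measured m+1 and m+2 mass was almost entirely natural ¹³C.
The tiny negative components reflect rounding in the three measured values
and are reported verbatim. Full precision is available programmatically:

```r
correctedMID(res)[1:4]
#>        m0        m1        m2        m3
#>  1.000508  0.001202 -0.001667 -0.000048
sse(res)
#> [1] 6.019936e-30
```

The same correction can be built entirely in code:

```r
spec <- FragmentSpec("TryptophanProtonated", "C11H13N2O2",
                     measuredMID = c(0.88885, 0.106829, 0.004322),
                     labeledElement = "C", highRes = c("N", "O", "H"))
res <- correctMID(spec)
```

## Command line

The installed scripts live under `system.file("exec", package = "midcorrect")`:

```sh
EXE=$(Rscript -e 'cat(system.file("exec", "midcorrect", package = "midcorrect"))')
Rscript "$EXE" trp.txt --output out.csv --format csv
Rscript "$EXE" batch_dir --batch --output results/ --verbose
```

`midcorrect-sim` forward-simulates a measurement with known ground truth
(`--seed`, `--noise`, `--out`), writing a valid input file plus a
`.truth.tsv` sidecar — useful for end-to-end validation.

## The abundance table

Natural isotope abundances are pinned in
`inst/extdata/isotope_abundances.tsv` (tab-separated columns `element`,
`mass_shift`, `abundance`; one row per naturally occurring isotope, IMD
length following each element's largest natural mass shift). The shipped
values are the IUPAC/CRC representative isotopic compositions for C, H, N,
O, S, Si and P. Alternative tables can be supplied with
`loadAbundanceTable()`.

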