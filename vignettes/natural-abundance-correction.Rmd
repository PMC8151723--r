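---
title: "Correcting mass isotopologue distributions for natural isotope abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting mass isotopologue distributions for natural isotope abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midcorrect)
```

## The model

A stable-isotope tracing measurement reports the mass isotopologue
distribution (MID) of a metabolite fragment: the relative abundance of
molecules 0, 1, 2, ... atomic mass units above the monoisotopic mass. Two
processes put molecules into the heavier bins: incorporation of
tracer-derived label (the signal) and incorporation of naturally occurring
heavy isotopes (a nuisance that affects every molecule, labeled or not).

The correction separates the two by expressing the measured MID as a
mixture of theoretical *component* MIDs. Component $k$ is the MID of the
fragment in which exactly $k$ tracer-element atoms are guaranteed to be
tracer-derived labels, while all remaining atoms incorporate heavy
isotopes at their natural rates. If $n$ atoms can acquire label, there are
$n + 1$ components — a fragment with three labelable carbons can carry 0,
1, 2 or 3 labels, nothing else — and the model is

$$\bar S_m = \overline{\overline{CM}} \, \bar S_c,$$

where the columns of the correction matrix $\overline{\overline{CM}}$ are
the component MIDs and $\bar S_c$ is the corrected MID: the physically
meaningful fraction of molecules at each label count. The corrected MID is
recovered as the minimum-norm least-squares solution

$$\bar S_c = \overline{\overline{CM}}{}^{+} \bar S_m$$

with $+$ the Moore–Penrose pseudoinverse (`MASS::ginv`). The same contract
covers square, overdetermined (measured bins beyond $n$, populated by
natural isotopes of other elements or derivatization-reagent atoms) and
underdetermined systems; residuals and their sum of squares are reported
with every fit.

### Component MIDs by polynomial expansion

Each element has an isotope mass distribution (IMD): a vector of relative
abundances indexed by integer mass shift above the nominal (lightest)
isotope mass. Treating each atom's IMD as a polynomial in the mass-shift
variable, the MID of a molecule is the product of its atoms' polynomials —
terms of equal collective mass group by coefficient addition
(`convolveIMD()`, `imdPower()`, `formulaMID()`). For serine,

$$\mathrm{MID}_{C_3H_7NO_3} = \mathrm{IMD}_C^3 \cdot \mathrm{IMD}_H^7
\cdot \mathrm{IMD}_N \cdot \mathrm{IMD}_O^3.$$

Component $k$ replaces $k$ tracer-element atoms by labeled atoms. A labeled
atom from a tracer of purity $P$ and atom enrichment $E$ has the mixture
IMD

$$\mathrm{IMD}_{E_L} = P E \,[0\; 1\; 0\; \ldots] + (1 - P E)\,
\mathrm{IMD}_{E},$$

i.e. with probability $PE$ it is the heavy isotope one mass unit up, and
otherwise behaves like a natural atom. Only the product $PE$ enters, so
purity and enrichment are not separately identifiable — both input fields
exist because they are how tracer vendors state their certificates.
Tracer-element atoms outside `CanAcquireLabel` (e.g. carbons contributed by
a derivatization reagent) always carry the natural IMD in every column.

### High-resolution data

On a high-resolution instrument the mass shift from, say, ¹⁵N is resolved
from that of ¹³C, and the extracted MID counts only tracer-element
isotopes. This is modeled by collapsing the IMD of every declared
high-resolution element to 100% nominal mass (`[1]`), per element rather
than from an instrument resolving power, so mixed situations (some
elements resolved, others not) are expressible. The tracer element itself
can never be declared high-resolution: its natural heavy isotopes are
exactly what must be corrected away.

## Parameters and conventions

- **Abundance table** (`defaultAbundanceTable()`): pinned IUPAC/CRC
  representative isotopic compositions for C, H, N, O, S, Si, P, shipped
  as a text resource. Pinning makes results bit-stable across upstream
  revisions; other published tables differ from these values by less than
  10⁻³, and corrected MIDs may differ accordingly at the third or fourth
  decimal from tools pinning a different edition. The length of each IMD
  follows the element's largest naturally occurring shift (2 for C, H, N;
  3 for O, Si; 5 for S with a zero +3 bin; 1 for P) — nothing assumes a
  fixed length of 3.
- **Enrichments are fractions in [0, 1].** Values above 1 are rejected
  with a message telling the user to divide by 100: silently guessing
  percent-versus-fraction corrupts results by factors of 100.
- **Formula grammar**: plain element+count tokens (`C11H13N2O2`), repeated
  tokens accumulating; no parentheses, hydrates or charges.
- **Measured MIDs are relative areas.** A measured MID whose sum deviates
  from one by more than `1e-3` is renormalized with a warning rather than
  rejected — user input is routinely rounded (the worked tryptophan input
  sums to 1.000001, within tolerance and left untouched).
- **Row count and padding.** The matrix row count is the larger of the
  measured length and the full theoretical support; no truncation happens
  during polynomial expansion, so every column sums to one and the
  corrected components sum to the measured total whenever the fit is
  exact. When the measured MID reports fewer bins than the support (three
  measured bins against twelve label counts for tryptophan), the measured
  vector is zero-padded and a warning states the mean theoretical column
  mass lying in the padded rows: zero is the natural estimate for
  unreported isotopologue bins, and padding keeps the system well-posed.
  With high-resolution data the support is compact and little mass lands
  in padded rows; with low-resolution data a short measurement leaves real
  isotopologue mass unreported, and the warning is the user's cue.
- **Negative corrected components** arise from measurement imperfection,
  carry no physical meaning, and are reported verbatim with a warning.
  Clipping them to zero would break the sum-to-one property.
- **Rank deficiency** (possible only in contrived cases, since distinct
  label counts shift distinct columns) yields the minimum-norm solution
  and a warning rather than an error.
- **Determinism.** The correction path contains no randomness; seeds exist
  only in the simulator.

## What the simulator emulates

`randomFragment()` draws fragments over C, H, N, O, S, Si (carbon tracer,
at most 20 atoms by default — metabolite-scale) and `forwardMeasure()` runs
the model forward: the correction-matrix columns weighted by true
label-count fractions, then independent multiplicative lognormal noise per
isotopologue and renormalization. Multiplicative noise is the natural
choice for relative peak areas, whose uncertainty scales with intensity.
The simulator does **not** emulate chromatographic interference, detector
saturation, isotope fractionation, or correlated errors between
isotopologues; passing recovery tests therefore demonstrates the
correctness of the linear-algebraic correction, not robustness to every
instrument artifact in real data.

Test problem sizes — all ≤ 6-atom formulas for the enumeration oracle, 200
noise-free and 100 noisy (CV 0.005) recovery pairs over ≤ 20-atom
fragments — were chosen so the whole suite exercises hundreds of distinct
correction problems while finishing in seconds.

## Design choices where the design was open

- **Correction-matrix assembly and polynomial math are implemented here**;
  only the pseudoinverse is delegated (`MASS::ginv`, SVD with its default
  rank tolerance). An independent brute-force oracle (`bruteForceMID()`,
  exhaustive per-atom isotope enumeration, guarded to 12 atoms) cross-checks
  the expansion in the tests.
- **Binary exponentiation** for IMD powers: large fragments (tens of
  labelable atoms, e.g. lipids) need many polynomial expansions; squaring
  reduces the convolution count from $n$ to $O(\log n)$ with results
  identical to repeated convolution within `1e-12`.
- **Weights below `1e-15` are kept**, never zeroed; rounding is cosmetic
  and happens only at output formatting (six decimals in reports, full
  precision in returned objects).
- **Headless I/O**: the input path is a required argument of the
  command-line script rather than a file picker, because pipeline
  integration is the point of a programmatic interface. Multi-record batch
  files start a new record at each `FragmentName:` line (blank lines are
  ignored everywhere, so they cannot double as record separators), and
  `#`-prefixed comment lines are ignored.
- **Monoisotopic basis**: mass shifts are counted above the
  nominal/lightest-isotope mass, never the average mass.

## Worked example

```{r tryptophan}
spec <- FragmentSpec("TryptophanProtonated", "C11H13N2O2",
                     measuredMID = c(0.88885, 0.106829, 0.004322),
                     labeledElement = "C", highRes = c("N", "O", "H"))
res <- correctMID(spec)
res
```

An unlabeled sample: after correction essentially all mass sits at m+0,
because the measured m+1 and m+2 abundance is fully explained by natural
¹³C across eleven carbons. The corrected components still sum to the
measured total:

```{r sums}
sum(correctedMID(res))
sse(res)
```

And a self-validating simulation round trip:

```{r roundtrip}
fr <- randomFragment(seed = 7, maxAtoms = 20)
w <- c(0.55, 0.25, 0.15, 0.05)[seq_len(nLabel(fr) + 1)]
w <- w / sum(w)
measuredMID(fr) <- forwardMeasure(fr, w)
max(abs(correctedMID(correctMID(fr)) - w))
```

## Known limitations

- Exactly one labeled element per experiment; simultaneous dual tracers
  (e.g. ¹³C + ¹⁵N) are out of scope.
- Resolution is declared per element, not derived from an instrument
  resolving power; there is no m/z-dependent peak-merging model.
- No exact-mass/m/z computation, adducts, charge states or radioisotopes;
  the MID vector (peak areas already integrated and made relative) is the
  contract boundary.
- Fine structure within one nominal-mass bin is not separated beyond the
  per-element high-resolution mechanism.
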