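---
title: "Annotating 2-alkylquinolone homologous series from LC-MS/MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating 2-alkylquinolone homologous series from LC-MS/MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqscreen)
```

## The annotation problem

A microbial extract screened by reversed-phase UHPLC coupled to a
high-resolution mass spectrometer yields a *feature table*: one row per
chromatographic peak with a retention time (RT), an accurate `[M+H]+` m/z,
and usually an ion-trap MS/MS spectrum of nominal-mass fragments. For a
compound family built on one scaffold with a variable alkyl chain — here
the 2-alkylquinolin-4(1H)-ones ("pseudanes") — four independent lines of
evidence identify members without isolating a single compound:

1. the accurate mass pins down a molecular formula;
2. the MS/MS spectrum matches a library of standards or literature spectra;
3. members form a CH2-spaced mass ladder whose RT grows linearly with
   chain length;
4. all members share the scaffold fragment (m/z 159, the quinolone core
   after alkyl loss).

`aqscreen` encodes each line as a module and combines them with a fixed
evidence hierarchy. This vignette documents the models, the defaults, and
the design decisions that were genuinely open.

## Mass model

Monoisotopic masses use IUPAC/CODATA constants (`mass_constants()`). The
theoretical m/z of a protonated ion is the sum of its atomic masses minus
one electron mass; starting from the neutral molecule it is the neutral
mass plus one proton mass. The two routes differ by the hydrogen atom's
binding energy (1.5e-8 Da) — irrelevant at the fourth decimal, but the
electron correction itself (5.5e-4 Da, about 2.5 ppm at m/z 220) is not:
without it sub-ppm mass errors on Orbitrap-class data are impossible to
reproduce.

Formula strings are accepted in Hill notation (`C14H17NO`) and in the
compact ion dialect common in screening tables (`C_14_H_18_ON`, implicit
count 1); canonical output is Hill order. Ion compositions are understood
to *include* the ionizing proton's hydrogen: `C14H18ON` at 216.1383 is the
`[M+H]+` of neutral C14H17NO.

```{r mass}
ion_mz(parse_formula("C12H14ON", "protonated_ion"))   # pseudane-III [M+H]+
rdbe(parse_formula("C12H14ON", "protonated_ion"))     # quinolone scaffold: 7
```

### Formula enumeration

`enumerate_formulas()` scans the full bounded CHNOS lattice (defaults
C ≤ 30, H ≤ 60, N ≤ 3, O ≤ 5, S ≤ 1 — generous for metabolites under
500 Da) and keeps ions within the ppm tolerance whose neutral-parent RDBE
lies in [0, 20]. Defaults that were open choices:

* **tolerance 5 ppm** — the screening data this targets shows sub-ppm
  errors, so 5 ppm is deliberately conservative: the true formula always
  survives, and implausible decoy compositions are still admitted rarely
  enough for the RDBE filter and ranking to matter;
* **nitrogen rule off** — even-electron `[M+H]+` ions make the classic
  odd/even nominal-mass parity rule unreliable, so it is opt-in;
* **ranking** — ascending |ppm error|, ties by fewer heteroatoms, then by
  formula string. Every tie-break is total, so output is deterministic.

Display rounding is half-away-from-zero at 4 decimals, matching instrument
software conventions (plain `round()` rounds half to even).

## Spectral matching

`cosine_similarity()` pairs peaks greedily one-to-one within `frag_tol`,
taking candidate pairs in descending product of square-root-scaled
intensities (ties to the lower m/z). Square-root scaling is standard
practice for electrospray MS/MS; for the uniform-intensity nominal ladders
used in the packaged peak list it is a no-op, which keeps worked examples
hand-checkable: two 7-peak ladders sharing 6 fragments score exactly 6/7.

```{r cosine}
a <- spectrum(216.1382, c(132, 146, 159, 172, 186, 200, 216))
b <- spectrum(216.1382, c(132, 146, 159, 172, 186, 197, 216))
cosine_similarity(a, b)$score
```

Defaults: fragment tolerance **0.35 Da** (nominal ion-trap fragments
against unit-m/z library entries), precursor tolerance **5 ppm**, minimum
reported score **0.7**. `common_fragments()` clusters pooled fragments by
single-linkage within 0.5 Da; each spectrum counts once per cluster, and
the diagnostic ion of a class is the largest cluster present in every
spectrum.

## Series detection and isomer resolution

`detect_series()` links feature pairs whose mass difference matches the
CH2 unit (14.0156500642 Da) and whose RT difference lies in
[`rt_min_gap`, `rt_max_gap`] = **[0.2, 1.5] min** with the heavier member
eluting later. The gap window brackets the ~0.7 min per CH2 increment
observed for the pseudane series while refusing links across unrelated
peaks. Two numerical choices deserve note:

* **Spacing tolerance.** A difference of two measured masses carries both
  measurement errors, so the link test uses
  `|Δm − CH2| ≤ tol_ppm × 1e-6 × (m_i + m_j)` — first-order error
  propagation, not a single-mass ppm band. The same scaling governs the
  attachment of same-mass isomer candidates.
* **Chain choice.** All maximal link chains are enumerated and ranked by
  length, then cumulative |Δm − CH2|, then the standard deviation of the
  RT gaps, then member ids. The ranking is a total order, so series are
  deterministic and invariant to input order (a tested property). Chains
  need at least 3 members: two points cannot establish a regular interval.

Member indices are anchored to alkyl chain length through library entries
named `pseudane-<roman>`; unanchored series keep relative indices and say
so.

`fit_rt_trend()` is ordinary least squares of RT on chain length.
`resolve_isomers()` then adjudicates each group of same-mass features: the
one closest to the trend prediction is the canonical member, the others
are isomer candidates. The trend used here is refitted on *uncontested*
members only (falling back to the full fit below three clean points) — a
chain that greedily picked up an off-trend twin must not bias its own
adjudication. A demoted feature becomes a *same-scaffold isomer candidate*
only if its spectrum contains the diagnostic fragment and scores at least
**0.6** against the canonical member (the 6/7 ≈ 0.857 cosine of the
worked example passes with margin); with no MS/MS it stays `unknown` —
a bare mass duplicate is not evidence of an isomer. Two same-mass peaks
closer than `rt_tol` = **0.05 min** are treated as one split peak, not
isomers.

## Classification

`classify_features()` applies the first matching rule:

1. **identified_standard** — best library hit ≥ 0.7 from a commercial
   standard, *and* the feature is not an isomer candidate. The second
   condition is essential, not cosmetic: a branched-chain isomer can share
   its linear twin's precursor mass and (at nominal resolution) its entire
   fragment ladder, so spectrum and mass alone would "confirm" it against
   the standard. What a standard actually certifies is identity *at the
   standard's retention behaviour*; a peak displaced from the series trend
   is exactly the case the isomer class exists for.
2. **putative_homolog** — canonical series member with a formula candidate
   and the diagnostic fragment.
3. **isomer_candidate** — flagged by `resolve_isomers()`.
4. **unknown** — everything else.

One pipeline-level refinement feeds rule 2: a canonical member of an
anchored series whose own accurate-mass search returned nothing inherits
the nearest member's formula shifted by the appropriate number of CH2
units. That is the homologous-series inference itself — the ladder pins
down the composition even when one scan's mass error falls outside the
search window — and it is what keeps recall high when mass noise
approaches the search tolerance.

Every record carries a human-readable evidence trail, and the whole
cascade is available three ways with identical results: in memory
(`annotate_features()`), on files (`run_annotation()`, writing TSV + JSON
+ log atomically), and from the shell (`inst/cli/aqscreen.R`).

```{r fixture}
ann <- annotate_features(
  read_feature_table(aq_example("table1_features.csv"),
                     spectra = read_mgf(aq_example("table1_spectra.mgf"))),
  read_msp(aq_example("pseudane_library.msp")),
  pipeline_config(log_level = "quiet"))
summary(ann)
```

## What the synthetic generator emulates — and what it does not

`generate_pseudane_dataset()` draws the nine-member pseudane series with:

* **mass noise**: observed m/z = theoretical × (1 + ε),
  ε ~ N(0, `ppm_sigma` × 1e-6), default **0.3 ppm** — the sub-ppm error
  regime of a 30,000-FWHM Orbitrap;
* **RT model**: RT(n) = 2.46 + 0.70·n + N(0, `rt_sigma`) minutes for chain
  length n, so pseudane-III elutes near 4.56 min. `rt_sigma` defaults to
  **0.005 min**: run-to-run RT repeatability on a modern UHPLC is
  sub-second, and any value approaching the 0.07 min isomer displacement
  would contradict the emulated instrument, which resolves those twin
  peaks;
* **fragments**: scaffold ladder {132, 146, 159, 172, 186, 200, 214}
  truncated below the precursor plus the precursor-derived peak, base
  intensity 100 with lognormal jitter (σ = 0.2) — uniform in the noiseless
  limit so the hand-computed cosine values stay valid;
* **isomer twins** at −0.07 min (chain length 5) and −0.14 min (chain
  length 6), the displacement pattern of the two novel branched
  alkylquinolones;
* **decoys**: random CHNO compositions redrawn until ≥ 20 ppm from every
  series mass, random RT and fragments;
* **dropout**: optional loss of MS/MS spectra (`dropout_rate`), refused at
  rate 1 together with isomer twins, whose evidence is purely spectral.

Everything is a deterministic function of the seed; `corrupt_dataset()`
applies exactly one labelled corruption (mass shift, MS/MS drop, RT
shuffle) for error-path tests.

The generator deliberately does **not** emulate chromatographic peak
shapes, co-elution, isotope envelopes, adducts other than `[M+H]+`,
in-source fragmentation, or intensity-dependent mass error. Passing the
recovery suites therefore shows that the *inference chain* is correct
under the stated noise model — not that the pipeline is robust to every
pathology of real raw data. Real feature tables should be inspected with
the evidence trail, not trusted blindly.

## Test problem sizes

The shipped suites run the eleven-peak fixture end to end; fuzz the
formula enumerator against an independent brute-force oracle on 1000
random masses over a reduced lattice (C ≤ 12, H ≤ 26, N ≤ 2, O ≤ 3,
S ≤ 1) plus 60 masses on a larger one; check cosine symmetry and scale
invariance on 140 random spectrum pairs; verify series order-invariance
under repeated shuffles; and score class assignment against ground truth
over 50 generator seeds at default noise (perfect recovery expected) and
50 seeds at 3 ppm noise (mean recall ≥ 0.95, degrading gracefully as the
noise reaches the 5 ppm search tolerance).

## Known limitations

* Positive mode, `[M+H]+` only; no adduct or isotope-pattern scoring, so a
  potassiated or doubly charged feature will simply be `unknown`.
* Nominal-mass fragment handling: the 0.35 Da tolerance is right for
  ion-trap MS/MS but far too wide for high-resolution MS2; tighten
  `frag_tol` for Orbitrap fragment spectra.
* Series anchoring relies on `pseudane-<roman>` library naming; other
  homologous families get relative indices.
* The RT trend is linear in chain length. That holds over pseudane-III–XI;
  strongly retained late homologs on other gradients may need a gap window
  adjustment.
* The classifier's isomer logic assumes one canonical member per mass
  class per series; three co-eluting isomers of one mass would need manual
  review (all but the trend-nearest become candidates against the same
  canonical partner).
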