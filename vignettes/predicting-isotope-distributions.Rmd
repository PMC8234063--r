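---
title: "Predicting aggregated isotope distributions of average oligonucleotides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aggregated isotope distributions of average oligonucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oligoisotope)
```

## The problem

An intact-mass spectrum of an unknown oligonucleotide yields a
monoisotopic mass and an isotope envelope, but no elemental composition.
To use that envelope — to support an identification, to deconvolve
overlapping species, or to tell DNA from RNA — one needs the envelope a
molecule of that mass is *expected* to produce. This package models the
aggregated isotope distribution of the *average* DNA or RNA molecule as
a smooth function of monoisotopic mass, learned from an exhaustive
in-silico database of nucleotide compositions.

The central assumption is that, at a given mass, the isotope pattern of
a phosphodiester oligonucleotide is tightly constrained: the four
monomers have similar elemental makeup, so composition-to-composition
scatter around the average pattern is small (per-isotope probability
deviations of a few thousandths; see the residual diagnostics computed
by the test suite). The model therefore trades exactness for
sequence-independence, exactly as averagine-style models do for
peptides.

## The database

`build_oligo_db()` enumerates every 4-part composition (multiset, not
sequence) of length 5–92 for DNA and 5–90 for RNA, in deterministic
lexicographic order of (length, n_A, n_C, n_G). Monomer formulas are the
nucleoside 5′-monophosphate free acids (dAMP C10H14N5O6P, dCMP
C9H14N3O7P, dGMP C10H14N5O7P, dTMP C10H15N2O8P, and their ribose
counterparts); a strand of length *l* loses (*l* − 1) waters. The
database convention keeps the 5′-terminal phosphate; synthesis-style
5′-OH strands differ by exactly one HPO3, exposed through the `terminus`
argument of `composition_formula()`. Within one backbone every
composition has a unique formula and therefore a unique mass — the
database is a function from mass to composition wherever it is defined.

The enumeration is only exhaustive *in length*: above the mass of the
lightest (max + 1)-mer (93 × dCMP at 26,899.32 Da; 91 × CMP at 27,776.77
Da) heavier length classes are missing and the composition density over
mass collapses. Predictions are therefore restricted to masses strictly
below that homopolymer limit (`restricted_mass_limit()`); the bound is
exclusive because the limit molecule itself is not a database record.

Masses use an embedded NIST/CIAAW isotope table (snapshot identifier
`NIST-CIAAW-2021`, recorded in every model bundle). For C, H, N, O, P,
S and F the lightest isotope is also the most abundant, so the
all-lightest species is the monoisotopic variant.

## Aggregated isotope distributions

`isotope_distribution()` computes, for an arbitrary elemental formula,
the probability q_j that the molecule carries exactly j − 1 extra
nucleons, together with the probability-weighted centroid mass of each
variant. The implementation is the Newton–Girard power-sum recursion
over the product of elemental generating polynomials: power sums of the
inverse roots are additive over atoms, so the whole-molecule recursion
needs only per-element constants, and `batch_isotope()` evaluates it as
dense matrix arithmetic over millions of records at once (chunked to
bound memory). Centroid masses come from a parallel mass-moment series,
so the first centroid equals the monoisotopic mass to machine precision.

Because the recursion is the package's computational core, it is paired
with an independent oracle: `convolution_oracle()` computes the same
distribution by direct polynomial convolution with binary
exponentiation, exact up to float rounding. The test suite holds the two
to 1e-10 agreement on hundreds of random formulas; the oracle, not the
recursion, defines the semantics if the two ever disagree.

Twenty variants are modelled. Light molecules are fully covered by far
fewer (the 5-mer d(C)5 by eight, at printed precision); at the
restricted-range boundary 20 peaks cover about 95%, and coverage keeps
falling beyond it — one more reason the model stops at the restricted
limit.

## The compositional regression

Truncating at 20 peaks breaks the unit sum, so a closure term
x₂₁ = 1 − Σ q absorbs the leftover probability and the 21-part vector
is a true composition. The additive log-ratio transform with the
monoisotopic variant as fixed reference,
z_j = ln(x_{j+1}/x₁), maps it to ℝ²⁰; the ALR was chosen over CLR/ILR
because it tolerates partially observed envelopes and back-transforms
with a plain modified softmax (an implicit unit entry for the
reference), which guarantees predictions that are nonnegative and sum
to one.

Each z_j is regressed separately on raw powers of the standardized mass
(m − μ)/σ, with μ and σ the mean and SD of the *full* (unrestricted)
database masses — 22,746.1953 and 4,788.8776 Da for DNA. Raw powers of
the standardized covariate keep the exported coefficient table usable
via a single matrix product; orthogonal polynomials were rejected for
that reason. The fit is two-stage: ordinary least squares, then weighted
least squares with the squared stage-one residuals as weights, read
literally (it up-weights the poorly fitted mass regions, which
sharpens the fit where the average-molecule approximation is worst);
`weights = "inverse_squared"` exposes the opposite convention for
comparison.

Order selection holds out 5% of the restricted-range records (test-set
size is round-half-up of the fraction times the *full* record count,
which reproduces the published split sizes 166,095/152,472), fits
orders 1–15, and picks the order at which the largest number of the 20
per-isotope models attain their test-MSE minimum (ties to the smaller
order). Past order ~6 the mean test MSE is flat to the fourth decimal,
so the per-isotope vote is the informative criterion; on the default
fitting sample it selects order 10, and the final model is refit on all
rows (training deliberately spans the full mass range so polynomial
edge artefacts fall outside the deployment range). Predicted centroid
masses are the input mass plus the database-average per-isotope offsets
(`compute_mass_diffs()`); entry 1 is identically zero and successive
offsets step by ≈1.0025 Da.

### Problem sizes

Fitting on all 3.3M records is supported but unnecessary: the default
path fits on a seeded, mass-decile-stratified subsample of 100,000
compositions, which reproduces the full-fit standardization constants by
construction (μ, σ always come from the full database) and the order-10
selection, and leaves per-isotope training MSEs around 0.006 in ALR
space. The average mass offsets in a bundle are computed over the
restricted-range rows of the fitting sample by default; pass
`mass_diffs = compute_mass_diffs(restricted_db)` for the full-database
vector (the two agree to well under the 1 mDa level that matters for
display).

## Numerical choices

- **Closure floor.** Low-mass molecules have Σ q = 1 to machine
  precision, and the float value of 1 − Σ q near zero is noise. The
  closure is floored at 1e-30 (one constant, `add_closure()`), keeping
  ln x₂₁ finite; the affected z₂₀ values at low mass carry no usable
  probability mass, and the regression absorbs them.
- **Weight floor.** Where OLS fits exactly, squared residuals would be
  zero weights; they are floored at 1e-12 × median(r²), which leaves
  exact interpolation recoverable to 1e-8.
- **Softmax overflow.** The inverse ALR is evaluated with a max-shift
  that is algebraically identical, so arbitrarily large coordinates
  saturate instead of overflowing.
- **Bundle serialisation.** Coefficients, offsets and scalars are
  written as text at 17 significant digits and parsed with base R's
  correctly rounded reader, so export → import is bit-identical.
- **Index assignment.** The envelope reader maps observed peak masses to
  isotope indices by rounding (mass − mono)/1.00235 with a ±0.3 Da
  window; the spacing constant and window are arguments, since raw-data
  pipelines differ.
- **Degenerate inputs.** Out-of-range masses are an error carrying the
  valid range (the batch CLI downgrades this to a warning and skips the
  record); an envelope without its monoisotopic peak cannot be scored in
  ALR space and raises a "reference unobserved" error, while the
  intensity-space statistic still applies.

## Goodness of fit and classification

`mse_alr()` averages squared differences between observed and predicted
log-ratios over the observed non-reference peaks: invariant to overall
intensity, defined for gapped peak sets, zero iff the envelope matches
the prediction up to scale. `chi2_simplex()` estimates the total
intensity as N = Σ O / Σ x over the observed indices and averages
(O − E)²/E: it needs no monoisotopic peak but scales linearly with
intensity at fixed relative misfit, so scores are comparable only
within one acquisition — it is reported raw, without p-values.
`classify_backbone()` labels an envelope by whichever backbone model
scores lower (ALR statistic when peak 1 is present, χ² otherwise;
exact ties are "ambiguous"). On noiseless theoretical envelopes the
correct backbone wins ≥95% of the time at full scale; the separation
grows with mass, and is weakest below ~6 kDa where average DNA and RNA
patterns nearly coincide relative to composition scatter.

## The synthetic-envelope generator

`synth_envelope()` emulates centroided TOF envelope traces: the
theoretical distribution is scaled to a total intensity, each peak gets
multiplicative log-normal noise, peaks below a relative detection
threshold are dropped, and the monoisotopic peak can be removed outright
(it is not always retrievable in practice). It does *not* simulate
profile peak shapes, chromatography, charge-state deconvolution,
detector saturation or baseline chemistry — so green tests demonstrate
correctness of the statistics and the model pipeline on envelope-shaped
data, not robustness to raw-spectrum artefacts. All generation is
seeded and reproducible.

## Limitations

- Compositions, not sequences: the model cannot distinguish isomers, by
  construction.
- Phosphodiester backbones only; modified chemistries (phosphorothioate,
  2′F, 2′OMe) are outside the database and model, although the
  mass/isotope engine accepts arbitrary formulas including S and F.
- Valid strictly inside the restricted mass range; no extrapolation.
- The ALR statistic requires the monoisotopic peak; the χ² statistic is
  intensity-dependent and not comparable across platforms.
- A single fixed ALR reference serves the whole mass range; region-wise
  models with locally optimal references would serve detection-limited
  high-mass spectra better and are not implemented.
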