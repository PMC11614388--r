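---
title: "Natural-abundance correction and differential statistics for 13C tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural-abundance correction and differential statistics for 13C tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midtracer)
library(dplyr)
```

## The problem

In a stable-isotope tracing experiment, cells are fed a uniformly
13C-labeled substrate (glucose or palmitate) and the label is followed into
downstream metabolites by GC-MS. For each metabolite the instrument reports
peak areas for the isotopologues m+0, m+1, ..., m+K — species whose mass
exceeds the monoisotopic mass by an integer number of mass units. Two
processes put mass into the heavy channels: tracer-derived 13C on the
carbons of interest, and naturally occurring heavy isotopes (13C at 1.07%,
but also 29/30Si, 17/18O, 15N, 2H, 33/34S) on *every* atom of the measured
species. For GC-MS the measured species is usually not the metabolite
itself but its TBDMS-derivatized M-57 fragment: each
tert-butyldimethylsilyl group replaces one active hydrogen with C6H15Si and
electron-impact ionization cleaves one tert-butyl (C4H9, 57 Da). A
three-site TBDMS fragment carries three silicon atoms, and silicon alone
contributes almost 8% heavy-isotope abundance per atom — without correction
a fully unlabeled metabolite looks substantially "labeled".

`midtracer` removes the natural-abundance contribution, turning raw
isotopologue areas into the tracer-only mass isotopomer distribution (MID),
and carries the result through condition-level summaries and two-group
differential statistics.

## The correction model

Let `f` be the elemental composition of the measured fragment with `n`
tracer-eligible carbons. Every atom contributes an independent mass-shift
distribution, and the distribution of a molecule is the convolution of its
atoms' distributions. Column `j` of the correction matrix `A` (for
`j = 0..n`) is the theoretical observed pattern when exactly `j` tracer
carbons carry label:

* the `n - j` unlabeled tracer carbons and all non-tracer atoms contribute
  their natural patterns (convolved);
* the `j` labeled carbons contribute a binomial in the tracer purity `p`
  (each is 13C with probability `p`); at `p = 1` this is a delta at shift
  `j`.

The observed vector is then `raw ≈ pool * A %*% x` where `x` is the true
MID and `pool` the total metabolite amount. With purity 1, `A` is lower
triangular with positive diagonal, hence invertible — the model is exactly
identifiable on noise-free data.

```{r matrix}
frag <- tbdms_m57_fragment(parse_formula("C3H6O3"), n_sites = 2)  # lactate
frag
A <- registry_correction_matrix(default_registry(), "lactate")
round(unclass(A)[1:5, ], 4)
```

Recovering `x` from noisy areas is a constrained least-squares problem:
noise can make the naive inverse `A^-1 raw` negative, so `correct_mid()`
solves `min ||A x - raw||` subject to `x >= 0` (non-negative least squares)
and renormalizes `x` to sum 1. The pre-normalization sum is kept as the
corrected total pool for abundance readouts. A relative residual above 5%
(configurable) flags the fit; an all-zero raw vector is an error, not a
silent NaN.

Numerical choices worth stating:

* **Isotope abundances** are a versioned built-in table (13C 0.0107, 2H
  0.000115, 15N 0.00364, 17O 0.00038 / 18O 0.00205, 29Si 0.04685 / 30Si
  0.03092, 33S 0.0075 / 34S 0.0425 / 36S 0.0001) and can be overridden per
  call; sulfur's shift-4 isotope is carried explicitly.
* **Pattern length** defaults to `K = n + 4` channels so the Si/S/O heavy
  tails of TBDMS fragments are captured; truncation only drops tail mass
  and retained entries are exact.
* **Per-element powers** of single-atom patterns use
  exponentiation-by-squaring; the contract is identical to repeated
  convolution.
* **Measured vectors** shorter than `K + 1` are zero-padded; longer ones
  are truncated with a warning.
* **NNLS scaling**: raw vectors spanning ~1e9 are rescaled by their maximum
  before the solve so the solver's internal tolerance is meaningful.

Fractional enrichment summarizes a MID as the mean labeled-carbon fraction
`sum(j * x_j) / n`. Abundances are reported relative to the internal
standard (D-myristic acid, 750 ng/sample) and per 1e6 cells:
`area / IS_area / cells * 1e6`.

## Fragment registry

The measured fragment per metabolite (parent formula, TBDMS site count or
"none", tracer carbons) lives in a registry table. The built-in registry
covers the metabolites of the bundled scenarios with site counts from
standard MTBSTFA derivatization chemistry (one site per carboxyl, hydroxyl
and amine hydrogen); these are curated defaults, and any entry can be
replaced via a user CSV/YAML registry or an explicit
`fragment_override_formula` when a lab's validated fragment differs.

## Experiment-level readouts

`correct_samples()` applies the correction across a whole study (samples x
metabolites), `summarize_labeling()` produces figure-style per-group
mean ± SEM of either a MID fraction or a normalized labeled abundance, and
`compare_conditions()` tests the two groups with a pooled-variance
Student's t (two-tailed, `df = n1 + n2 - 2`). The pooled rather than Welch
form is the package default because it matches the convention of the
two-group comparisons this pipeline reproduces; Welch is available behind
`welch = TRUE`. Group sizes of 3 are accepted without normality checks —
a deliberate match to common tracing designs and a documented limitation,
not an endorsement. Zero-variance degeneracies are handled explicitly:
equal constant groups give t = 0, p = 1; unequal constant groups give p = 0
with a `degenerate` flag rather than an exception.

For media-transfer experiments (conditioned media incubated with recipient
cells), `media_transfer_table()` joins donor-media labeled abundance with
recipient intracellular labeled abundance on shared
metabolite/isotopologue keys; recipient-only keys are dropped with a
message.

## Differential statistics

`differential_table()` reproduces the two table shapes of a two-group
differential metabolomics analysis:

* **CSF style** — fold change (treated/control), log2FC, two-tailed
  Student's t p, -log10 p, and an enrichment call, sorted by |log2FC|.
* **Conditioned-media style** — exact Wilcoxon rank-sum p (full exact null
  when there are no ties and groups are small; otherwise the normal
  approximation with tie and continuity correction), BH q-values over the
  submitted table, sorted by p. Pooled overall mean/SD per row come from
  `pooled_summary()`, which is exact: composing it with per-group summaries
  equals summarizing the concatenated raw data.

The enrichment rule is `|log2FC| > 1 AND p < 0.05` with both thresholds as
parameters. This is the unique simple rule consistent with the bundled CSF
reference labels — e.g. glutarylcarnitine (p = 0.004 but log2FC = 0.68)
is "Not Sig", while both fatty acids (log2FC > 1, p < 0.05) are called.
Zero group means are floored at half the smallest nonzero abundance in the
table before fold changes. Per-metabolite failures become flagged rows
(`note` column) rather than aborting the table. Machine output keeps full
precision; rounding (FC/log2FC to 2 decimals) happens only in rendered
tables, because reference tables that round FC and p independently cannot
be reproduced from their own rounded columns.

The smallest achievable two-sided exact Wilcoxon p at n = 6 per group is
2/C(12,6) = 2/924 ≈ 0.0022 — reference media tables bottom out at a printed
p of 0.002 for exactly this reason.

## The synthetic-data generator

Every stage is testable without instrument data because the generator
forward-simulates the same model the correction inverts:

```
raw = pool * A %*% true_mid * lognormal(cv) + baseline
```

* **Noise** is multiplicative lognormal per channel (peak areas are
  positive and right-skewed), mean-unbiased, with CV defaults of 15% for
  cell extracts and 25% for media — media measurements are noisier; the
  glucose-tracing fixture uses 10% throughout. The internal-standard
  channel has its own 5% CV; an additive baseline area models integration
  floor.
* **Designs** mirror the study shapes the pipeline targets: tracing with
  n = 3 per group (BSA vs PA), conditioned-media abundance tables with
  n = 6 per group, and a CSF-style table with n = 10 per group and 34
  metabolites whose true fold changes are the bundled reference values
  (2.27 and 2.17 for the two fatty acids among them).
* **Determinism**: one documented PRNG stream per run, seed required;
  the same seed regenerates byte-identical CSVs, and the caller's RNG
  state is never disturbed.
* **Ground truth is always emitted** (scenario, pools, true MIDs), so
  recovery tests compare against the sidecar rather than reaching into
  generator internals. `true_mid_dispersion()` additionally reports the
  true per-sample SD of each corrected fraction under the noise model,
  estimated once by a 2000-draw Monte-Carlo.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: detector saturation and nonlinearity, correlated
channel noise within a scan, retention-time drift and integration errors,
isotope fine structure and resolution effects, and real biological
between-replicate variance beyond a lognormal CV. The generator validates
the algebra and the statistics, not the instrument.

## Validation design

Two recovery checks deserve explanation because their acceptance bands are
easy to get wrong:

* **Round trip.** For random fragments and random MIDs, correcting the
  noise-free forward model recovers the MID to 1e-6 (in practice to
  machine precision), and NNLS agrees with direct forward substitution on
  the triangular system — two independent routes to the same answer.
* **Replicate recovery.** For the glucose-tracing fixture we require the
  group-mean labeled fractions to fall within 3 standard errors *of the
  scenario truth* — `3 * true_sd / sqrt(3)` with `true_sd` from
  `true_mid_dispersion()` — in at least 95% of replicate studies. The SEM
  here is deliberately the truth's own dispersion, not the 3-sample
  estimate: a bound built from the estimated SD of n = 3 samples is a
  t-statistic with 2 degrees of freedom and covers the truth only ~90% of
  the time no matter how small the noise, so it cannot certify recovery;
  the true-SEM bound covers ~99.7% when the pipeline is unbiased and fails
  loudly when it is not.
* **Unlabeled control.** An unlabeled sample generated with the same
  isotope table corrects to m+0 ≥ 0.99. This is a table-consistency check
  and is run noise-free: with channel noise even at 2% CV, a
  triple-TBDMS (Si3) fragment's ~35% natural tail lets the solver
  misattribute noise to m+1 and the bound is unattainable; noise
  robustness is what the replicate-recovery check is for.
* **Type-I error.** On all-null two-group tables (n = 10 per group, CV
  20%, 1000 tables) the enrichment rule calls essentially nothing: the
  |log2FC| > 1 gate alone keeps the false-call rate far below the 5% that
  p < 0.05 would allow.

Problem sizes used by the packaged checks — 500 round-trip fragments, 200
replicate tracings, 1000 null tables, 2000 Monte-Carlo draws for the truth
dispersion — were chosen so each check resolves its question comfortably
(Monte-Carlo standard errors well below the margins tested) while the whole
suite stays desk-scale.

## Worked example

```{r pipeline}
fx <- bundled_fixture("glucose_6h", seed = 42)
corrected <- correct_samples(fx$areas, fx$design)
summarize_labeling(corrected, "lactate", 3, compartment = "media")
r <- summarize_labeling(corrected, "lactate", 3, compartment = "media")
compare_conditions(r)
```

```{r diff}
csf <- bundled_fixture("csf_3dHFD", seed = 42)
head(differential_table(csf$abundances, csf$groups, treated = "HFD_3d"), 5)
```

## Known limitations

* Correction assumes unit ionization/transmission efficiency across
  isotopologues and no resolution-dependent interference (no mass-accuracy
  modeling).
* Tracer purity is a single global binomial parameter; position-specific
  labeling and impurity spectra are out of scope.
* The registry ships curated TBDMS site counts; labs should override
  entries for fragments their method validates differently.
* The exact Wilcoxon refuses ties rather than implementing a tie-aware
  exact null; `auto` mode falls back to the corrected normal
  approximation, which is what reference media tables use as well.
* BH q-values are computed over the submitted table only; they are not
  comparable across differently sized metabolite families.
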