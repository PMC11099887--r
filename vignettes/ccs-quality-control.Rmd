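---
title: "Internal CCS quality control by isotope-labeled standardization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal CCS quality control by isotope-labeled standardization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidccs)
```

## The measurement problem

Collision cross sections (CCS, Å², nitrogen) from drift-tube ion mobility
are traceable to the primary experimental method; CCS values from
externally calibrated analyzers (trapped-ion-mobility, traveling-wave)
inherit whatever bias the calibration process introduces, and for lipids
this bias is systematic and lipid class– and adduct-specific, typically
within about ±1%. Because the bias originates in calibration rather than
in a physical model, it cannot be removed from first principles; it can,
however, be *measured and compensated internally* if every sample carries
a palette of standards that are chemically identical to the analytes but
distinguishable by mass. A uniformly ¹³C-labeled yeast lipid extract is
exactly such a palette: each labeled lipid behaves chromatographically
and conformationally like its unlabeled counterpart while its m/z is
shifted by 1.0033548 Da per carbon.

`lipidccs` implements the three stages of this idea: curating a reference
library of drift-tube CCS values for the labeled lipids, monitoring the
bias of any experiment against that library, and correcting all measured
lipids with class/adduct-specific linear function ensembles.

## Species model and labeling

Lipids are handled at *species level* — class plus total acyl carbons and
double bonds, e.g. `PC 34:2` — with an optional elution-order index
(`TG 48:2 (2)`) when a species resolves into chromatographic isomers.
Fatty-acyl-level and sn-position-resolved names are out of scope: the
reference values are defined at species level. The labeling state is a
separate column (`U13C` / `12C`), never part of the name, because the
same species identity exists in both forms and must match across them.
Five singly charged adducts are supported ([M+H]⁺, [M+NH₄]⁺, [M+Na]⁺,
[M−H]⁻, [M+HCOO]⁻) with fixed charge-carrier mass changes.

A small diagnostic utility, `isotopologue_apparent_shift()`, quantifies
the apparent CCS offset expected between isotopologues purely from
reduced-mass considerations, `sqrt(mu_heavy/mu_light) - 1` with
`mu = m·M/(m+M)`: for a typical phospholipid and its fully labeled form
in N₂ this is ~0.1%, the right order for the small systematic offsets
seen between labeled and unlabeled lipids on moderate-resolution
instruments. It is a diagnostic, not a correction, and the package makes
no claim that it reproduces any particular measured offset exactly.

## Library curation

`curate_library()` aggregates a dilution-series observation table into
one entry per (species, adduct), applying four criteria in a fixed
order — the order fixes which reason a rejected group is reported with:

1. **mass accuracy**: every replicate within 5 ppm (inclusive, on the
   absolute error);
2. **minimum detections**: at least 2 distinct dilutions. The criterion
   is counted over dilution levels (not raw files) because the dilution
   series is the designed source of replication;
3. **coelution of adducts**: all adducts of a species must elute
   together. The tolerance is not part of the published criterion, so it
   is a parameter; the default, |RT − species median RT| ≤ 0.1 min with
   the median taken over the species' adduct groups pooled across both
   polarities, is a conventional targeted-lipidomics alignment width.
   Note that when only two adducts disagree, *both* fail (the median
   cannot arbitrate), which is the conservative choice;
4. **repeatability**: CCS relative standard deviation strictly below 1%.

Retained groups get the arithmetic mean CCS across dilutions as the
reference value and the sample RSD as their precision record — both
conventional choices. Curation is idempotent on the observations it
retains, and the rejection report carries exactly one (the first
failing) reason per group.

The curated values are validated against the equivalent-carbon-number
(ECN) ordering transferred from retention time to the CCS dimension:
within a class–adduct group, more acyl carbons at equal unsaturation
must increase CCS, and more double bonds at equal chain length must
decrease it. `ecn_trend_validate()` returns every ordered pair violating
this, by exhaustive scan; an empty report is the acceptance state of a
library.

### The packaged reference library

The shipped library (`default_ccs_library()`) is a **synthetic**
stand-in: the original drift-tube reference table for the labeled yeast
lipids is not redistributable here, so the package constructs a library
with the same composition — 377 entries, 162 species, 15 classes
(AcCa, Cer, Co, DG, HexCer, LPC, LPE, PA, PC, PE, PG, PI, PS, SPH, TG),
5 adduct types, m/z 318.3501–966.9794, CCS 189.4–327.1 Å² — whose CCS
values follow a strictly monotone per-class ECN model and whose m/z
values are built from per-class mass anchors plus the uniform-¹³C shift
and exact adduct deltas. Ten classes (Cer, DG, HexCer, LPC, PA, PC, PE,
PI, PS, TG) have at least three species in at least one adduct and are
therefore correctable; the other five are present only for monitoring.
The construction is deterministic (`data-raw/make_library_fixture.R`).
Conclusions that depend on the *values* (not the composition) of the
real library cannot be drawn from this fixture.

## Bias monitoring

Matching is by exact (canonical name incl. isomer index, adduct) key and
uses only labeled measured ions — the library contains labeled lipids.
Unlabeled ions are carried through to correction application only. A
measured name without an isomer index that faces multiple library
isomers of the same backbone and adduct is excluded as ambiguous and
reported, rather than resolved by nearest retention time: a silent
mis-assignment would corrupt the correction fit, while an exclusion only
costs one standard.

The monitored statistic is the signed percent bias
`(measured − reference)/reference × 100`. Summaries are per (class,
adduct, polarity) plus polarity-level rollups in which **each matched
ion counts equally** (not each class); this weighting is a package
choice where convention is ambiguous. Two granularities exist: per-file
bias, and a "mean mode" that first averages each ion's CCS across files
(`aggregate_measured()`), mirroring summaries over a measurement
sequence. For a single file the two coincide.

## The correction model

For each class–adduct group with ≥ 3 labeled standards, subsets of 3–6
standards are drawn and one ordinary least-squares line

> reference CCS = slope × measured CCS + intercept

is fitted per subset. The regression orientation (reference on measured)
is deliberate: applying a function is then a direct plug-in of a
measured value. The fit uses the QR path of `stats::lm.fit`; tests
cross-check the coefficients against an independent closed-form
normal-equations oracle at 1e−9 relative.

**Subset scheme.** All subsets of sizes 3–6 are eligible; when their
total count exceeds the cap (default 100) exactly `cap` subsets are
drawn uniformly *without replacement from the pooled collection* (sizes
are not stratified — the published description says only "up to 100
distinct functions employing 3–6 lipids", so the simplest uniform scheme
was chosen). The draw samples ranks and unranks them combinadically, so
the full collection is never materialized; it is deterministic for a
fixed seed and the seed is recorded in the model object and in every
output header.

**Quality rule.** The published account flags functions by gross slope
deviation from 1 (examples: 0.01, 0.46, 2.42) but states no numeric
rule; the package defaults to slope ∈ [0.8, 1.2] and r² ≥ 0.99, both
configurable. Flagged functions are excluded from point estimates but
retained in every report, so users can inspect them. Under realistic
noise (0.2% of CCS) and the narrow CCS spread of a small lipid class,
r² ≥ 0.99 is a strict rule and can flag a large fraction of 3-point
functions; this errs on the side of robustness of the point estimate,
and the per-function report shows what was excluded. A group whose
functions are all flagged yields `NA` point estimates rather than a
silent fallback.

**Point estimate.** One corrected value per lipid is reported as the
median across non-flagged functions — robust against residual poor fits
— alongside the full per-function distribution; reporting only an
ensemble would push the aggregation problem onto the user, and the
median is the standard robust reduction.

**Degenerate inputs.** A subset whose measured CCS values are all
identical has no identifiable slope and raises a dedicated
degenerate-fit error; an r² of a zero-variance response is defined as 1
when residuals vanish. Correction applies to all lipids of a covered
group irrespective of labeling status.

**A statistical caveat.** The measured CCS is the *predictor*, so its
noise induces regression dilution: fitted slopes shrink by roughly
`Var(x)/(Var(x)+σ²)`. At 0.2% noise and typical within-class CCS spreads
this is a ~1% relative effect on the slope and is negligible against the
bias being corrected, but it is why parameter-recovery tests distinguish
response-side noise (where OLS is exactly unbiased) from predictor-side
noise (where the attenuation factor is checked explicitly).

## The synthetic-data generator

`simulate_ccs_dataset()` emulates the data shapes of the real workflow
with full ground truth. Its defaults are the study conditions the
package is designed around: the 10 correctable classes with their
library adduct types, 8 standards per class–adduct group, a 5-point
dilution series, 3 measured files, multiplicative Gaussian CCS noise of
0.2% (comfortably inside the 1% RSD acceptance criterion, as observed
repeatability on modern instruments is a few tenths of a percent), and
per-group affine biases cycling deterministically over slopes
0.9935–1.0025 and intercepts −1 to 0.4 Å², producing measured-vs-reference
biases spanning roughly −0.4% to +1.1% — the scale reported for real
cross-platform lipid CCS comparisons. Noise is multiplicative because
the field's repeatability criterion is a percent RSD. The injected bias
is parameterized in the correction orientation (reference =
slope·measured + intercept), so a noise-free fit must recover the
configured parameters exactly — the identifiability property the tests
assert.

Violations of each curation filter can be injected as extra species with
exact truth labels: a 10 ppm mass offset, presence in a single dilution,
a 0.5 min retention shift on one adduct (which fails *both* adducts of
that species, by the median rule), and ±2.5% alternating CCS replicates
(guaranteed RSD ≈ 2.5%).

What the generator does **not** emulate: raw mobilograms and peak
shapes, isotope envelopes and interferences, retention drift between
runs, missingness patterns, intensity-dependent noise, or any
m/z-dependence of the CCS bias (the correction model is affine in CCS
only, and so is the truth here). Passing tests therefore demonstrate the
pipeline's correctness and its statistical behavior under the stated
noise model — not performance on real raw data.

## Problem sizes and numerical tolerances used by the test suite

The suite exercises: exact-recovery and oracle checks on groups of 3–12
standards (1,000 random OLS instances against the closed-form oracle at
1e−9 relative); ensemble determinism bit-for-bit; a 100-replicate
stochastic study (one class, three adducts, 8 standards per group, 0.2%
noise, ~1% injected bias) in which the mean absolute group bias after
correction stays below 0.1%; and full-pipeline runs on the default
10-class simulation. These sizes keep the whole suite within a couple of
minutes on a single CPU while leaving every statistical assertion
comfortably powered; they are choices of this package, and all scale up
through `sim_config()`.

## Known limitations

* Matching is by name and adduct (targeted workflow); no m/z- or
  RT-tolerance identification.
* Corrections are per class–adduct and affine; no pooled, nonlinear or
  m/z-dependent models. Traveling-wave instruments, whose calibration
  characteristics differ, may need additional scrutiny before the
  defaults are trusted.
* The shipped reference library is a synthetic stand-in (composition
  faithful, values constructed); real-data use requires the user's own
  curated library, which `read_ccs_library()` accepts in a documented
  CSV schema.
* Mode-level rollups weight ions equally; class-weighted summaries can
  be had by averaging the per-class rows of `summarize_bias()`.
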