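---
title: "Absolute quantification of faecal host DNA by droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute quantification of faecal host DNA by droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoolddpcr)
```

## The problem

Stool carries DNA shed from the host's gastrointestinal epithelium alongside
a vast excess of microbial DNA (host DNA is typically under 1% of the
total). Quantifying it absolutely — copies per microlitre of extract, copies
per milligram of stool, ultimately cells per milligram — enables
non-invasive monitoring of the GI tract, but requires assays that are
sensitive (multicopy targets: LINE-1 repeats at thousands of copies per
haploid genome, mitochondrial genes at tens to thousands of copies per
cell), species-specific, and robust to the PCR inhibitors that co-purify
with stool DNA. Droplet digital PCR (ddPCR) fits these constraints: each
reaction is partitioned into ~20,000 nanolitre droplets, every droplet is
scored positive or negative for amplification, and the target concentration
follows from Poisson partition statistics with no standard curve.

`stoolddpcr` implements the complete computational side of that workflow,
plus a synthetic droplet generator so every stage is testable without
instrument exports.

## The model

Let a well have $N$ accepted droplets of volume $v$ (default $v = 0.85$ nl,
the instrument convention), and let $k$ of them be negative at the calling
threshold. Under Poisson loading, the mean copies per droplet is

$$\hat\lambda = -\ln\left(\frac{k}{N}\right),$$

and the concentration in the reaction is $\hat\lambda / v$ (copies per
microlitre); copies per 20 µl reaction — the absolute copy number, ACN —
is that times the reaction volume. The confidence interval is a normal
approximation on the negative fraction $p = k/N$, transformed through
$-\ln$; at $N \ge 10{,}000$ it is practically identical to exact intervals.
A well with $k = 0$ is reported as saturated (flag, not error); a well with
no positives has concentration exactly 0.

Droplets are called positive when their amplitude is *strictly greater*
than the threshold: a droplet sitting exactly at a threshold chosen to
delimit negative droplets is negative. Fixed thresholds of 3400 (human
assays), 6300 (bacterial 16S) and 3000 (mouse assays) are the defaults;
`threshold_from_ntc()` provides an opt-in data-driven alternative
(1.2 × the 99.9th percentile of pooled NTC amplitudes).

Sample-level quantities then follow the fixed arithmetic of the pipeline:

1. **QC** — only wells with ≥ 10,000 accepted droplets are quantified.
2. **Replicate averaging** — duplicate extraction ACNs are averaged
   (`average_replicates()`), with the range kept for error bars; NTCs are
   averaged across their four technical replicates.
3. **Background/dilution adjustment** —
   $(\mathrm{ACN}_{sample} - \mathrm{ACN}_{ntc}) \times \text{dilution}$
   gives copies per µl extract, because each reaction receives exactly 1 µl
   of diluted extract. A negative difference is clipped to zero and
   flagged, never reported as a negative concentration.
4. **Normalisation** — copies per µl extract divided by the stool mass (mg)
   in the ~200 µl homogenate aliquot gives copies per mg stool. This
   "literal" mode is the default; a "total" mode multiplying by the elution
   volume first is available for users who want total recovered copies.

Averaging precedes subtraction and dilution; this order matters only when
replicates could carry unequal dilutions, which the pipeline therefore
disallows.

Derived statistics: spike-in recovery
$R = 100\,(\mathrm{ACN}_{spike} - \mathrm{ACN}_{buffer}) / \mathrm{ACN}_{alone}$
(reported even outside [0, 100], flagged); signal-to-noise ratios of
per-pg ACNs with zero-noise values censored as lower bounds; percent yield
$100 \times \text{measured}/\text{expected}$; percent CV with the $n-1$
standard deviation; OLS standard curves on the linear scale.

Unit conversions: 290 genome equivalents per ng of human gDNA (the constant
reproducing the reference pairs 800 ng = 232,000 GE, 80 ng = 23,200 GE,
8 ng = 2,320 GE exactly); empirical LINE-1 copies per genome equivalent as
the in silico prediction (~5,800) times the empirical median yield fraction
(3.95), i.e. 22,910; cell counts as the *floored* quotient
copies-per-mg / copies-per-GE — floor reproduces both published bounds
(2 and 176 cells/mg) where rounding would not, and a partial genome is not
a cell. All three constants are config-overridable, and the cell count is
an estimate: LINE-1 copy number is polymorphic across individuals.

## In silico PCR

`find_amplicons()` enumerates predicted products of a primer pair on
arbitrary IUPAC templates: the forward primer must match one strand and the
reverse complement of the reverse primer downstream on the same strand
within `max_product_bp` (default 4000, the usual web-tool cap), with at
most `max_mismatch` mismatches per primer (default 0). Degenerate codes in
primers match their base set at zero cost (a Y matches C or T — the 16S
primers need this); template letters are literal. Both strands are
searched, overlapping products are all reported, and coordinates are
0-based half-open on the forward strand (`amplicons_onebased()` converts
for display). Matching is delegated to `Biostrings::matchPattern()`; the
test suite checks it against an independent naive quadratic scan.

`restriction_site_count()` counts non-overlapping, left-to-right site
occurrences (mirroring digestion) and reports the expected mean fragment
length $L/(\text{count}+1)$ — e.g. HaeIII (GGCC) fragmentation used to
break target linkage before ddPCR.

The two bundled gBlock standards (`gblock_templates()`) each contain
exactly one product — 60 bp for the LINE-1 assay, 83 bp for the ND5
assay — and one engineered EcoRI site. The LINE-1 record is 125 nt in our
transcription although its label says 126 bp; since the amplicon-internal
arithmetic (20 + 19 + 21 = 60) is self-consistent, the fixture is used for
amplicon assertions, and the total-length label is treated as advisory.

## The synthetic-data generator

`simulate_well()` draws per-droplet occupancy as independent Poisson counts
(the standard digital-PCR assumption; indistinguishable from multinomial
allocation at these scales), then amplitudes from a two-cluster model:
negatives N(1800, 200²), positives N(6500, 400²), a `rain_fraction`
(default 2%) of positives re-drawn uniformly between the cluster means,
and a `false_positive_rate` (default 5 × 10⁻⁵) of empties emitting
positive-cluster amplitudes. The accepted count is a fixed fraction
(default 0.9) of 20,000 generated droplets, so the ≥ 10,000 QC rule is
exercisable. All randomness flows from one explicit seed, with per-well
sub-seeds derived deterministically from enumeration order; identical
inputs and seed give bit-identical wells.

The amplitude parameters are deliberately minimal synthetic choices — no
public amplitude distributions or NTC contamination rates exist to
calibrate against — and are exposed in `sim_config()`. Passing tests on
this generator demonstrates the *arithmetic* of the pipeline, not the
behaviour of any instrument: real droplet readers produce
concentration-dependent rain, baseline drift and well-to-well coupling
that this model does not attempt.

Higher-level designs:

* `simulate_dilution_series()` — five levels spanning ~193–120,440 copies
  per reaction in triplicate (the validated linear range), with an optional
  generative `yield` scaling measured below theoretical copies, emulating
  the sub-unity yields of dilute synthetic standards.
* `simulate_spikein_experiment()` — the three arms of the recovery
  experiment at 232,000/23,200/2,320 GE. GE are scaled to per-reaction
  copies via `copies_per_ge` (default 5,800) and a `reaction_fraction`
  (default 1/50,000: 100 µl elution × 500-fold dilution × 1 µl loaded),
  giving λ ≈ 1.1 at the top level — comfortably inside the precise range
  of the estimator.
* `simulate_longitudinal_study()` — per subject and day, stool mass
  uniform on 20–80 mg (around the observed 49.5 mg median), true copies
  per mg log-normal around a 200,000 copies/mg baseline (inside the
  healthy-donor range of 52,000–4,050,000) with log-SD 0.8 ("several-fold"
  day-to-day variation), duplicate extractions perturbed by a 10% CV,
  500-fold dilution, plus four shared NTC wells.
* `simulate_preservation_timecourse()` — exponential decay (or growth, for
  negative rates, as seen for 16S in EDTA) of the true level over
  0/4/24/72/96 h, duplicate extractions except for buffers flagged
  single-extraction (the OMNI case).

These defaults were fixed once from the study conditions above and are not
test-tuning knobs.

## Numerical and design choices

* **Estimator-recovery experiments use the rain-free, false-positive-free
  configuration.** The property under test there is the Poisson inversion;
  with rain on, a fixed mid-gap threshold misclassifies ~0.7% of positive
  droplets by construction of the amplitude model, a small known negative
  bias that belongs to threshold placement, not to the estimator. The
  threshold-sensitivity behaviour is exercised separately with rain on.
* **Simultaneous coverage.** The end-to-end conservation check asserts
  that every sample's generative copies-per-mg lies inside its interval;
  per-sample levels are Bonferroni-adjusted (confidence
  $1 - 0.05/n_{samples}$) so the simultaneous statement itself has ~95%
  coverage. A fixed per-sample 95% level would fail such a run about half
  the time by multiplicity alone.
* **Pooled-count intervals.** A sample's interval pools the
  positive/negative counts of its replicate wells (replicates share a
  dilution factor by construction) and transforms the bounds through the
  same linear adjustment and normalisation as the point estimate.
* **Degenerate inputs** are flags, not crashes, wherever a batch must
  complete: saturated wells, clipped backgrounds, single-replicate
  samples, QC rejections. Structural errors (missing NTCs without an
  explicit override, unknown assays, malformed files) stop with messages
  listing every violation.
* **Problem sizes.** The packaged validation experiments use 200 wells per
  concentration for estimator recovery, 20 replicates for spike-in
  recovery, triplicate five-level dilution series, and a 2-subject ×
  3-day noise-free study for end-to-end conservation — sizes at which the
  binomial sampling error of an 18,000-droplet well (well under 1% at
  moderate λ) makes the stated tolerances meaningful.

## Limitations

Physical stages — collection devices, preservation chemistry, extraction,
digestion, thermocycling — are out of scope: published medians such as
707 ng recovered DNA or 57–75% spike recoveries derive from physical
specimens and are mirrored here only as parameter-recovery tests on
synthetic data. The amplitude model is synthetic (see above). Proprietary
instrument exports are not parsed; the documented droplet CSV dialect is
the interchange format. Genome downloads for repeat-copy estimation are
the user's responsibility — `copies_per_genome()` operates on any FASTA
supplied to it.
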