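---
title: "Screening methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedscreen)
```

This vignette explains the screening model implemented by `sedscreen`, the
assumptions behind each line of evidence, the tunable parameters and their
defaults, what the synthetic-study generator does and does not emulate, and
the numerical and design choices made where the design was genuinely open.

## The screening problem

Bed sediment integrates hydrophobic organic contamination over time and acts
as a secondary source to the water column. A monitoring study produces a
site × chemical table of sediment concentrations (µg/kg dry weight) with
left-censoring at laboratory reporting limits, per-site total organic carbon
(TOC, %), a registry of per-chemical constants, compiled quality
benchmarks, and high-throughput bioactivity cutoffs. The screening question
is relative, not absolute: which chemicals, and which sites, show the
greatest *potential* for adverse biological effects? Every metric here is a
screening statistic, not a risk estimate.

## Lines of evidence

### Equilibrium-partitioning porewater estimation

Dissolved porewater concentration is estimated as
$C_{PW} = C_{SED} / (K_{OC} \cdot f_{OC})$, with $f_{OC}$ the organic-carbon
mass fraction (`toc_percent / 100`). The units work out to µg/L. The model
assumes single-phase partitioning into amorphous organic carbon at
equilibrium; no black-carbon sorption, salinity, temperature, or
dissolved-organic-carbon corrections are applied. Literature $K_{OC}$ values
can vary by an order of magnitude between sources, which propagates directly
into porewater-based metrics — a known limitation of the approach, accepted
because the downstream use is order-of-magnitude screening. Chemicals
without a $K_{OC}$ are carried with status `no_koc` and excluded from all
porewater-based metrics rather than imputed; sites without usable TOC get
`no_toc`. Values are carried at full floating precision and rounded only
for display.

### Toxicity quotients

A TQ is concentration / benchmark in matching units. Chemicals commonly
have several benchmarks per medium, spanning up to an order of magnitude;
the quotient against the *lowest* (most sensitive) benchmark is
TQ~Max~, which equals the maximum per-benchmark quotient. Benchmark value
ties are broken by first occurrence in file order, so the recorded
benchmark provenance is deterministic; the TQ value itself is unaffected.
Sediment and porewater screening are fully parallel pipelines distinguished
by a medium tag, and no summation ever mixes media.

Censored (below reporting limit) concentrations are stored as zero and kept
in the tables, so they contribute zero to every sum and can never be counted
as exceedances; this matches the zero-substitution convention of the
summations and biases mixture sums low by construction. A chemical with *no*
benchmark in a medium is absent from that medium's results — absence and
zero are deliberately distinct states throughout the package (a censored
value is data; a missing benchmark is not).

TQ~Class~ sums TQ~Max~ over the chemicals of one class and TQ~Sample~ over
all chemicals. Because the 14 classes partition the registry, TQ~Sample~
equals the sum of the class values exactly, and the test suite asserts this
identity to a floating tolerance of 1e-12.

### Exposure–activity ratios

EARs divide estimated porewater concentrations by activity concentrations
at cutoff (ACC) from high-throughput in vitro screening. ACC entries are
stored canonically in µg/L; micromolar entries are converted at load time
via the molecular weight (1 µM of a compound of MW $m$ g/mol is $m$ µg/L),
and micromolar entries without a molecular weight are dropped with a
warning. Assay rows carrying exclusion flags (data-quality problems, poor
dose–response curves) are retained in the table but never contribute to any
EAR; the tests verify that deleting them changes no output.

EAR~Max~ is the maximum over a chemical's endpoints within a sample;
EAR~Class~/EAR~Sample~ sum EAR~Max~ like the TQ aggregates. EAR~Endpoint~
sums the EARs of all chemicals acting on one endpoint in one sample,
assuming concentration addition — biologically the strongest additivity
assumption available here, since the chemicals act on the same measured
response. Endpoint mixtures are prioritized when EAR~Endpoint~ exceeds 0.1
(strict `>`) at at least `max(1, floor(0.2 * n_sites))` sites — 14 sites
for a 71-site study. The prevalence count uses `floor` so that the rule
reproduces the 14-of-71 convention; whether that convention was derived by
flooring or chosen by hand is not documented anywhere authoritative, so the
fraction is a parameter. Mixture membership uses a second rule: a chemical
belongs to an endpoint's mixture at a site when its EAR is at least 0.001
(10% of the 0.01 screening benchmark), and it is flagged a *major
contributor* when its EAR reaches 0.01 at the prevalence number of sites.
Membership and major-contributor comparisons use `>=` ("at least"), while
all retention/exceedance thresholds are strict `>` ("greater than") —
the comparison operators deliberately mirror that wording split.

Priority endpoints are annotated by a left join against a static
endpoint → gene → AOP mapping table; unmapped endpoints are kept with empty
annotation. Live pathway-database queries are out of scope: the map is an
input.

### Mixture scores

* **16-PAH quotients.** The summed concentration of the 16
  priority-pollutant PAHs (bulk sediment, *not* TOC-normalized) is divided
  by the consensus threshold effect concentration (TEC, 1610 µg/kg) and
  probable effect concentration (PEC, 22800 µg/kg). Categories: `likely`
  when PECQ > 1, `unlikely` when TECQ ≤ 1, `possible` in between. The
  boundaries are strict: a quotient of exactly 1.0 does not promote. The
  sums use zero-substituted (censored → 0) values like every other
  summation.
* **∑ESBTU.** Each 35-PAH-set member's TOC-normalized concentration in
  µg/g OC is `c_sed / (10 * toc_percent)` (µg/kg divided by 10 g OC per kg
  per TOC percent); divided by the chemical's final chronic value (FCV,
  µg/g OC) it gives a toxic unit, and the per-site sum over members flags
  narcosis potential above 1. A *detected* member without an FCV is a hard
  error naming the chemicals (silently dropping a detected member would
  bias the sum low invisibly); a censored member without an FCV contributes
  the zero it would contribute anyway. FCVs are registry data: the package
  ships no third-party FCV table, and the synthetic generator fills the
  column with lognormal values (median 800 µg/g OC, the right order for
  published PAH chronic values) that are labelled synthetic.
* **Alkylphenol TEQ.** Members of the detergent-metabolite class are summed
  as nonylphenol toxic equivalents, TEQ = Σ C~i~ · TEF~i~. The reference
  compound carries TEF 1.0 by definition; ethoxylates and structural
  analogues default to 0.5. All TEFs live in the registry so users can
  override them. The organic carbon-adjusted quotient is
  TQ~AP~ = TEQ / (1400 · TOC%), implemented literally with TOC in percent:
  the 1400 µg/kg freshwater interim guideline applies at 1% organic carbon,
  and keeping TOC in percent reproduces that convention without a hidden
  conversion.

### Chemical and site prioritization

Chemicals are prioritized by exceedance frequency and magnitude across the
three per-chemical metrics. The top rung (P1: sediment or porewater
TQ~Max~ > 10, or EAR~Max~ > 0.1, at more than 20% of sites) and the lowest
rung (0.1 / 0.001, separating `low` from `uncategorized`) are fixed by the
screening design; the intermediate rungs P2 (1.0 / 0.01) and P3
(0.1 / 0.001, at more than the prevalence fraction) interpolate
geometrically with ×10 spacing, consistent with the fixed endpoints. The
intermediate rungs are a design assumption of this package, exposed through
the configurable `priority_ladder()`. Undetected chemicals are `low`;
detected chemicals screenable by none of the three methods are
`no_benchmarks`; chemicals exceeding the lowest rung at between one site
and the prevalence fraction are `uncategorized`. The chemical-priority
prevalence comparison is strict (`> 20%` of sites), unlike the
endpoint-mixture rule's `>= 14` count — the two rules genuinely differ and
both are kept configurable.

Sites are scored by eight methods (sediment/porewater TQ~Max~ exceedance
counts, EAR~Max~ > 0.01 count, PAH mixture category, TQ~AP~, sediment and
porewater TQ~Sample~, EAR~Sample~), each binned into levels 4 (lowest
priority) through 1. Values outside the published bins are clamped
monotonically: TQ~Sample~ below 1 is level 4, above 10000 level 1, TQ~AP~
in (0, 0.01) level 3. The overall score is the arithmetic mean over
*available* methods, recording `n_methods_available`; a method whose inputs
are entirely absent (no bioactivity data at all, no usable TOC) is `NA`
rather than a fake zero, so a study without ACC data averages six methods
instead of eight. Ranking is deterministic: ascending score, ties broken by
descending sediment TQ~Sample~, then site id.

Watershed correlations use Spearman's rank correlation with tie-aware
midranks and an asymptotic two-sided p-value
(`stats::cor.test(..., method = "spearman", exact = FALSE)`), screened at
α = 0.05 on raw p-values. Screening studies conventionally report
uncorrected rank correlations; a Benjamini–Hochberg switch is provided
(`adjust_correlations = TRUE`) but off by default. Constant inputs yield a
flagged `NA` rather than an error.

## The synthetic-study generator

`generate_study()` exists so the entire pipeline can be exercised, with
known ground truth, without any external data. It emulates:

* a lognormal per-site contamination gradient (median 1, `sdlog` 0.25)
  with `n_hot = 3` planted hot sites at ×10, representing point-source
  contamination superimposed on an urbanization gradient;
* per-chemical lognormal concentrations (`sdlog` 1) around
  site intensity × chemical baseline;
* detectability increasing with hydrophobicity: chemical baselines scale as
  $10^{1.2\,(\log_{10} K_{OC} - \text{mid})}$ with baseline 3× the
  reporting limit at the central $K_{OC}$, over a log-uniform $K_{OC}$
  spanning 4 decades centred on 3710 L/kg. This reproduces the
  characteristic split of near-saturated detection above the median
  $K_{OC}$ versus sparse detection below it
  (`koc_detection_summary()` reports the two halves);
* left-censoring applied post-draw against each chemical's reporting limit,
  the way a laboratory reports "<RL";
* 1–7 benchmarks per chemical per medium with at most a 10× spread, for
  64% of chemicals per medium; porewater benchmarks are placed via a
  typical partitioning scale so both media screen on comparable quotients;
* ACC values log-normal in micromolar (log10 mean −1, sd 1.2 — the range
  typical of high-throughput screening, with potent actives well below
  1 µM), 1–8 endpoints per chemical drawn from a shared 40-endpoint pool
  (shared endpoints are what make additive endpoint mixtures possible),
  5% exclusion flags, and a gene vocabulary of nine common molecular
  targets feeding a sparse endpoint → gene → AOP map;
* TOC lognormal with median 2% clipped to (0.2, 10)%;
* watershed attributes (population density, percent impervious) with rank
  correlation 0.6 to the contamination gradient via a Gaussian copula;
* field duplicates at six sites with a 20% coefficient of variation, for
  exercising the duplicate-QC statistic.

One master seed drives fixed per-table substreams, so generation is
deterministic down to written CSV bytes and regenerating one table never
perturbs another.

Two calibration notes. First, the gradient spread (`intensity_sdlog`
0.25) is deliberately narrower than real tributary gradients, which span
two or more decades: the generator's design target is that the planted ×10
hot sites are cleanly separable from gradient noise, so that rank-recovery
diagnostics measure the pipeline rather than the overlap of two
distributions. Consequently, passing the recovery tests demonstrates that
the ranking machinery orders a planted signal correctly — it does *not*
demonstrate performance on real data where contamination gradients and
"hot" sites overlap. Second, the FCV scale (median 800 µg/g OC) was chosen
to be realistic for PAH chronic values and yields toxic-unit exceedance at
a plausible minority of sites.

What the generator does not emulate: spatial structure and
fate-and-transport (sites are exchangeable draws), correlated chemical
co-occurrence beyond the shared site intensity (real PAH profiles are
strongly inter-correlated), source signatures, measurement bias,
between-laboratory differences, and realistic assay-endpoint naming.

## Numerical choices and degenerate inputs

* All summations over censored values are exact zero contributions, not
  small constants; conservation identities (sample sum = class sum) are
  tested at 1e-12.
* Division guards: benchmarks, $K_{OC}$, $f_{OC}$, TOC, ACC, TEC/PEC and
  the guideline must be strictly positive; violations are errors, not NA.
* Degenerate states are encoded, not dropped: porewater `no_koc`/`no_toc`,
  toxic-unit `no_toc`, correlation `constant input`, and the distinction
  between a censored zero and an absent (unscreenable) result.
* The duplicate-QC statistic is undefined at (0, 0) and returns a flagged
  `NA` with a warning.
* An all-censored (zero-intensity) study propagates to zero for every
  metric and an overall score of exactly 4.0 at every site; the tests pin
  this path.

## Problem sizes in the test suite

The suite exercises the defaults the generator describes: single full-size
studies (71 sites × 87 chemicals) for the screening integration tests, 20
seeded replicates for planted-hot-site recovery, 50 replicates at
multiplier 1 for null calibration of the ranking, 100 random fixtures for
the conservation identities, 1000 random triples for the partitioning
algebra, and exhaustive brute-force comparison of the selection rules on
fixtures up to 6 sites × 5 chemicals × 5 endpoints. These sizes give each
statistical check enough replication to be meaningful while keeping the
default test run fast.

## Known limitations

* Single-phase $K_{OC}$ partitioning ignores black carbon, which can
  overestimate porewater concentrations of combustion-derived PAHs.
* All additive mixture scores assume concentration addition; antagonism and
  synergy are invisible to them.
* Zero-substitution biases every sum low; heavily censored chemicals are
  under-represented in class and sample sums by construction.
* EARs inherit the mammalian bias of high-throughput assay panels; the
  gene/AOP annotation join does not perform ortholog inference.
* The intermediate chemical-priority rungs (P2/P3) are a package design
  assumption, not an external standard, and are reported as such.
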