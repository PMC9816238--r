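---
title: "Degradation-induced SNV trajectories and TsD marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation-induced SNV trajectories and TsD marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvdrift)
```

## The problem

DNA in a deposited biological trace degrades chemically, chiefly by
hydrolysis: depurination destabilises the backbone (fragmentation,
coverage loss) and deamination converts cytosine to uracil, which
sequencing reads as thymine. On the reference strand this surfaces as an
excess of G>A and C>T substitutions — *artificial* SNVs that were not in
the donor's genome. Their abundance, and in particular the fraction of
reads carrying the artificial allele at a site, grows with storage time,
which makes them candidate clocks for the time since deposition (TsD) of
a trace.

`snvdrift` implements the read-count side of that analysis. The unit of
data is a (site, sample) observation: reference, alternative and
other-allele read counts at a biallelic SNV position, for one sample of a
study laid out as (biological matrix) × (storage condition) × (storage
time), with the day-0 sample of each series taken as the donor's true
genotype.

## PRV and genotype allocation

The core statistic is the percentage of reads of the variant allele,

$$\mathrm{PRV} = 100\cdot\frac{n_\text{alt}}{n_\text{ref}+n_\text{alt}+n_\text{other}},$$

whose denominator counts all detected alleles. Conceptually PRV = 0 maps
to genotype 0/0, PRV = 100 to 1/1, and intermediate values to 0/1. Applied
literally, that rule would let a single miscalled read flip a genotype, so
`allocate_genotype()` uses a band caller:

| parameter | default | meaning |
|---|---|---|
| `het_band_low` | 5 | PRV below this → 0/0 |
| `het_band_high` | 95 | PRV above this (and ref reads below the guard) → 1/1 |
| `min_alt_reads_for_het` | 2 | minimum alt reads to leave 0/0; symmetric guard on ref reads for 1/1 |
| `coverage_floor` | 1 | total reads below this → FAILED (i.e. exactly zero coverage fails) |

With the bands pushed to 0/100 and the guard at one read the caller
reduces to the literal rule (property-tested). A FAILED call is strictly
"no coverage", matching how failed genotype calls are counted in
degradation studies; raising `coverage_floor` is possible but off by
default. Units: bands are percentage points of PRV; the guard is a read
count.

## Trajectories

Within one (matrix, condition) series the ordered genotype calls of a site
form a trajectory, labelled by `classify_trajectory()`:
loss of coverage at any stored time point dominates (`FAILED_ONSET`,
tabulated separately from genotype changes); the exact three-step patterns
0/0→0/1→1/1 and 1/1→0/1→0/0 are the homozygote switches — the most extreme
storage effect; otherwise the (day-0, last) pair decides (`STABLE`,
`GAIN_HET`, `LOSS_HET`, `RESOLVE_TO_HOM`), and anything else (e.g. a
direct homozygote jump with no intermediate het observed) is `OTHER`.
Labels partition all sites with a usable day-0 call; sites FAILED at day 0
have no truth reference and are excluded with a reported count (a real
phenomenon in saliva day-0 samples, which can carry pre-damaged
extracellular DNA). The classifier is verified against an exhaustive
64-triple enumeration.

"Gradual" PRV drift — the property that makes a site a useful longer-term
TsD marker — is deliberately vague in the field's narrative
("ideally distributed PRVs over time"). We formalise it in
`monotone_config()` as tolerance-bounded monotonicity: PRVs must move in
one direction allowing `per_step_tolerance` (default 2 pp) of backsliding
per step, with a total excursion of at least `min_total_delta`
(default 20 pp). The 20 pp floor is our explicit proxy for the distinction
between the handful of "ideal" marker positions and the hundreds of
merely monotone ones; both knobs are configurable, and setting the
tolerance to zero with a vanishing delta recovers strict monotonicity
(property-tested).

## Marker selection

`apply_filters()` applies the stepwise gates in a fixed order, reporting
attrition at each: (1) spectrum — only G>A and C>T changes, the
deamination signature, are eligible; (2) day-0 genotype — homozygous in
every retained series (heterozygous sites can still be informative, so a
flag disables this); (3) read-count threshold — every observation of the
site in every sample must reach `min_total_reads` (default 10, inclusive).
The threshold is interpreted as minimum *total* depth per sample; the
narrative it derives from does not say whether total or variant-read depth
was meant, so `depth_mode = "alt"` provides the alternative reading.
`select_candidates()` then keeps sites whose trajectory is gradual with
the *same direction* in every required series (direction concordance, not
magnitude concordance: PRV magnitudes legitimately differ between
conditions). Filters are conservative (survivors ⊆ input, attrition counts
conserve) and relaxing the read threshold can only grow the surviving set;
both are tested as properties.

## Statistics

`prv_rank_test()`, `prv_anova()` and `counts_chisq()` expose the study's
comparisons (Mann–Whitney U between storage times, one-way ANOVA of PRV
across time points, Pearson χ² on spanning-deletion proportions) as thin,
validated wrappers over the standard R routines — the contract is the
formula, and the unit tests pin hand-computed fixtures (exact one-sided
p = 1/20 on complete separation of two triples; F = 27 on the 3×3
fixture; χ² = 40 on a diagonal 2×2). ANOVA is pooled across candidate
sites per (series, time point) — the per-position alternative is not
reported because three observations per site carry no power. All p-values
are unadjusted, as is conventional in these descriptive screens; callers
wanting FDR control can apply `stats::p.adjust` to the summary table.

## The simulator

`simulate_truth()` + `simulate_counts()` generate read counts with the
statistical structure the analysis assumes. Damage acts on the per-read
conversion probability, not on the genotype state: at a
deamination-eligible site with true alt-allele fraction $g \in \{0, \tfrac12, 1\}$,

$$f(t) = g + (1-g)\,d(t), \qquad d(t) = 1 - e^{-\lambda m t},$$

with $\lambda$ the per-day site conversion rate and $m$ the humid
multiplier. This is what produces *partial* PRV drift rather than clean
genotype jumps — the observed behaviour that motivates PRV-based markers
in the first place. Sequencing error mixes alleles symmetrically at rate
$e$ per read; depth is Poisson with exponentially decaying mean; and an
independent per-site dropout process (probability $1-e^{-\lambda_f m t}$
of total coverage loss, the fragmentation / flanking-damage mechanism)
generates failed calls. Modelling coverage loss as mean decay alone cannot
do both jobs at once: a mean low enough to yield zero-depth draws at 30×
would push a large fraction of observations under the 10-read marker
threshold, so gradual decay and outright dropout are separate processes
with separate rates.

Site roles and defaults:

| parameter | default | rationale |
|---|---|---|
| `deam_rate` | 0.005/day | background damage-prone sites: d(92) ≈ 37 %, a clear but partial drift |
| `marker_rate` | 0.01/day | planted markers: d(22) ≈ 20 %, d(92) ≈ 60 % — the exemplar gradual profile |
| `switch_rate` | 0.06/day | planted switches: d(92) ≈ 99.6 %, traverses 0/0→0/1→1/1 at depth 30 |
| `cov_decay_rate` | 0.002/day | ~17 % mean-coverage loss by day 92 |
| `dropout_rate` | 5e-5/day | ~0.5 % failed calls at day 92 (dry) |
| `humid_multiplier` | 1.5 | all rates scaled under humid storage |
| `seq_error_rate` | 0.001/read | high-quality short-read error scale |
| `spandel_rate` | 0.003/day | spanning-deletion evidence accumulation |

The default design plants 85 % null sites (uniform base composition,
population genotype frequencies 0.70 / 0.20 / 0.10), 12 % damage-prone,
2 % markers and 1 % switches over 10 000 sites at 30× with samples at 0,
22 and 92 days in blood and saliva, dry and humid — the follow-up layout
of the storage study this package targets. No quantitative damage rates
are available for such traces; these values were fixed once to reproduce
the qualitative directions of effect (a majority of type 2 transitions
among changes, failed-call growth over time, humid > dry) and are clearly
artifact choices, not measurements. Planted roles are always C>T/G>A
sites with 0/0 truth genotype; spanning-deletion records (1 % of sites)
are carved from the null quota. An optional `saliva_prestore_days` offset
(default 0) models saliva day-0 samples as already slightly degraded.

Randomness discipline: one master seed; each (sample, draw-stage) pair
derives its own substream seed, and draws are generated in site order, so
enlarging the site panel appends new draws without perturbing existing
sites' data.

`estimate_deam_rate()` inverts the mean-PRV curve of damage-prone 0/0
sites ($\hat\lambda = -\log(1-\overline{\mathrm{PRV}}(t)/100)/t$, averaged
over stored time points); it recovers rates across 0.002–0.01/day within
a few percent at 5 000 sites and serves as a parameter-recovery oracle for
the whole simulation chain.

### What the simulator does and does not emulate

It reproduces: per-read deamination with time and condition dependence,
coverage decay and zero-coverage failed calls, sequencing-error
background, spanning-deletion accumulation, planted markers shared across
matrices and conditions. It does **not** model read-level artefacts
(position-within-read damage profiles, mapping bias, contamination,
microbial reads aligning to the human reference), joint-calling artefacts
of a real variant-calling pipeline, or linkage between sites. Passing
tests on simulated data therefore demonstrate that the *analysis* is
correct and sensitive under the assumed generative process — not that
real traces obey that process quantitatively.

## Numerical and design choices

* Zero-coverage observations are stored explicitly as (0,0,0) rows, so
  failed-call counting never re-reads the source VCF. Multi-allelic VCF
  records are decomposed per alternative allele with sibling-alt depth in
  `other_reads`; symbolic alleles other than `*` are skipped and counted.
* `other_reads` counts toward the PRV denominator, never the numerator.
* Changed-site detection defaults to genotype-call changes. An optional
  PRV-drift tolerance exists, but is off by default because read-sampling
  noise at heterozygous sites (±9 pp at 30×) would otherwise register
  undamaged sites as changed and break the package's no-damage identity
  (all rates zero ⇒ zero changed sites, zero candidates — a tested
  invariant).
* Spectrum counting does not fold strands; `fold_strands = TRUE` provides
  the aggregated "or vice versa" grouping.
* All report writers are deterministic (fixed column orders, genomic sort,
  LF endings); rerunning a pipeline on the same input yields byte-identical
  bundles, which is tested.
* Test and acceptance problem sizes: unit tests run at 10²–10³ sites;
  the spectrum-majority check uses 100 000 sites, marker recovery the
  default 10 000-site design, rate recovery 5 000 sites per rate, and the
  failure-direction checks 50 000 sites — sizes at which the binomial
  noise of the checked proportions is negligible while a full suite run
  stays under a minute.

## Limitations

* The band caller is a deterministic substitute for likelihood-based
  genotyping; it has no genotype qualities and assumes diploidy.
* Day-0 truth is axiomatic: genuine somatic variation or day-0 damage is
  indistinguishable from storage change by construction.
* The gradual-drift definition (20 pp excursion, 2 pp tolerance) is a
  formalisation choice; different settings change which sites are called
  "ideal" markers, though not the direction of any result.
* No TsD *prediction* is attempted — marker nomination stops where a
  calibrated regression on an independent donor panel would have to begin.
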