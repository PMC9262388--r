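---
title: "Pooled strain frequencies and starvation-resistance traits from MIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled strain frequencies and starvation-resistance traits from MIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipmeter)
```

## The measurement problem

A pooled competition assay mixes many genotyped strains into one culture,
applies selection (here, starvation during *C. elegans* L1 arrest), and reads
out each strain's relative frequency over time by sequencing. Frequency is
measured at single-nucleotide resolution: for each strain, a molecular
inversion probe (MIP) captures a genomic window containing a single-nucleotide
variant (SNV) that is homozygous-alternative in that strain alone. The
fraction of alternative reads at that site is then an estimate of the strain's
frequency in the pool. mipmeter implements this measurement chain end to end:
panel design, allele counting, probe quality control, frequency estimation,
trait derivation, and the supporting validation statistics, together with a
simulator that generates pooled experiments with recorded ground truth.

## Probe model

A probe is an 80-nt single-stranded oligo. Two 20-nt arms (extension and
ligation) hybridize to the reference strand flanking a 100-nt capture window
(the *scan* sequence); gap-fill and ligation circularize the molecule, and the
captured gap is sequenced. Between the arms sit a fixed 30-nt backbone
carrying the amplification landing sites and a 10-nt unique molecular
identifier (UMI). The assembled oligo is reported 5'→3' as
extension arm + backbone + UMI (as `N`s) + ligation arm; the component order
and the backbone sequence are configuration, since different probe chemistries
order their parts differently.

Reads are 50-nt single-end. The package assumes a documented read
architecture: UMI (10 nt), then the 20-nt ligation-arm target site on the
reference strand (the *assignment key*), then the scan sequence. The window
placement search slides the capture window left-to-right over every placement
that keeps the SNV within the first `read_length - umi_length` = 40 bases
after the UMI and accepts the first placement whose arms fit inside the contig
with no ambiguous bases. Sites that admit no such placement are rejected with
a machine-readable reason (`offset`, `contig_end`, `ambiguous_base`,
`ref_mismatch`), and rejection is an ordinary value, not an error, so panel
construction degrades gracefully strain by strain.

Candidate ranking within a strain is deliberately simple and deterministic:
arm GC content closest to 50%, ties broken by genomic coordinate. Published
panels used an external designer with a trained scoring model; a reimplementation
of that model is out of scope here, and the GC heuristic gives reproducible
panels with a sensible thermodynamic preference.

Unique-SNV selection is conservative: a site is usable only if exactly one
panel strain is homozygous-alternative, all others are homozygous-reference,
and no panel genotype is missing or heterozygous. Excluding partially
genotyped sites costs candidates but guarantees the downstream frequency
interpretation — every alternative read at a kept site is evidence for exactly
one strain. A consequence worth knowing: a strain nearly identical to the
reference genome (such as the laboratory strain the reference was built from)
has almost no unique SNVs and may legitimately receive fewer probes or none.

## Allele counting

Reads are assigned to probes by exact match of the 20-nt assignment key at the
post-UMI position. Exact matching is the default (a Hamming-distance-tolerant
mode is not provided because the match target is short and unique); mismatched
reads are counted as unassigned, never errors. The allele class is the single
base at the probe's SNV slot: reference, alternative, or one of the two
remaining nucleotides, which map to `OTHER_A`/`OTHER_B` in lexicographic
order. "Other" reads are sequencing or synthesis artifacts and are tracked
because their abundance is one of the probe QC criteria.

Two match tiers are reported per sample: the fraction of reads matching the
key, and the fraction also matching the captured scan sequence (with any base
tolerated at the SNV slot). Counting supports UMI deduplication —
reads sharing (probe, UMI, allele) collapse to one — but it defaults off: with
high-mass DNA input, deduplication discards real molecules faster than it
removes PCR duplicates, and the published analysis left the UMI unused. Base
qualities are ignored and reads are used untrimmed.

## Probe QC and frequency estimation

Against an equimolar pilot (all strains mixed at equal mass), every probe
should report a frequency near `1/S`. Probes are filtered with three criteria:

* **band** — observed frequency within 3.5-fold of `1/S`, boundaries
  inclusive (the band is closed; inclusivity is a documented choice since
  "within" does not state it);
* **other** — combined other-allele reads below 20,000;
* **total** — reference + alternative reads between 20,000 and 2,000,000.

The count thresholds are tied to the sequencing depth at which they were
published (~1.25e5 reads per probe); `depth_scale` rescales all three
proportionally for shallower runs, including simulated ones. All violated
criteria are reported, not just the first. Probes can be exempted (they pass
regardless but stay flagged), mirroring the reference-derived strain whose
probes were retained despite failing.

A strain's frequency in a sample is the unweighted mean of its passing
probes' `n_alt / (n_alt + n_ref)` values. Unweighted, because the source
method averages frequencies across probes; a depth-weighted mean is a
plausible alternative but changes the estimator, so it is not silently
substituted. Strains with no usable probe are omitted and reported as
dropouts, never imputed.

Standard curves (strains mixed at known proportions spanning orders of
magnitude) are evaluated by regressing `log10(observed)` on
`log10(expected)`; zero observations are floored at half the smallest nonzero
observed frequency, with a warning, before logging.

## Traits

Frequencies are normalized per replicate to a baseline aliquot taken on day 1
of starvation: `y = log2(f(day) / f(baseline))`. Baseline normalization is
what turns a pool of uneven composition into comparable trajectories; without
it, the leading component of variation is simply who got loaded into each
replicate. Zero baselines and zero day-frequencies are masked with recorded
reasons rather than propagated as infinities.

**Slope** is the zero-intercept least-squares slope of the replicate-averaged
trajectory over days 1, 9 and 13: `slope = sum(t * ybar(t)) / sum(t^2)`,
in log2 units per day. The zero intercept encodes the model that a
baseline-normalized trajectory starts at zero at the start of starvation —
an approximation, since day-1 samples go through recovery while the baseline
does not. Replicates are averaged before fitting (the per-replicate
fit-then-average mode is available behind a flag for sensitivity analysis).
Day 17 is excluded from Slope: late in starvation, mass mortality bottlenecks
the recovery cultures and frequency differences compress, which a straight
line mishandles.

**PC1** is each strain's score on the first principal component of the
strain × day matrix of replicate-averaged trajectories across days 1, 9, 13
and 17. Columns are mean-centered without variance scaling (all columns are
on the same log2 scale, so scaling is not needed; both toggles exist). The
component's sign is arbitrary from the decomposition and is fixed by positive
correlation with Slope, so resistant strains score consistently positive.
Strains with any missing fitted day are dropped from the PCA (complete-case)
but keep their Slope if at least two days exist. Replicate-level scores
(samples × strains) are returned as diagnostics; their first component should
track duration of starvation if the normalization worked.

## Supporting statistics

*Enrichment.* Categories (e.g. protein domains) among candidate genes are
tested with the hypergeometric upper tail, counting each gene at most once per
category (the alternative — counting domain instances — inflates genes that
carry a domain repeatedly). The Bonferroni divisor is the number of categories
observed in the hit set, not the genome-wide count; with 102 categories at
alpha 0.05 the threshold is 0.00049 at reporting precision (two significant
figures; full precision is kept internally). Categories occurring fewer than
five times among hit genes are flagged and excluded from significance calls.

*Hyper-divergence.* A strain is hyper-divergent at a locus if any of its
hyper-divergent regions overlaps the locus by at least one base; intervals are
0-based half-open, so touching intervals do not overlap. Group comparisons of
trait values use Welch's t-test (the unequal-variance form is the safer
default when only "t-test" is specified).

*Survival.* Starvation survival curves are fitted by nonlinear least squares
to `p(t) = A / (1 + exp(rate * (t - t50)))` with the asymptote fixed at 1 by
default (survival starts near 100%; a free-asymptote mode exists for degraded
day-1 viability). The half-life `t50` always comes from the fitted curve, not
raw interpolation; series that never cross 0.5 are fitted anyway and flagged
as extrapolated so replicate t-tests keep a value. Half-life comparisons are
Welch t-tests over replicate fits. The detectable-effect calculation inverts
the two-sided two-sample noncentral-t power relation numerically for the
standardized effect `d` and scales by the control SD; at n = 5, alpha = 0.05,
power = 0.5 this gives d ≈ 1.41.

*Interaction effect size.* The difference-in-differences of mean worm length,
`[mean(A, late) - mean(A, early)] - [mean(B, late) - mean(B, early)]`, is
positive when strain A (listed first) is less affected by extended starvation.
P-values for the corresponding interaction belong to mixed-effects tooling and
are intentionally out of scope.

## The simulator

The simulator generates the full data-generating process so that every
downstream stage can be tested against recorded truth:

* **Baseline composition** per replicate is Dirichlet around equal
  proportions; the concentration parameter (default 200, ~7% CV) emulates
  loading variation across replicates.
* **Selection**: strain weight at day `t` is
  `baseline * S(t)^phi(t) * exp(recovery_gain * (t - baseline_day))`, with
  `S(t)` the same logistic survival form the fitting code uses (default
  half-lives graded 8–16 days, rate 0.5/day — order-of-magnitude choices
  matching wild-strain L1 survival; no quantitative mortality table exists to
  calibrate against). The optional saturation exponent
  `phi = Sbar / (Sbar + sat * (1 - Sbar))` models recovery cultures growing to
  saturation from few survivors: as mean survival collapses, the effective
  resolution of strain differences scales with the surviving fraction, which
  reproduces the late-day compression of frequency differences. Survival and
  recovery knobs are per-strain so tests can decouple mortality from
  fecundity effects.
* **Capture**: per-probe depth is Poisson around 1e4 reads per probe (a
  desk-scale default; a flag emulates published depth of ~1.25e5), and each
  probe carries a mean-one log-normal capture bias (log-SD 0.25) that distorts
  its alternative-read fraction. Mean-one bias keeps the strain estimator
  unbiased by construction while giving the 3.5-fold QC band real work to do.
* **Error**: substitution error at the SNV slot reallocates reads uniformly
  to the three other nucleotides (default 1e-3), populating the "other"
  classes.
* **Determinism**: all randomness flows from one integer seed (sub-stages use
  small fixed offsets of it); FASTQ emission materializes the same count draws
  it would report directly, so counts mode and FASTQ mode piped back through
  the counter agree exactly.

What the simulator does *not* model: PCR duplicate structure beyond UMI
multiplicity, arm-site polymorphisms that break capture in specific strains,
index hopping, batch effects between libraries, and any real worm physiology
(density dependence, feeding dynamics during recovery). Passing
parameter-recovery tests therefore shows the estimators are correct for this
generative model, not that real experiments are free of those artifacts.

## Numerical and scale choices

Simulated problem sizes in the test suite are chosen so the whole suite runs
in a couple of minutes: panels of tens of strains at ~1e4 reads per probe for
property tests, the full 103 × 4 geometry where panel arithmetic itself is
under test, 200-replicate loops for unbiasedness and half-life recovery.
Coordinates are 1-based in VCF I/O and 0-based half-open internally, with
conversion only at boundaries. Ties in probe ranking break by genomic
coordinate; window search order is left-to-right; both make panel design a
pure function of its inputs.

```{r example, eval = FALSE}
cfg <- sim_config(n_strains = 30, replicates = 5, seed = 1)
panel <- sim_reference_panel(cfg)$panel
sim <- simulate_reads(simulate_trajectories(cfg), panel)
freqs <- strain_frequencies(sim$counts, NULL, panel)
traj <- normalize_to_baseline(freqs, sim$sample_map)
trait_table(slope_trait(traj), pc1_trait(traj))
```

## Known limitations

* Probe scoring is a GC heuristic, not a trained capture-efficiency model;
  real panels should expect more probe dropout at QC than simulated ones.
* Exact key matching discards reads with any arm-site sequencing error
  (~1 - (1 - e)^20 of reads at per-base error e), which lowers yield but not
  accuracy.
* The zero-intercept Slope inherits the linearity assumption it is defined
  by; strongly non-monotone trajectories are better captured by PC1.
* Frequencies are estimated per strain independently, so a sample's
  estimated frequencies need not sum exactly to one; downstream log-ratio
  normalization is insensitive to this.
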