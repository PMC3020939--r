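---
title: "Benchmarking CNV callers: matching criteria, stratified recovery, and validation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking CNV callers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvbench)
```

## The problem

Software that calls copy-number variants (CNVs) from SNP-array intensity
data — HMM-based callers and segmentation-based callers alike — disagrees
substantially, both with independent gold standards (fosmid paired-end
sequencing, high-density aCGH) and with each other. Before CNV calls are
used in an association study, three questions need quantitative answers:

1. **Recovery**: what fraction of independently validated CNVs does a
   caller find, and how does that depend on probe support and on the CNV's
   population frequency?
2. **Agreement**: how concordant are callers (or two gold standards) with
   each other, and how many calls are program-specific singletons?
3. **Validity**: when calls are checked against qPCR-measured copy
   numbers, what are the positive predictive value and the false
   positive/negative rates — and are "common CNV" calls confounded by
   genotyping plate?

cnvbench implements this evaluation framework as reusable, tested
components, together with a synthetic-data generator so the whole pipeline
runs and can be validated without any external data.

## The matching statistic

All comparisons rest on one statistic. For two intervals $a, b$ on the same
chromosome, the *combined-span overlap fraction* is

$$ f(a,b) \;=\; \frac{|a \cap b|}{|a \cup b|}, $$

the number of base pairs shared divided by the number of base pairs the two
intervals span together. It is symmetric, lies in $[0,1]$, and is 0 for
intervals on different chromosomes. Two CNVs are considered the same event
when $f \ge 0.25$ (truth-set recovery, cross-study concordance) or
$f \ge 0.5$ (matching different callers' versions of a common CNV, where a
single qPCR probe must represent all of them). The union (not a bounding
box) is the denominator; for disjoint intervals the fraction is 0 either
way, so the distinction only matters for overlapping pairs, where the union
is the natural "length spanned together".

A reference CNV is **recovered** when at least one call in the same sample
with copy number $\ne 2$ passes the threshold. The *state-consistency*
refinement additionally requires the call's direction to agree with the
reference: copy number 0 or 1 must correspond to a reference deletion,
copy number $> 2$ to a duplication. Since deletions called as duplications
(and vice versa) are not rare, overlap-only recovery overstates
performance; the package computes both, and the state-consistent rate can
only be lower (a tested invariant). Matching is many-to-many: one call may
recover several references and several calls may recover one reference —
no assignment step is performed.

Coordinates are 0-based half-open internally, so lengths are simple
differences and adjacent intervals share nothing. All text I/O is 1-based
inclusive (the style used in genome browsers and publications) unless the
BED dialect is requested explicitly; the convention is never auto-detected,
because silent off-by-one shifts are the dominant failure mode in CNV
comparison.

## Stratified recovery

Recovery is reported per probe-count bin (1, 2–5, 6–10, 11–20, > 20
markers; the conventional printed "10–20" stratum is implemented as 11–20
so the bins partition the integers) and per frequency bin
((0, 0.2], (0.2, 0.4], ..., (0.8, 1] carrier frequency). References that
span zero probes of the manifest are excluded and counted separately — an
array-based caller cannot see them, and binning them as "1 probe" would
bias the lowest stratum.

Region frequency comes from `merge_into_regions()`: single-linkage
clustering of per-sample reference CNVs that share at least 1 bp on the
same chromosome. The region interval is the union span of its members and
the frequency is distinct carriers over cohort size. How per-sample events
were grouped into "regions" is genuinely underdetermined in published
practice, so the clustering rule is an argument: `"any_overlap"` (default)
or `"fraction"` (single linkage on $f \ge$ threshold). Per-region
sensitivity (recovered members / members) and the shares of regions above
0.9 and at or below 0.1 summarise the characteristic bimodality of caller
performance on common CNVs.

## Concordance, singletons, size profiles

`cross_dataset_consistency()` restricts two call sets to their common
samples and tabulates, per size bin and in both directions, how many CNVs
in one set are matched ($f \ge 0.25$) by the other. State consistency is
deliberately not required here. Because matching is many-to-many, the two
directions need not give equal counts.

A **singleton** is a deletion or duplication that occurs exactly once in
the whole cohort and overlaps no other call made by the same caller — by
default a call of *either* class disqualifies (the strictest reading of
"did not overlap with any other CNVs"); `scope = "same_class"` relaxes
this. Across callers, a singleton is **shared** when it overlaps a
singleton of the same class from any other caller by at least one base
pair, else **program-specific**. The any-bp rule here and the 25% rule
elsewhere are deliberately distinct constants: sharing between programs is
about corroboration at a locus, not about breakpoint agreement.

## qPCR validation

Relative quantification uses the delta-delta-Ct model. With $C_t$ the
threshold cycle, $\Delta C_t = C_t^{target} - C_t^{control}$ within a
sample, and $\Delta\Delta C_t$ the difference between a test sample and a
2-copy calibrator, the target quantity relative to the calibrator is
$2^{-\Delta\Delta C_t}$ and the copy-number estimate is
$2 \cdot 2^{-\Delta\Delta C_t}$. Replicate wells are averaged on the Ct
scale before differencing. Estimates are classified with strict
thresholds, deletion below 1.5 and duplication above 2.5 copies; published
work rarely prints its class boundaries, so these are arguments with
midpoint defaults, applied exactly once.

Against qPCR truth, the package reports PPV $= TP/(TP+FP)$, the
false-positive rate $FP/(FP+TN)$ over qPCR-normal samples and the
false-negative rate $FN/(FN+TP)$ over qPCR-variant samples — the standard
confusion-matrix definitions. (Some reports invert the phrasing and call
$1-$FPR "sensitivity"; cnvbench keeps the standard definitions and reports
the rates themselves as primary.) By default carrier status is compared
ignoring direction; `require_state = TRUE` counts a wrong-direction call
on a variant sample as a miss.

## Plate-effect scan

Common-CNV calls are vulnerable to batch artifacts: a genotyping plate
whose carrier frequency differs systematically from the rest of the cohort.
For every region and every plate, `plate_effect_scan()` forms the 2×2 table
carriers/non-carriers × on-plate/off-plate and computes an exact
hypergeometric p-value; a region is flagged when its smallest per-plate
p-value falls below $\alpha$ (default $0.05/\#plates$, Bonferroni within
region, exposed as an argument).

The default p-value is the **mid-p** variant (the probability-based
two-sided tail minus half the probability of the observed table). The
conventional Fisher p-value is available via `method = "fisher"`, but on
discrete 2×2 tables it is conservative — at 48-sample plates its per-test
rejection rate at nominal $\alpha = 0.05$ falls visibly below 5% — while
the mid-p test holds the nominal level closely, which is what a calibrated
scan should do. This choice is a property of the test, verified by the
null-calibration simulation in the test suite.

## The synthetic-data generator

`simulate_truth()` builds the study conditions every test runs under:

* non-overlapping truth regions placed uniformly, log-uniform sizes
  between 2 kb and 500 kb by default;
* a probe manifest at 0.6 probes/kb (SNP-array-like density);
* a frequency spectrum with a configurable singleton fraction (default
  0.6, reflecting the singleton-dominated spectra of sequencing-based
  truth sets) and Beta(0.4, 0.8)-distributed carrier frequencies for
  polymorphic regions, giving both rare and very common regions;
* deletion/duplication states, optionally frequency-dependent
  (`p_deletion` may be a function of frequency, e.g. `function(f) 1 - f`
  to make common regions predominantly duplications, as observed
  empirically);
* 48-sample plates.

`caller_profile()`/`simulate_caller()` encode how real callers fail:
per-probe-bin detection probabilities (detection rises with marker count),
Gaussian breakpoint jitter, deletion↔duplication confusion, Poisson false
calls at non-truth loci, log-normal LOD scores, a duplication sensitivity
penalty (a duplication is a 1.5-fold intensity change versus 2-fold for a
deletion), and an optional plate-restricted artifact that adds calls for
one region on one plate. `simulate_qpcr()` inverts the delta-delta-Ct
relation with Gaussian cycle noise; copy number 0 has no finite Ct and is
floored at 0.25 copies with a flag.

What the generator does **not** emulate: probe-level intensities and
log2-ratios, nested or overlapping truth regions (non-overlap keeps region
frequency well-defined for testing), linkage between CNVs, and
chemistry-level qPCR effects. Passing tests therefore demonstrate that the
evaluation machinery measures what it claims on data with the assumed
structure — not that any particular caller performs well on real arrays.

## Numerical and design choices

* Breakpoint jitter can invert or collapse an interval; jittered ends are
  re-ordered, clipped to the chromosome, and calls that collapse below
  1 bp are dropped and count as misses.
* All simulators take an explicit seed and restore the RNG state
  afterwards; a fixed seed gives byte-identical outputs.
* Calls lacking a LOD score pass LOD filters by default (segmentation
  callers emit none); `strict = TRUE` inverts this.
* Empty recovery bins report `NA` rates rather than 0.
* Matching thresholds outside (0, 1] and inverted classification
  thresholds are rejected, not clamped.
* Chromosome labels are only ever normalised by adding/stripping a `chr`
  prefix, on request.

## Problem sizes used in the shipped checks

The package's own verification uses cohorts of 40–200 samples with 40–300
truth regions on two 20–80 Mb chromosomes (several thousand per-carrier
reference events), 100-seed replicate studies for caller-ranking
stability, 1,500 per-plate tests for null calibration of the plate scan,
and a 2,000-sample cohort with one 48-sample plate doubled from 40% to 80%
carrier frequency for the power check. These sizes give the binomial
standard errors the assertions rely on while keeping a full run fast on a
laptop.

## A worked example

```{r example}
cfg <- sim_config(n_samples = 96, n_regions = 80, frac_singleton = 0.5)
sim <- simulate_truth(cfg, seed = 42)
prof <- caller_profile("hmm_like", sensitivity = c(0.05, 0.3, 0.5, 0.6, 0.9))
calls <- filter_by_lod(simulate_caller(sim, prof, seed = 43), min_lod = 5)

m <- match_reference(sim$truth, calls, threshold = 0.25, require_state = TRUE)
recovery_by_probe_bin(m, sim$truth, sim$probes)

mr <- merge_into_regions(sim$truth, cfg$n_samples)
recovery_by_frequency_bin(m, mr$regions, mr$membership)
```

## Limitations

Recovery against a truth set is only as good as the truth set: two
published gold standards for the same eight HapMap individuals agree
poorly with each other, so absolute recovery rates should be read as
properties of the (caller, truth set) pair. The qPCR module assumes ideal
amplification efficiency (the exact $2^{-\Delta\Delta C_t}$ law); the
plate scan tests marginal per-plate frequency shifts and will not detect
artifacts that are balanced across plates.
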