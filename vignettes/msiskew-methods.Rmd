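---
title: "Calling microsatellite instability from read-length skewness: methods and design"
author: "msiskew"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling microsatellite instability from read-length skewness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiskew)
```

## The problem

Microsatellites are tracts of a tandemly repeated 1-6 bp motif. In tumors
with defective mismatch repair, replication slippage at these tracts goes
uncorrected and tract lengths drift genome-wide -- the microsatellite
instability (MSI-H) phenotype, which matters clinically for prognosis and
immunotherapy eligibility. Most sequencing-based MSI callers need either a
matched normal sample or a pre-built baseline of stable samples.
`msiskew` needs neither: it classifies a single tumor sample from the
*shape* of its per-marker read-length distributions alone.

The premise is that a microsatellite in a stable (MSS) sample produces a
tight, roughly symmetric distribution of observed tract lengths centered on
the reference length (PCR stutter scatters a few reads one repeat unit
either way), whereas an unstable locus in an impure tumor is a mixture of a
reference-length component (normal cells plus the unmutated allele) and a
contracted component (the mutant allele), which is *asymmetric* -- and
asymmetry can be measured without any reference cohort.

## The statistic and the decision rules

For each marker the observed tract length of every spanning read is
normalized against the reference tract length (delta = observed - reference,
so a reference-length read scores 0). The per-marker statistic is Pearson's
(second) skewness coefficient of the delta multiset:

$$\mathrm{PSC} = \frac{3\,(\bar{x} - \tilde{x})}{s},$$

with $\bar{x}$ the mean, $\tilde{x}$ the median and $s$ the sample
(n-1 denominator) standard deviation. Since
$|\bar{x} - \tilde{x}| \le s$, PSC always lies in $[-3, 3]$. It is
location-invariant, so scoring deltas or raw lengths is equivalent, and
scale-invariant up to sign.

Decision rules, in pipeline order:

* **Coverage filter.** A marker is *valid* only when strictly more than 20
  spanning reads cover it (markers at $\le 20\times$ are filtered out
  entirely). Low-coverage markers underrepresent alleles and shrink |PSC|,
  so they are removed rather than scored.
* **Marker instability.** A valid marker is *unstable* when
  $|\mathrm{PSC}| > 1$, strictly. A zero-variance distribution is defined
  to score 0 (it is the most stable possible observation).
* **Sample status.** The unstable fraction is the number of unstable
  markers divided by the number of *valid* markers -- filtered markers do
  not appear in either numerator or denominator. The sample is MSI-H when
  the fraction reaches the tissue-type cutoff (inclusive): 0.4 for fresh
  tissue and cell lines, 0.25 for FFPE tissue, where artifact noise and
  coverage dropout depress the observed fraction. These cutoffs were set
  empirically on colorectal cancer cohorts; both are plain parameters
  (`cutoff`, `coverage_min`, `psc_threshold`) and never hard-coded. A
  sample in which *no* marker passes the coverage filter is reported
  `indeterminate`, never silently MSS.

## Tract-length extraction

`tractLength()` measures what a read says about a marker in one walk over
the CIGAR, trusting the upstream aligner (no realignment):

* **Spanning requirement.** The read's aligned reference span must cover
  the marker plus `flank` (default 5) anchor bases on each side, with
  aligned (`M/=/X`) or deleted (`D`) bases only; a reference skip (`N`)
  inside the window, or an alignment boundary (including clipped tails)
  inside it, disqualifies the read. Indels at tract edges are only
  interpretable when flanking sequence is anchored.
* **Counting convention.** Tract length = reference length + query bases
  inserted at reference breakpoints *strictly inside* the marker interval
  - reference bases deleted within the closed-open marker interval.
  Insertions exactly at the marker start or end are attributed to the
  flank. The ambiguity at boundaries is real; fixing it one deterministic,
  documented way matters more than which way.
* **Read hygiene.** Unmapped, secondary, supplementary, duplicate and
  QC-fail reads are excluded, as are reads under mapping quality 20
  (defaults; the choices are conventional short-read hygiene). Each read
  contributes at most one delta per marker.

Coordinates are BED-convention 0-based half-open in panel files and in the
`tractLength()` interface; the `GRanges` inside a `MarkerPanel` is the
usual Bioconductor 1-based inclusive representation.

## The cohort simulator

`simulateCohort()` exists so the entire pipeline -- extraction, scoring,
classification, evaluation -- is testable end to end with recorded ground
truth and no external data. Per marker and sample:

* **Coverage** is negative binomial with mean `coverage_mean` (default
  100) and dispersion 0.02 (fresh/cell line) or 0.2 (FFPE), so FFPE
  cohorts show much wider coverage variation. With probability
  `dropout_rate` (FFPE default 0.15) a marker's coverage is resampled
  uniformly on [0, 25], deliberately straddling the 20x filter.
* **Stable law.** A read scores delta 0, except with probability
  `stutter_rate` (default 0.05) it slips one full repeat unit up or down
  with equal probability -- tight and symmetric, hence |PSC| stays small.
* **Unstable law.** In an MSI-H sample, `round(0.6 * panel size)` randomly
  chosen markers carry a contracted allele at
  `-shift_units * nchar(repeat_unit)` bp (default 3 units). Each read
  comes from the contracted allele with probability `tumor_fraction` and
  from the stable law otherwise; both components carry their own stutter.
  Deltas are floored at minus the reference tract length (a tract cannot
  have negative length).
* **FFPE artifact noise** adds an extra independent +/-1 bp to each read
  with probability `ffpe_noise_rate` (default 0.05), emulating
  fixation-induced length noise.

**Why `tumor_fraction` defaults to 0.35.** The default models a
heterozygous tract contraction at realistic tumor purity (about 70% tumor
cells, one contracted allele of two, gives a contracted-read fraction near
0.35). The value 0.5 is a singular point of this mixture: the distribution
becomes an evenly balanced bimodal -- i.e. *symmetric* -- and a skewness
statistic is blind exactly there. One can see it in closed form: with
modes at 0 and $-s$ and the median landing on a stutter read at $-1$,
$|\mathrm{PSC}| = 3 - 6/s$, which is exactly 1.0 at the default shift
$s = 3$; Monte Carlo puts per-marker detection at ~0.84 for a 50/50 split
versus ~0.997 at 0.35. Since the method's founding observation is that
unstable loci produce *skewed* distributions, the generator's default
regime is the skewed one; a user who wants to study the symmetric
worst case can simply set `tumor_fraction = 0.5`.

`emitSam()` additionally materializes a cohort as a toy reference FASTA
(random bases, each marker tract being its motif) plus one SAM per sample:
every delta becomes one single-end read with a 55 bp anchored flank on
each side of the tract and a three-segment CIGAR (`M`, then `I` strictly
inside or `D` at the tract's 3' end, then `M`); reads are therefore
~120-150 bp depending on tract length and delta, a deliberate
flank-anchored geometry that keeps the encoded delta exactly recoverable
and every CIGAR path of the extractor exercised. Headers carry no
timestamps, so identical seeds emit byte-identical files.

What the simulator does **not** emulate: sequencing base errors and
quality-score structure, length-dependent polymerase stutter (real stutter
grows with tract length and is deletion-biased even in normal tissue),
tumor subclonality, paired-end geometry, alignment ambiguity around long
homopolymers, and the ~10% of real MSS marker distributions that cross the
|PSC| > 1 threshold. Passing the simulated twins therefore demonstrates
the pipeline's internal correctness and the statistic's behavior under the
stated noise model -- not clinical performance on real FFPE libraries.

## Panels

The panel file format is a 6-column BED-compatible TSV (chrom, 0-based
start, exclusive end, marker id, repeat unit, reference tract length).
Validation enforces unique ids, motif alphabet/length, coordinate sorting,
`ref_length == end - start`, and rejects overlapping loci (one locus, one
statistic). The package ships `panel23.tsv`, a hand-built 23-marker
fixture using the classic mononucleotide marker names (BAT25, BAT26,
NR-21, MONO-27, ...) with hg19-like coordinates -- a realistic small panel
for examples and tests, not a published capture design. Larger panels
(230, 3,154 markers) are generated by `syntheticPanel()` on compact toy
chromosomes (wide unique flanks, A/T-homopolymer-dominated motif mix) and
subset reproducibly with `subsetPanel(panel, n, seed)`.

## Evaluation harness

`msiConfusion()` scores calls against truth with MSI-H as the positive
class; indeterminate calls are excluded and counted, and any metric with a
zero denominator is `NA`, never 0. `mcnemarPaired()` compares two
classifiers on paired samples by per-sample correctness: with fewer than
25 discordant pairs it uses the exact two-sided binomial test at p = 1/2
(small cohorts make the asymptotic test anti-conservative), otherwise the
continuity-corrected chi-square $(|b-c|-1)^2/(b+c)$ on 1 df; zero
discordance gives p = 1. Restricting to truth-positive or truth-negative
samples compares sensitivities or specificities respectively.

## Numerical and degenerate-input choices

* Sample (n-1) standard deviation; the |PSC| <= 3 bound holds either way.
* Even-coverage medians are the midpoint of the two central order
  statistics (the standard convention).
* `sd == 0` (including coverage 1) gives PSC = 0 by definition.
* All threshold comparisons are strict where the rule says "more than"
  (coverage > 20, |PSC| > 1) and inclusive where it says "at least"
  (fraction >= cutoff); each boundary is pinned by a unit test.
* All randomness flows through explicit integer seeds
  (`SimParams(seed=)`, `subsetPanel(seed=)`, `syntheticPanel(seed=)`);
  seeded entry points save and restore the caller's RNG state.

## Problem sizes used in the test suite

The shipped tests run the full caller on simulated twins of a two-arm
design -- a fresh-tissue cohort (16 MSI-H + 68 MSS) evaluated on 23-, 230-
and 3,154-marker panels at cutoff 0.4, and an FFPE cohort (40 MSI-H + 77
MSS) on the 23-marker panel at cutoff 0.25 -- plus oracle suites: 10,000
random multisets against a brute-force skewness implementation (1e-12
agreement), randomized CIGARs against a per-base coordinate-map oracle,
and exact SAM round trips on small panels. These sizes keep the whole
suite at a few minutes on one core while leaving the binomial noise on
cohort metrics far smaller than the margins being tested.

## Known limitations

* Tumor-only by design: a germline-variable microsatellite shifts the
  whole distribution but stays symmetric, which the statistic tolerates --
  yet truly polymorphic multi-allelic loci can mimic skew; curated panels
  should avoid them.
* A pure homozygous shift (every read contracted by the same amount) has
  zero variance and scores PSC = 0: invisible to a skewness statistic.
  This is intrinsic to the method, not an implementation limit.
* Cutoffs (0.4 / 0.25) were established on colorectal cohorts; other
  tumor types or very low purity may need recalibration, which is why
  every threshold is a parameter.
* The extractor trusts the aligner's CIGAR; indel left-alignment
  differences between aligners can shift boundary attributions.
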