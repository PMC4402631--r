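---
title: "IBD case-control mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IBD case-control mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdmapr)
```

## The method

Population-based linkage analysis treats a cohort of nominally
unrelated cases and controls as a very large, very sparse pedigree:
an IBD detector (refined IBD or similar) supplies pairwise haplotype
segments judged identical by descent, and the question becomes whether,
at some marker, case–case pairs share segments in excess of the
genome-wide background. `ibdmapr` implements the post-detection half of
that analysis — everything from genotype QC to the permutation
significance call — plus a synthetic-data generator that reproduces the
statistical structure the analysis assumes, so the whole chain is
testable end to end without access-controlled genotype data.

### Sharing statistic

Let a kept segment *span* marker *m* when its physical interval
contains the marker position (inclusive on both ends, same chromosome).
Writing $c(m)$ for the number of case–case segments spanning $m$ and
$N_{cc}$ for the number of case–case pairs, the per-marker rate
$c(m)/N_{cc}$ is normalised by its genome-wide mean
$\bar g = \mathrm{mean}_m\, c(m)/N_{cc}$:

$$ s(m) = \frac{c(m)/N_{cc}}{\bar g}. $$

$s$ is scale-free ($s \equiv 1$ for a flat profile) and is the minimal
statistic consistent with "corrected for the average genome-wide
sharing": cohorts or permutations with globally higher sharing are not
rewarded, only *local* excess is. Each haplotype-pair record counts
once per segment; haplotype multiplicity is deliberately not collapsed,
since the segment records are per haplotype pair.

### Permutation significance

Case/control labels are permuted preserving class sizes; for each of
$B$ permutations the whole profile and its own genome-wide average are
recomputed (the normaliser must be re-estimated per permutation, or the
null distribution would be biased toward the observed labeling).
Pointwise p-values use the add-one estimator
$p(m) = (1 + \#\{s_b(m) \ge s(m)\})/(B+1)$, which is valid (its null
distribution is stochastically at least uniform), at the price of a
floor of $1/(B+1)$.

Genome-wide (family-wise) significance uses the max-statistic
construction: marker $m$ is compared against the permutation
distribution of $\max_m s_b(m)$, and is significant when its
genome-wide p-value is at most the level $\alpha = 0.05$. Under label
exchangeability this controls the probability of *any* false positive
at $\alpha$ — the acceptance suite measures the realised rate at
$10/201 \approx 0.0498$ minus a small tie-induced conservativeness. A
literal alternative reading of the published threshold — the 0.05th
percentile of the pointwise permutation p-values — is available as
`mapping_params(gw_rule = "p_quantile")`; it is a fixed-proportion
marker call rather than an error-rate guarantee, which is why it is not
the default.

All comparisons between statistics are performed by integer
cross-multiplication ($c_b(m) \cdot S \ge c(m) \cdot S_b$, where $S$ is
the genome-wide count total), so permutation ties are resolved exactly
rather than at floating-point mercy.

### Low-coverage filter

IBD detection is weaker near chromosome ends: segments overhanging the
end are truncated or missed, so fewer segments span terminal markers,
and a small absolute excess there turns into a large relative one.
Apparent case–case peaks in such regions are method artifacts. The
filter computes the total number of kept segments (all pair classes)
spanning each marker and masks markers strictly below the 10%
(`coverage_fraction`) quantile — linear interpolation between order
statistics, strict inequality so an all-tied profile masks nothing.
Reported hits (`significant_markers()`) must be genome-wide significant
*and* unmasked; the raw permutation call is kept separately
(`gw_significant`) so the calibration of the significance procedure can
be assessed on its own.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lod_min` | 3 | minimum segment LOD (log10 likelihood IBD vs not) |
| `length_min_cm` | 1 cM | minimum genetic segment length |
| `fwer_level` | 0.05 | family-wise significance level |
| `coverage_fraction` | 0.10 | masked quantile of per-marker segment counts |
| `n_permutations` | 10,000 | label permutations (5 × 10⁶ in the original cluster-scale analysis; desk-scale default here, configurable) |
| QC: `maf_min`, `hwe_p_min`, `ind_missing_max`, `marker_missing_max` | 0.05, 1e-6, 0.07, 0.1 | standard pre-IBD genotype filters |
| outliers: `n_pcs`, `n_neighbors`, `density_cutoff`, `interior_min` | 6, 10, 0.15, 9 | two-stage nearest-neighbour rule |

The exclusion sentence behind the segment filter names two criteria;
we read them as independent (keep iff LOD ≥ 3 **and** length ≥ 1 cM),
the conventional thresholds for refined-IBD post-processing. The
literal conjunctive-exclusion reading (drop only segments failing both)
is exposed as `segment_filter_params(rule = "both")`.

The HWE filter uses the conditional exact test (total probability of
heterozygote configurations no more probable than the observed one,
conditioning on allele counts), the standard GWAS-QC choice; it is
computed on all samples by default, with `hwe_samples = "controls"`
available since practice varies. Individuals are filtered before
markers, and marker statistics are recomputed after individual removal.

### The 0.15 cutoff is scale-dependent

`compute_pcs()` returns unit-norm sample eigenvectors (the smartPCA
output convention), so coordinate magnitudes scale like $1/\sqrt{n}$.
The default `density_cutoff = 0.15` presumes a cohort-scale $n$ (a few
thousand samples); on a 60-sample toy panel typical mean 10-NN
distances are 0.3–0.4 and the default would remove everything. The
cutoff is therefore a parameter, not a constant — the package's own
small-panel examples set it explicitly.

Two further points in the outlier procedure were genuinely open and are
configurable: stage-2 neighbours are looked up in the **full** sample
set by default (the samples "inside the cluster" criterion is evaluated
against stage-1 membership, not a re-run k-NN among survivors;
`stage2_neighbors = "stage1"` selects the other reading), and exactly
one pass of the two stages is run. k-NN ties break by sample order,
deterministically.

## The synthetic-data generator

`sim_spec()` fixes the generator's conditions; the defaults are the
package's validation conditions and are not tuned per test:

* **Genome** — 2 chromosomes × 100 Mb at a uniform 1 cM/Mb (one Morgan
  each), 250 evenly spaced markers per chromosome.
* **Segment lengths** — Pareto($\alpha$ = 2.5, $x_m$ = 0.65 cM), giving
  mean $\alpha x_m/(\alpha-1) = 1.083$ cM, i.e. "slightly above 1 cM",
  matching the empirical length histogram the method is known for. The
  published analysis reports that distribution only qualitatively, so
  these two numbers are a calibration choice made once.
* **Segment placement** — per-pair counts Poisson(`base_share_rate` ×
  genome Morgans) with midpoints uniform in *genetic* distance, so the
  length distribution is exactly Pareto before end-truncation. The
  default rate 1.5/pair/Morgan makes the expected case–case spanning
  count per marker $\binom{50}{2} \times 0.015 \times 1.083 \approx 20$
  at the default 50 + 50 sample sizes.
* **Telomere depletion** — segments with midpoints within
  `telomere_width_cm` (5 cM) of a chromosome end are kept with
  probability `telomere_retention`, emulating reduced detection near
  chromosome ends; retention 1 (off) is the default so the null is
  exactly exchangeable.
* **Planted locus** — case–case segments covering the locus are
  duplicated so their expected mass is multiplied by `enrichment`;
  duplication (rather than re-drawing) leaves the marginal length
  distribution untouched. With `enrichment = 1` labels never enter the
  generator, so all pair classes are exchangeable by construction.
* **LOD scores** — 3 + Exponential(mean 2), so simulated segments pass
  the LOD filter unless a `lod_low_frac` fraction is deliberately
  pushed into Uniform(0, 3) to exercise it.
* **Genotypes** — HWE proportions at a Uniform(0.15, 0.45) MAF,
  markers independent (no LD). Planted QC failures are constructed
  exactly: a rare coded allele for MAF failures, a complete
  heterozygote excess for HWE failures (feasibility checked against
  the exact test before planting), and missingness pushed well past
  the respective thresholds; clean markers are rejection-sampled to
  pass all filters with margin on the samples that survive individual
  removal, so the QC truth is unambiguous.

What the generator does **not** emulate: linkage disequilibrium,
phasing error, coalescent depth structure (segment counts per pair are
independent Poisson, not genealogy-driven), allele-frequency
stratification between cases and controls, and detector-specific
artifacts beyond the telomere knob. Passing tests therefore demonstrate
the correctness and calibration of the *analysis* under its stated
assumptions, not the behaviour of any IBD detector on real genotypes.

## Numerical and degenerate-input choices

* Map interpolation is linear between anchors, extrapolates at the
  terminal interval's rate and floors at 0 cM; it is exact at anchors
  and monotone.
* Quantiles (coverage filter) use linear interpolation between order
  statistics; masking is strict, so ties never mask whole plateaus.
* A permutation with an all-zero profile compares as "at least as
  extreme" everywhere — the conservative direction.
* An observed all-zero case–case profile is an error (statistic
  undefined), as is a label vector without two cases and two controls.
* A zero-variance genotype panel yields an all-zero embedding with a
  flag rather than an error.
* Segment records are canonicalised to sorted sample order on read,
  carrying haplotype indices along; all generators are bit-reproducible
  from `seed`.

## Problem sizes used in validation

The test-suite calibrations run at: 200 null cohorts × 200 permutations
(family-wise error), 50 replicates × 1000 permutations at 100 + 100
samples (planted-locus power, 5× enrichment), 500 + 10 samples × 50
seeds (outlier recovery), 10,000 markers (coverage-filter fraction),
100,000 draws (Pareto mean), all genotype configurations with n ≤ 50
(exact HWE vs an independent enumeration oracle) and 200 random
instances (sweep vs brute-force spanning counts). These sizes were
chosen as the smallest at which the Monte-Carlo intervals in use are
meaningful for the quantities being checked.

## Known limitations

* The statistic uses case–case sharing only; excess *case–control*
  sharing deficit is not modelled, and the genome-wide normaliser is
  the case–case average (an all-pair normaliser would mix classes under
  permutation and is not offered).
* The permutation floor $1/(B+1)$ means small $B$ cannot certify very
  small p-values; the original analysis used $5 \times 10^6$
  permutations for exactly this reason.
* The coverage filter is computed on the same segment set being tested,
  so in tiny simulations the mask itself is noisy; with continuous
  (tie-free) counts it masks the nominal fraction to within a marker.
* PCA is plain genotype PCA; no Tracy–Widom dimension selection and no
  iterative outlier re-fitting, which full smartPCA performs.
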