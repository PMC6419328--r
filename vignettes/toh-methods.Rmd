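---
title: "Tracts of homozygosity: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracts of homozygosity: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tohscan)
```

## The analysis in one paragraph

A tract of homozygosity (TOH, often called a run of homozygosity) is a
contiguous stretch of homozygous SNP genotypes in one individual.  When a
minimum number of subjects carry a TOH over the same stretch of markers,
that stretch is a *common TOH* (cTOH) — a candidate locus where recessive
or haplotype-level variation may be shared.  `tohscan` calls TOHs per
individual, builds cTOH regions from the per-SNP coverage of those calls,
codes each individual as carrier/non-carrier of each region, tests the
carrier indicator for case-control association with a logistic model
adjusted for sex and genotype principal components, adjusts across
regions with the Benjamini-Hochberg procedure, and finally integrates
repeat-element and insertion/deletion annotations inside the significant
regions to shortlist genes.  Because real cohorts of this kind are not
redistributable, the package ships a synthetic-data module that generates
cohorts with *planted* tracts at chosen case/control carrier frequencies;
every statistical claim the test suite makes is checked against that
recorded ground truth or against an independent brute-force oracle.

## Genotype model and quality control

Genotypes are coded 0/1/2 copies of an arbitrary "B" allele with `NA`
for missing calls.  The simulator draws each marker's allele frequency
uniformly inside a minor-allele-frequency band (default 0.05–0.5),
genotypes from Hardy-Weinberg proportions, and applies independent
per-call dropout (default 1%) so the QC filters have realistic work to
do.  Optional two-subpopulation structure uses the Balding-Nichols
model: subpopulation frequencies are drawn
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$ around
the ancestral frequency $p$, with drift parameter $F \in [0,1)$.

`apply_qc()` removes samples first (call rate < 95% by default), then
SNPs, recomputing every SNP statistic on the retained samples: missingness
(> 5% removed), the exact conditional Hardy-Weinberg test (p < 1e-7
removed) and minor allele frequency (< 3% removed).  The HWE test
enumerates every heterozygote count compatible with the observed allele
counts and sums the probabilities of configurations no more likely than
the observed one; the implementation uses the ratio recurrence
$P(h+2)/P(h) = 4\,n_{AA}n_{BB}/((h+1)(h+2))$ in log space, which is
numerically stable to a few hundred samples and beyond.  The test is
conditionally exact and therefore conservative: under the null,
$P(p \le \alpha) \le \alpha$, which the suite verifies empirically.
Two thresholds deserve comment.  The MAF band is operated as a single
lower bound (`min_maf = 0.03`) — the conventional reading of a 3–5%
screening band — and the HWE test is computed on the full genotyped
cohort by default (`hwe_on = "controls"` switches to controls-only);
neither convention is forced by the method itself, so both are
configurable.

## Tract calling

A tract is a *maximal* window of consecutive markers on one chromosome
that (i) contains at least `min_snps` homozygous calls (default 100),
(ii) contains at most `max_het` heterozygous calls (default 0) and at
most `max_missing` missing calls (default 2), and (iii) starts and ends
on a homozygous call.  Maximal means no valid window strictly contains
it.  The defaults encode strict homozygosity — "identical homozygous
calls" at the cTOH stage — while tolerating the dropout level a dense
array actually shows; there is no bp-length minimum by default
(`min_bp = 0` disables it) because the consensus rule below operates at
SNP resolution.

The caller computes, for each homozygous start, the furthest admissible
end (just before the allowance-exceeding het/missing call) with a
vectorised rank lookup; since that bound is monotone in the start
position, the first start attaining each distinct trimmed end yields
exactly the set of maximal windows in linear time.  One subtlety follows
directly from the definition: with `max_missing > 0`, two maximal
windows can overlap (homozygous segments separated by single missing
calls can be combined in more than one allowance-respecting way).  The
package keeps all maximal windows — this is what "every window tested
for validity and maximality" means — and the coverage stage counts
*distinct individuals*, so overlapping tracts of one individual never
double-count.  Under `max_het = 0, max_missing = 0` tracts are provably
disjoint, and the suite asserts disjointness in that configuration.

## cTOH regions and carrier status

`toh_coverage()` counts, at every marker, the individuals whose tracts
cover it; `define_ctohs()` takes the maximal runs of consecutive markers
with coverage at least `min_subjects` (default 10) and keeps runs of at
least `min_snps` markers (default 100) — the "10 subjects share 100
identical homozygous calls" consensus.  Regions never span chromosome
boundaries, are reported as the maximal qualifying run (not trimmed to a
shared core), and are disjoint by construction.

Carrier status is the binary predictor of the association model.  The
carrier rule is not dictated by the consensus definition, so the package
makes it explicit: an individual carries a region when their own tracts
cover at least `min_cover_frac` (default 0.9) of the region's markers.
The threshold arithmetic is exact in SNP counts —
`ceiling(min_cover_frac * n_snps - 1e-9)` — with the epsilon guarding
binary-float artifacts (0.9 × 150 evaluates just above 135) so that
coverage exactly at the fraction counts as carriage.  The 0.9 default
lets boundary jitter and a broken tract edge through while excluding
individuals who share only half a region.

## Association model

For each region the model is

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_1\,\text{carrier}
  + \beta_2\,\text{sex} + \sum_{j=1}^{k}\gamma_j\,\text{PC}_j ,$$

fitted by iteratively reweighted least squares (tolerance 1e-10, 50
iterations).  Standard errors come from the observed information matrix
evaluated at the returned estimates — not from the IRLS working weights
of the previous iteration, a distinction that matters at the 1e-6 level
the closed-form checks demand.  Reported per region: the carrier
log-odds, SE, Wald $z$ and two-sided $p = 2(1-\Phi(|z|))$, the odds
ratio $e^{\beta_1}$ with a 95% CI using the exact normal quantile
$\Phi^{-1}(0.975)$, and a Benjamini-Hochberg q-value computed across all
converged region fits.  Regions whose carrier column is constant are
flagged non-estimable; fits that fail to converge or show the
fitted-probability collapse typical of separation are flagged and
excluded from the FDR adjustment (their count is logged) rather than
reported as if trustworthy.  Firth-penalised fits would be the natural
extension but are deliberately out of scope.  The FDR adjustment is
genome-wide across the tested regions, and raw Wald p plus BH q are the
only significance columns — no second "adjusted p" is invented.

### Why the covariate PCA excludes the tested regions

Stratification PCs are EigenStrat-style: genotypes standardised per SNP
to $(x - 2\hat p)/\sqrt{2\hat p(1-\hat p)}$, missing set to 0 after
centering, monomorphic SNPs dropped, scores taken as left singular
vectors with the sign fixed by the largest-magnitude loading.  At the
desk scale this package validates at (around 8,000 markers), a shared
150-SNP homozygous block is an enormous feature: empirically PC1
correlates at $|r| \approx 0.94$ with carrier status, and entering such
a PC as a covariate makes the carrier coefficient nearly inestimable.
Exactly as EigenStrat practice excludes known long-range LD regions,
`run_toh_pipeline()` therefore computes the covariate PCA on markers
*outside* the detected cTOH regions (`make_covariates(exclude_snps =)`).
On a real array (hundreds of thousands of markers) the exclusion is
numerically irrelevant — one region is a vanishing fraction of the
panel — but at validation scale it is the difference between a
well-posed and an ill-posed design.  The default is `k = 2` components;
the cohorts simulated here are panmictic or two-population, for which
two axes suffice.

## Feature integration

Inside the significant regions (q < 0.05 by default) the package
consumes three annotation sets — repeat elements (inverted or simple),
per-sample indel calls, and gene models — and applies two conjunctive
filters.  Indel calls cluster across samples by single linkage on their
reference spans, linking calls separated by a gap of fewer than
`merge_window` bp (default 10; cross-sample positional matching is
alignment-jittery, and exact-position matching would be brittle).  A
cluster is retained when it is supported by at least `min_samples`
distinct samples (default 3, the "3 of 8" recurrence rule) *and* its
span overlaps at least one repeat interval — the repeat condition is
applied at cluster level, matching how the two requirements are
conjoined.  A gene is shortlisted when it overlaps a significant region
and overlaps a retained cluster.  All interval work is 0-based
half-open with strand ignored; overlap means at least one shared base.
Per-chromosome repeat summaries (`ir_summary()`) restrict repeats to
those overlapping cTOH regions and report count, min/max/mean length
and the number of genes touched by such repeats.

The exome simulator plants one gene per truth entry — a cluster of
co-located indels in exactly `min_samples` samples, an overlapping
repeat, inside a significant region — plus two kinds of decoys that fail
exactly one conjunct (an under-recurrent cluster with a repeat, and a
recurrent cluster with no repeat).  In its default "tight" mode,
background indels avoid gene bodies and background repeats avoid the
decoy segments, so the expected shortlist equals the planted truth
exactly; `background_in_genes = TRUE` relaxes this for stress testing.
Indel lengths are uniform on 1–191 bp and repeat lengths log-uniform on
39–21,947 bp, the scale ranges annotated repeat/indel sets of this kind
span.

## Validation design and what it does and does not show

The simulated cohorts reproduce the *statistical* structure the method
assumes — Hardy-Weinberg genotypes, independent markers, planted carrier
signals with a known implied odds ratio
$p_1(1-p_0)/\bigl(p_0(1-p_1)\bigr)$ — but deliberately not linkage
disequilibrium, haplotype sharing by descent, or sequencing error
processes.  Passing tests therefore demonstrate correctness of the
algorithms and calibration of the inference under the stated model, not
robustness to LD-induced coverage inflation, which on real arrays is
handled upstream by marker pruning.

The validation experiments, at the problem sizes the suite runs:

* **Oracle equivalence.** The tract caller is compared with an
  exhaustive $O(n^2)$ window oracle on 1,000 random 500-SNP rows across
  two allowance settings; region building, interval intersection
  (2,000 random records) and indel clustering (2,000 calls) are compared
  with brute-force maximal-run, all-pairs and union-find oracles.
  Agreement is exact.
* **Statistical identities.** The exact HWE test is checked against the
  direct log-factorial enumeration on *every* genotype configuration
  with total ≤ 200 (tolerance 1e-10); 2×2 logistic fits against the
  cross-product OR and Woolf SE (1e-6); BH q-values against the
  explicit step-up formula; the Wald p at $|z| = 1.959964$ against 0.05.
* **Parameter recovery.** 200 replicates of 100 cases + 100 controls on
  4 × 2,000 markers with one planted 150-SNP tract at carrier
  probabilities 0.3 vs 0.1 (implied OR 3.857): the planted span must
  intersect a detected region in ≥ 95% of replicates and the 95% CI
  must cover 3.857 in ≥ 90%.
* **Null calibration.** The same design with twelve tracts planted at
  *equal* carrier probability in both arms and the phenotype permuted:
  per-region Wald p-values are uniform (per-run KS p > 0.01 in ≥ 95% of
  60 runs) and essentially no q < 0.05 discoveries occur.  Planting
  non-differential tracts is the only way to have regions to test under
  the null: with realistic allele frequencies an unplanted 100-SNP
  homozygous run has vanishing probability, so a literal "no tracts"
  null would be vacuously empty.
* **Integration truth recovery and determinism.** The planted shortlist
  is recovered exactly with both decoy types rejected across seeds, and
  two pipeline runs of one configuration produce byte-identical output
  files (the run log carries no wall-clock timestamps for this reason).

## Numerical and degenerate-input conventions

* All randomness derives from one integer seed via fixed stage-level
  sub-seeds; identical configurations are bit-reproducible.
* HWE tie handling: configurations whose null probability is within a
  relative 1e-9 of the observed one count as "as extreme"; both the
  implementation and the oracle use the same rule, so exact ties (which
  occur at symmetric configurations) are never split by rounding noise.
* Monomorphic markers: MAF 0 (removed by QC at any positive `min_maf`),
  HWE p of 1, dropped from PCA standardisation.
* Empty inputs return empty, well-typed results (no tracts, no regions,
  empty summaries with count 0) rather than errors; truly degenerate
  requests (zero-length genotype rows, zero totals, all samples failing
  QC, rank-deficient designs, constant outcomes) raise explicit errors.
* PLINK text coding: alleles `A`/`B` (missing `0`), sex 1 = male /
  2 = female, phenotype 2 = case / 1 = control; internally sex is a 0/1
  indicator (0 = male) entered as a covariate, and 1-based map
  positions convert to 0-based half-open intervals only at the BED
  boundary.

## Interface

The package is function-first: `run_toh_pipeline()` drives
simulate → QC → tract calling → region building → (region-excluded)
PCA → association → integration, writing every intermediate as
PLINK/TSV/BED plus a reconciling run log, and each stage is equally
usable on its own (`apply_qc()`, `call_tohs()`, `toh_coverage()` +
`define_ctohs()` + `assign_carriers()`, `associate_all()`,
`cluster_indels()` + `recurrent_indels()` + `shortlist_genes()`).
Readers and writers (`read_plink()`, `read_bed()`, `read_indel_vcf()`,
`read_tsv()` and their writers) round-trip every file the pipeline
emits, so external genotypes and annotations in those formats drop in
directly.

## Known limitations

* No LD model in the simulator, hence no test of coverage inflation by
  haplotype blocks; real-array use should prune or prune-and-exclude as
  usual.
* Separated fits are flagged and excluded rather than Firth-corrected.
* The HWE exact enumeration is per (total, allele-count) group and
  comfortable at array scale, but a saddlepoint or mid-p variant would
  be preferable for biobank-scale totals.
* The integration stage consumes repeat and indel annotations; it does
  not discover repeats or call indels from reads.
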