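# tohscan

Case-control analysis of **tracts of homozygosity** (TOH) from SNP array
genotypes, for statistical geneticists studying recessive or
haplotype-level disease components: call per-individual TOHs, build
**common-TOH (cTOH) regions** shared by many subjects, test each region
for disease association, and integrate repeat-element and
insertion/deletion annotations inside the significant regions to
shortlist candidate genes.

## The method

For individual $i$, a TOH is a maximal window of consecutive markers on
one chromosome containing at least `min_snps` homozygous calls (default
100), at most `max_het` heterozygous calls (default 0) and at most
`max_missing` missing calls (default 2), starting and ending on a
homozygous call.  A cTOH region is a maximal run of consecutive markers
at which at least `min_subjects` individuals (default 10) carry a TOH,
retained when the run spans at least `min_snps` markers (default 100).
Individual $i$ *carries* region $r$ when their tracts cover at least 90%
of its markers, and carriage is tested per region with

$$\operatorname{logit} P(\text{case}) = \beta_0 + \beta_1\,\text{carrier}
  + \beta_2\,\text{sex} + \textstyle\sum_j \gamma_j\,\text{PC}_j,$$

reporting the Wald $p$-value, the odds ratio $e^{\beta_1}$ with 95% CI,
and Benjamini–Hochberg q-values across regions.  Genotype QC (sample
call rate ≥ 95%, SNP missingness ≤ 5%, exact Hardy–Weinberg $p \ge
10^{-7}$, MAF ≥ 3%) and EigenStrat-style PCA covariates are built in.
Downstream, indel calls are clustered across samples, clusters recurring
in ≥ 3 samples *and* overlapping an inverted/simple repeat are retained,
and genes overlapping both a significant region and a retained cluster
form the shortlist.

A synthetic-data module simulates cohorts with *planted* tracts at
chosen case/control carrier probabilities (implied odds ratio
$p_1(1-p_0)/p_0(1-p_1)$) and annotation sets with planted truth genes,
so the whole pipeline validates end to end without external data.

## Worked example

```r
library(tohscan)

cfg <- default_pipeline_config(seed = 42)   # 100 cases + 100 controls,
res <- run_toh_pipeline(cfg)                # 4 chr x 2,000 SNPs, 2 planted tracts
res
#> toh_pipeline_result:
#>   regions: 2  significant: 1
#>   shortlisted genes: 1

res$assoc[, c("region_id","chrom","n_snps","n_carriers","odds_ratio",
              "ci_low","ci_high","p_value","fdr_q")]
#>   region_id chrom n_snps n_carriers odds_ratio ci_low ci_high  p_value    fdr_q
#> 1  ctoh_001  chr1    157         55     27.874  9.288   83.65 2.94e-09 5.89e-09
#> 2  ctoh_002  chr2    158         49      0.629  0.322    1.23 1.76e-01 1.76e-01

res$shortlist[, c("gene","chrom","n_samples","samples","region_ids")]
#>          gene chrom n_samples        samples region_ids
#> 1 GENE_TRUE01  chr1         3 ex04,ex05,ex08   ctoh_001
```

The demo config plants a strongly associated tract on chr1 (carrier
probability 0.6 in cases vs 0.05 in controls — true OR 28.5) and a null
tract on chr2 (0.25 in both arms).  The pipeline recovers both as cTOH
regions; only the chr1 region is significant (OR 27.9, 95% CI 9.3–83.7,
q ≈ 6e-9), the null region is not (OR 0.63, CI crossing 1), and the
planted truth gene — supported by an indel cluster in 3 of 8 exome
samples overlapping a repeat inside the significant region — is the
entire shortlist.  `toh_length_summary(res$tohs)` gives the usual
count/min/max/mean/quartile description of tract lengths in SNPs and bp.
Pass `out_dir =` to write every intermediate (PLINK genotypes, TSV
tables, BED tracks, reconciling run log); reruns of one configuration
are byte-identical.

Each stage is usable on its own: `apply_qc()`, `make_covariates()`,
`call_tohs()`, `toh_coverage()` + `define_ctohs()` +
`assign_carriers()`, `associate_all()`, `cluster_indels()` +
`recurrent_indels()` + `shortlist_genes()`, with `read_plink()` /
`read_bed()` / `read_indel_vcf()` for external data.

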