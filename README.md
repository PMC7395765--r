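# fetallineage

Somatic mutation accumulation and developmental lineages in clonally
expanded fetal stem and progenitor cells.

## The problem

Single stem cells carry too little DNA for direct whole-genome sequencing,
so somatic mutations in individual haematopoietic stem/progenitor cells
(HSPCs) and intestinal stem cells (ISCs) are catalogued by clonally
expanding single cells in culture and sequencing the clone against a
polyclonal bulk sample (skin or intestine) from the same donor. From such
clone-versus-bulk whole-genome calls this package implements, end to end:

1. **Somatic filtering** — per-clone clonal substitutions and indels via the
   full quality chain (caller PASS; QUAL ≥ 50, MQ ≥ 60; clone GQ ≥ 99,
   VAF > 0.1, DP ≥ 20; bulk GQ ≥ 10, VAF = 0, DP ≥ 20; clonality cut
   VAF ≥ 0.3 with VAF ≥ 0.2 on chromosome 21 in trisomic cells and a
   hemizygous VAF ≥ 0.99 rule on male X; indels at QUAL ≥ 250, GQ ≥ 99 both
   sides, 100 bp germline-indel exclusion), a two-component beta-binomial
   EM clonality check, and shared-variant calling: a variant is kept when
   at least one clone is confidently *present* and one confidently
   *absent*.
2. **Lineage reconstruction** — binary clones × mutations matrix rooted by a
   zero profile, Hamming-distance neighbor joining, assignment of each
   mutation to the branch above its carrier clade, early (pre-gastrulation)
   mutations from bulk subclonality, per-branch contribution to bulk tissue
   as `min(1, 2 × median nonzero bulk VAF)` with a chi-square test that
   splits branches spanning several cell divisions, and Fisher exact
   comparison of branch contributions.
3. **Burden models** — loads extrapolated to the whole genome by the
   surveyed fraction (positions with DP ≥ 20 in clone *and* bulk); linear
   mixed-effects models: mutation rate per year across fetal / cord /
   post-infant cohorts (donor random intercept, fold change with a
   parametric-bootstrap CI), load against age with trisomy × cell-type
   fixed effects, a donor random slope and karyotype-specific residual
   variances, a likelihood-ratio test of the variance difference,
   leave-n-out robustness, standard-normal residual outlier detection with
   BH-FDR, an early-mutation model without age, and the Wilcoxon rank-sum
   DBS comparison.
4. **Signature machinery** — 96-channel trinucleotide spectra pooled per
   category (per-donor deduplication), chi-square spectrum comparison,
   non-negative least-squares refitting against a signature catalog,
   iterative reverse selection (remove the lowest-contribution signature
   until the mean reconstruction cosine drops by more than 0.05 between
   iterations), bootstrapped selection (resampling each profile's
   mutations), a fixed-margin permutation test of exposures (Patefield
   sampling, two-tailed p with a 2/n_perm floor), and constrained refits
   against a fixed signature set.
5. **Synthetic cohort generator** — the validation backbone: binary
   embryonic division trees with Poisson mutations per division, germ-layer
   allocation with tunable first-daughter dominance of the ectoderm-derived
   bulk, clone-private late mutations at ~100 substitutions/year (plus a
   trisomy excess), germline heterozygous variants, low-VAF culture
   artifacts, singleton-read error candidates, and binomial read sampling
   at Poisson 30× depth with VAF 1/2 (autosome), 1/3 (trisomic chr21) and
   1 (male X). Every variant carries a truth label, and true trees /
   branch contributions are exported.

## Worked example

```r
library(fetallineage)

coh <- simulate_embryo(cohort_config(seed = 1))     # 9 donors, ~5 clones each
cs  <- cohort_clonal_sets(coh$calls, coh$meta)      # clonal somatic SNVs
st  <- filtering_truth_stats(coh, cs)
round(c(precision = st$precision, recall = st$recall,
        invitro_rejected = st$invitro_rejected), 3)
#>        precision           recall invitro_rejected
#>            0.993            0.967            0.988

sh  <- cohort_shared_tables(coh$calls, coh$meta)    # shared-variant tables
cl  <- coh$meta$sample_id[coh$meta$donor_id == "N01" & coh$meta$role == "clone"]
lin <- donor_lineage(sh$N01, cs[cs$donor_id == "N01", ], cl)
ape::write.tree(lin$assigned$tree)                  # branch lengths = mutations

obs <- simulate_load_table(seed = 1)                # 5 D21 + 4 T21 donors
fit <- fit_trisomy_model(obs)
fit$fixed[fit$fixed$term == "trisomy21T21", ]
#>            term estimate       se df        t            p    ci_lo   ci_hi
#> 1: trisomy21T21 36.46276 3.774943 40 9.659155 5.199767e-12 28.83331 44.0922
```

The filter metrics say: of all retained calls 99.3% are true in-vivo
somatic variants, 96.7% of the recoverable truth is found, and 98.8% of
culture-acquired low-VAF artifacts are rejected. The model table reports
the estimated extra substitutions per trisomic cell (simulated truth: 34)
with its 95% CI.

The numbered scripts under `analysis/` run the same study as a narrative
workflow (simulate → filter → lineage → burden → signatures) and write
their tables under `results/`.

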