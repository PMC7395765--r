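---
title: "Methods: somatic mutation accumulation and developmental lineages in clonally expanded fetal stem cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mutation accumulation and developmental lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, its tunable
parameters, the design choices that were genuinely open, and what the
synthetic validation does and does not demonstrate about real data.

## The measurement design

A single fetal stem or progenitor cell (an HSPC from liver/bone marrow, or
an ISC grown as an organoid) is clonally expanded until it yields enough
DNA for ~30x whole-genome sequencing; a polyclonal bulk sample (skin, or
intestine) from the same donor controls for germline variants. Mutations
present in the founding cell are carried by essentially every cell of the
expansion and appear at the clonal variant allele fraction — about 0.5 on
a disomic autosome, about 1/3 on a trisomic chromosome 21 (one mutated
copy of three), and about 1 on the X of a male donor — whereas mutations
acquired *during* the expansion are subclonal and sit well below that
band. This VAF separation is what the clonality cut exploits.

## Somatic filtering

The substitution filter chain is applied in a fixed order so per-stage
attrition is reportable: candidate call in the clone; SNV; caller PASS;
site QUAL >= 50; MQ >= 60 (a missing MQ fails, conservatively —
configurable); single alternative allele; optional site-exclusion list
with an ID-based rescue list (stand-ins for a SNP database and a somatic
catalog — no network resource is consulted); clone GQ >= 99, VAF > 0.1,
DP >= 20; bulk GQ >= 10, VAF = 0, DP >= 20; and finally the clonality cut
VAF >= 0.3, replaced by VAF >= 0.2 on the trisomic chromosome of T21
donors and by the male-X rule (VAF >= 0.99, GQ >= 10, DP >= 10 in both
samples). "Bulk VAF = 0" is interpreted strictly as zero alternative
reads, not as VAF below some epsilon. Indels additionally require
QUAL >= 250, GQ >= 99 in both samples, and distance > 100 bp from any
germline indel called in the bulk. All thresholds live in
`filter_config()`.

Two consequences of this design matter for interpretation. First, a
variant genuinely present in bulk — which is exactly what a
pre-gastrulation mutation is — fails the bulk VAF = 0 gate, *by design*:
per-clone "clonal somatic" sets mean *unique* somatic variants not seen in
bulk. Second, the filter cannot recover variants at positions that were
not adequately sequenced; coverage is handled separately by the surveyed
fraction. The truth-recovery statistics follow these semantics: precision
counts every retained germline/culture/error call as false, while recall
is measured against in-vivo somatic variants with a true bulk cell
fraction of zero at positions with DP >= 20 in both samples.

The clonality control ("is this expansion really clonal?") is realized as
a two-component beta-binomial mixture fitted by EM to the candidate (alt,
depth) pairs: component means are free, a common precision (default 60) is
fixed, and the clone passes when the total weight of components with mean
in [0.35, 0.65] reaches `clonality_pass_weight` (default 0.7). The
published description of this step names no concrete model, so the
realization is documented here and deliberately swappable.

Shared-variant calling starts from the pre-QUAL candidate set ("somatic
VCF": caller PASS, MQ, single alt, exclusion list, autosome/X), splits the
clones of a donor into present/absent by genotype, gates the present side
with the clone thresholds and the absent side with the bulk thresholds,
and keeps a variant when at least one clone qualifies on each side. The
bulk sample contributes only the recorded VAF and allele counts. Note
that a variant carried by *every* clone of a donor has no absent clone and
is therefore not callable as shared somatic — the rooted trees can carry a
trunk of length zero for this reason.

## Lineage trees and branch contributions

The binary clones x mutations matrix (union of clonal and shared variants;
presence = membership in the clone's qualifying set) is rooted by an
appended zero row. Distances are plain Hamming counts — no normalization,
so branch lengths stay in mutation units — and the tree is built by
neighbor joining (UPGMA behind a flag), re-rooted at the zero profile,
with negative NJ lengths clamped to zero. Each mutation is then assigned
to the branch above the smallest clade equal to its carrier set; carrier
sets matching no clade are reported as conflicts and excluded from branch
lengths. On conflict-free matrices with informative branches this
reproduces the perfect phylogeny exactly (the test suite checks this
against exhaustive topology enumeration for up to six clones), and
because the Hamming distances of such a matrix are exactly additive,
neighbor joining recovers the true topology deterministically.

Early (pre-gastrulation) mutations are the shared variants with nonzero
VAF in the germ-layer-discordant bulk: a mutation shared by
mesoderm-derived HSPCs and endoderm-derived ISCs and also present in
ectoderm-derived skin must predate gastrulation. At 30x this
classification is read-limited: a variant at a division-4/5 node has a
true bulk VAF of only 2-6%, so the binomial read draw returns zero
alternative reads for a noticeable fraction of genuinely early variants.
On the synthetic cohort the early call has perfect precision, but its
Jaccard overlap with the truth is ~0.87 for multi-clone shared variants
(and lower when private variants are included); deeper bulk sequencing,
not a different rule, is what would improve it.

Per branch, the contribution to bulk tissue is `min(1, 2 x median nonzero
bulk VAF)`; zero-VAF mutations are reported as non-contributing. A
chi-square test on the contributing mutations' ref/alt counts (threshold
p < 0.05) decides whether the branch's mutations arose in different cell
divisions; if so the branch is reported subdivided, each mutation as its
own segment with its own 2 x VAF. VAFs on the trisomy-proxy contig are
excluded from contribution estimates to avoid copy-number distortion.

**First-branch comparison.** The published procedure sums ref/alt counts
over all contributing mutations of a branch and compares two branches by
Fisher's exact test. A collapsed branch of the clone tree, however, can
span several embryonic divisions whose mutations have systematically
halving bulk fractions; summed counts then compare mixtures, and the test
fires even when the first division is perfectly symmetric (about a
quarter of symmetric replicates in a 50-replicate pilot). The package's
`first_branch_comparison()` therefore represents each first branch by its
earliest detectable marker — the mutation with the maximum bulk VAF, the
one closest to the trunk — and applies the same Fisher test to those
counts. Measured on 50-replicate designs with eight clones per donor,
symmetric embryos (dominance 0.5) are then flagged in 0% of replicates
and strongly asymmetric ones (dominance 0.9) in ~95%. `compare_branches()`
itself remains the summed-count Fisher test for any pair of branches.

## Burden models

The observed clonal autosomal count of a clone is extrapolated by the
surveyed fraction — the fraction of positions with DP >= 20 in both clone
and matched bulk — giving `load = n_observed / fraction` (identity at
fraction 1, linear in the count).

*Rate model:* `rate ~ cohort` (fetal / cord / post-infant; rate =
load/age since conception) with a donor random intercept; per-cohort
means, all pairwise contrasts, and the fetal-vs-post-infant fold change
defined as the ratio of fitted means with a CI from 1000 parametric
bootstrap draws of the fixed-effect covariance.

*Trisomy model:* `load ~ age + trisomy x cell type` with a donor random
slope on age (every clone of a donor shares one age, so a random slope is
the identified donor term) and karyotype-specific residual variances via
`nlme::varIdent`. *Early model:* the same without age, with a donor
random intercept, fitted to the early-mutation loads.

Estimation is REML for reported effects; likelihood-ratio comparisons
(the test of equal residual variances, chi-square df = 1) refit by ML.
Two-tailed t-tests and CIs use the residual-df approximation
(N − number of fixed effects); under the null this choice is well
calibrated for these designs (measured rejection 0.050 at alpha 0.05 over
200 replicates, versus 0.015 for the grouping-level df), while cohort
means and contrasts in the rate model — a purely donor-level contrast —
use between-donor df. Degenerate inputs with zero residual variance fall
back to exact ordinary least squares on the group structure. Leave-n-out
(n = 1, 2) refits the model on every combination of removed points and
reports the p-value distribution per fixed effect; combinations that
break the design are skipped and logged. Outliers are flagged from
standardized residuals via two-sided standard-normal p-values with
Benjamini-Hochberg FDR (threshold 0.05). DBS counts (adjacent clonal
substitutions, donor-deduplicated to a single clone) are compared with
the two-sided Wilcoxon rank-sum test with continuity correction.

## Signature machinery

Spectra are 96-channel pyrimidine-centred trinucleotide counts pooled per
category, with a mutation recurring in several clones of one donor counted
once. Refitting is non-negative least squares — the single numeric choice
all tests pin. Reverse selection iterates: fit all profiles, record the
mean reconstruction cosine, remove the signature with the lowest *summed
absolute exposure* across profiles (the published description does not
say absolute or relative; absolute is used and flagged here), and stop
when the cosine drop between two consecutive iterations exceeds the
cutoff (0.05), returning the set before the violating removal. The
comparison is consecutive-iteration, the closest literal reading; the
alternative (against the full-set fit) is configuration-selectable by
wrapping the trace.

The bootstrap resamples each profile's mutations with replacement
(multinomial over its empirical channel frequencies — the mutation is the
resampling unit), reruns the selection, and reports selection frequencies
and exposure quantiles; the pairwise exposure correlation across
iterations is the collinearity diagnostic — two signatures with cosine
~0.83 competing for the same mutations show strongly negative correlation,
which is why selection frequencies rather than single fits should be
interpreted.

The permutation test fixes both margins of the categories x 96 count
matrix (Patefield sampling via `r2dtable`), refits every permuted row with
the signatures selected in at least 50% of bootstrap iterations, and
reports per category and signature a two-tailed p: twice the smaller tail
frequency of the null relative exposures around the observed one, floored
at 2/n_perm (never reported as zero) and capped at 1. "More extreme" is
implemented symmetrically in both tails, as the published doubling
implies. The constrained refit is plain NNLS against a fixed set, used
when stringent selection would drop ever-present low-contribution
signatures. DBS and indel spectra are reported as raw dinucleotide-change
and indel-length tallies only.

## The synthetic cohort: what it emulates

Each donor is an embryo: a strictly binary, synchronous division tree of
7 pre-gastrulation divisions (the true division count before gastrulation
is not established; both are exposed in `cohort_config()`), Poisson(2.5)
mutations per division (+0.4 in T21), random allocation of the 128
gastrulation-stage cells to ectoderm/mesoderm/endoderm, a bulk-skin
readout of 500 ectoderm cells whose descent from the first daughter cell
is governed by `ectoderm_dominance`, HSPC clones sampled from mesoderm
leaves and ISC clones from endoderm leaves, late clone-private mutations
at 100/year (+180/year in T21, i.e. ~34 extra at gestational ages 12-17
weeks), 2000 germline heterozygous variants per donor, Poisson(30)
culture-acquired variants per clone at VAF uniform in (0.02, 0.15) —
culture mutations are carried by a minority of the expansion, so their
VAF sits well below the clonal band — and singleton-read error candidates
at 1e-3 per callable site per sample, which give the filter something to
reject. Reads are Binomial(depth, VAF) at Poisson(30) depth; mutation
channels are drawn from a signature mixture and placed at
trinucleotide-consistent positions of a seeded random 6 x 2 Mb genome
(chr1-chr4 plus the trisomy proxy chr21 and chrX; the leading 90% of each
contig is callable). Ages use 7/365.25 years per gestational week minus
two weeks.

What it does *not* emulate: real human sequence composition and mutation
hotspots, replication-timing or transcriptional covariates, mapping
artifacts with positional structure (errors are independent singletons),
copy-number change beyond the single trisomy proxy, and caller-specific
genotype-quality behavior (GQ/QUAL are drawn from simple plausible
distributions). Passing the validation therefore shows that the
*statistical logic* of the pipeline is correct under its stated
assumptions — not that the thresholds are optimal for any particular
sequencing pipeline.

## Study sizes used in validation

The replicated studies use problem sizes chosen to estimate each operating
characteristic with useful precision: the filter study uses the full
default cohort (9 donors, ~5 clones, ~3.6M call rows); tree recovery 20
seeded matrices (4-7 clones, >= 5 mutations per branch, which makes the
topology identifiable and neighbor joining exact); branch contributions 50
replicates per dominance design with 8 clones per donor (dense clone
sampling keeps first branches short; error injection is disabled in these
replicates since singleton errors never reach the shared table);
signature calibration 200 null runs at 500 permutations and a 300-draw
bootstrap; model calibration 100 coverage and 200 null replicates. The
acceptance script scales some replicate counts down further (30/100) and
states each `n` in its output.

## Known limitations

Trunk mutations (present in every clone) are not callable as shared
somatic without a confidently absent clone. Early-mutation recall is
bounded by bulk depth, as quantified above. The in-vitro rejection rate
operates near 99% by construction of the VAF overlap at 30x — individual
culture variants whose binomial draw lands above the clonality cut are
indistinguishable from clonal ones. The clonality EM uses a fixed
precision rather than estimating overdispersion per clone. The NJ tree is
a point estimate; no uncertainty is attached to the topology.
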