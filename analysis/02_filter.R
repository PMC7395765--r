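#!/usr/bin/env Rscript
# Step 2 — clone-versus-bulk somatic filtering.
#
# Applies the full substitution filter chain (caller PASS, QUAL >= 50,
# MQ >= 60, single alt, clone GQ >= 99 / VAF > 0.1 / DP >= 20, bulk
# GQ >= 10 / zero alt reads / DP >= 20, clonality cut at VAF >= 0.3 with the
# T21-chr21 and male-X exceptions), the beta-binomial clonality check per
# clone, and shared-variant calling per donor; then scores everything
# against the simulation truth.

suppressPackageStartupMessages(library(fetallineage))
suppressPackageStartupMessages(library(data.table))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

coh <- simulate_embryo(cohort_config(seed = 1))

cs <- cohort_clonal_sets(coh$calls, coh$meta)
fwrite(cs, "scratch/02_clonal_snvs.tsv", sep = "\t")

clonality <- rbindlist(lapply(unique(cs$clone), function(cl) {
  x <- cs[cs$clone == cl, ]
  # copy-number-neutral sites only: hemizygous X and the trisomic contig
  # have shifted clonal VAFs
  m <- coh$meta[match(cl, coh$meta$sample_id), ]
  drop_contigs <- c(if (m$sex == "M") "chrX",
                    if (m$trisomy21) "chr21")
  x <- x[!x$contig %in% drop_contigs, ]
  if (nrow(x) < 20)  # young clones can carry too few candidates for the EM
    return(data.table(clone = cl, n = nrow(x), clonal_weight = NA_real_,
                      pass = NA))
  r <- clonality_check(x$ad_alt, x$dp)
  data.table(clone = cl, n = r$n, clonal_weight = r$clonal_weight,
             pass = r$pass)
}))
fwrite(clonality, "results/02_clonality.tsv", sep = "\t")

sh <- cohort_shared_tables(coh$calls, coh$meta)
shared_all <- rbindlist(lapply(names(sh), function(d)
  if (nrow(sh[[d]])) cbind(donor = d, sh[[d]]) else NULL), fill = TRUE)
fwrite(shared_all, "scratch/02_shared_variants.tsv", sep = "\t")

st <- filtering_truth_stats(coh, cs)
fwrite(st$per_clone, "results/02_truth_recovery_per_clone.tsv", sep = "\t")
summary_dt <- data.table(
  metric = c("precision", "recall", "germline_retained", "invitro_rejected"),
  value = c(st$precision, st$recall, st$germline_retained, st$invitro_rejected))
fwrite(summary_dt, "results/02_truth_recovery.tsv", sep = "\t")

dbs <- count_dbs(cs)
fwrite(dbs, "results/02_dbs_counts.tsv", sep = "\t")

cat(sprintf(
  "Filtered %d clones: %d clonal SNVs; precision %.3f, recall %.3f, %d germline leaked, %.1f%% in-vitro rejected; all clones pass clonality: %s.\n",
  length(unique(cs$clone)), nrow(cs), st$precision, st$recall,
  st$germline_retained, 100 * st$invitro_rejected,
  all(clonality$pass, na.rm = TRUE)))
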