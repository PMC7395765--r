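# Cohort-level orchestration: run the per-clone filters across a simulated
# (or disk-loaded) cohort, build per-donor lineage results, and score the
# filter output against simulation truth.

#' Run clonal SNV filtering over all clones of a cohort
#'
#' @param calls Long call table (all donors) with a `donor` column.
#' @param meta Metadata table.
#' @param cfg A [filter_config()].
#' @return data.table: all retained clonal SNV calls, with `clone` and
#'   `donor_id`.
#' @export
cohort_clonal_sets <- function(calls, meta, cfg = filter_config()) {
  calls <- data.table::as.data.table(calls)
  out <- list()
  for (d in unique(meta$donor_id)) {
    dm <- meta[meta$donor_id == d, ]
    bulk <- dm$sample_id[dm$role == "bulk"][1]
    rec <- calls[calls$donor == d, ]
    for (cl in dm$sample_id[dm$role == "clone"]) {
      out[[length(out) + 1L]] <- filter_clonal_snvs(rec, cl, bulk, meta, cfg)
    }
  }
  data.table::rbindlist(out)
}

#' Call shared variants for every donor of a cohort
#'
#' @inheritParams cohort_clonal_sets
#' @return Named list (per donor) of shared-variant tables.
#' @export
cohort_shared_tables <- function(calls, meta, cfg = filter_config()) {
  calls <- data.table::as.data.table(calls)
  out <- list()
  for (d in unique(meta$donor_id)) {
    dm <- meta[meta$donor_id == d, ]
    clones <- dm$sample_id[dm$role == "clone"]
    bulks <- dm$sample_id[dm$role == "bulk"]
    out[[d]] <- call_shared_variants(calls[calls$donor == d, ], clones, bulks,
                                     meta, cfg)
  }
  out
}

#' Score filtered clonal SNVs against simulation truth
#'
#' Per clone-level definitions:
#' * a retained call is a true positive when the truth table lists the
#'   variant as in-vivo somatic (early or late) carried by that clone;
#'   germline, in-vitro, error or unknown calls are false positives;
#' * recall is computed over the recoverable truth set: in-vivo somatic
#'   variants of the clone with zero true bulk-cell fraction (the
#'   clone-vs-bulk design deliberately excludes variants genuinely present
#'   in bulk) at surveyed sites (DP >= `dp_min` in both clone and bulk);
#' * in-vitro rejection is the fraction of the clone's culture-acquired
#'   variants absent from the retained set.
#'
#' @param cohort A [simulate_embryo()] result.
#' @param clonal_sets Result of [cohort_clonal_sets()].
#' @param dp_min Depth defining "surveyed" (default 20).
#' @return List: `per_clone` (data.table), `precision`, `recall`,
#'   `germline_retained`, `invitro_rejected` (overall fractions).
#' @export
filtering_truth_stats <- function(cohort, clonal_sets, dp_min = 20) {
  truth <- cohort$truth
  calls <- cohort$calls
  meta <- cohort$meta
  ret <- data.table::as.data.table(clonal_sets)
  ret$key <- paste(ret$donor_id, site_key(ret))

  rows <- list()
  for (i in which(meta$role == "clone")) {
    clone <- meta$sample_id[i]; d <- meta$donor_id[i]
    bulk <- meta$sample_id[meta$donor_id == d & meta$role == "bulk"][1]
    tt <- truth[truth$donor == d, ]
    tkey <- paste(d, site_key(tt))
    carried <- vapply(strsplit(tt$carriers, ","), function(x) clone %in% x,
                      logical(1))
    somatic <- tt$class %in% c("early", "late") & carried
    rkey <- ret$key[ret$clone == clone]

    tp <- sum(rkey %in% tkey[somatic])
    fp <- length(rkey) - tp

    # surveyed, bulk-free truth for recall
    denom_keys <- tkey[somatic & tt$true_bulk_frac == 0]
    ck <- calls[calls$donor == d & calls$sample == clone, ]
    bk <- calls[calls$donor == d & calls$sample == bulk, ]
    ckey <- paste(d, site_key(ck)); bkey <- paste(d, site_key(bk))
    surveyed <- denom_keys[ck$dp[match(denom_keys, ckey)] >= dp_min &
                             bk$dp[match(denom_keys, bkey)] >= dp_min]
    rec <- if (length(surveyed)) sum(rkey %in% surveyed) / length(surveyed) else NA_real_

    germ_keys <- tkey[tt$class == "germline"]
    vitro_keys <- tkey[tt$class == "invitro" & carried]
    rows[[length(rows) + 1L]] <- data.table::data.table(
      clone = clone, donor = d,
      n_retained = length(rkey), tp = tp, fp = fp,
      n_truth_surveyed = length(surveyed),
      recall = rec,
      germline_retained = sum(rkey %in% germ_keys),
      invitro_total = length(vitro_keys),
      invitro_retained = sum(rkey %in% vitro_keys))
  }
  per_clone <- data.table::rbindlist(rows)
  list(
    per_clone = per_clone,
    precision = sum(per_clone$tp) / max(1, sum(per_clone$tp + per_clone$fp)),
    recall = sum(per_clone$recall * per_clone$n_truth_surveyed, na.rm = TRUE) /
      max(1, sum(per_clone$n_truth_surveyed)),
    germline_retained = sum(per_clone$germline_retained),
    invitro_rejected = 1 - sum(per_clone$invitro_retained) /
      max(1, sum(per_clone$invitro_total)))
}

#' Full lineage analysis of one donor
#'
#' Binary matrix, NJ tree rooted at the zero profile, branch assignment,
#' early-mutation set and branch contributions.
#'
#' @param shared_table Shared-variant table of the donor.
#' @param clonal_sets Clonal SNV calls of the donor (with `clone` column).
#' @param clones Clone sample ids.
#' @param exclude_contigs Contigs excluded from contribution estimates
#'   (e.g. the trisomy proxy for T21 donors).
#' @return List: `matrix`, `tree`, `assigned`, `early`, `contributions`.
#' @export
donor_lineage <- function(shared_table, clonal_sets, clones,
                          exclude_contigs = character(0)) {
  bm <- build_matrix(shared_table, clonal_sets, clones)
  tree <- build_tree(bm$matrix)
  assigned <- assign_branch_mutations(tree, bm$matrix)
  early <- early_mutations(shared_table)
  contributions <- branch_contribution(assigned, bm$mutations,
                                       exclude_contigs = exclude_contigs)
  list(matrix = bm$matrix, mutations = bm$mutations, tree = tree,
       assigned = assigned, early = early, contributions = contributions)
}
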