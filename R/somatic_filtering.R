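# Clone-versus-bulk somatic filtering: reduces raw calls to clonal somatic
# SNVs/indels per clone and to the shared-variant table used for lineage
# reconstruction. Filter order is fixed so per-stage attrition is reportable.

#' Filtering thresholds
#'
#' Defaults reproduce the published filter set: site QUAL >= 50 and MQ >= 60
#' for substitutions (QUAL >= 250 for indels), clone GQ >= 99 / VAF > 0.1,
#' bulk GQ >= 10 / VAF = 0 (zero alt reads), DP >= 20 in both, clonality cut
#' VAF >= 0.3 (>= 0.2 on the trisomic contig of T21 donors), male-X rule
#' VAF >= 0.99 with GQ >= 10 and DP >= 10 in both samples, indel GQ >= 99 in
#' both samples plus a 100 bp germline-indel exclusion zone.
#'
#' @param ... Named overrides of any default listed above.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(...) {
  cfg <- list(
    snv_qual_min = 50, mq_min = 60,
    clone_gq_min = 99, clone_vaf_min = 0.1,
    bulk_gq_min = 10, bulk_vaf_max = 0.0,
    dp_min = 20,
    clonal_vaf_min = 0.3, clonal_vaf_min_tri21 = 0.2,
    male_x_vaf_min = 0.99, male_x_gq_min = 10, male_x_dp_min = 10,
    indel_qual_min = 250, indel_gq_min = 99,
    germline_indel_flank_bp = 100,
    clonality_pass_weight = 0.7,
    clonality_precision = 60,
    missing_mq_fails = TRUE,
    trisomy_contig = "chr21", x_contig = "chrX"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown filter_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$clonal_vaf_min_tri21 >= cfg$clonal_vaf_min)
    stop("clonal_vaf_min_tri21 must be below clonal_vaf_min")
  structure(cfg, class = "filter_config")
}

is_sex_contig <- function(contig, cfg) {
  contig %in% c(cfg$x_contig, "chrY", "Y", "chrM", "MT")
}
is_x_contig <- function(contig, cfg) contig == cfg$x_contig

gt_has_alt <- function(gt) {
  !is.na(gt) & grepl("[1-9]", gt)
}

site_key <- function(x) paste(x$contig, x$pos, x$ref, x$alt, sep = ":")

donor_info <- function(sample, meta) {
  i <- match(sample, meta$sample_id)
  if (is.na(i)) stop("sample not in metadata: ", sample)
  list(donor = meta$donor_id[i], trisomy21 = isTRUE(meta$trisomy21[i] | {
    d <- meta$donor_id[i]; any(meta$trisomy21[meta$donor_id == d])
  }), sex = meta$sex[i][1])
}

# shared basic site-level gate masks (everything before the sample-level
# filters), as an ordered named list of logical vectors
basic_site_stages <- function(x, cfg, qual_min, exclusion, rescue_ids,
                              use_qual = TRUE) {
  n <- nrow(x)
  stages <- list(
    pass_filter = is.na(x$filter) | x$filter %in% c("PASS", "."),
    qual = if (use_qual) !is.na(x$qual) & x$qual >= qual_min else rep(TRUE, n),
    mq = if (cfg$missing_mq_fails) !is.na(x$mq) & x$mq >= cfg$mq_min
         else is.na(x$mq) | x$mq >= cfg$mq_min,
    single_alt = !x$multiallelic & !grepl(",", x$alt),
    autosome_or_x = !is_sex_contig(x$contig, cfg) | is_x_contig(x$contig, cfg)
  )
  if (!is.null(exclusion) && nrow(exclusion)) {
    excl <- site_key(x) %in% site_key(exclusion)
    if (!is.null(rescue_ids)) excl <- excl & !(x$id %in% rescue_ids)
    stages$exclusion_list <- !excl
  }
  stages
}

basic_site_pass <- function(x, cfg, qual_min, exclusion, rescue_ids,
                            use_qual = TRUE) {
  Reduce(`&`, basic_site_stages(x, cfg, qual_min, exclusion, rescue_ids, use_qual))
}

#' Filter clonal somatic SNVs for one clone against its bulk
#'
#' Applies, in order: candidate call in clone; SNV; caller PASS; QUAL; MQ;
#' single alt allele; exclusion list (with ID rescue); clone GQ/VAF/DP gates;
#' bulk GQ/VAF=0/DP gates; clonality cut (VAF >= 0.3, >= 0.2 on the trisomic
#' contig of T21 donors, male-X rule on X). Only autosomal and X variants are
#' retained. The per-stage attrition log is attached as attribute
#' `"attrition"`.
#'
#' @param records Long call table of the donor (clone and bulk rows present).
#' @param clone,bulk Sample names.
#' @param meta Metadata table (see [read_metadata()]).
#' @param cfg A [filter_config()].
#' @param exclusion Optional site exclusion table (contig, pos, ref, alt).
#' @param rescue_ids Optional IDs exempt from the exclusion list.
#' @return data.table of retained clone calls with bulk VAF attached.
#' @export
filter_clonal_snvs <- function(records, clone, bulk, meta, cfg = filter_config(),
                               exclusion = NULL, rescue_ids = NULL) {
  records <- data.table::as.data.table(records)
  cl <- records[records$sample == clone, ]
  if (!nrow(cl)) stop("clone sample absent from records: ", clone)
  bk <- records[records$sample == bulk, ]
  if (!nrow(bk)) stop("bulk sample absent from records: ", bulk)
  info <- donor_info(clone, meta)

  bk_idx <- match(site_key(cl), site_key(bk))
  cl$bulk_gq <- bk$gq[bk_idx]
  cl$bulk_dp <- bk$dp[bk_idx]
  cl$bulk_ad_alt <- bk$ad_alt[bk_idx]
  cl$bulk_ad_ref <- bk$ad_ref[bk_idx]
  cl$bulk_vaf <- bk$vaf[bk_idx]

  male_x <- is_x_contig(cl$contig, cfg) & info$sex == "M"
  gq_min <- ifelse(male_x, cfg$male_x_gq_min, cfg$clone_gq_min)
  dp_min <- ifelse(male_x, cfg$male_x_dp_min, cfg$dp_min)
  vaf_cut <- ifelse(male_x, cfg$male_x_vaf_min,
                    ifelse(info$trisomy21 & cl$contig == cfg$trisomy_contig,
                           cfg$clonal_vaf_min_tri21, cfg$clonal_vaf_min))

  stages <- c(
    list(candidate_in_clone = gt_has_alt(cl$gt),
         snv = nchar(cl$ref) == 1L & nchar(cl$alt) == 1L & !cl$multiallelic),
    basic_site_stages(cl, cfg, cfg$snv_qual_min, exclusion, rescue_ids),
    list(
      clone_gq_dp_vaf = !is.na(cl$gq) & cl$gq >= gq_min &
        !is.na(cl$dp) & cl$dp >= dp_min &
        !is.na(cl$vaf) & cl$vaf > cfg$clone_vaf_min,
      bulk_absent = !is.na(cl$bulk_gq) & cl$bulk_gq >= cfg$bulk_gq_min &
        !is.na(cl$bulk_dp) & cl$bulk_dp >= dp_min &
        !is.na(cl$bulk_ad_alt) & cl$bulk_ad_alt == 0L,
      clonality_cut = !is.na(cl$vaf) & cl$vaf >= vaf_cut
    )
  )
  keep <- rep(TRUE, nrow(cl))
  log <- list(input = nrow(cl))
  for (nm in names(stages)) {
    keep <- keep & stages[[nm]]
    log[[nm]] <- sum(keep)
  }

  out <- cl[keep, ]
  out$clone <- clone
  out$donor_id <- info$donor
  data.table::setattr(out, "attrition", log)
  out
}

#' Beta-binomial clonality check of a clone
#'
#' Fits a two-component beta-binomial mixture to the (alt count, depth)
#' pairs of the clone's candidate somatic variants by EM (component means
#' free, common precision fixed). The clone passes when the clonal component
#' (mean in \[0.35, 0.65\]) carries at least `clonality_pass_weight` of the
#' mass. This realizes the published (unspecified) "Dirichlet modelling"
#' clonality control and is deliberately swappable.
#'
#' @param alt,dp Alt read counts and depths of candidate somatic variants
#'   (>= 20 required). Supply copy-number-neutral sites only: hemizygous
#'   (male X) and trisomic-contig variants have shifted clonal VAFs and do
#'   not belong in the 0.5-centred clonal band.
#' @param cfg A [filter_config()].
#' @return List: `pass`, `weights`, `means`, `clonal_weight`, `converged`,
#'   `n`.
#' @export
clonality_check <- function(alt, dp, cfg = filter_config()) {
  stopifnot(length(alt) == length(dp))
  if (length(alt) < 20) stop("clonality_check requires >= 20 candidate variants")
  s <- cfg$clonality_precision
  ldbb <- function(k, n, p) {
    lchoose(n, k) + lbeta(k + p * s, n - k + (1 - p) * s) - lbeta(p * s, (1 - p) * s)
  }
  p <- c(0.5, 0.1); w <- c(0.5, 0.5)
  ll_old <- -Inf; converged <- FALSE
  for (it in 1:500) {
    l1 <- log(w[1]) + ldbb(alt, dp, p[1])
    l2 <- log(w[2]) + ldbb(alt, dp, p[2])
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    r1 <- 1 / (1 + exp(l2 - l1))
    w <- c(mean(r1), 1 - mean(r1))
    p[1] <- min(0.99, max(0.01, sum(r1 * alt) / max(sum(r1 * dp), 1e-9)))
    p[2] <- min(0.99, max(0.01, sum((1 - r1) * alt) / max(sum((1 - r1) * dp), 1e-9)))
    if (is.finite(ll) && abs(ll - ll_old) < 1e-7 * (abs(ll) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  in_band <- p >= 0.35 & p <= 0.65
  clonal_weight <- sum(w[in_band])
  pass <- converged && clonal_weight >= cfg$clonality_pass_weight
  list(pass = pass, weights = w, means = p, clonal_weight = clonal_weight,
       converged = converged, n = length(alt))
}

#' Call variants shared between clones of a donor
#'
#' From the pre-QUAL "somatic" candidate set (caller PASS, MQ, single alt,
#' exclusion list, autosome/X), each variant's clones are split by genotype
#' into present/absent; clone-grade gates (GQ/DP/VAF) are applied to the
#' present side, bulk-grade gates (GQ/DP/zero alt reads) to the absent side,
#' and the variant is retained when at least one clone qualifies on each
#' side. Bulk VAFs (0 when no alt reads) and allele counts are attached per
#' bulk sample.
#'
#' @param records Long call table of one donor.
#' @param clones,bulks Sample names.
#' @param meta Metadata table.
#' @param cfg A [filter_config()].
#' @param exclusion,rescue_ids Optional exclusion machinery as in
#'   [filter_clonal_snvs()].
#' @return data.table: one row per retained variant with `present`,
#'   `absent` (comma-joined clone ids) and `bulk_vaf` / `bulk_alt` /
#'   `bulk_ref` for the first bulk plus `.<sample>`-suffixed columns for all.
#' @export
call_shared_variants <- function(records, clones, bulks, meta,
                                 cfg = filter_config(),
                                 exclusion = NULL, rescue_ids = NULL) {
  if (length(clones) < 2) {
    warning("shared-variant calling undefined for a single clone; skipping")
    return(data.table::data.table())
  }
  records <- data.table::as.data.table(records)
  info <- donor_info(clones[1], meta)
  x <- records[records$sample %in% clones, ]
  is_snv <- nchar(x$ref) == 1L & nchar(x$alt) == 1L & !x$multiallelic
  x <- x[is_snv & basic_site_pass(x, cfg, 0, exclusion, rescue_ids,
                                  use_qual = FALSE), ]
  if (!nrow(x)) return(data.table::data.table())
  x$key <- site_key(x)
  cand_keys <- unique(x$key[gt_has_alt(x$gt)])
  x <- x[x$key %in% cand_keys, ]

  male_x <- is_x_contig(x$contig, cfg) & info$sex == "M"
  gq_min <- ifelse(male_x, cfg$male_x_gq_min, cfg$clone_gq_min)
  dp_min <- ifelse(male_x, cfg$male_x_dp_min, cfg$dp_min)
  x$present <- gt_has_alt(x$gt)
  x$present_pass <- x$present & !is.na(x$gq) & x$gq >= gq_min &
    !is.na(x$dp) & x$dp >= dp_min & !is.na(x$vaf) & x$vaf > cfg$clone_vaf_min
  x$absent_pass <- !x$present & !is.na(x$gq) & x$gq >= cfg$bulk_gq_min &
    !is.na(x$dp) & x$dp >= dp_min & !is.na(x$ad_alt) & x$ad_alt == 0L

  agg <- x[, list(
    contig = contig[1], pos = pos[1], ref = ref[1], alt = alt[1],
    present = paste(sort(sample[present]), collapse = ","),
    absent = paste(sort(sample[!present]), collapse = ","),
    n_present = sum(present), n_absent = sum(!present),
    ok = any(present_pass) && any(absent_pass)
  ), by = "key"]
  shared <- agg[agg$ok, !c("key", "ok"), with = FALSE]
  if (!nrow(shared)) return(shared)

  for (b in bulks) {
    bk <- records[records$sample == b, ]
    i <- match(site_key(shared), site_key(bk))
    av <- ifelse(!is.na(bk$ad_alt[i]) & bk$ad_alt[i] > 0,
                 bk$ad_alt[i] / (bk$ad_alt[i] + bk$ad_ref[i]), 0)
    shared[[paste0("bulk_vaf.", b)]] <- av
    shared[[paste0("bulk_alt.", b)]] <- ifelse(is.na(bk$ad_alt[i]), 0L, bk$ad_alt[i])
    shared[[paste0("bulk_ref.", b)]] <- ifelse(is.na(bk$ad_ref[i]), 0L, bk$ad_ref[i])
  }
  shared$bulk_vaf <- shared[[paste0("bulk_vaf.", bulks[1])]]
  shared$bulk_alt <- shared[[paste0("bulk_alt.", bulks[1])]]
  shared$bulk_ref <- shared[[paste0("bulk_ref.", bulks[1])]]
  shared[]
}

#' Filter clonal somatic indels for one clone
#'
#' Same pipeline as [filter_clonal_snvs()] with the indel-specific rules:
#' QUAL >= `indel_qual_min`, GQ >= `indel_gq_min` in both clone and bulk,
#' and exclusion of candidates within `germline_indel_flank_bp` of a called
#' germline indel.
#'
#' @inheritParams filter_clonal_snvs
#' @param germline_indels Optional data.frame(contig, pos); derived from the
#'   bulk genotypes when `NULL`.
#' @return data.table of retained clone indel calls.
#' @export
filter_indels <- function(records, clone, bulk, meta, cfg = filter_config(),
                          germline_indels = NULL, exclusion = NULL,
                          rescue_ids = NULL) {
  records <- data.table::as.data.table(records)
  cl <- records[records$sample == clone, ]
  if (!nrow(cl)) stop("clone sample absent from records: ", clone)
  bk <- records[records$sample == bulk, ]
  if (!nrow(bk)) stop("bulk sample absent from records: ", bulk)
  info <- donor_info(clone, meta)
  if (is.null(germline_indels)) {
    gi <- bk[gt_has_alt(bk$gt) & nchar(bk$ref) != nchar(bk$alt) &
               !bk$multiallelic, ]
    germline_indels <- gi[, c("contig", "pos")]
  }

  is_indel <- nchar(cl$ref) != nchar(cl$alt) & !cl$multiallelic
  cl <- cl[is_indel, ]
  if (!nrow(cl)) return(cl)
  bk_idx <- match(site_key(cl), site_key(bk))
  cl$bulk_gq <- bk$gq[bk_idx]; cl$bulk_dp <- bk$dp[bk_idx]
  cl$bulk_ad_alt <- bk$ad_alt[bk_idx]; cl$bulk_ad_ref <- bk$ad_ref[bk_idx]

  keep <- gt_has_alt(cl$gt) &
    basic_site_pass(cl, cfg, cfg$indel_qual_min, exclusion, rescue_ids)
  male_x <- is_x_contig(cl$contig, cfg) & info$sex == "M"
  dp_min <- ifelse(male_x, cfg$male_x_dp_min, cfg$dp_min)
  keep <- keep & !is.na(cl$gq) & cl$gq >= cfg$indel_gq_min &
    !is.na(cl$dp) & cl$dp >= dp_min &
    !is.na(cl$vaf) & cl$vaf > cfg$clone_vaf_min &
    !is.na(cl$bulk_gq) & cl$bulk_gq >= cfg$indel_gq_min &
    !is.na(cl$bulk_dp) & cl$bulk_dp >= dp_min &
    !is.na(cl$bulk_ad_alt) & cl$bulk_ad_alt == 0L
  vaf_cut <- ifelse(male_x, cfg$male_x_vaf_min,
                    ifelse(info$trisomy21 & cl$contig == cfg$trisomy_contig,
                           cfg$clonal_vaf_min_tri21, cfg$clonal_vaf_min))
  keep <- keep & cl$vaf >= vaf_cut

  if (nrow(germline_indels)) {
    near <- rep(FALSE, nrow(cl))
    for (ct in unique(germline_indels$contig)) {
      gp <- sort(germline_indels$pos[germline_indels$contig == ct])
      i <- which(cl$contig == ct)
      if (!length(i)) next
      lo <- findInterval(cl$pos[i], gp)
      d_lo <- ifelse(lo >= 1, cl$pos[i] - gp[pmax(lo, 1L)], Inf)
      d_hi <- ifelse(lo < length(gp), gp[pmin(lo + 1L, length(gp))] - cl$pos[i], Inf)
      near[i] <- pmin(d_lo, d_hi) <= cfg$germline_indel_flank_bp
    }
    keep <- keep & !near
  }
  out <- cl[keep, ]
  out$clone <- clone
  out$donor_id <- info$donor
  out
}

#' Flag candidate driver mutations
#'
#' A clonal variant is flagged when it carries a MODERATE or HIGH predicted
#' effect AND either its ID is in the rescue list (COSMIC stand-in) or its
#' gene is in the cancer-gene list. The flag is a report, never an exclusion.
#'
#' @param clonal_sets data.table of clonal variants with `effect`, `gene`,
#'   `id` columns.
#' @param cancer_gene_list Character vector of gene symbols.
#' @param rescue_ids Character vector of variant IDs.
#' @return Input with logical column `driver_candidate`.
#' @export
flag_driver_candidates <- function(clonal_sets, cancer_gene_list = character(0),
                                   rescue_ids = character(0)) {
  eff <- !is.na(clonal_sets$effect) &
    clonal_sets$effect %in% c("MODERATE", "HIGH")
  listed <- (!is.na(clonal_sets$id) & clonal_sets$id %in% rescue_ids) |
    (!is.na(clonal_sets$gene) & clonal_sets$gene %in% cancer_gene_list)
  out <- data.table::copy(clonal_sets)
  out$driver_candidate <- eff & listed
  out[]
}

#' Count double base substitutions per clone
#'
#' A DBS is a pair of clonal SNVs at consecutive positions on one contig in
#' one clone. A DBS observed in several clones of the same donor is credited
#' to a single clone (the first in sample-ID order), so donor totals are not
#' inflated by shared events.
#'
#' @param clonal_sets data.table of clonal SNVs with columns `clone`
#'   (sample), `donor_id`, `contig`, `pos`, `ref`, `alt`.
#' @return data.table: clone, donor_id, n_dbs (zero-filled for all clones
#'   present in `clonal_sets`).
#' @export
count_dbs <- function(clonal_sets) {
  clonal_sets <- data.table::as.data.table(clonal_sets)
  x <- clonal_sets[nchar(clonal_sets$ref) == 1 & nchar(clonal_sets$alt) == 1, ]
  clones <- unique(clonal_sets[, c("clone", "donor_id")])
  if (!nrow(x)) {
    clones$n_dbs <- 0L
    return(clones[])
  }
  x <- x[order(x$clone, x$contig, x$pos), ]
  dbs <- x[, {
    d <- which(diff(pos) == 1L & contig[-1] == contig[-.N])
    if (length(d)) list(contig = contig[d], pos = pos[d],
                        ref2 = paste0(ref[d], ref[d + 1L]),
                        alt2 = paste0(alt[d], alt[d + 1L]))
    else list(contig = character(0), pos = integer(0),
              ref2 = character(0), alt2 = character(0))
  }, by = c("clone", "donor_id")]
  if (nrow(dbs)) {
    dbs <- dbs[order(dbs$clone), ]
    dbs <- dbs[!duplicated(dbs[, c("donor_id", "contig", "pos", "ref2", "alt2")]), ]
  }
  counts <- dbs[, list(n_dbs = .N), by = c("clone", "donor_id")]
  out <- merge(clones, counts, by = c("clone", "donor_id"), all.x = TRUE)
  out$n_dbs[is.na(out$n_dbs)] <- 0L
  out[order(out$clone)]
}
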