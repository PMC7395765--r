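# Reading and writing the standard formats the pipeline touches, and
# normalization into the internal long call table:
# one row per variant x sample with columns
#   donor?, contig, pos, ref, alt, id, qual, mq, filter, multiallelic,
#   effect, gene, sample, gt, gq, dp, ad_ref, ad_alt, vaf
# Coordinates are 1-based inclusive (VCF convention). VAF is always
# recomputed from AD, never trusted from the file.

#' Read a VCF into the internal call table
#'
#' Accepts plain or bgzipped VCFv4.x with FORMAT fields GT, GQ, DP, AD.
#' Multi-allelic rows are retained but flagged (`multiallelic = TRUE`, alt
#' holds the comma-joined alleles); downstream filtering removes them.
#' Site MQ is taken from INFO (NA when absent). Optional snpEff-style
#' annotation (`ANN=...`) populates `effect` and `gene` when parseable.
#'
#' @param path VCF path.
#' @param sample_filter Optional character vector of sample names to keep.
#' @return data.table in the internal long call layout.
#' @export
read_vcf <- function(path, sample_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  n <- nrow(fx)
  if (n == 0) stop("empty VCF: ", path)
  fmt_keys <- unique(unlist(strsplit(unname(v@gt[, "FORMAT"]), ":")))
  for (f in c("GT", "GQ", "DP", "AD")) {
    if (!f %in% fmt_keys)
      stop("missing required FORMAT field ", f, " in ", path)
  }
  pos <- as.integer(fx$POS)
  for (ct in unique(fx$CHROM)) {
    p <- pos[fx$CHROM == ct]
    if (is.unsorted(p)) {
      warning("unsorted VCF positions on ", ct, " in ", path)
      break
    }
  }
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_filter)) {
    missing <- setdiff(sample_filter, samples)
    if (length(missing))
      stop("samples not in VCF: ", paste(missing, collapse = ", "))
    samples <- intersect(samples, sample_filter)
  }
  gt <- vcfR::extract.gt(v, "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, "AD")
  info <- fx$INFO
  mq <- suppressWarnings(as.numeric(sub(".*MQ=([0-9.e+-]+).*", "\\1", info)))
  mq[!grepl("(^|;)MQ=", info)] <- NA_real_
  eff <- rep(NA_character_, n); gene <- rep(NA_character_, n)
  has_ann <- grepl("(^|;)ANN=", info)
  if (any(has_ann)) {
    ann <- sub(".*(?:^|;)ANN=([^;]*).*", "\\1", info[has_ann])
    parts <- strsplit(ann, "\\|")
    eff[has_ann] <- vapply(parts, function(x) if (length(x) >= 3) x[3] else NA_character_, character(1))
    gene[has_ann] <- vapply(parts, function(x) if (length(x) >= 4) x[4] else NA_character_, character(1))
  }
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    adr <- ad[, s]
    ad2 <- data.table::tstrsplit(ifelse(is.na(adr), "NA,NA", adr), ",")
    ad_ref <- suppressWarnings(as.integer(ad2[[1]]))
    ad_alt <- if (length(ad2) >= 2) suppressWarnings(as.integer(ad2[[2]])) else NA_integer_
    out[[k]] <- data.table::data.table(
      contig = fx$CHROM, pos = pos, ref = fx$REF, alt = fx$ALT,
      id = ifelse(is.na(fx$ID), ".", fx$ID),
      qual = suppressWarnings(as.numeric(fx$QUAL)),
      mq = mq,
      filter = ifelse(is.na(fx$FILTER) | fx$FILTER == ".", "PASS", fx$FILTER),
      multiallelic = grepl(",", fx$ALT),
      effect = eff, gene = gene,
      sample = s,
      gt = gt[, s],
      gq = as.integer(gq[, s]),
      dp = as.integer(dp[, s]),
      ad_ref = ad_ref, ad_alt = ad_alt
    )
  }
  calls <- data.table::rbindlist(out)
  denom <- calls$ad_ref + calls$ad_alt
  calls$vaf <- ifelse(!is.na(denom) & denom > 0, calls$ad_alt / denom, NA_real_)
  calls[]
}

#' Write a single-sample VCF from the internal call table
#'
#' Emits VCFv4.2 with FORMAT `GT:GQ:DP:AD` and site `MQ` in INFO; one row per
#' variant, calls taken from the rows of `calls` belonging to `sample`.
#'
#' @param calls Internal long call table.
#' @param sample Sample name to export.
#' @param path Output path.
#' @param contigs Optional data.frame(contig, length) for header contig lines.
#' @export
write_vcf <- function(calls, sample, path, contigs = NULL) {
  sel <- calls[["sample"]] == sample
  x <- calls[sel, ]
  if (nrow(x) == 0) stop("no calls for sample ", sample)
  x <- x[order(x$contig, x$pos), ]
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=fetallineage",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", contigs$contig, as.integer(contigs$length)),
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- paste(
    x$contig, x$pos, ifelse(is.na(x$id) | x$id == "", ".", x$id),
    x$ref, x$alt,
    ifelse(is.na(x$qual), ".", format(x$qual, trim = TRUE, scientific = FALSE)),
    ifelse(is.na(x$filter), "PASS", x$filter),
    ifelse(is.na(x$mq), ".", paste0("MQ=", format(x$mq, trim = TRUE))),
    "GT:GQ:DP:AD",
    paste0(x$gt, ":", x$gq, ":", x$dp, ":", x$ad_ref, ",", x$ad_alt),
    sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns sample_id, donor_id, role (clone|bulk),
#' cell_type, trisomy21, sex, age_since_conception.
#'
#' @param path TSV path.
#' @return data.table.
#' @export
read_metadata <- function(path) {
  m <- data.table::fread(path, sep = "\t")
  need <- c("sample_id", "donor_id", "role", "cell_type", "trisomy21", "sex",
            "age_since_conception")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  m$trisomy21 <- as.logical(m$trisomy21)
  if (any(m$age_since_conception <= 0)) stop("ages must be positive")
  bulkless <- setdiff(m$donor_id, m$donor_id[m$role == "bulk"])
  if (length(bulkless))
    stop("donor without a bulk sample: ", paste(bulkless, collapse = ", "))
  m[]
}

#' Write a simulated cohort to disk
#'
#' One VCF per clone and per bulk sample (each containing all candidate
#' sites of its donor), the reference FASTA with a .fai index, the sample
#' metadata TSV and the per-variant truth TSV.
#'
#' @param cohort A [simulate_embryo()] result.
#' @param directory Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  ok <- dir.exists(directory) && file.access(directory, 2) == 0
  if (!ok) stop("directory not writable: ", directory)

  fa_path <- file.path(directory, "reference.fa")
  Biostrings::writeXStringSet(cohort$genome$seqs, fa_path)
  Rsamtools::indexFa(fa_path)

  vcfs <- character(0)
  for (s in cohort$meta$sample_id) {
    p <- file.path(directory, paste0(s, ".vcf"))
    donor <- cohort$meta$donor_id[cohort$meta$sample_id == s]
    write_vcf(cohort$calls[cohort$calls$donor == donor, ], s, p,
              contigs = cohort$genome$contigs)
    vcfs <- c(vcfs, p)
  }
  meta_path <- file.path(directory, "metadata.tsv")
  data.table::fwrite(cohort$meta, meta_path, sep = "\t")
  truth_path <- file.path(directory, "truth_variants.tsv")
  data.table::fwrite(cohort$truth, truth_path, sep = "\t")
  invisible(list(fasta = fa_path, vcfs = vcfs, metadata = meta_path,
                 truth = truth_path))
}

#' Truth tables of a simulated cohort
#'
#' @param cohort A [simulate_embryo()] result.
#' @return List: `loads` (per-clone true in-vivo somatic load, split early /
#'   late), `trees` (named character vector of true Newick strings),
#'   `branch_contributions` (per-donor true branch table: clade, mutation
#'   count, true bulk-cell fraction, first-branch flag).
#' @export
true_summary <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  tr <- cohort$truth[cohort$truth$class %in% c("early", "late"), ]
  carr <- strsplit(tr$carriers, ",")
  loads <- data.table::data.table(
    clone = unlist(carr),
    class = rep(tr$class, lengths(carr)))
  loads <- loads[, list(n = .N), by = c("clone", "class")]
  loads <- data.table::dcast(loads, clone ~ class, value.var = "n", fill = 0L)
  if (!"early" %in% names(loads)) loads$early <- 0L
  if (!"late" %in% names(loads)) loads$late <- 0L
  loads$true_load <- loads$early + loads$late

  trees <- vapply(cohort$trees, function(t) t$newick, character(1))
  bc <- data.table::rbindlist(lapply(names(cohort$trees), function(d) {
    b <- data.table::copy(cohort$trees[[d]]$branches)
    b$donor <- d
    b
  }))
  list(loads = loads[], trees = trees, branch_contributions = bc[])
}
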