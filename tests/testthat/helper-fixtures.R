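# Shared fixtures: tiny genomes, hand-built call tables and independent
# oracles used across the test files. Everything is generated in code.

# small deterministic genome reused by io/spectrum tests
tiny_genome <- function(seed = 42) {
  simulate_genome(data.frame(contig = c("chr1", "chr2"), length = c(5000L, 4000L)),
                  callable_fraction = 0.9, seed = seed)
}

# one internal-format call row with overridable fields
call_row <- function(...) {
  base <- list(
    donor = "N01", contig = "chr1", pos = 100L, ref = "A", alt = "T",
    id = ".", qual = 200, mq = 60, filter = "PASS", multiallelic = FALSE,
    effect = NA_character_, gene = NA_character_,
    sample = "N01-H1", gt = "0/1", gq = 99L, dp = 30L,
    ad_ref = 15L, ad_alt = 15L)
  over <- list(...)
  base[names(over)] <- over
  base$vaf <- if (base$ad_ref + base$ad_alt > 0)
    base$ad_alt / (base$ad_ref + base$ad_alt) else NA_real_
  data.table::as.data.table(base)
}

calls_table <- function(...) data.table::rbindlist(list(...), fill = TRUE)

# matching two-sample (clone + bulk) records for one variant
pair_rows <- function(clone = "N01-H1", bulk = "N01-BULK", contig = "chr1",
                      pos = 100L, ref = "A", alt = "T",
                      clone_args = list(), bulk_args = list()) {
  cl <- do.call(call_row, c(list(sample = clone, contig = contig, pos = pos,
                                 ref = ref, alt = alt), clone_args))
  bk_base <- list(sample = bulk, contig = contig, pos = pos, ref = ref,
                  alt = alt, gt = "0/0", gq = 30L, dp = 25L,
                  ad_ref = 25L, ad_alt = 0L)
  bk_base[names(bulk_args)] <- bulk_args
  bk <- do.call(call_row, bk_base)
  calls_table(cl, bk)
}

test_meta <- function(donor = "N01", clones = c("N01-H1", "N01-H2"),
                      bulk = "N01-BULK", trisomy21 = FALSE, sex = "F",
                      age = 0.25) {
  data.table::data.table(
    sample_id = c(clones, bulk), donor_id = donor,
    role = c(rep("clone", length(clones)), "bulk"),
    cell_type = c(rep("HSPC", length(clones)), "other"),
    trisomy21 = trisomy21, sex = sex, age_since_conception = age)
}

# --- independent oracles -------------------------------------------------

# all clades (as sorted comma strings) of a rooted phylo, root tip excluded
phylo_clades <- function(tree) {
  cl <- edge_sets <- lapply(fetallineage:::edge_clades(tree), function(x)
    paste(sort(x), collapse = ","))
  unique(unlist(cl))
}

# exhaustive perfect-phylogeny oracle: enumerate all rooted topologies and
# keep those on which every carrier set is a clade
perfect_phylogeny_oracle <- function(mat) {
  stopifnot(nrow(mat) <= 6)
  carriers <- unique(apply(mat, 2, function(col)
    paste(sort(rownames(mat)[col > 0]), collapse = ",")))
  carriers <- setdiff(carriers, "")
  tops <- phangorn::allTrees(nrow(mat), rooted = TRUE,
                             tip.label = rownames(mat))
  compatible <- Filter(function(tr) {
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    clades <- c(vapply(parts, function(p) paste(sort(labs[p]), collapse = ","),
                       character(1)),
                labs)  # singletons
    all(carriers %in% clades)
  }, tops)
  compatible
}

# exact two-sided rank-sum p-value by enumeration (midranks for ties)
exact_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  combos <- utils::combn(length(r), n1)
  sums <- apply(combos, 2, function(i) sum(r[i]))
  w_obs <- sum(r[seq_len(n1)])
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact two-sided Fisher p via hypergeometric enumeration
exact_fisher_p <- function(a11, a12, a21, a22) {
  m <- a11 + a21; n <- a12 + a22; k <- a11 + a12
  xs <- max(0, k - n):min(k, m)
  d <- stats::dhyper(xs, m, n, k)
  sum(d[d <= stats::dhyper(a11, m, n, k) * (1 + 1e-7)])
}
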