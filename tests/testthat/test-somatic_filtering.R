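# Somatic filtering: gate-by-gate behavior, clonality EM, shared-variant
# calling, indel rules, driver flags, DBS counting.

test_that("clonal SNV gates retain and reject exactly as specified", {
  meta <- test_meta()
  keep_pair <- pair_rows()      # VAF 0.5 / GQ 99 / DP 30; bulk clean
  expect_equal(nrow(filter_clonal_snvs(keep_pair, "N01-H1", "N01-BULK", meta)), 1)

  cases <- list(
    list(clone_args = list(ad_ref = 26L, ad_alt = 4L)),             # VAF 0.13 < 0.3 clonality cut
    list(clone_args = list(qual = 40)),                             # QUAL < 50
    list(clone_args = list(mq = 50)),                               # MQ < 60
    list(clone_args = list(mq = NA_real_)),                         # missing MQ conservative
    list(clone_args = list(gq = 90L)),                              # clone GQ < 99
    list(clone_args = list(dp = 15L, ad_ref = 7L, ad_alt = 8L)),    # clone DP < 20
    list(clone_args = list(alt = "T,G", multiallelic = TRUE)),      # multi-allelic
    list(clone_args = list(filter = "LowQual")),                    # caller fail
    list(bulk_args = list(ad_alt = 1L, ad_ref = 24L)),              # bulk alt reads
    list(bulk_args = list(gq = 5L)),                                # bulk GQ < 10
    list(bulk_args = list(dp = 12L, ad_ref = 12L))                  # bulk DP < 20
  )
  for (k in seq_along(cases)) {
    pr <- do.call(pair_rows, cases[[k]])
    expect_equal(nrow(filter_clonal_snvs(pr, "N01-H1", "N01-BULK", meta)), 0,
                 info = paste("case", k))
  }

  # attrition log is cumulative and ends at the retained count
  res <- filter_clonal_snvs(calls_table(keep_pair, do.call(pair_rows, c(
    list(pos = 200L), cases[[1]]))), "N01-H1", "N01-BULK", meta)
  log <- attr(res, "attrition")
  expect_equal(log$candidate_in_clone, 2)
  expect_equal(log$clonality_cut, nrow(res))
})

test_that("T21 chromosome-21 and male-X rules override the clonality cut", {
  meta_t21 <- test_meta(donor = "T01", clones = "T01-H1", bulk = "T01-BULK",
                        trisomy21 = TRUE, sex = "M")
  # chr21 VAF 0.25 retained in a T21 clone, rejected in a D21 clone
  pr <- pair_rows(clone = "T01-H1", bulk = "T01-BULK", contig = "chr21",
                  clone_args = list(ad_ref = 22L, ad_alt = 8L))
  expect_equal(nrow(filter_clonal_snvs(pr, "T01-H1", "T01-BULK", meta_t21)), 1)
  meta_d21 <- test_meta(donor = "T01", clones = "T01-H1", bulk = "T01-BULK",
                        trisomy21 = FALSE, sex = "M")
  expect_equal(nrow(filter_clonal_snvs(pr, "T01-H1", "T01-BULK", meta_d21)), 0)

  # male X: hemizygous VAF ~1 with GQ >= 10 and DP >= 10 both samples passes
  prx <- pair_rows(clone = "T01-H1", bulk = "T01-BULK", contig = "chrX",
                   clone_args = list(gt = "1/1", gq = 20L, dp = 12L,
                                     ad_ref = 0L, ad_alt = 12L),
                   bulk_args = list(dp = 11L, ad_ref = 11L))
  expect_equal(nrow(filter_clonal_snvs(prx, "T01-H1", "T01-BULK", meta_t21)), 1)
  # het-like X VAF 0.5 fails the 0.99 male rule
  prx2 <- pair_rows(clone = "T01-H1", bulk = "T01-BULK", contig = "chrX")
  expect_equal(nrow(filter_clonal_snvs(prx2, "T01-H1", "T01-BULK", meta_t21)), 0)
})

test_that("exclusion list removes sites unless the ID is rescued", {
  meta <- test_meta()
  pr <- pair_rows(clone_args = list(id = "COSM1"))
  excl <- data.frame(contig = "chr1", pos = 100L, ref = "A", alt = "T")
  expect_equal(nrow(filter_clonal_snvs(pr, "N01-H1", "N01-BULK", meta,
                                       exclusion = excl)), 0)
  expect_equal(nrow(filter_clonal_snvs(pr, "N01-H1", "N01-BULK", meta,
                                       exclusion = excl,
                                       rescue_ids = "COSM1")), 1)
})

test_that("raising any threshold never grows the retained set", {
  cfg0 <- cohort_config(n_donors_d21 = 1, n_donors_t21 = 0,
                        clones_per_donor = 2, n_germline = 100,
                        n_invitro = 20, error_rate = 1e-4,
                        genome = data.frame(contig = c("chr1", "chr21", "chrX"),
                                            length = 200000L), seed = 31)
  coh <- simulate_embryo(cfg0)
  rec <- coh$calls
  base <- filter_clonal_snvs(rec, "N01-H1", "N01-BULK", coh$meta)
  for (raise in list(filter_config(snv_qual_min = 300),
                     filter_config(mq_min = 61),
                     filter_config(dp_min = 28),
                     filter_config(clonal_vaf_min = 0.45),
                     filter_config(clone_gq_min = 100),
                     filter_config(bulk_gq_min = 26))) {
    tighter <- filter_clonal_snvs(rec, "N01-H1", "N01-BULK", coh$meta, raise)
    expect_true(all(site_key <- fetallineage:::site_key(tighter) %in%
                      fetallineage:::site_key(base)))
    expect_lte(nrow(tighter), nrow(base))
  }
})

test_that("clonality EM recovers clonal, subclonal and mixed clones", {
  set.seed(11)
  dp <- rpois(200, 30) + 1L
  # all clonal at 0.5 -> pass with dominant clonal weight
  r1 <- clonality_check(rbinom(200, dp, 0.5), dp)
  expect_true(r1$pass)
  expect_gt(r1$clonal_weight, 0.95)
  # all subclonal at 0.1 -> fail
  r2 <- clonality_check(rbinom(200, dp, 0.1), dp)
  expect_false(r2$pass)
  # 50/50 mixture -> weights ~ 0.5/0.5, fails the 0.7 rule
  vafs <- c(rep(0.5, 100), rep(0.1, 100))
  r3 <- clonality_check(rbinom(200, dp, vafs), dp)
  expect_false(r3$pass)
  expect_equal(r3$clonal_weight, 0.5, tolerance = 0.12)
  expect_equal(sort(r3$means), c(0.1, 0.5), tolerance = 0.05)
  expect_error(clonality_check(1:5, rep(30, 5)), ">= 20")
})

test_that("shared-variant calling requires one confident present and absent clone", {
  meta <- test_meta(clones = c("N01-H1", "N01-H2", "N01-H3"))
  mk <- function(pos, gts, gqs, vafs, dps = rep(30L, 3), bulk_alt = 0L) {
    rows <- lapply(1:3, function(i) {
      adl <- round(dps[i] * vafs[i])
      call_row(pos = pos, sample = paste0("N01-H", i), gt = gts[i],
               gq = gqs[i], dp = dps[i], ad_ref = dps[i] - adl, ad_alt = adl)
    })
    rows$bulk <- call_row(pos = pos, sample = "N01-BULK", gt = "0/0",
                          gq = 30L, dp = 30L, ad_ref = 30L - bulk_alt,
                          ad_alt = bulk_alt)
    data.table::rbindlist(rows)
  }
  rec <- data.table::rbindlist(list(
    # present {H1,H2}: H1 confident; absent {H3} confident -> retained
    mk(100L, c("0/1", "0/1", "0/0"), c(99L, 50L, 40L), c(0.5, 0.4, 0)),
    # alt in all clones, nobody absent -> dropped
    mk(200L, c("0/1", "0/1", "0/1"), c(99L, 99L, 99L), c(0.5, 0.5, 0.5)),
    # present clone fails clone-grade gates -> dropped
    mk(300L, c("0/1", "0/0", "0/0"), c(50L, 40L, 40L), c(0.5, 0, 0)),
    # bulk VAF recorded from AD (3/30 = 0.1)
    mk(400L, c("0/1", "0/0", "0/0"), c(99L, 40L, 40L), c(0.5, 0, 0),
       bulk_alt = 3L)))
  sh <- call_shared_variants(rec, c("N01-H1", "N01-H2", "N01-H3"),
                             "N01-BULK", meta)
  expect_equal(sort(sh$pos), c(100L, 400L))
  expect_equal(sh$present[sh$pos == 100], "N01-H1,N01-H2")
  expect_equal(sh$absent[sh$pos == 100], "N01-H3")
  expect_equal(sh$bulk_vaf[sh$pos == 400], 0.1)
  expect_equal(sh$bulk_vaf[sh$pos == 100], 0)

  expect_warning(call_shared_variants(rec, "N01-H1", "N01-BULK", meta),
                 "single clone")
})

test_that("indel filtering applies QUAL 250, GQ 99 both sides and the 100 bp zone", {
  meta <- test_meta()
  mk_indel <- function(pos, qual = 300, bulk_gq = 99L, clone_gq = 99L) {
    pair_rows(pos = pos, ref = "A", alt = "AT",
              clone_args = list(qual = qual, gq = clone_gq),
              bulk_args = list(qual = qual, gq = bulk_gq))
  }
  # germline indel at chr1:1000 (bulk genotype non-ref)
  germ <- pair_rows(pos = 1000L, ref = "G", alt = "GAA",
                    clone_args = list(gt = "0/1"),
                    bulk_args = list(gt = "0/1", gq = 99L, ad_ref = 15L,
                                     ad_alt = 15L))
  rec <- calls_table(mk_indel(300L), mk_indel(1040L), mk_indel(5000L, qual = 200),
                     mk_indel(7000L, bulk_gq = 50L), germ)
  got <- filter_indels(rec, "N01-H1", "N01-BULK", meta)
  # 300 survives (700 bp from germline indel); 1040 within 100 bp; 5000 QUAL
  # below 250; 7000 bulk GQ below 99; the germline indel itself has bulk alt
  expect_equal(got$pos, 300L)
})

test_that("driver flags need MODERATE/HIGH effect and a listed gene or ID", {
  cs <- data.table::data.table(
    clone = "c", contig = "chr1", pos = 1:4, ref = "A", alt = "T",
    effect = c("HIGH", "HIGH", "LOW", "MODERATE"),
    gene = c("GATA1", "OTHER", "GATA1", "OTHER"),
    id = c(".", ".", "COSM9", "COSM9"))
  got <- flag_driver_candidates(cs, cancer_gene_list = "GATA1",
                                rescue_ids = "COSM9")
  expect_equal(got$driver_candidate, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("DBS counting uses adjacency and donor-level deduplication", {
  cs <- data.table::data.table(
    clone = c("A", "A", "A", "A", "B", "B"),
    donor_id = "N01",
    contig = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1"),
    pos = c(100L, 101L, 200L, 202L, 100L, 101L),
    ref = c("C", "T", "A", "A", "C", "T"),
    alt = c("A", "G", "T", "T", "A", "G"))
  got <- count_dbs(cs)
  # chr1:100-101 adjacent pair shared by A and B -> credited once (to A);
  # 200/202 not adjacent
  expect_equal(got$n_dbs[got$clone == "A"], 1L)
  expect_equal(got$n_dbs[got$clone == "B"], 0L)
  expect_equal(sum(got$n_dbs), 1L)

  # different donors are counted independently
  cs2 <- data.table::copy(cs); cs2$donor_id <- c(rep("N01", 4), "N02", "N02")
  got2 <- count_dbs(cs2)
  expect_equal(sum(got2$n_dbs), 2L)
})
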