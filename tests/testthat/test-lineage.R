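# Lineage reconstruction: matrix construction, NJ tree vs perfect-phylogeny
# oracle, branch assignment, early mutations, contributions, Fisher and
# Newick round trips.

shared_row <- function(pos, present, absent, bulk_vaf = 0, bulk_alt = 0L,
                       bulk_ref = 30L, contig = "chr1") {
  data.table::data.table(
    contig = contig, pos = pos, ref = "A", alt = "T",
    present = paste(present, collapse = ","),
    absent = paste(absent, collapse = ","),
    n_present = length(present), n_absent = length(absent),
    bulk_vaf = bulk_vaf, bulk_alt = bulk_alt, bulk_ref = bulk_ref)
}

clonal_rows <- function(clone, pos, contig = "chr1") {
  data.table::data.table(clone = clone, contig = contig, pos = pos,
                         ref = "A", alt = "T")
}

test_that("binary matrix unions clonal and shared variants and appends the root row", {
  clones <- c("A", "B")
  sh <- data.table::rbindlist(list(
    shared_row(1L, "A", "B"), shared_row(2L, "A", "B"), shared_row(3L, "B", "A")))
  cs <- data.table::rbindlist(list(clonal_rows("A", 10:14), clonal_rows("B", 20:23)))
  bm <- build_matrix(sh, cs, clones)
  expect_equal(dim(bm$matrix), c(3L, 12L))
  expect_equal(rownames(bm$matrix)[3], "root")
  expect_true(all(bm$matrix["root", ] == 0))

  # all-present shared variant gives a column of ones over the clones
  sh2 <- rbind(sh, shared_row(4L, c("A", "B"), character(0), bulk_vaf = 0.45))
  bm2 <- build_matrix(sh2, cs, clones)
  col <- bm2$matrix[, paste("chr1", 4, "A", "T", sep = ":")]
  expect_equal(unname(col), c(1L, 1L, 0L))

  # disjoint private sets -> block pattern, no shared columns
  bm3 <- build_matrix(data.table::data.table(), cs, clones)
  expect_equal(sum(bm3$matrix["A", ] * bm3$matrix["B", ]), 0)
})

test_that("NJ tree matches the perfect-phylogeny oracle on conflict-free matrices", {
  sm <- simulate_mutation_matrix(n_clones = 5, lambda = 7, min_mut = 5, seed = 3)
  mat <- rbind(sm$matrix, root = 0L)
  tr <- build_tree(mat)
  compatible <- perfect_phylogeny_oracle(sm$matrix)
  expect_length(compatible, 1)   # branch counts >= 5 make the topology unique
  expect_equal(phangorn::RF.dist(ape::unroot(ape::drop.tip(tr, "root")),
                                 ape::unroot(compatible[[1]])), 0)
  # and equals the generating topology
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(sm$tree)), 0)

  # branch assignment reproduces the per-clade mutation counts
  asg <- assign_branch_mutations(tr, mat)
  expect_length(asg$conflicts, 0)
  merged <- merge(asg$branches[asg$branches$n_mutations > 0, ],
                  sm$branches, by = "clade")
  expect_equal(merged$n_mutations.x, merged$n_mutations.y)
  # conservation: assigned + conflicts = all columns
  expect_equal(sum(asg$branches$n_mutations) + length(asg$conflicts), ncol(mat))
})

test_that("example topologies, star trees and conflicts behave as specified", {
  # ((A,B),(C,D)) with internal branches 5 and 7
  mat <- cbind(
    matrix(rep(c(1, 1, 0, 0), 5), 4), matrix(rep(c(0, 0, 1, 1), 7), 4),
    diag(4)[, rep(1:4, each = 10)])
  rownames(mat) <- c("A", "B", "C", "D")
  colnames(mat) <- sprintf("m%02d", seq_len(ncol(mat)))
  tr <- build_tree(rbind(mat, root = 0))
  asg <- assign_branch_mutations(tr, rbind(mat, root = 0))
  expect_equal(asg$branches$n_mutations[asg$branches$clade == "A,B"], 5)
  expect_equal(asg$branches$n_mutations[asg$branches$clade == "C,D"], 7)
  expect_length(asg$conflicts, 0)

  # incompatible carrier set {A,C} is a conflict and excluded from lengths
  mat2 <- cbind(mat, conflict = c(1, 0, 1, 0))
  asg2 <- assign_branch_mutations(tr, rbind(mat2, root = 0))
  expect_equal(asg2$conflicts, "conflict")
  expect_equal(sum(asg2$branches$n_mutations), ncol(mat))

  # all-zero matrix -> star tree with zero lengths
  mz <- matrix(0L, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("x", "y")))
  expect_error(build_matrix(data.table::data.table(), clonal_rows("A", integer(0)),
                            c("A", "B")), "no mutations")
  trz <- build_tree(rbind(mz, root = 0L))
  expect_s3_class(trz, "phylo")
  expect_true(all(trz$edge.length == 0))

  # trunk column of ones maps to the branch above the full clone clade
  mat3 <- cbind(mat, trunk = 1)
  tr3 <- build_tree(rbind(mat3, root = 0))
  asg3 <- assign_branch_mutations(tr3, rbind(mat3, root = 0))
  expect_equal(asg3$branches$n_mutations[asg3$branches$clade == "A,B,C,D"], 1)
  # private mutations sit on terminal branches
  expect_equal(asg3$branches$n_mutations[asg3$branches$clade == "A"], 10)
})

test_that("early mutations are the shared variants with nonzero bulk VAF", {
  sh <- data.table::rbindlist(list(
    shared_row(1L, c("A", "B"), "C", bulk_vaf = 0.45, bulk_alt = 14L, bulk_ref = 16L),
    shared_row(2L, c("A", "C"), "B", bulk_vaf = 0.2, bulk_alt = 6L, bulk_ref = 24L),
    shared_row(3L, "A", c("B", "C"), bulk_vaf = 0)))
  em <- early_mutations(sh)
  expect_equal(sort(em$early$pos), c(1L, 2L))
  expect_equal(em$per_clone$early_load[em$per_clone$clone == "A"], 2L)
  expect_equal(em$per_clone$early_load[em$per_clone$clone == "B"], 1L)
  expect_error(early_mutations(sh, bulk_vaf_col = "bulk_vaf.skin"), "bulk")
})

test_that("branch contributions follow the 2 x median rule with subdivision", {
  clones <- c("A", "B")
  # one internal branch with three contributing mutations at VAF 0.25
  sh <- data.table::rbindlist(list(
    shared_row(1L, c("A", "B"), character(0), 0.25, 10L, 30L),
    shared_row(2L, c("A", "B"), character(0), 0.25, 11L, 29L),
    shared_row(3L, c("A", "B"), character(0), 0.25, 9L, 31L),
    shared_row(4L, "A", "B", 0.2, 6L, 24L),
    shared_row(5L, "A", "B", 0.3, 9L, 21L),
    shared_row(6L, "A", "B", 0)))
  bm <- build_matrix(sh, NULL, clones)
  tr <- build_tree(bm$matrix)
  asg <- assign_branch_mutations(tr, bm$matrix)
  bc <- branch_contribution(asg, bm$mutations)

  trunk <- bc[bc$clade == "A,B", ]
  expect_equal(trunk$contribution, 0.5)            # 2 x median(0.25)
  expect_false(trunk$subdivided)                   # homogeneous counts
  expect_gt(trunk$chisq_p, 0.05)

  brA <- bc[bc$clade == "A", ]
  expect_equal(brA$n_contributing, 2L)             # zero-VAF mutation excluded
  expect_equal(brA$n_mutations, 3L)
  expect_equal(brA$contribution, 2 * stats::median(c(0.2, 0.3)))

  # wildly different VAFs on one branch -> subdivided into per-mutation segments
  sh2 <- data.table::rbindlist(list(
    shared_row(1L, c("A", "B"), character(0), 0.45, 27L, 33L),
    shared_row(2L, c("A", "B"), character(0), 0.05, 3L, 57L)))
  bm2 <- build_matrix(sh2, NULL, clones)
  asg2 <- assign_branch_mutations(build_tree(bm2$matrix), bm2$matrix)
  bc2 <- branch_contribution(asg2, bm2$mutations)
  tk2 <- bc2[bc2$clade == "A,B", ]
  expect_true(tk2$subdivided)
  expect_equal(sort(tk2$segments[[1]]), c(0.1, 0.9))

  # contribution capped at 1, excluded contigs ignored
  sh3 <- shared_row(9L, c("A", "B"), character(0), 0.6, 18L, 12L, contig = "chr21")
  bm3 <- build_matrix(sh3, NULL, clones)
  asg3 <- assign_branch_mutations(build_tree(bm3$matrix), bm3$matrix)
  expect_equal(branch_contribution(asg3, bm3$mutations)$contribution, 1)
  expect_equal(nrow(branch_contribution(asg3, bm3$mutations,
                                        exclude_contigs = "chr21")), 0)
})

test_that("Fisher branch comparison matches the hypergeometric oracle", {
  same <- compare_branches(30L, 30L, 30L, 30L)
  expect_equal(same$p, 1)
  strong <- compare_branches(30L, 30L, 5L, 55L)
  expect_lt(strong$p, 0.001)
  expect_equal(strong$p, exact_fisher_p(30L, 5L, 30L, 55L), tolerance = 1e-8)
  expect_error(compare_branches(integer(0), integer(0), 3L, 7L), "empty")
})

test_that("Newick output round-trips topology, lengths and polytomies", {
  sm <- simulate_mutation_matrix(n_clones = 4, seed = 8)
  mat <- rbind(sm$matrix, root = 0L)
  tr <- build_tree(mat)
  asg <- assign_branch_mutations(tr, mat)
  p <- withr::local_tempfile(fileext = ".nwk")
  bc <- branch_contribution(asg, data.frame(
    key = colnames(mat), contig = "chr1", pos = seq_len(ncol(mat)),
    ref = "A", alt = "T", bulk_vaf = 0.25, bulk_alt = 8L, bulk_ref = 24L))
  write_newick(asg, p, contributions = bc)
  back <- ape::read.tree(p)
  expect_equal(phangorn::RF.dist(ape::unroot(back), ape::unroot(asg$tree)), 0)
  expect_equal(sum(back$edge.length), sum(asg$tree$edge.length))
  expect_true(file.exists(paste0(p, ".branches.tsv")))

  # 2-leaf tree and star polytomy are legal
  two <- ape::read.tree(text = "(root:0,(A:10,B:12):3);")
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(two, p2)
  expect_equal(sort(ape::read.tree(p2)$tip.label), c("A", "B", "root"))
  star <- ape::read.tree(text = "(A:0,B:0,C:0,root:0);")
  write_newick(star, p2)
  expect_equal(ape::read.tree(p2)$Nnode, 1)
})
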