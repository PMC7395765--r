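# Signature machinery: spectra with per-donor deduplication, chi-square
# spectrum comparison, NNLS refitting, reverse selection, bootstrap,
# fixed-margin permutation test and constrained refits.

toy_catalog <- function(n_sig = 10, seed = 1) synthetic_signature_catalog(n_sig, seed)

test_that("spectra pool per category with per-donor deduplication", {
  g <- tiny_genome()
  # find a C-centred site on chr1
  pos <- g$index[["ACA"]]$pos[g$index[["ACA"]]$contig == "chr1"][1]
  one <- data.frame(donor = "N01", contig = "chr1", pos = pos, ref = "C", alt = "T")
  sp <- build_spectrum(one, g$seqs, "test")
  expect_s3_class(sp, "spectrum_profile")
  expect_equal(sp$n_mutations, 1)
  expect_equal(unname(sp$counts["A[C>T]A"]), 1)
  expect_equal(sum(sp$counts), 1)

  # same variant in 3 clones of one donor -> counted once
  tri <- data.frame(donor = "N01", clone = c("a", "b", "c"),
                    contig = "chr1", pos = pos, ref = "C", alt = "T")
  expect_equal(build_spectrum(tri, g$seqs)$n_mutations, 1)
  # same variant in clones of two donors -> counted twice
  two <- data.frame(donor = c("N01", "N02"), contig = "chr1", pos = pos,
                    ref = "C", alt = "T")
  expect_equal(build_spectrum(two, g$seqs)$n_mutations, 2)
})

test_that("chi-square spectrum comparison is exact on edge cases and calibrated", {
  K <- toy_catalog()
  set.seed(3)
  a <- as.numeric(rmultinom(1, 300, K[, 1]))
  same <- compare_spectra(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # disjoint channels, n = 200 each
  d1 <- c(rep(25, 8), rep(0, 88)); d2 <- c(rep(0, 88), rep(25, 8))
  expect_lt(compare_spectra(d1, d2)$p, 1e-10)
  expect_error(compare_spectra(rep(0, 96), a), "zero-total")

  # two multinomial draws from one distribution: rejection ~ 5%
  mix <- as.numeric(K %*% c(0.5, 0.3, 0.2, rep(0, 7)))
  rej <- 0; B <- 500
  for (i in 1:B) {
    x <- as.numeric(rmultinom(1, 400, mix))
    y <- as.numeric(rmultinom(1, 400, mix))
    rej <- rej + (compare_spectra(x, y)$p < 0.05)
  }
  expect_gte(rej / B, 0.03)
  expect_lte(rej / B, 0.07)
})

test_that("NNLS refitting recovers exact mixtures and identity designs", {
  K <- toy_catalog()
  y <- as.numeric(300 * K[, "S01"] + 200 * K[, "S02"])
  r <- refit_nnls(y, K[, c("S01", "S02")])
  expect_equal(unname(r$exposures), c(300, 200), tolerance = 1e-6)
  expect_equal(r$cosine, 1, tolerance = 1e-9)

  # single catalog column x 100
  r2 <- refit_nnls(as.numeric(100 * K[, "S03"]), K)
  expect_equal(unname(r2$exposures["S03"]), 100, tolerance = 1e-6)
  expect_equal(sum(r2$exposures[-3]), 0, tolerance = 1e-6)

  # one-hot catalog: exposures equal channel counts exactly
  I9 <- diag(96)[, 1:9]; rownames(I9) <- sbs_channels()
  colnames(I9) <- paste0("E", 1:9)
  cts <- c(5, 0, 3, 8, 1, 0, 0, 2, 7)
  y3 <- as.numeric(I9 %*% cts)
  expect_equal(unname(refit_nnls(y3, I9)$exposures), cts, tolerance = 1e-9)
})

test_that("reverse selection keeps exact mixtures and obeys its stopping rule", {
  K <- toy_catalog()
  y <- round(as.numeric(600 * K[, "S02"] + 400 * K[, "S07"]))
  rs <- reverse_select(list(y), K, cutoff = 0.05)
  expect_setequal(rs$selected, c("S02", "S07"))
  # trace cosine is non-increasing over removals
  expect_true(all(diff(rs$trace$mean_cosine) < 1e-9))

  # profile equal to one column -> singleton
  rs1 <- reverse_select(list(as.numeric(500 * K[, "S05"])), K)
  expect_equal(rs1$selected, "S05")

  # cutoff 1.0 never triggers: removal proceeds to a single signature
  rs2 <- reverse_select(list(y), K, cutoff = 1.0)
  expect_length(rs2$selected, 1)
  expect_equal(nrow(rs2$trace), 10)
  expect_error(reverse_select(list(y), K, cutoff = 0), "cutoff")
})

test_that("bootstrap selection frequencies and exposure correlations behave", {
  K <- toy_catalog()
  y <- round(as.numeric(600 * K[, "S02"] + 400 * K[, "S07"]))
  b1 <- bootstrap_selection(list(y), K, n_boot = 1, seed = 1)
  expect_true(all(b1$frequency %in% c(0, 1)))

  b <- bootstrap_selection(list(y), K, n_boot = 60, seed = 2)
  expect_gte(b$frequency[["S02"]], 0.95)
  expect_gte(b$frequency[["S07"]], 0.95)
  expect_lt(max(b$frequency[setdiff(names(b$frequency), c("S02", "S07"))]), 0.5)

  # seeded runs are bit-reproducible
  b2 <- bootstrap_selection(list(y), K, n_boot = 60, seed = 2)
  expect_identical(b$exposures, b2$exposures)

  # two signatures with cosine ~0.83 compete for the same mutations:
  # bootstrapped exposures are negatively correlated
  A <- K[, "S01"]
  U <- rep(0, 96); U[88:96] <- 1 / 9
  B <- 0.55 * A + 0.45 * U; B <- B / sum(B)
  expect_equal(cosine_similarity(A, B), 0.83, tolerance = 0.01)
  KC <- cbind(K[, 1:6], near = B)
  y2 <- local({set.seed(4); as.numeric(rmultinom(1, 1000, 0.5 * A + 0.5 * B))})
  bc <- bootstrap_selection(list(y2), KC, n_boot = 80, seed = 3)
  expect_lt(bc$correlation["S01", "near"], 0)
})

test_that("fixed-margin permutation preserves margins and flags separation", {
  K <- toy_catalog()
  set.seed(5)
  p1 <- as.numeric(rmultinom(1, 500, K[, "S01"]))
  p2 <- as.numeric(rmultinom(1, 500, K[, "S02"]))
  M <- rbind(a = p1, b = p2)

  # margins of every generated table are exact (Patefield sampler)
  tabs <- local({set.seed(7); r2dtable(50, rowSums(M), colSums(M))})
  expect_true(all(vapply(tabs, function(tt)
    all(rowSums(tt) == rowSums(M)) && all(colSums(tt) == colSums(M)),
    logical(1))))

  pt <- permutation_exposure_test(M, K[, c("S01", "S02")], n_perm = 200, seed = 1)
  # complete separation: p at the reporting floor for both categories
  expect_equal(unname(pt$p["a", "S01"]), 2 / 200)
  expect_equal(unname(pt$p["b", "S02"]), 2 / 200)
  # reproducible under the seed
  pt2 <- permutation_exposure_test(M, K[, c("S01", "S02")], n_perm = 200, seed = 1)
  expect_identical(pt$p, pt2$p)

  expect_error(permutation_exposure_test(M[1, , drop = FALSE], K[, 1:2]),
               ">= 2")
  M0 <- M; M0[1, ] <- 0
  expect_error(permutation_exposure_test(M0, K[, 1:2]), "zero")
})

test_that("constrained refits agree with selection and tolerate orthogonal sets", {
  K <- toy_catalog()
  y <- round(as.numeric(600 * K[, "S02"] + 400 * K[, "S07"]))
  rs <- reverse_select(list(y), K)
  cr <- constrained_refit(list(y), K[, rs$selected, drop = FALSE])
  expect_equal(cr[[1]]$exposures, rs$fits[[1]]$exposures)

  # mixture of a fixed 3-signature set recovered within NNLS tolerance
  fixed <- K[, c("S01", "S05", "S09")]
  y2 <- as.numeric(fixed %*% c(120, 60, 20))
  cr2 <- constrained_refit(y2, fixed)
  expect_equal(unname(cr2[[1]]$exposures), c(120, 60, 20), tolerance = 1e-6)

  # profile orthogonal to the fixed set: near-zero exposures, low cosine
  I2 <- diag(96)[, 1:2]; rownames(I2) <- sbs_channels()
  colnames(I2) <- c("E1", "E2")
  y3 <- c(rep(0, 94), 50, 50)
  cr3 <- constrained_refit(y3, I2)
  expect_lt(sum(cr3[[1]]$exposures), 1e-9)
  expect_true(is.na(cr3[[1]]$cosine) || cr3[[1]]$cosine < 0.2)
  expect_error(constrained_refit(y3, I2[, 0]), "empty")
})

test_that("reconstruction residual never decreases as signatures are removed", {
  K <- toy_catalog()
  set.seed(13)
  y <- as.numeric(rmultinom(1, 800, K %*% c(.3, .3, .2, .1, .1, 0, 0, 0, 0, 0)))
  sets <- list(1:10, 1:8, 1:5, 1:3, 1:2)
  res <- vapply(sets, function(s) {
    r <- refit_nnls(y, K[, s, drop = FALSE])
    sqrt(sum((y - r$reconstruction)^2))
  }, numeric(1))
  expect_true(all(diff(res) > -1e-9))
})
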