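# Mutational-signature machinery: 96-channel spectra pooled per category
# (with per-donor deduplication), chi-square spectrum comparison, NNLS
# refitting, iterative reverse selection at a cosine cutoff, bootstrapped
# selection, fixed-margin permutation testing of exposures, and constrained
# refits against a fixed signature set.

#' Build a 96-channel mutation spectrum for a category
#'
#' Channel counts via [trinucleotide_context()]; a mutation recurring in
#' several clones of one donor is counted once (deduplication is per donor,
#' so the same variant in two donors counts twice). Variants whose context
#' cannot be resolved are skipped with a message.
#'
#' @param mutations data.frame with `contig`, `pos`, `ref`, `alt` and a
#'   donor column (`donor` or `donor_id`). SNVs only.
#' @param fasta Reference (path or DNAStringSet).
#' @param category Category label.
#' @return List of class `spectrum_profile`: `category`, `counts` (named
#'   96-vector), `n_mutations`.
#' @export
build_spectrum <- function(mutations, fasta, category = "profile") {
  m <- data.table::as.data.table(mutations)
  dcol <- intersect(c("donor", "donor_id"), names(m))[1]
  if (is.na(dcol)) { m$donor <- "donor"; dcol <- "donor" }
  m <- unique(m[, c(dcol, "contig", "pos", "ref", "alt"), with = FALSE])
  counts <- stats::setNames(rep(0, 96), CHANNELS_96)
  if (nrow(m)) {
    seqs <- load_fasta(fasta)
    ch <- tryCatch(
      trinucleotide_context(seqs, m$contig, m$pos, m$ref, m$alt),
      error = function(e) NULL)
    if (is.null(ch)) {  # resolve per variant, skipping failures
      ch <- rep(NA_character_, nrow(m))
      for (i in seq_len(nrow(m))) {
        ch[i] <- tryCatch(
          trinucleotide_context(seqs, m$contig[i], m$pos[i], m$ref[i], m$alt[i]),
          error = function(e) NA_character_)
      }
      message(sum(is.na(ch)), " variant(s) skipped: unresolvable context")
    }
    tab <- table(factor(ch[!is.na(ch)], levels = CHANNELS_96))
    counts <- counts + as.numeric(tab)
  }
  structure(list(category = category, counts = counts,
                 n_mutations = sum(counts)),
            class = "spectrum_profile")
}

spectrum_counts <- function(x) {
  if (inherits(x, "spectrum_profile")) x$counts else x
}

#' Chi-square comparison of two mutation spectra
#'
#' 2 x 96 contingency chi-square on the channel counts (channels with zero
#' counts in both profiles are dropped).
#'
#' @param profile_a,profile_b `spectrum_profile`s or count vectors.
#' @return List: `statistic`, `df`, `p`.
#' @export
compare_spectra <- function(profile_a, profile_b) {
  a <- spectrum_counts(profile_a); b <- spectrum_counts(profile_b)
  if (sum(a) == 0 || sum(b) == 0) stop("zero-total profile")
  keep <- a + b > 0
  ht <- suppressWarnings(stats::chisq.test(rbind(a[keep], b[keep])))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Refit a spectrum against signatures by non-negative least squares
#'
#' @param profile `spectrum_profile` or 96-count vector.
#' @param catalog_subset 96 x k column-stochastic signature matrix.
#' @return List of class `refit_result`: `exposures` (named, mutation
#'   units), `reconstruction`, `cosine`.
#' @export
refit_nnls <- function(profile, catalog_subset) {
  y <- spectrum_counts(profile)
  C <- as.matrix(catalog_subset)
  if (ncol(C) == 0) stop("empty signature set")
  fit <- pracma::lsqnonneg(C, as.numeric(y))
  expo <- stats::setNames(fit$x, colnames(C))
  recon <- as.numeric(C %*% fit$x)
  structure(list(exposures = expo, reconstruction = recon,
                 cosine = cosine_similarity(as.numeric(y), recon)),
            class = "refit_result")
}

fit_profiles <- function(profiles, catalog) {
  lapply(profiles, refit_nnls, catalog_subset = catalog)
}

#' Iterative reverse signature selection
#'
#' All profiles are fitted jointly against the candidate signatures; at each
#' iteration the signature with the lowest total (absolute) exposure across
#' profiles is removed and the mean reconstruction cosine recomputed. The
#' process stops when the drop in mean cosine between two consecutive
#' iterations exceeds `cutoff`, returning the set before the violating
#' removal; with a cutoff that never triggers, removal proceeds down to a
#' single signature.
#'
#' @param profiles List of `spectrum_profile`s (or count vectors).
#' @param catalog Full candidate catalog (96 x S).
#' @param cutoff Cosine-difference stopping cutoff (> 0; default 0.05).
#' @return List: `selected` (signature names), `fits` (final per-profile
#'   refits), `trace` (data.table: iteration, n_signatures, removed,
#'   mean_cosine).
#' @export
reverse_select <- function(profiles, catalog, cutoff = 0.05) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!length(profiles)) stop("no profiles")
  if (inherits(profiles, "spectrum_profile") || is.numeric(profiles))
    profiles <- list(profiles)
  current <- colnames(catalog)
  fits <- fit_profiles(profiles, catalog[, current, drop = FALSE])
  mean_cos <- mean(vapply(fits, function(f) f$cosine, numeric(1)))
  trace <- list(data.table::data.table(
    iteration = 0L, n_signatures = length(current), removed = NA_character_,
    mean_cosine = mean_cos))
  while (length(current) > 1L) {
    total <- Reduce(`+`, lapply(fits, function(f) f$exposures))
    drop_sig <- names(total)[which.min(total)]
    cand <- setdiff(current, drop_sig)
    cand_fits <- fit_profiles(profiles, catalog[, cand, drop = FALSE])
    cand_cos <- mean(vapply(cand_fits, function(f) f$cosine, numeric(1)))
    if (mean_cos - cand_cos > cutoff) break
    current <- cand; fits <- cand_fits
    trace[[length(trace) + 1L]] <- data.table::data.table(
      iteration = length(trace), n_signatures = length(current),
      removed = drop_sig, mean_cosine = cand_cos)
    mean_cos <- cand_cos
  }
  list(selected = current, fits = fits,
       trace = data.table::rbindlist(trace))
}

#' Bootstrapped signature selection
#'
#' Each iteration resamples every profile's mutations with replacement
#' (multinomial over its empirical channel frequencies), reruns
#' [reverse_select()], and records the selected set and exposures. Reports
#' per-signature selection frequencies, exposure quantiles, and the pairwise
#' exposure correlations across iterations (the collinearity diagnostic:
#' near-identical signatures compete and correlate negatively).
#'
#' @param profiles List of `spectrum_profile`s.
#' @param catalog Candidate catalog.
#' @param n_boot Iterations (published analysis: 1000).
#' @param seed Integer seed.
#' @param cutoff Passed to [reverse_select()].
#' @return List: `frequency` (named), `exposures` (n_boot x S matrix of
#'   summed exposures), `quantiles`, `correlation` (S x S, NA where a
#'   signature was never selected), `n_boot`.
#' @export
bootstrap_selection <- function(profiles, catalog, n_boot = 1000, seed = 1,
                                cutoff = 0.05) {
  if (inherits(profiles, "spectrum_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no profiles")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sigs <- colnames(catalog)
  sel <- matrix(FALSE, n_boot, length(sigs), dimnames = list(NULL, sigs))
  expo <- matrix(0, n_boot, length(sigs), dimnames = list(NULL, sigs))
  for (b in seq_len(n_boot)) {
    res_profiles <- lapply(profiles, function(p) {
      y <- spectrum_counts(p)
      n <- sum(y)
      if (n == 0) return(y)
      as.numeric(stats::rmultinom(1, n, y / n))
    })
    rs <- reverse_select(res_profiles, catalog, cutoff = cutoff)
    sel[b, rs$selected] <- TRUE
    tot <- Reduce(`+`, lapply(rs$fits, function(f) f$exposures))
    expo[b, names(tot)] <- tot
  }
  qs <- apply(expo, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  corr <- suppressWarnings(stats::cor(expo))
  list(frequency = colMeans(sel), exposures = expo, quantiles = qs,
       correlation = corr, n_boot = n_boot)
}

#' Fixed-margin permutation test of signature exposures
#'
#' Permutes the categories x 96 count matrix `n_perm` times with both
#' margins fixed (Patefield sampling via `r2dtable`), refits every permuted
#' category row against the given signatures, and compares the observed
#' relative exposures to the permutation distribution. Two-tailed p-values
#' are twice the smaller tail frequency, floored at `2/n_perm` and capped
#' at 1.
#'
#' @param count_matrix Categories x 96 matrix (>= 2 rows, no zero row).
#' @param signatures Catalog subset to refit with (the >= 50%
#'   bootstrap-selected set in the published workflow).
#' @param n_perm Permutations (published analysis: 2000).
#' @param seed Integer seed.
#' @return List: `p` (categories x signatures), `observed` (relative
#'   exposures), `null_mean`, `n_perm`.
#' @export
permutation_exposure_test <- function(count_matrix, signatures, n_perm = 2000,
                                      seed = 1) {
  M <- as.matrix(count_matrix)
  if (nrow(M) < 2) stop("need >= 2 category rows to permute against")
  if (any(rowSums(M) == 0)) stop("degenerate margins: zero category row")
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  C <- as.matrix(signatures)
  rel_expo <- function(y) {
    e <- pracma::lsqnonneg(C, as.numeric(y))$x
    s <- sum(e)
    if (s == 0) rep(0, ncol(C)) else e / s
  }
  obs <- t(apply(M, 1, rel_expo))
  dimnames(obs) <- list(rownames(M), colnames(C))
  tables <- stats::r2dtable(n_perm, rowSums(M), colSums(M))
  null <- array(0, c(n_perm, nrow(M), ncol(C)))
  for (k in seq_len(n_perm)) {
    null[k, , ] <- t(apply(tables[[k]], 1, rel_expo))
  }
  p <- obs
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(C))) {
    hi <- sum(null[, i, j] >= obs[i, j])
    lo <- sum(null[, i, j] <= obs[i, j])
    p[i, j] <- min(1, max(2 / n_perm, 2 * min(hi, lo) / n_perm))
  }
  list(p = p, observed = obs, null_mean = apply(null, c(2, 3), mean),
       n_perm = n_perm)
}

#' Constrained refit against a fixed signature set
#'
#' Plain NNLS against exactly the given signatures, no selection — the
#' fallback used when stringent selection would drop ever-present
#' low-contribution signatures (e.g. the clock-like and HSPC signatures).
#'
#' @param profiles List of `spectrum_profile`s (or a single one).
#' @param fixed_signatures Catalog subset (96 x k, k >= 1).
#' @return List of `refit_result`s, one per profile.
#' @export
constrained_refit <- function(profiles, fixed_signatures) {
  if (inherits(profiles, "spectrum_profile") || is.numeric(profiles))
    profiles <- list(profiles)
  if (is.null(dim(fixed_signatures)) || ncol(fixed_signatures) == 0)
    stop("empty fixed signature set")
  fit_profiles(profiles, fixed_signatures)
}

#' Raw DBS and indel tallies
#'
#' Desk-scale summaries of non-SBS mutation classes: dinucleotide change
#' counts for DBS pairs and indel length counts (negative = deletion).
#'
#' @param dbs data.frame with `ref2`, `alt2` (as from [count_dbs()] keys).
#' @param indels data.frame with `ref`, `alt`.
#' @return List: `dbs` (table of ref2>alt2), `indel_lengths` (table).
#' @export
tally_dbs_indels <- function(dbs = NULL, indels = NULL) {
  out <- list()
  if (!is.null(dbs) && nrow(dbs))
    out$dbs <- table(paste0(dbs$ref2, ">", dbs$alt2))
  if (!is.null(indels) && nrow(indels))
    out$indel_lengths <- table(nchar(indels$alt) - nchar(indels$ref))
  out
}
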