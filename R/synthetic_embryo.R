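# Synthetic embryo/cohort generator.
#
# Each donor is an embryo: a strictly binary, synchronous cell-division tree
# of `pre_gastrulation_divisions` rounds, Poisson-distributed mutations per
# division edge, germ-layer allocation of the gastrulation-stage cells, a
# bulk skin sample of ectoderm cells (with tunable dominance of the first
# daughter cell), clonally expanded HSPC (mesoderm) and ISC (endoderm)
# samples, clone-private late mutations at an annual rate, heterozygous
# germline variants, low-VAF in-vitro culture artifacts, and singleton-read
# sequencing-error candidates. Read counts are binomial at Poisson depth;
# clonal VAF is 0.5 on autosomes, 1/3 on the trisomy-proxy contig of T21
# donors and 1.0 on X in males.

#' Configuration of a synthetic cohort
#'
#' Defaults follow the study conditions the pipeline targets: 5 disomic and
#' 4 trisomic donors at gestational ages 12-17 weeks (age since conception =
#' GA - 2 weeks), ~5 clones per donor (3 HSPC + 2 ISC), 7 pre-gastrulation
#' divisions at 2.5 mutations/division (+0.4 per division in T21), ~100 late
#' substitutions per year (+180/yr in T21, i.e. ~34 extra at these ages),
#' 30x depth, and a desk-scale 6-contig mock genome including a trisomy
#' proxy ("chr21") and "chrX".
#'
#' @param n_donors_d21,n_donors_t21 Donor counts per karyotype.
#' @param clones_per_donor Clones per donor (split ~3:2 HSPC:ISC).
#' @param age_years Ages since conception (years), recycled over donors;
#'   default evenly spans GA weeks 12-17 minus 2 weeks.
#' @param pre_gastrulation_divisions Binary divisions before gastrulation.
#' @param mu_early Mean mutations per division.
#' @param extra_early_t21 Additional early mutations per division in T21.
#' @param annual_rate Late mutations per year.
#' @param extra_rate_t21 Additional late mutations per year in T21.
#' @param signature_weights Nonnegative weights over catalog columns, sum 1.
#' @param catalog 96 x S signature catalog used to draw mutation channels.
#' @param depth_mean Mean sequencing depth.
#' @param n_germline Heterozygous germline variants per donor.
#' @param n_invitro Expected in-vitro subclonal mutations per clone.
#' @param invitro_vaf_range VAF interval of in-vitro mutations, within (0, 0.3).
#' @param ectoderm_dominance Fraction of bulk-skin cells descending from the
#'   first daughter of the zygote (0.5 = symmetric).
#' @param genome data.frame(contig, length); one contig must equal
#'   `trisomy_contig`.
#' @param trisomy_contig,x_contig Contig names for the trisomy proxy and X.
#' @param callable_fraction Fraction of each contig with adequate depth.
#' @param error_rate Sequencing-error candidate rate per site per sample
#'   (emitted as singleton alt reads).
#' @param n_bulk_cells Ectoderm cells sampled into the bulk-skin readout.
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_donors_d21 = 5L,
                          n_donors_t21 = 4L,
                          clones_per_donor = 5L,
                          age_years = NULL,
                          pre_gastrulation_divisions = 7L,
                          mu_early = 2.5,
                          extra_early_t21 = 0.4,
                          annual_rate = 100,
                          extra_rate_t21 = 180,
                          signature_weights = NULL,
                          catalog = NULL,
                          depth_mean = 30,
                          n_germline = 2000L,
                          n_invitro = 30,
                          invitro_vaf_range = c(0.02, 0.15),
                          ectoderm_dominance = 0.5,
                          genome = NULL,
                          trisomy_contig = "chr21",
                          x_contig = "chrX",
                          callable_fraction = 0.9,
                          error_rate = 1e-3,
                          n_bulk_cells = 500L,
                          seed = 1L) {
  if (is.null(genome)) {
    genome <- data.frame(
      contig = c("chr1", "chr2", "chr3", "chr4", "chr21", "chrX"),
      length = rep(2e6L, 6L))
  }
  n_donors <- n_donors_d21 + n_donors_t21
  if (is.null(age_years)) {
    ga <- seq(12, 17, length.out = max(n_donors, 2L))[seq_len(n_donors)]
    age_years <- (ga - 2) * 7 / 365.25
  }
  age_years <- rep_len(age_years, n_donors)
  if (is.null(catalog)) catalog <- synthetic_signature_catalog(seed = seed)
  if (is.null(signature_weights)) {
    signature_weights <- stats::setNames(rep(0, ncol(catalog)), colnames(catalog))
    signature_weights[seq_len(min(3L, ncol(catalog)))] <- c(0.5, 0.3, 0.2)[seq_len(min(3L, ncol(catalog)))]
    signature_weights <- signature_weights / sum(signature_weights)
  }
  cfg <- structure(list(
    n_donors_d21 = as.integer(n_donors_d21),
    n_donors_t21 = as.integer(n_donors_t21),
    clones_per_donor = as.integer(clones_per_donor),
    age_years = age_years,
    pre_gastrulation_divisions = as.integer(pre_gastrulation_divisions),
    mu_early = mu_early,
    extra_early_t21 = extra_early_t21,
    annual_rate = annual_rate,
    extra_rate_t21 = extra_rate_t21,
    signature_weights = signature_weights,
    catalog = catalog,
    depth_mean = depth_mean,
    n_germline = as.integer(n_germline),
    n_invitro = n_invitro,
    invitro_vaf_range = invitro_vaf_range,
    ectoderm_dominance = ectoderm_dominance,
    genome = genome,
    trisomy_contig = trisomy_contig,
    x_contig = x_contig,
    callable_fraction = callable_fraction,
    error_rate = error_rate,
    n_bulk_cells = as.integer(n_bulk_cells),
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_donors_d21 >= 0, cfg$n_donors_t21 >= 0,
    cfg$n_donors_d21 + cfg$n_donors_t21 >= 1,
    cfg$clones_per_donor >= 1,
    all(cfg$age_years > 0),
    cfg$pre_gastrulation_divisions >= 1,
    cfg$mu_early >= 0, cfg$extra_early_t21 >= 0,
    cfg$annual_rate >= 0, cfg$extra_rate_t21 >= 0,
    cfg$depth_mean > 0, cfg$n_germline >= 0, cfg$n_invitro >= 0,
    cfg$callable_fraction > 0, cfg$callable_fraction <= 1,
    cfg$error_rate >= 0, cfg$n_bulk_cells >= 1
  )
  if (abs(sum(cfg$signature_weights) - 1) > 1e-9)
    stop("signature_weights must sum to 1")
  if (any(cfg$signature_weights < 0)) stop("signature_weights must be nonnegative")
  if (length(cfg$signature_weights) != ncol(cfg$catalog))
    stop("signature_weights length must match catalog columns")
  r <- cfg$invitro_vaf_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 0.3 || r[1] > r[2])
    stop("invitro_vaf_range must lie within (0, 0.3)")
  if (cfg$ectoderm_dominance < 0 || cfg$ectoderm_dominance > 1)
    stop("ectoderm_dominance must be in [0, 1]")
  invisible(cfg)
}

# clonal VAF multiplier by contig / karyotype / sex
vaf_scale <- function(contig, trisomy21, sex, cfg) {
  out <- rep(0.5, length(contig))
  if (trisomy21) out[contig == cfg$trisomy_contig] <- 1 / 3
  if (sex == "M") out[contig == cfg$x_contig] <- 1.0
  out
}

rtpois <- function(n, lambda, min = 0L) {
  x <- stats::rpois(n, lambda)
  while (any(x < min)) x[x < min] <- stats::rpois(sum(x < min), lambda)
  x
}

#' Simulate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param genome Optional precomputed [simulate_genome()] result for the same
#'   config (the genome has its own derived seed, so passing a cached genome
#'   leaves the cohort unchanged).
#' @return Object of class `simulated_cohort`: `calls` (long call table: one
#'   row per variant x sample per donor), `truth` (per-variant truth labels),
#'   `meta` (sample metadata), `trees` (per-donor true induced lineage tree
#'   and branch truth), `config`, `genome`.
#' @export
simulate_embryo <- function(config, genome = NULL) {
  validate_cohort_config(config)
  if (is.null(genome)) genome <- simulate_genome(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  n_donors <- config$n_donors_d21 + config$n_donors_t21
  donor_ids <- c(sprintf("N%02d", seq_len(config$n_donors_d21)),
                 sprintf("T%02d", seq_len(config$n_donors_t21)))
  t21_flags <- c(rep(FALSE, config$n_donors_d21), rep(TRUE, config$n_donors_t21))
  sexes <- rep(c("F", "M"), length.out = n_donors)

  mixture <- as.numeric(config$catalog %*% config$signature_weights)

  calls <- vector("list", n_donors)
  truth <- vector("list", n_donors)
  meta <- vector("list", n_donors)
  trees <- vector("list", n_donors)
  names(trees) <- donor_ids
  for (d in seq_len(n_donors)) {
    sim <- simulate_donor(donor_ids[d], t21_flags[d], sexes[d],
                          config$age_years[d], config, genome, mixture)
    calls[[d]] <- sim$calls
    truth[[d]] <- sim$truth
    meta[[d]] <- sim$meta
    trees[[donor_ids[d]]] <- sim$tree
  }
  structure(list(
    calls = data.table::rbindlist(calls),
    truth = data.table::rbindlist(truth),
    meta = data.table::rbindlist(meta),
    trees = trees,
    config = config,
    genome = genome
  ), class = "simulated_cohort")
}

simulate_donor <- function(donor, t21, sex, age, cfg, genome, mixture) {
  D <- cfg$pre_gastrulation_divisions
  n_leaf <- 2L^D
  n_node <- 2L^(D + 1L) - 1L
  leaves <- n_leaf:(2L * n_leaf - 1L)

  n_clone <- cfg$clones_per_donor
  n_h <- ceiling(n_clone * 3 / 5)
  n_i <- n_clone - n_h

  # mutations per division edge (edge above node v, v >= 2)
  mu <- cfg$mu_early + if (t21) cfg$extra_early_t21 else 0
  edge_mut <- c(0L, stats::rpois(n_node - 1L, mu))  # index by node id

  # germ layers; require enough mesoderm/endoderm leaves and ectoderm on both
  # sides of the first division so that clones and the dominance-weighted bulk
  # can always be drawn
  repeat {
    layer <- sample(c("ecto", "meso", "endo"), n_leaf, replace = TRUE)
    ecto1 <- leaves[layer == "ecto" & leaves < 3L * 2L^(D - 1L)]
    ecto2 <- leaves[layer == "ecto" & leaves >= 3L * 2L^(D - 1L)]
    if (sum(layer == "meso") >= n_h && sum(layer == "endo") >= max(n_i, 1L) &&
        length(ecto1) >= 1L && length(ecto2) >= 1L) break
  }

  clone_leaves <- c(sample_keep(leaves[layer == "meso"], n_h),
                    sample_keep(leaves[layer == "endo"], n_i))
  clone_ids <- c(sprintf("%s-H%d", donor, seq_len(n_h)),
                 if (n_i > 0) sprintf("%s-I%d", donor, seq_len(n_i)))
  names(clone_leaves) <- clone_ids
  bulk_id <- paste0(donor, "-BULK")
  samples <- c(clone_ids, bulk_id)

  # bulk skin: n_bulk_cells ectoderm cells; first-daughter descent governed
  # by ectoderm_dominance
  n_cells <- cfg$n_bulk_cells
  n_side1 <- stats::rbinom(1L, n_cells, cfg$ectoderm_dominance)
  bulk_cells <- c(sample_keep(ecto1, n_side1, replace = TRUE),
                  sample_keep(ecto2, n_cells - n_side1, replace = TRUE))
  leaf_tab <- tabulate(bulk_cells - n_leaf + 1L, nbins = n_leaf)

  # per-node bulk fractions and clone counts (bottom-up over the heap tree)
  node_bulk <- c(rep(0L, n_leaf - 1L), leaf_tab)
  node_clones <- matrix(FALSE, n_node, n_clone)
  node_clones[cbind(clone_leaves, seq_len(n_clone))] <- TRUE
  for (v in (n_leaf - 1L):1L) {
    node_bulk[v] <- node_bulk[2L * v] + node_bulk[2L * v + 1L]
    node_clones[v, ] <- node_clones[2L * v, ] | node_clones[2L * v + 1L, ]
  }
  node_frac <- node_bulk / n_cells

  # --- mutation inventory ------------------------------------------------
  # early: only instances carried by >= 1 sampled clone materialize as calls
  early_nodes <- which(edge_mut > 0L & rowSums(node_clones) > 0L)
  early_nodes <- early_nodes[early_nodes >= 2L]
  early_node <- rep(early_nodes, edge_mut[early_nodes])
  n_early <- length(early_node)

  late_rate <- (cfg$annual_rate + if (t21) cfg$extra_rate_t21 else 0) * age
  late_per_clone <- stats::rpois(n_clone, late_rate)
  invitro_per_clone <- stats::rpois(n_clone, cfg$n_invitro)

  n_late <- sum(late_per_clone)
  n_invitro <- sum(invitro_per_clone)
  n_som <- n_early + n_late + n_invitro

  som_class <- rep(c("early", "late", "invitro"), c(n_early, n_late, n_invitro))
  som_owner <- c(rep(NA_integer_, n_early),
                 rep(seq_len(n_clone), late_per_clone),
                 rep(seq_len(n_clone), invitro_per_clone))
  som_node <- c(early_node, rep(NA_integer_, n_late + n_invitro))

  # channels and sequence-consistent positions
  ch_idx <- sample.int(96L, n_som, replace = TRUE, prob = mixture)
  pos_dt <- place_channel_mutations(ch_idx, genome)

  callable_sites <- sum(genome$contigs$callable_end - 1L)
  n_germ <- cfg$n_germline
  err_per_sample <- stats::rpois(length(samples), callable_sites * cfg$error_rate)
  n_err <- sum(err_per_sample)
  unif <- place_uniform_mutations(n_germ + n_err, genome, used = pos_dt)

  germ_dt <- unif[seq_len(n_germ), , drop = FALSE]
  err_dt <- unif[n_germ + seq_len(n_err), , drop = FALSE]
  err_sample <- rep(samples, err_per_sample)

  sites <- data.table::data.table(
    contig = c(pos_dt$contig, germ_dt$contig, err_dt$contig),
    pos = c(pos_dt$pos, germ_dt$pos, err_dt$pos),
    ref = c(pos_dt$ref, germ_dt$ref, err_dt$ref),
    alt = c(pos_dt$alt, germ_dt$alt, err_dt$alt),
    class = c(som_class, rep("germline", n_germ), rep("error", n_err)),
    owner = c(som_owner, rep(NA_integer_, n_germ + n_err)),
    node = c(som_node, rep(NA_integer_, n_germ + n_err)),
    channel = c(CHANNELS_96[ch_idx], rep(NA_character_, n_germ + n_err)),
    err_sample = c(rep(NA_character_, n_som + n_germ), err_sample)
  )
  n_site <- nrow(sites)

  # --- true per-sample VAF matrix ----------------------------------------
  scale <- vaf_scale(sites$contig, t21, sex, cfg)
  V <- matrix(0, n_site, length(samples), dimnames = list(NULL, samples))
  i_germ <- sites$class == "germline"
  V[i_germ, ] <- scale[i_germ]
  i_early <- which(sites$class == "early")
  if (length(i_early)) {
    carrier <- node_clones[sites$node[i_early], , drop = FALSE]
    V[i_early, seq_len(n_clone)] <- carrier * scale[i_early]
    V[i_early, bulk_id] <- node_frac[sites$node[i_early]] * scale[i_early]
  }
  i_late <- which(sites$class == "late")
  if (length(i_late))
    V[cbind(i_late, sites$owner[i_late])] <- scale[i_late]
  i_vitro <- which(sites$class == "invitro")
  if (length(i_vitro))
    V[cbind(i_vitro, sites$owner[i_vitro])] <-
      stats::runif(length(i_vitro), cfg$invitro_vaf_range[1], cfg$invitro_vaf_range[2])
  sites$true_bulk_frac <- V[, bulk_id] / ifelse(scale > 0, scale, 1)
  sites$true_bulk_frac[i_germ] <- 1

  # --- read sampling ------------------------------------------------------
  nm <- n_site * length(samples)
  dp <- matrix(stats::rpois(nm, cfg$depth_mean), n_site)
  alt_ct <- matrix(stats::rbinom(nm, dp, V), n_site)
  i_err <- which(sites$class == "error")
  if (length(i_err)) {
    j_err <- match(sites$err_sample[i_err], samples)
    dp[cbind(i_err, j_err)] <- pmax(dp[cbind(i_err, j_err)], 1L)
    alt_ct[cbind(i_err, j_err)] <- 1L
  }

  gt <- matrix("0/0", n_site, length(samples))
  gt[V > 0 & V < 0.99] <- "0/1"
  gt[V >= 0.99] <- "1/1"
  gq <- matrix(pmin(99L, dp), n_site, length(samples))
  i_carr <- which(V > 0)
  gq[i_carr] <- ifelse(stats::runif(length(i_carr)) < 0.995, 99L, 30L)
  if (length(i_err)) {
    gt[cbind(i_err, j_err)] <- "0/1"
    gq[cbind(i_err, j_err)] <- sample(5:60, length(i_err), replace = TRUE)
  }

  qual <- ifelse(sites$class == "error",
                 pmax(1, round(stats::rexp(n_site, 1 / 40))),
                 floor(stats::runif(n_site, 150, 1200)))
  mq <- ifelse(sites$class == "error",
               ifelse(stats::runif(n_site) < 0.7, 60,
                      sample(20:59, n_site, replace = TRUE)),
               ifelse(stats::runif(n_site) < 0.995, 60, 40))

  calls <- data.table::data.table(
    donor = donor,
    contig = rep(sites$contig, length(samples)),
    pos = rep(sites$pos, length(samples)),
    ref = rep(sites$ref, length(samples)),
    alt = rep(sites$alt, length(samples)),
    id = ".",
    qual = rep(qual, length(samples)),
    mq = rep(mq, length(samples)),
    filter = "PASS",
    multiallelic = FALSE,
    effect = NA_character_,
    gene = NA_character_,
    sample = rep(samples, each = n_site),
    gt = as.vector(gt),
    gq = as.vector(gq),
    dp = as.vector(dp),
    ad_ref = as.vector(dp - alt_ct),
    ad_alt = as.vector(alt_ct)
  )
  calls$vaf <- ifelse(calls$dp > 0, calls$ad_alt / calls$dp, NA_real_)

  carriers <- character(n_site)
  carriers[i_germ] <- paste(samples, collapse = ",")
  if (length(i_early))
    carriers[i_early] <- apply(node_clones[sites$node[i_early], , drop = FALSE], 1,
                               function(x) paste(clone_ids[x], collapse = ","))
  own <- sites$owner
  carriers[!is.na(own)] <- clone_ids[own[!is.na(own)]]
  carriers[sites$class == "error"] <- sites$err_sample[sites$class == "error"]
  label <- sites$class
  label[i_early] <- paste0("early:node", sites$node[i_early])
  label[!is.na(own)] <- paste0(sites$class[!is.na(own)], ":", carriers[!is.na(own)])

  truth <- data.table::data.table(
    donor = donor, contig = sites$contig, pos = sites$pos,
    ref = sites$ref, alt = sites$alt, class = sites$class, label = label,
    carriers = carriers, node = sites$node, channel = sites$channel,
    true_bulk_frac = sites$true_bulk_frac
  )

  meta <- data.table::data.table(
    sample_id = samples,
    donor_id = donor,
    role = c(rep("clone", n_clone), "bulk"),
    cell_type = c(rep("HSPC", n_h), rep("ISC", n_i), "other"),
    trisomy21 = t21,
    sex = sex,
    age_since_conception = age
  )

  tree <- induced_true_tree(clone_leaves, edge_mut, node_frac, D)
  tree$donor <- donor

  list(calls = calls, truth = truth, meta = meta, tree = tree)
}

sample_keep <- function(x, n, replace = FALSE) {
  # sample() liable to misbehave when length(x) == 1
  if (n == 0L) return(integer(0))
  if (length(x) == 1L && !replace) return(rep(x, min(n, 1L)))
  x[sample.int(length(x), n, replace = replace)]
}

# place channel-drawn mutations at sequence-consistent positions, without
# replacement within the call
place_channel_mutations <- function(ch_idx, genome) {
  n <- length(ch_idx)
  out <- data.table::data.table(contig = character(n), pos = integer(n),
                                ref = character(n), alt = character(n))
  if (n == 0) return(out)
  channels <- CHANNELS_96[ch_idx]
  for (ch in unique(channels)) {
    i <- which(channels == ch)
    trips <- channel_triplets(ch)  # c(pyr, pur) genomic triplets
    pools <- lapply(trips, function(tr) genome$index[[tr]])
    sizes <- vapply(pools, function(p) if (is.null(p)) 0L else nrow(p), integer(1))
    if (sum(sizes) < length(i))
      stop("genome too small to host requested mutations for channel ", ch,
           " without position collision")
    strand <- ifelse(stats::runif(length(i)) < sizes[1] / sum(sizes), 1L, 2L)
    for (s in 1:2) {
      excess <- sum(strand == s) - sizes[s]
      if (excess > 0)  # rebalance if one pool is exhausted
        strand[which(strand == s)[seq_len(excess)]] <- 3L - s
    }
    for (s in 1:2) {
      k <- which(strand == s)
      if (!length(k)) next
      rows <- pools[[s]][sample.int(sizes[s], length(k)), ]
      out$contig[i[k]] <- rows$contig
      out$pos[i[k]] <- rows$pos
      out$ref[i[k]] <- substr(trips[[s]], 2, 2)
      out$alt[i[k]] <- channel_alt(ch, if (s == 1L) "pyr" else "pur")
    }
  }
  out
}

# uniform positions over the callable mask, avoiding a set of used positions
place_uniform_mutations <- function(n, genome, used = NULL) {
  out <- data.table::data.table(contig = character(0), pos = integer(0),
                                ref = character(0), alt = character(0))
  if (n == 0) return(out)
  used_keys <- if (!is.null(used) && nrow(used)) paste(used$contig, used$pos) else character(0)
  sizes <- genome$contigs$callable_end - 1L
  need <- n
  while (need > 0) {
    ci <- sample.int(nrow(genome$contigs), need, replace = TRUE, prob = sizes)
    pos <- 1L + as.integer(ceiling(stats::runif(need) * sizes[ci]))  # in [2, callable_end]
    dt <- data.table::data.table(contig = genome$contigs$contig[ci], pos = pos)
    key <- paste(dt$contig, dt$pos)
    ok <- !duplicated(key) & !(key %in% used_keys)
    dt <- dt[ok]
    used_keys <- c(used_keys, key[ok])
    out <- rbind(out, cbind(dt, ref = "", alt = ""), fill = TRUE)
    need <- n - nrow(out)
  }
  out <- out[seq_len(n)]
  # look up reference base, draw a random alt
  refs <- character(n)
  for (ct in unique(out$contig)) {
    i <- which(out$contig == ct)
    v <- Biostrings::extractAt(genome$seqs[[ct]],
                               IRanges::IRanges(start = out$pos[i], width = 1L))
    refs[i] <- as.character(v)
  }
  out$ref <- refs
  shift <- sample.int(3L, n, replace = TRUE)
  out$alt <- DNA_BASES[(match(refs, DNA_BASES) - 1L + shift) %% 4L + 1L]
  out
}

# Induced (collapsed) true lineage tree over the sampled clones, rooted via a
# zero-profile "root" tip; branch lengths are summed division-edge mutation
# counts and each branch records the bulk fraction of its uppermost node.
induced_true_tree <- function(clone_leaves, edge_mut, node_frac, D) {
  branches <- list()
  rec <- function(v) {
    if (v >= 2L^D) {
      i <- which(clone_leaves == v)
      if (!length(i)) return(NULL)
      return(list(lab = names(clone_leaves)[i[1]], len = edge_mut[v], top = v,
                  tips = names(clone_leaves)[i[1]], split = NA_integer_))
    }
    l <- rec(2L * v)
    r <- rec(2L * v + 1L)
    if (is.null(l) && is.null(r)) return(NULL)
    if (is.null(l) || is.null(r)) {
      child <- if (is.null(l)) r else l
      child$len <- child$len + edge_mut[v]
      child$top <- v
      return(child)
    }
    for (ch in list(l, r)) {
      branches[[length(branches) + 1L]] <<- data.table::data.table(
        clade = paste(sort(ch$tips), collapse = ","),
        top_node = ch$top, split_node = v,
        n_mutations = ch$len, true_frac = node_frac[ch$top])
    }
    list(lab = paste0("(", l$lab, ":", l$len, ",", r$lab, ":", r$len, ")"),
         len = edge_mut[v], top = v, tips = c(l$tips, r$tips), split = v)
  }
  res <- rec(1L)
  if (is.null(res)) stop("no clones sampled")
  mrca <- if (is.na(res$split)) res$top else res$split
  branches[[length(branches) + 1L]] <- data.table::data.table(
    clade = paste(sort(res$tips), collapse = ","),
    top_node = res$top, split_node = 0L,
    n_mutations = res$len, true_frac = node_frac[res$top])
  nwk <- paste0("(root:0,", res$lab, ":", res$len, ");")
  branch_dt <- data.table::rbindlist(branches)
  branch_dt$is_first <- branch_dt$split_node == mrca
  list(phylo = ape::read.tree(text = nwk), newick = nwk,
       branches = branch_dt, mrca_node = mrca)
}
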