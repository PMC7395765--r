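# Focused synthetic designs: a matrix-level lineage generator (random clone
# tree with a guaranteed minimum number of mutations per branch) and direct
# burden-table simulators used for mixed-model parameter-recovery studies.

#' Simulate a binary mutation matrix from a random clone tree
#'
#' Draws a random rooted binary tree over `n_clones` clones (uniform random
#' joins), assigns each branch (terminal, internal and trunk) a truncated
#' Poisson number of mutations (at least `min_mut`, so the topology is always
#' identifiable from the matrix), and emits the corresponding clones x
#' mutations 0/1 matrix.
#'
#' @param n_clones Number of clones (>= 2).
#' @param lambda Mean mutations per branch.
#' @param min_mut Minimum mutations per branch.
#' @param seed Integer seed.
#' @return List: `matrix` (clones x mutations, rownames = clone ids),
#'   `tree` (ape phylo incl. a zero-length `root` tip; branch lengths =
#'   mutation counts), `branches` (data.table clade / n_mutations).
#' @export
simulate_mutation_matrix <- function(n_clones, lambda = 8, min_mut = 5, seed = 1) {
  stopifnot(n_clones >= 2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  ids <- sprintf("C%02d", seq_len(n_clones))
  units <- lapply(ids, function(x) list(frag = x, tips = x))
  branches <- list()
  cols <- list()
  add_branch <- function(tips, len) {
    branches[[length(branches) + 1L]] <<- data.table::data.table(
      clade = paste(sort(tips), collapse = ","), n_mutations = len)
    if (len > 0) {
      col <- as.integer(ids %in% tips)
      cols[[length(cols) + 1L]] <<- matrix(rep(col, len), ncol = len)
    }
  }
  while (length(units) > 1L) {
    pick <- sample.int(length(units), 2L)
    a <- units[[pick[1]]]; b <- units[[pick[2]]]
    la <- rtpois(1L, lambda, min_mut); lb <- rtpois(1L, lambda, min_mut)
    add_branch(a$tips, la); add_branch(b$tips, lb)
    joined <- list(frag = paste0("(", a$frag, ":", la, ",", b$frag, ":", lb, ")"),
                   tips = c(a$tips, b$tips))
    units <- c(units[-pick], list(joined))
  }
  trunk <- rtpois(1L, lambda, min_mut)
  add_branch(ids, trunk)
  nwk <- paste0("(root:0,", units[[1]]$frag, ":", trunk, ");")
  mat <- do.call(cbind, cols)
  rownames(mat) <- ids
  colnames(mat) <- sprintf("M%04d", seq_len(ncol(mat)))
  list(matrix = mat, tree = ape::read.tree(text = nwk),
       branches = data.table::rbindlist(branches))
}

#' Simulate per-clone mutation rates across age cohorts
#'
#' Direct generative model for the rate comparison: one row per clone with
#' `rate = group mean + donor effect + residual`.
#'
#' @param n_donors Named integer vector of donors per cohort, e.g.
#'   `c(fetal = 3, cord = 2, post_infant = 6)`.
#' @param clones_per_donor Clones per donor (recycled over cohorts).
#' @param rates True mean rate (mutations/year) per cohort, same names.
#' @param donor_sd SD of the donor-level random intercept.
#' @param resid_sd Residual SD.
#' @param seed Integer seed.
#' @return data.table: clone, donor, cohort, rate.
#' @export
simulate_rate_table <- function(n_donors = c(fetal = 3, cord = 2, post_infant = 6),
                                clones_per_donor = 5,
                                rates = c(fetal = 100, cord = 50, post_infant = 17),
                                donor_sd = 5, resid_sd = 8, seed = 1) {
  stopifnot(all(names(n_donors) %in% names(rates)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  cpd <- rep_len(clones_per_donor, length(n_donors))
  rows <- list()
  for (g in seq_along(n_donors)) {
    coh <- names(n_donors)[g]
    for (d in seq_len(n_donors[g])) {
      u <- stats::rnorm(1, 0, donor_sd)
      k <- cpd[g]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        clone = sprintf("%s_d%d_c%d", coh, d, seq_len(k)),
        donor = sprintf("%s_d%d", coh, d),
        cohort = coh,
        rate = rates[[coh]] + u + stats::rnorm(k, 0, resid_sd))
    }
  }
  out <- data.table::rbindlist(rows)
  out$cohort <- factor(out$cohort, levels = names(n_donors))
  out
}

#' Simulate per-clone mutation loads for the trisomy / early-burden models
#'
#' Generative model matching the fitted structure: per-donor age, a donor
#' random slope on age, a trisomy main effect, optional cell-type effect,
#' and karyotype-specific residual SDs (T21 cells are allowed a larger
#' spread, as observed in trisomic cohorts).
#'
#' @param n_d21,n_t21 Donors per karyotype.
#' @param clones_per_donor Clones per donor.
#' @param ga_weeks Gestational-age range (weeks) spanned by the donors; age
#'   since conception = (GA - 2 weeks) in years.
#' @param rate Mean load increase per year (`0` with `include_age = FALSE`
#'   yields the early-mutation design).
#' @param base Baseline load at age 0.
#' @param excess_t21 True trisomy main effect (extra mutations per cell).
#' @param effect_cell Additive ISC effect (default 0).
#' @param slope_sd SD of the donor random slope (per year).
#' @param sd_d21,sd_t21 Residual SDs per karyotype.
#' @param include_age If `FALSE`, ages are generated but the load does not
#'   depend on them (early-mutation design).
#' @param seed Integer seed.
#' @return data.table: clone, donor, trisomy21 (factor D21/T21), cell_type,
#'   age, load.
#' @export
simulate_load_table <- function(n_d21 = 5, n_t21 = 4, clones_per_donor = 5,
                                ga_weeks = c(12, 17), rate = 100, base = 0,
                                excess_t21 = 34, effect_cell = 0,
                                slope_sd = 10, sd_d21 = 7, sd_t21 = 15,
                                include_age = TRUE, seed = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n_donors <- n_d21 + n_t21
  ga <- seq(ga_weeks[1], ga_weeks[2], length.out = max(n_donors, 2L))[seq_len(n_donors)]
  ages <- (ga - 2) * 7 / 365.25
  # interleave karyotypes over the age range so age and trisomy are not confounded
  t21 <- c(rep(c(FALSE, TRUE), min(n_d21, n_t21)),
           rep(n_d21 > n_t21, abs(n_d21 - n_t21)))
  rows <- list()
  for (d in seq_len(n_donors)) {
    b <- stats::rnorm(1, 0, slope_sd)
    k <- clones_per_donor
    ct <- rep(c("HSPC", "ISC"), length.out = k)
    sd_res <- if (t21[d]) sd_t21 else sd_d21
    mu <- base + (if (include_age) (rate + b) * ages[d] else 0) +
      (if (t21[d]) excess_t21 else 0) + (ct == "ISC") * effect_cell
    rows[[d]] <- data.table::data.table(
      clone = sprintf("d%02d_c%d", d, seq_len(k)),
      donor = sprintf("d%02d", d),
      trisomy21 = factor(if (t21[d]) "T21" else "D21", levels = c("D21", "T21")),
      cell_type = factor(ct, levels = c("HSPC", "ISC")),
      age = ages[d],
      load = mu + stats::rnorm(k, 0, sd_res))
  }
  data.table::rbindlist(rows)
}
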