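# Developmental lineage reconstruction: binary mutation matrix -> rooted
# neighbor-joining tree -> branch mutation assignment -> bulk-contribution
# estimation (2 x median VAF) with chi-square branch subdivision and
# pairwise Fisher comparison of branches.

#' Build the binary clones x mutations matrix of a donor
#'
#' Union of the per-clone clonal variant sets and the shared-variant table;
#' presence means membership in the clone's qualifying set (clonal call or
#' shared-table present set). A zero row named `root` is appended to root
#' the tree. All-zero mutation columns are unplaceable and dropped with a
#' message.
#'
#' @param shared_table Result of [call_shared_variants()] (may be empty).
#' @param clonal_sets data.table of clonal calls with columns `clone`,
#'   `contig`, `pos`, `ref`, `alt`.
#' @param clones Character vector of all clone sample ids of the donor.
#' @return List: `matrix` ((clones+root) x mutations 0/1), `mutations`
#'   (data.table keyed by column: contig, pos, ref, alt, bulk_vaf/alt/ref
#'   where known).
#' @export
build_matrix <- function(shared_table, clonal_sets, clones) {
  if (length(clones) < 2) stop("at least 2 clones required")
  clonal_sets <- data.table::as.data.table(clonal_sets)
  muts <- list()
  if (!is.null(clonal_sets) && nrow(clonal_sets)) {
    cs <- clonal_sets[, c("contig", "pos", "ref", "alt", "clone")]
    muts$clonal <- cs
  }
  pres <- list()
  has_shared <- !is.null(shared_table) && nrow(shared_table)
  if (has_shared) {
    sh <- data.table::as.data.table(shared_table)
    pres <- sh[, list(clone = strsplit(present, ",")[[1]]),
               by = c("contig", "pos", "ref", "alt")]
    muts$shared <- pres[, c("contig", "pos", "ref", "alt", "clone")]
  }
  long <- data.table::rbindlist(muts)
  if (!nrow(long)) stop("no mutations to place")
  long <- unique(long)
  long$key <- site_key(long)
  keys <- unique(long$key)
  mat <- matrix(0L, length(clones) + 1L, length(keys),
                dimnames = list(c(clones, "root"), keys))
  long <- long[long$clone %in% clones, ]
  mat[cbind(match(long$clone, clones), match(long$key, keys))] <- 1L

  keep <- colSums(mat) > 0L
  if (any(!keep)) {
    message(sum(!keep), " all-zero mutation column(s) dropped (unplaceable)")
    mat <- mat[, keep, drop = FALSE]
    keys <- keys[keep]
  }
  info <- unique(long[, c("key", "contig", "pos", "ref", "alt")])
  info <- info[match(keys, info$key), ]
  if (has_shared) {
    sh$key <- site_key(sh)
    i <- match(keys, sh$key)
    info$bulk_vaf <- sh$bulk_vaf[i]
    info$bulk_alt <- sh$bulk_alt[i]
    info$bulk_ref <- sh$bulk_ref[i]
  } else {
    info$bulk_vaf <- NA_real_; info$bulk_alt <- NA_integer_; info$bulk_ref <- NA_integer_
  }
  list(matrix = mat, mutations = info[])
}

#' Build the rooted lineage tree by neighbor joining
#'
#' Pairwise Hamming distances over the 0/1 matrix (mutation units, no
#' normalization), neighbor joining, re-rooting at the zero-profile `root`
#' row; negative NJ branch lengths are clamped to 0.
#'
#' @param mat Binary matrix including the `root` row (as from
#'   [build_matrix()], pass `$matrix`), or the [build_matrix()] result list.
#' @param method `"nj"` (default) or `"upgma"`.
#' @return ape `phylo`, rooted, including the `root` tip.
#' @export
build_tree <- function(mat, method = c("nj", "upgma")) {
  method <- match.arg(method)
  if (is.list(mat) && !is.matrix(mat)) mat <- mat$matrix
  if (nrow(mat) < 3) stop("need >= 2 clones plus the root row")
  r <- rowSums(mat)
  H <- outer(r, r, "+") - 2 * tcrossprod(mat)
  if (method == "nj") {
    if (nrow(mat) == 3) {
      # nj() needs >= 4 tips; 3 taxa have a unique unrooted topology
      tr <- ape::read.tree(text = sprintf("(%s:1,%s:1,%s:1);",
                                          rownames(mat)[1], rownames(mat)[2],
                                          rownames(mat)[3]))
    } else {
      tr <- ape::nj(stats::as.dist(H))
    }
  } else {
    hc <- stats::hclust(stats::as.dist(H), method = "average")
    tr <- ape::as.phylo(hc)
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- ape::root(tr, outgroup = "root", resolve.root = TRUE)
  tr
}

# leaf-set (excluding the root tip) below each edge of a rooted tree
edge_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  # accumulate children into parents in postorder
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) {
    setdiff(desc[[tree$edge[e, 2]]], "root")
  })
}

#' Assign mutations to tree branches
#'
#' A mutation maps to the branch above the smallest clade whose leaf set
#' equals its carrier set; carrier sets matching no clade are reported as
#' conflicts and excluded from branch lengths. Edge lengths of the returned
#' tree are replaced by mutation counts.
#'
#' @param tree Rooted `phylo` including the `root` tip.
#' @param mat Binary matrix (or [build_matrix()] list) whose columns are the
#'   mutations to place.
#' @return List: `tree` (lengths = counts), `assignment` (data.table:
#'   mutation key, edge index or NA, clade string), `branches` (per-edge
#'   clade and mutation count), `conflicts` (keys).
#' @export
assign_branch_mutations <- function(tree, mat) {
  if (is.list(mat) && !is.matrix(mat)) mat <- mat$matrix
  clades <- edge_clades(tree)
  clade_key <- vapply(clades, function(x) paste(sort(x), collapse = ","), character(1))
  carriers <- apply(mat, 2, function(col) {
    paste(sort(setdiff(rownames(mat)[col > 0], "root")), collapse = ",")
  })
  edge_idx <- match(carriers, clade_key)
  assignment <- data.table::data.table(
    mutation = colnames(mat), edge = edge_idx, clade = carriers)
  counts <- tabulate(edge_idx[!is.na(edge_idx)], nbins = nrow(tree$edge))
  tree$edge.length <- counts
  branches <- data.table::data.table(
    edge = seq_along(clade_key), clade = clade_key, n_mutations = counts)
  branches <- branches[clade_key != "", ]
  list(tree = tree, assignment = assignment, branches = branches,
       conflicts = assignment$mutation[is.na(edge_idx)])
}

#' Early (pre-gastrulation) mutations of a donor
#'
#' Early mutations are retained shared variants with a nonzero VAF in the
#' germ-layer-discordant bulk sample; per-clone early load counts the early
#' mutations each clone carries.
#'
#' @param shared_table Result of [call_shared_variants()].
#' @param bulk_vaf_col Bulk VAF column to use (default `"bulk_vaf"`, the
#'   first bulk sample).
#' @return List: `early` (subset of the shared table), `per_clone`
#'   (data.table clone / early_load).
#' @export
early_mutations <- function(shared_table, bulk_vaf_col = "bulk_vaf") {
  sh <- data.table::as.data.table(shared_table)
  if (!nrow(sh)) return(list(early = sh, per_clone = data.table::data.table(
    clone = character(0), early_load = integer(0))))
  if (!bulk_vaf_col %in% names(sh)) stop("no bulk sample VAF column: ", bulk_vaf_col)
  early <- sh[sh[[bulk_vaf_col]] > 0, ]
  per_clone <- data.table::data.table(clone = unlist(strsplit(early$present, ",")))
  per_clone <- per_clone[, list(early_load = .N), by = "clone"]
  list(early = early, per_clone = per_clone[order(per_clone$clone)])
}

#' Estimate per-branch contributions to bulk tissue
#'
#' For each branch: mutations with nonzero bulk VAF are the "contributing"
#' ones; a chi-square test on their ref/alt counts decides whether the
#' branch spans multiple cell divisions (p < 0.05 -> subdivided, each
#' mutation reported as its own segment); the branch contribution is
#' `min(1, 2 x median nonzero VAF)`. Mutations on excluded contigs (e.g.
#' the trisomy proxy, where copy number distorts VAF) are ignored.
#'
#' @param assigned Result of [assign_branch_mutations()].
#' @param mutations Mutation table of [build_matrix()] (bulk_alt/bulk_ref
#'   columns required).
#' @param subdivide_alpha Chi-square threshold (default 0.05).
#' @param exclude_contigs Contigs excluded from contribution estimates.
#' @return data.table: edge, clade, n_mutations, n_contributing,
#'   median_vaf, contribution, chisq_p, subdivided, segments (list column of
#'   per-mutation 2xVAF when subdivided).
#' @export
branch_contribution <- function(assigned, mutations,
                                subdivide_alpha = 0.05,
                                exclude_contigs = character(0)) {
  mut <- data.table::as.data.table(mutations)
  mut$edge <- assigned$assignment$edge[match(mut$key, assigned$assignment$mutation)]
  mut <- mut[!is.na(mut$edge) & !(mut$contig %in% exclude_contigs), ]
  out <- list()
  for (e in sort(unique(mut$edge))) {
    m <- mut[mut$edge == e, ]
    clade <- assigned$branches$clade[assigned$branches$edge == e]
    nz <- !is.na(m$bulk_vaf) & m$bulk_vaf > 0
    n_con <- sum(nz)
    if (n_con == 0) {
      out[[length(out) + 1L]] <- data.table::data.table(
        edge = e, clade = clade, n_mutations = nrow(m), n_contributing = 0L,
        median_vaf = NA_real_, contribution = NA_real_, chisq_p = NA_real_,
        subdivided = FALSE, segments = list(numeric(0)))
      next
    }
    counts <- rbind(m$bulk_alt[nz], m$bulk_ref[nz])
    p <- if (n_con >= 2)
      suppressWarnings(stats::chisq.test(counts)$p.value) else NA_real_
    subdiv <- !is.na(p) && p < subdivide_alpha
    med <- stats::median(m$bulk_vaf[nz])
    out[[length(out) + 1L]] <- data.table::data.table(
      edge = e, clade = clade, n_mutations = nrow(m), n_contributing = n_con,
      median_vaf = med, contribution = min(1, 2 * med), chisq_p = p,
      subdivided = subdiv,
      segments = list(if (subdiv) pmin(1, 2 * m$bulk_vaf[nz]) else numeric(0)))
  }
  data.table::rbindlist(out)
}

#' Fisher comparison of two branches' bulk contributions
#'
#' Sums ref and alt allele counts over the nonzero-VAF mutations of each
#' branch and tests the 2x2 table with a two-sided Fisher exact test.
#'
#' @param alt_a,ref_a,alt_b,ref_b Per-mutation bulk allele counts of the two
#'   branches (nonzero-VAF mutations; each branch must have >= 1).
#' @return List: `p`, `table`.
#' @export
compare_branches <- function(alt_a, ref_a, alt_b, ref_b) {
  if (!length(alt_a) || !length(alt_b)) stop("empty branch in comparison")
  tab <- matrix(c(sum(alt_a), sum(ref_a), sum(alt_b), sum(ref_b)), 2,
                dimnames = list(c("alt", "ref"), c("a", "b")))
  list(p = stats::fisher.test(tab)$p.value, table = tab)
}

#' Compare the first two developmental lineage branches
#'
#' Identifies the two branches below the most recent common ancestor of all
#' clones and compares their bulk contributions with [compare_branches()].
#' A collapsed branch can span several cell divisions whose mutations have
#' systematically halving bulk VAFs, so summing all of a branch's counts
#' would compare mixtures of divisions rather than the first division
#' itself. The comparison therefore uses each branch's earliest detectable
#' marker: the mutation with the maximum bulk VAF (the division closest to
#' the trunk). The chi-square subdivision diagnostic is still reported.
#'
#' @param lineage A [donor_lineage()] result.
#' @param clones Clone sample ids of the donor.
#' @param subdivide_alpha Chi-square threshold for the reported subdivision
#'   flag (default 0.05).
#' @param exclude_contigs Contigs excluded (e.g. trisomy proxy).
#' @return List: `p` (Fisher), `branches` (data.table: clade,
#'   n_contributing, n_used, subdivided, contribution), or NULL when a first
#'   branch has no contributing mutation.
#' @export
first_branch_comparison <- function(lineage, clones, subdivide_alpha = 0.05,
                                    exclude_contigs = character(0)) {
  tr <- lineage$assigned$tree
  tips <- intersect(clones, tr$tip.label)
  mrca <- ape::getMRCA(tr, tips)
  edges <- which(tr$edge[, 1] == mrca)
  clades <- edge_clades(tr)
  edges <- edges[vapply(edges, function(e) length(clades[[e]]) > 0, logical(1))]
  if (length(edges) < 2) return(NULL)

  mut <- data.table::as.data.table(lineage$mutations)
  mut$edge <- lineage$assigned$assignment$edge[match(mut$key,
                                                     lineage$assigned$assignment$mutation)]
  mut <- mut[!is.na(mut$edge) & !(mut$contig %in% exclude_contigs) &
               !is.na(mut$bulk_vaf) & mut$bulk_vaf > 0, ]
  pick <- function(e) {
    m <- mut[mut$edge == e, ]
    if (!nrow(m)) return(NULL)
    subdiv <- FALSE
    if (nrow(m) >= 2) {
      p <- suppressWarnings(stats::chisq.test(rbind(m$bulk_alt, m$bulk_ref))$p.value)
      subdiv <- !is.na(p) && p < subdivide_alpha
    }
    list(all = m, used = m[which.max(m$bulk_vaf), ], subdivided = subdiv)
  }
  a <- pick(edges[1]); b <- pick(edges[2])
  if (is.null(a) || is.null(b)) return(NULL)
  cmp <- compare_branches(a$used$bulk_alt, a$used$bulk_ref,
                          b$used$bulk_alt, b$used$bulk_ref)
  row_of <- function(x, e) data.table::data.table(
    clade = paste(sort(clades[[e]]), collapse = ","),
    n_contributing = nrow(x$all), n_used = nrow(x$used),
    subdivided = x$subdivided,
    contribution = min(1, 2 * stats::median(x$used$bulk_vaf)))
  br <- rbind(row_of(a, edges[1]), row_of(b, edges[2]))
  list(p = cmp$p, branches = br, table = cmp$table)
}

#' Write a lineage tree as Newick plus a branch annotation sidecar
#'
#' @param assigned Result of [assign_branch_mutations()] (or a bare phylo).
#' @param path Newick output path.
#' @param contributions Optional [branch_contribution()] table written as
#'   `<path>.branches.tsv`.
#' @param drop_root Drop the zero-profile root tip before writing.
#' @return Invisibly, the Newick path.
#' @export
write_newick <- function(assigned, path, contributions = NULL, drop_root = FALSE) {
  tree <- if (inherits(assigned, "phylo")) assigned else assigned$tree
  if (drop_root && "root" %in% tree$tip.label)
    tree <- ape::drop.tip(tree, "root")
  ok <- tryCatch({ ape::write.tree(tree, file = path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("failed to write Newick to ", path)
  if (!is.null(contributions)) {
    ct <- data.table::as.data.table(contributions)
    ct$segments <- vapply(ct$segments, function(s) paste(round(s, 4), collapse = ","),
                          character(1))
    data.table::fwrite(ct, paste0(path, ".branches.tsv"), sep = "\t")
  }
  invisible(path)
}
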