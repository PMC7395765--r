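# Reference signature catalogs: reading/writing the 96-context TSV layout and
# generating synthetic catalogs for simulation and validation.

#' Read a 96-context signature catalog from TSV
#'
#' Expects the COSMIC layout: one row per trinucleotide channel (a character
#' column such as `A[C>A]A`; the first non-numeric column is used), one
#' numeric column per signature. Rows may appear in any order; the result is
#' canonicalized to the 96 lexicographic pyrimidine-centred contexts and each
#' column is renormalized to sum to 1.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric 96 x S matrix, rownames = channels, colnames = signatures.
#' @export
read_signature_catalog <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  is_chr <- vapply(dt, is.character, logical(1))
  if (!any(is_chr)) stop("no context label column found in catalog")
  ctx_col <- which(is_chr)[1]
  ctx <- dt[[ctx_col]]
  if (nrow(dt) != 96L)
    stop("catalog must have exactly 96 context rows, found ", nrow(dt))
  if (!setequal(ctx, CHANNELS_96) || anyDuplicated(ctx))
    stop("context column does not cover the 96 canonical channels exactly")
  mat <- as.matrix(dt[, -ctx_col, drop = FALSE])
  if (!is.numeric(mat)) stop("signature columns must be numeric")
  if (any(mat < 0)) stop("negative entry in signature catalog")
  mat <- mat[match(CHANNELS_96, ctx), , drop = FALSE]
  rownames(mat) <- CHANNELS_96
  cs <- colSums(mat)
  if (any(cs == 0)) stop("signature column sums to zero: ",
                         paste(colnames(mat)[cs == 0], collapse = ", "))
  sweep(mat, 2, cs, "/")
}

#' Write a signature catalog as TSV
#'
#' @param catalog 96 x S matrix with channel rownames.
#' @param path Output path.
#' @export
write_signature_catalog <- function(catalog, path) {
  stopifnot(nrow(catalog) == 96L)
  dt <- data.table::data.table(context = rownames(catalog))
  dt <- cbind(dt, data.table::as.data.table(catalog))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Generate a synthetic signature catalog
#'
#' Signatures are built on near-disjoint channel blocks (plus a small uniform
#' background), so columns are mutually distinguishable (pairwise cosine close
#' to 0). Useful for simulation truth and for exercising the refitting
#' machinery; labelled `S01`, `S02`, ... to make their synthetic origin clear.
#'
#' @param n_sig Number of signatures (<= 32).
#' @param seed Integer seed; the catalog is deterministic given the seed.
#' @param background Uniform mass added to every channel before normalization.
#' @return Column-stochastic 96 x `n_sig` matrix.
#' @export
synthetic_signature_catalog <- function(n_sig = 10, seed = 1, background = 1e-3) {
  stopifnot(n_sig >= 1, n_sig <= 32)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed) + 531L)
  block <- 96L %/% n_sig
  mat <- matrix(background, 96L, n_sig,
                dimnames = list(CHANNELS_96, sprintf("S%02d", seq_len(n_sig))))
  for (j in seq_len(n_sig)) {
    rows <- ((j - 1L) * block + 1L):(j * block)
    mat[rows, j] <- mat[rows, j] + stats::rexp(length(rows))
  }
  sweep(mat, 2, colSums(mat), "/")
}
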