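# Synthetic reference genome: random DNA contigs plus a positional index of
# trinucleotide contexts used to place simulated mutations consistently with
# the sequence.

#' Simulate a reference genome with a trinucleotide position index
#'
#' Generates uniform-random DNA for each configured contig and indexes, for
#' every genomic trinucleotide, the callable positions at which it occurs.
#' The callable mask is the leading `callable_fraction` of each contig
#' (excluding the first and last base, which lack a flank).
#'
#' @param config A [cohort_config()] (only `genome`, `callable_fraction` and
#'   `seed` are used), or a data.frame with columns `contig`, `length`.
#' @param callable_fraction Used when `config` is a plain data.frame.
#' @param seed Used when `config` is a plain data.frame.
#' @return A list of class `sim_genome`: `seqs` (DNAStringSet), `index`
#'   (named list trinucleotide -> data.table(contig, pos) of callable centre
#'   positions), `contigs` (data.table contig/length/callable_end).
#' @export
simulate_genome <- function(config, callable_fraction = NULL, seed = NULL) {
  if (inherits(config, "cohort_config")) {
    gdf <- config$genome
    callable_fraction <- config$callable_fraction
    seed <- genome_seed(config$seed)
  } else {
    gdf <- config
    if (is.null(callable_fraction)) callable_fraction <- 0.9
    if (is.null(seed)) seed <- 1L
  }
  stopifnot(all(c("contig", "length") %in% names(gdf)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  seqs <- Biostrings::DNAStringSet(vapply(gdf$length, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- gdf$contig

  contigs <- data.table::data.table(
    contig = gdf$contig,
    length = as.integer(gdf$length),
    callable_end = pmax(2L, as.integer(floor(gdf$length * callable_fraction)))
  )

  index_parts <- vector("list", nrow(contigs))
  for (k in seq_len(nrow(contigs))) {
    s <- as.character(seqs[[k]])
    v <- match(strsplit(s, "")[[1]], DNA_BASES) - 1L
    n <- length(v)
    centre <- 2L:(n - 1L)
    code <- v[centre - 1L] * 16L + v[centre] * 4L + v[centre + 1L]
    keep <- centre <= contigs$callable_end[k]
    index_parts[[k]] <- data.table::data.table(
      trinuc = trinuc_from_code(code[keep]),
      contig = contigs$contig[k],
      pos = centre[keep]
    )
  }
  idx <- data.table::rbindlist(index_parts)
  index <- split(idx[, c("contig", "pos")], idx$trinuc)

  structure(list(seqs = seqs, index = index, contigs = contigs),
            class = "sim_genome")
}

trinuc_from_code <- function(code) {
  paste0(DNA_BASES[code %/% 16L + 1L],
         DNA_BASES[(code %/% 4L) %% 4L + 1L],
         DNA_BASES[code %% 4L + 1L])
}

genome_seed <- function(seed) (as.integer(seed) %% 1000000L) + 900001L

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
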