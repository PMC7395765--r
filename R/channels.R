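# 96-channel single-base-substitution conventions (COSMIC SBS layout):
# six pyrimidine-centred substitution types x 16 flanking-base combinations.

SBS_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' The 96 trinucleotide substitution channels
#'
#' Channel labels in canonical COSMIC order: substitution types
#' `C>A, C>G, C>T, T>A, T>C, T>G`, and within each type the 16 flanking
#' combinations with the 5' base varying slowest (`A[C>A]A`, `A[C>A]C`, ...).
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  unlist(lapply(SBS_TYPES, function(tp) {
    as.vector(t(outer(DNA_BASES, DNA_BASES,
                      function(l, r) paste0(l, "[", tp, "]", r))))
  }))
}

CHANNELS_96 <- sbs_channels()

revcomp_chr <- function(x) {
  # reverse complement of plain character strings (vectorized)
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

is_pyrimidine <- function(base) base %in% c("C", "T")

#' Genomic trinucleotides matching a channel
#'
#' Each channel matches two genomic triplets: the pyrimidine-strand triplet
#' itself and its reverse complement (purine-centred).
#'
#' @param channel Channel label, e.g. `"A[C>T]A"`.
#' @return Character vector of the two matching triplets (pyrimidine first).
#' @keywords internal
channel_triplets <- function(channel) {
  l <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  r <- substr(channel, 7, 7)
  pyr <- paste0(l, ref, r)
  c(pyr = pyr, pur = revcomp_chr(pyr))
}

#' Channel alt allele on a given strand
#'
#' @param channel Channel label.
#' @param strand `"pyr"` if the genomic centre base is the pyrimidine of the
#'   channel, `"pur"` otherwise.
#' @return Single alt base as observed on the genomic plus strand.
#' @keywords internal
channel_alt <- function(channel, strand) {
  alt <- substr(channel, 5, 5)
  ifelse(strand == "pyr", alt, complement_base(alt))
}

#' Cosine similarity between two nonnegative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]` for nonnegative input; `NA` if either
#'   vector is all zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Pyrimidine-strandized trinucleotide channel of an SNV
#'
#' Looks up the reference trinucleotide around each variant and maps the
#' substitution to one of the 96 canonical channels, reverse-complementing
#' when the reference base is a purine. Vectorized over `contig`, `pos`,
#' `ref`, `alt`.
#'
#' @param fasta A `Biostrings::DNAStringSet` (names = contigs) or path to a
#'   FASTA file.
#' @param contig,pos,ref,alt Variant coordinates (1-based) and alleles.
#' @return Character vector of channel labels.
#' @export
trinucleotide_context <- function(fasta, contig, pos, ref, alt) {
  seqs <- load_fasta(fasta)
  n <- length(pos)
  stopifnot(length(contig) == n, length(ref) == n, length(alt) == n)
  if (n == 0) return(character(0))
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("trinucleotide_context() is defined for SNVs only")
  bad_contig <- !(contig %in% names(seqs))
  if (any(bad_contig))
    stop("unknown contig: ", paste(unique(contig[bad_contig]), collapse = ", "))
  lens <- Biostrings::width(seqs)[match(contig, names(seqs))]
  if (any(pos < 2L | pos > lens - 1L))
    stop("position without both flanking bases inside the contig (pos must be in [2, length-1])")

  trip <- character(n)
  for (ct in unique(contig)) {
    i <- which(contig == ct)
    v <- Biostrings::extractAt(seqs[[ct]],
                               IRanges::IRanges(start = pos[i] - 1L, width = 3L))
    trip[i] <- as.character(v)
  }
  centre <- substr(trip, 2, 2)
  plus <- centre == ref
  minus <- centre == complement_base(ref)
  if (any(!plus & !minus))
    stop("reference mismatch: FASTA base differs from ref and its complement at ",
         paste(head(paste0(contig, ":", pos)[!plus & !minus], 5), collapse = ", "))

  # put everything on the strand where the stated ref is the genomic base;
  # ref and alt are stated on the same strand, so alt is unchanged
  eff_trip <- ifelse(plus, trip, revcomp_chr(trip))
  eff_alt <- alt
  # then strandize to the pyrimidine centre
  pyr <- is_pyrimidine(substr(eff_trip, 2, 2))
  eff_alt <- ifelse(pyr, eff_alt, complement_base(eff_alt))
  eff_trip <- ifelse(pyr, eff_trip, revcomp_chr(eff_trip))
  paste0(substr(eff_trip, 1, 1), "[", substr(eff_trip, 2, 2), ">", eff_alt,
         "]", substr(eff_trip, 3, 3))
}

load_fasta <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) return(fasta)
  if (is.character(fasta) && length(fasta) == 1L) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  stop("fasta must be a DNAStringSet or a path to a FASTA file")
}
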