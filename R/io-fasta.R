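#' Read a genome FASTA into a contig table
#'
#' Contigs are returned as a tibble with one row per sequence. Sequences are
#' uppercased on read and restricted to the `{A,C,G,T,N}` alphabet. A
#' pan-genome here is a set of reference chromosomes plus non-reference
#' contigs assembled from reads that did not map to the single reference;
#' the `is_reference` flag records which side of that split each contig
#' belongs to, decided by matching `reference_pattern` against the name.
#'
#' @param path FASTA file.
#' @param reference_pattern Regular expression; contig names matching it are
#'   flagged `is_reference = TRUE`. Default `"^chr"`.
#' @return A tibble with columns `name`, `seq`, `is_reference`.
#' @export
read_fasta <- function(path, reference_pattern = "^chr") {
  dna <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort("non-ACGTN characters in FASTA")
      }
      invokeRestart("muffleWarning")
    })
  nm <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(nm)) abort("duplicate contig name in FASTA")
  seqs <- toupper(as.character(dna))
  if (any(nchar(seqs) == 0L)) abort("empty sequence in FASTA")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("non-ACGTN characters in contig(s): %s",
                  paste(nm[bad], collapse = ", ")))
  }
  tibble(name = nm, seq = unname(seqs),
         is_reference = grepl(reference_pattern, nm))
}

#' Write a contig table to FASTA
#'
#' @param contigs Tibble as returned by [read_fasta()].
#' @param path Output file.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70L) {
  assert_cols(contigs, c("name", "seq"), "contigs")
  if (anyDuplicated(contigs$name)) abort("duplicate contig name")
  dna <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$name))
  Biostrings::writeXStringSet(dna, path, width = width)
  invisible(path)
}

contig_seq <- function(contigs, name) {
  i <- match(name, contigs$name)
  if (is.na(i)) abort(sprintf("unknown contig '%s'", name))
  contigs$seq[[i]]
}
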