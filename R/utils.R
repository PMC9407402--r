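# Shared internal helpers. All genomic coordinates in this package are
# 1-based and inclusive, matching the native GFF3/VCF convention; the
# coverage dialect consumed by read_coverage() is declared 1-based inclusive
# for the same reason.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps the
#' package's character-vector currency.
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) unname(COMPLEMENT[b])

# intervals are tibbles with integer columns start, end (1-based inclusive)
interval_tbl <- function(start = integer(), end = integer()) {
  tibble(start = as.integer(start), end = as.integer(end))
}

interval_len <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  sum(iv$end - iv$start + 1L)
}

# collapse a sorted vector of positions into maximal runs
positions_to_intervals <- function(pos) {
  pos <- sort(unique(as.integer(pos)))
  if (length(pos) == 0L) return(interval_tbl())
  brk <- c(TRUE, diff(pos) != 1L)
  grp <- cumsum(brk)
  tibble(
    start = as.integer(tapply(pos, grp, min)),
    end   = as.integer(tapply(pos, grp, max))
  )
}

intervals_to_positions <- function(iv) {
  if (nrow(iv) == 0L) return(integer())
  unlist(Map(seq.int, iv$start, iv$end), use.names = FALSE)
}

in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= iv$start & p <= iv$end), logical(1))
}

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

# deterministic per-stage seed derived from one user seed; stays < 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stage)
}
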