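#' Read and write per-accession coverage tracks
#'
#' Coverage is a run-length table with columns `contig`, `start`, `end`,
#' `depth`. In this package's dialect the coordinates are 1-based and
#' inclusive (the same convention as GFF3/VCF), so a single covered base is
#' `start == end`. Positions absent from the table have depth 0.
#'
#' @param path TSV file.
#' @return Coverage tibble.
#' @export
read_coverage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    contig = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    depth = readr::col_double()
                  ))
}

#' @rdname read_coverage
#' @param coverage Coverage tibble.
#' @export
write_coverage <- function(coverage, path) {
  assert_cols(coverage, c("contig", "start", "end", "depth"), "coverage")
  readr::write_tsv(coverage, path)
  invisible(path)
}

#' Read and write differential-expression tables
#'
#' One row per gene per comparison, with columns `dataset`, `comparison`,
#' `gene_id`, `log2fc`, `padj` (BH-adjusted p, may be NA for untested
#' genes).
#'
#' @param path TSV file.
#' @return DEG tibble.
#' @export
read_deg <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    dataset = readr::col_character(),
                    comparison = readr::col_character(),
                    gene_id = readr::col_character(),
                    log2fc = readr::col_double(),
                    padj = readr::col_double()
                  ))
}

#' @rdname read_deg
#' @param deg DEG tibble.
#' @export
write_deg <- function(deg, path) {
  assert_cols(deg, c("dataset", "comparison", "gene_id", "log2fc", "padj"),
              "deg")
  readr::write_tsv(deg, path)
  invisible(path)
}

#' Read and write QTL marker tables
#'
#' Columns: `qtl_id`, `marker_id`, and either a marker `sequence` (to be
#' placed by exact matching with [place_markers()]) or a resolved placement
#' `contig` + `pos`; at least one of the two must be present per row.
#'
#' @param path TSV file.
#' @return Marker tibble.
#' @export
read_markers <- function(path) {
  mk <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(mk, c("qtl_id", "marker_id"), "markers")
  if (!"sequence" %in% names(mk)) mk$sequence <- NA_character_
  if (!"contig" %in% names(mk)) mk$contig <- NA_character_
  if (!"pos" %in% names(mk)) mk$pos <- NA_integer_
  unresolved <- is.na(mk$sequence) & (is.na(mk$contig) | is.na(mk$pos))
  if (any(unresolved)) {
    abort("marker rows need a sequence or a contig+pos placement")
  }
  as_tibble(mk)
}

#' @rdname read_markers
#' @param markers Marker tibble.
#' @export
write_markers <- function(markers, path) {
  assert_cols(markers, c("qtl_id", "marker_id"), "markers")
  readr::write_tsv(markers, path)
  invisible(path)
}

#' Read and write presence/absence matrices
#'
#' Stored as a TSV of 0/1 with a leading `gene_id` column and one column
#' per accession.
#'
#' @param path TSV file.
#' @return Presence tibble (`gene_id` + logical accession columns).
#' @export
read_presence <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(x, "gene_id", "presence")
  acc <- setdiff(names(x), "gene_id")
  x[acc] <- lapply(x[acc], function(v) as.logical(as.integer(v)))
  as_tibble(x)
}

#' @rdname read_presence
#' @param presence Presence tibble.
#' @export
write_presence <- function(presence, path) {
  acc <- setdiff(names(presence), "gene_id")
  out <- presence
  out[acc] <- lapply(out[acc], as.integer)
  readr::write_tsv(out, path)
  invisible(path)
}

# presence tibble -> logical matrix (genes x accessions)
presence_matrix <- function(presence) {
  acc <- setdiff(names(presence), "gene_id")
  m <- as.matrix(as.data.frame(presence[acc]))
  rownames(m) <- presence$gene_id
  storage.mode(m) <- "logical"
  m
}
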