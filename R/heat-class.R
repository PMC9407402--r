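#' Heat-response classes
#'
#' The five spikelet-fertility classes used to grade rice accessions after
#' heat exposure, ordered from most to least tolerant: highly tolerant (HT),
#' tolerant (T), moderately tolerant (MT), susceptible (S) and highly
#' susceptible (HS).
#'
#' @export
heat_classes <- c("HT", "T", "MT", "S", "HS")

#' Classify spikelet fertility into a heat-response class
#'
#' Accessions are graded by the percentage of spikelets that remain fertile
#' after heat exposure. The published ranges overlap at their boundaries
#' (50, 35 and 15), so this implementation resolves them half-open upward:
#' HT: f > 65; T: 50 < f <= 65; MT: 35 < f <= 50; S: 15 < f <= 35;
#' HS: f <= 15. The partition is exhaustive and mutually exclusive over
#' \[0, 100\].
#'
#' @param fertility Numeric vector of spikelet-fertility percentages in
#'   \[0, 100\].
#' @return Character vector of heat classes (one of [heat_classes]).
#' @examples
#' classify_heat_response(c(70, 65, 50, 35, 15))
#' @export
classify_heat_response <- function(fertility) {
  if (!is.numeric(fertility)) abort("`fertility` must be numeric")
  bad <- !is.na(fertility) & (fertility < 0 | fertility > 100)
  if (any(bad)) {
    abort(sprintf("fertility out of [0, 100]: %s",
                  paste(fertility[bad], collapse = ", ")))
  }
  out <- rep(NA_character_, length(fertility))
  out[fertility > 65] <- "HT"
  out[fertility > 50 & fertility <= 65] <- "T"
  out[fertility > 35 & fertility <= 50] <- "MT"
  out[fertility > 15 & fertility <= 35] <- "S"
  out[fertility <= 15] <- "HS"
  out
}

#' Read and write accession metadata
#'
#' Metadata is a TSV with header and columns `accession`, `subpopulation`,
#' `fertility` (percent, may be NA), `heat_class` and `depth` (fold
#' coverage, may be NA). When both `fertility` and `heat_class` are present
#' they must agree with [classify_heat_response()].
#'
#' @param path File path.
#' @return `read_meta()` returns a tibble with the columns above.
#' @export
read_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            accession = readr::col_character(),
                            subpopulation = readr::col_character(),
                            fertility = readr::col_double(),
                            heat_class = readr::col_character(),
                            depth = readr::col_double()
                          ))
  validate_meta(meta)
}

#' @rdname read_meta
#' @param meta Metadata tibble.
#' @export
write_meta <- function(meta, path) {
  validate_meta(meta)
  readr::write_tsv(meta, path)
  invisible(path)
}

validate_meta <- function(meta) {
  assert_cols(meta, c("accession", "heat_class"), "meta")
  if (anyDuplicated(meta$accession)) abort("duplicate accession in metadata")
  bad_class <- !meta$heat_class %in% heat_classes
  if (any(bad_class)) {
    abort(sprintf("unknown heat_class: %s",
                  paste(unique(meta$heat_class[bad_class]), collapse = ", ")))
  }
  if ("fertility" %in% names(meta)) {
    have <- !is.na(meta$fertility)
    expect <- classify_heat_response(meta$fertility[have])
    if (any(expect != meta$heat_class[have])) {
      abort("heat_class inconsistent with spikelet fertility")
    }
  }
  as_tibble(meta)
}
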