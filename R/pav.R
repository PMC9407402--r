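#' PAV-calling parameters
#'
#' Defaults mirror a coverage-based gene-loss screen: a gene body base
#' counts as covered at depth >= `min_cov` (default 5 reads) and a gene is
#' absent when the uncovered fraction reaches `lost_cutoff` (default 0.2,
#' i.e. present requires strictly more than 80% of the body covered).
#' Accessions sequenced at `min_depth_accession` fold-coverage or less
#' (default 10x) are excluded from matrix construction.
#'
#' @param min_cov Minimum read depth for a base to count as covered.
#' @param lost_cutoff Maximum uncovered fraction compatible with presence.
#' @param min_depth_accession Accession-level fold-coverage cutoff.
#' @param gene_body Which bases constitute the gene body: `"exons"`
#'   (default, exon bases only) or `"span"` (the full gene span including
#'   introns).
#' @return A list of class `pav_params`.
#' @export
pav_params <- function(min_cov = 5, lost_cutoff = 0.2,
                       min_depth_accession = 10,
                       gene_body = c("exons", "span")) {
  if (min_cov < 1) abort("min_cov must be >= 1")
  if (lost_cutoff <= 0 || lost_cutoff >= 1) abort("lost_cutoff must be in (0, 1)")
  structure(list(min_cov = min_cov, lost_cutoff = lost_cutoff,
                 min_depth_accession = min_depth_accession,
                 gene_body = match.arg(gene_body)),
            class = "pav_params")
}

gene_body_intervals <- function(model_row, gene_body) {
  if (gene_body == "span") {
    interval_tbl(model_row$start, model_row$end)
  } else {
    model_row$exons[[1]]
  }
}

#' Call presence/absence of one gene from a coverage track
#'
#' A gene is present when strictly more than `1 - lost_cutoff` (by default
#' >80%) of its gene body is covered by at least `min_cov` reads; otherwise
#' absent. Positions missing from the coverage table count as depth 0.
#'
#' @param model_row One-row gene-model tibble.
#' @param coverage Coverage tibble for the accession (see
#'   [read_coverage()]).
#' @param params [pav_params()].
#' @return Logical scalar: `TRUE` when present.
#' @export
call_presence <- function(model_row, coverage, params = pav_params()) {
  body <- gene_body_intervals(model_row, params$gene_body)
  total <- interval_len(body)
  if (total == 0L) abort("empty gene body")
  cov <- coverage[coverage$contig == model_row$contig &
                    coverage$depth >= params$min_cov, , drop = FALSE]
  covered <- 0L
  if (nrow(cov) > 0L) {
    body_ir <- IRanges::IRanges(body$start, body$end)
    cov_ir <- IRanges::reduce(IRanges::IRanges(cov$start, cov$end))
    covered <- sum(IRanges::width(IRanges::intersect(body_ir, cov_ir)))
  }
  (covered / total) > (1 - params$lost_cutoff)
}

#' Build the gene presence/absence matrix across accessions
#'
#' Accessions whose sequencing depth (from `meta$depth`) is at or below
#' `params$min_depth_accession` are excluded; the exclusion list is
#' attached as the `"excluded"` attribute and reported via a message.
#'
#' @param models Gene-model tibble.
#' @param coverages Named list of coverage tibbles, one per accession.
#' @param meta Accession metadata with `accession` and `depth` columns.
#' @param params [pav_params()].
#' @return Presence tibble: `gene_id` plus one logical column per retained
#'   accession, with attribute `"excluded"` (tibble of accession, depth,
#'   reason).
#' @export
build_matrix <- function(models, coverages, meta, params = pav_params()) {
  assert_cols(meta, c("accession", "depth"), "meta")
  meta <- meta[meta$accession %in% names(coverages), , drop = FALSE]
  low <- !is.na(meta$depth) & meta$depth <= params$min_depth_accession
  excluded <- tibble(accession = meta$accession[low],
                     depth = meta$depth[low],
                     reason = sprintf("depth <= %gx",
                                      params$min_depth_accession))
  keep <- meta$accession[!low]
  if (length(keep) == 0L) abort("no accession passes the depth filter")
  if (nrow(excluded) > 0L) {
    inform(sprintf("excluding %d accession(s) at <= %gx depth: %s",
                   nrow(excluded), params$min_depth_accession,
                   paste(excluded$accession, collapse = ", ")))
  }

  body <- lapply(seq_len(nrow(models)), function(i) {
    gene_body_intervals(models[i, ], params$gene_body)
  })
  body_gr <- GenomicRanges::GRanges(
    rep(models$contig, vapply(body, nrow, integer(1))),
    IRanges::IRanges(
      unlist(lapply(body, `[[`, "start")),
      unlist(lapply(body, `[[`, "end"))
    )
  )
  body_gene <- rep(seq_len(nrow(models)), vapply(body, nrow, integer(1)))
  total_len <- vapply(body, interval_len, integer(1))
  if (any(total_len == 0L)) abort("empty gene body")

  cols <- lapply(keep, function(acc) {
    cov <- coverages[[acc]]
    cov <- cov[cov$depth >= params$min_cov, , drop = FALSE]
    covered <- numeric(nrow(models))
    if (nrow(cov) > 0L) {
      cov_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        cov$contig, IRanges::IRanges(cov$start, cov$end)))
      hits <- GenomicRanges::findOverlaps(body_gr, cov_gr)
      if (length(hits) > 0L) {
        ov <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(body_gr)[S4Vectors::queryHits(hits)],
          IRanges::ranges(cov_gr)[S4Vectors::subjectHits(hits)]))
        covered <- as.numeric(tapply(
          ov, factor(body_gene[S4Vectors::queryHits(hits)],
                     levels = seq_len(nrow(models))), sum, default = 0))
        covered[is.na(covered)] <- 0
      }
    }
    (covered / total_len) > (1 - params$lost_cutoff)
  })
  out <- tibble(gene_id = models$gene_id)
  out[keep] <- cols
  attr(out, "excluded") <- excluded
  out
}

#' Classify genes as core, variable and private
#'
#' Core genes are present in every accession of the panel; variable
#' (dispensable) genes are absent in at least one; private genes, a subset
#' of the variable class, are present in exactly one accession. The two
#' classes partition the gene set.
#'
#' @param presence Presence tibble.
#' @return Tibble with `gene_id`, `n_present`, `class`
#'   (`"core"`/`"variable"`) and `private` (logical).
#' @export
classify_genes <- function(presence) {
  m <- presence_matrix(presence)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("empty presence matrix")
  n_present <- rowSums(m)
  tibble(
    gene_id = presence$gene_id,
    n_present = as.integer(n_present),
    class = ifelse(n_present == ncol(m), "core", "variable"),
    private = n_present == 1L
  )
}

#' Genes uniquely present in a phenotype group
#'
#' Returns the genes present in at least one accession of the target group
#' and in none of the accessions outside it (e.g. genes found only in
#' heat-resistant cultivars).
#'
#' @param presence Presence tibble.
#' @param meta Accession metadata with `accession` and `heat_class`.
#' @param group Character vector of heat classes defining the group.
#' @return Tibble with `gene_id` and `n_in_group` (carrier count).
#' @export
group_unique_genes <- function(presence, meta, group) {
  if (length(group) == 0L) abort("group must select at least one class")
  acc <- setdiff(names(presence), "gene_id")
  cls <- meta$heat_class[match(acc, meta$accession)]
  if (anyNA(cls)) abort("metadata missing for some matrix accessions")
  in_grp <- acc[cls %in% group]
  out_grp <- setdiff(acc, in_grp)
  if (length(in_grp) == 0L) abort("group selects no accessions")
  m <- presence_matrix(presence)
  n_in <- rowSums(m[, in_grp, drop = FALSE])
  n_out <- if (length(out_grp)) rowSums(m[, out_grp, drop = FALSE]) else 0
  keep <- n_in >= 1L & n_out == 0L
  tibble(gene_id = presence$gene_id[keep],
         n_in_group = as.integer(n_in[keep]))
}

#' Pairwise Jaccard similarity of presence profiles
#'
#' `J(a, b) = |genes present in both| / |genes present in either|`.
#' An accession with no present genes has similarity 0 against any
#' non-empty accession and 1 against itself.
#'
#' @param presence Presence tibble.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
jaccard_matrix <- function(presence) {
  m <- presence_matrix(presence)
  if (ncol(m) < 2L) abort("need at least 2 accessions")
  mm <- m * 1L
  inter <- crossprod(mm)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  j <- ifelse(uni == 0, 0, inter / uni)
  diag(j) <- 1
  j
}

#' PAV distance matrix (1 - Jaccard)
#'
#' @param presence Presence tibble.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pav_distance <- function(presence) {
  1 - jaccard_matrix(presence)
}
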