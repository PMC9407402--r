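#' Call differentially expressed genes per comparison
#'
#' A gene is upregulated in a comparison when `padj <= padj_max` and
#' `log2fc >= lfc_min`, downregulated when `padj <= padj_max` and
#' `log2fc <= -lfc_min` (both thresholds inclusive, defaults
#' `padj <= 0.05` and `|log2FC| >= 1`). Genes with NA `padj` are never
#' significant. Duplicate (dataset, comparison, gene) rows are an error.
#'
#' @param deg DEG tibble (`dataset`, `comparison`, `gene_id`, `log2fc`,
#'   `padj`).
#' @param padj_max Adjusted-p threshold in (0, 1].
#' @param lfc_min Absolute log2 fold-change threshold, >= 0.
#' @return Tibble of significant calls: `dataset`, `comparison`,
#'   `gene_id`, `direction` (`"up"`/`"down"`), `log2fc`, `padj`.
#' @export
call_degs <- function(deg, padj_max = 0.05, lfc_min = 1.0) {
  if (padj_max <= 0 || padj_max > 1) abort("padj_max must be in (0, 1]")
  if (lfc_min < 0) abort("lfc_min must be >= 0")
  assert_cols(deg, c("dataset", "comparison", "gene_id", "log2fc", "padj"),
              "deg")
  dup <- duplicated(deg[, c("dataset", "comparison", "gene_id")])
  if (any(dup)) {
    abort(sprintf("duplicate (dataset, comparison, gene) row(s), e.g. %s/%s/%s",
                  deg$dataset[dup][1], deg$comparison[dup][1],
                  deg$gene_id[dup][1]))
  }
  sig <- !is.na(deg$padj) & deg$padj <= padj_max &
    abs(deg$log2fc) >= lfc_min
  deg[sig, , drop = FALSE] |>
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    select("dataset", "comparison", "gene_id", "direction", "log2fc", "padj")
}

#' Cross-dataset DEG consensus with contradiction exclusion
#'
#' A gene is a consensus up-gene when it is called up in at least one
#' comparison and down in none, and symmetrically for down. Genes called
#' up somewhere and down elsewhere — across datasets or between
#' comparisons of one dataset — carry a contradicting expression profile
#' and are excluded. Genes untested in a dataset are neutral: absence of a
#' row neither supports nor contradicts.
#'
#' @param calls Significant calls from [call_degs()].
#' @return Tibble with one row per called gene: `gene_id`, `status`
#'   (`"up"`, `"down"`, `"contradictory"`), `n_up`, `n_down` (comparison
#'   counts), `datasets_up`, `datasets_down` (comma-collapsed dataset
#'   names, for Venn-style reporting).
#' @export
consensus_degs <- function(calls) {
  assert_cols(calls, c("dataset", "comparison", "gene_id", "direction"),
              "calls")
  calls |>
    group_by(.data$gene_id) |>
    summarise(
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      datasets_up = paste(sort(unique(.data$dataset[.data$direction == "up"])),
                          collapse = ","),
      datasets_down = paste(sort(unique(.data$dataset[.data$direction == "down"])),
                            collapse = ","),
      .groups = "drop") |>
    mutate(status = dplyr::case_when(
      .data$n_up > 0 & .data$n_down > 0 ~ "contradictory",
      .data$n_up > 0 ~ "up",
      TRUE ~ "down")) |>
    select("gene_id", "status", "n_up", "n_down",
           "datasets_up", "datasets_down")
}

#' Intersect consensus DEGs with group-SNP-bearing genes
#'
#' Candidate genes are those with a consistent differential-expression
#' consensus (up or down, contradictions already excluded) *and* at least
#' one group-specific SNP. Each candidate carries its evidence: the SNP
#' categories on the gene and the datasets supporting the expression call,
#' plus the reference/non-reference contig flag for the split reporting.
#'
#' @param consensus Tibble from [consensus_degs()].
#' @param group_snps A `group_snp_result` from [select_group_specific()].
#' @return Tibble of candidates: `gene_id`, `direction`, `is_reference`,
#'   `snp_categories`, `n_snps`, `datasets`.
#' @export
intersect_with_snp_genes <- function(consensus, group_snps) {
  if (!inherits(group_snps, "group_snp_result")) {
    abort("`group_snps` must be a group_snp_result")
  }
  per_gene <- group_snps$per_gene
  if (nrow(consensus) > 0L && nrow(per_gene) > 0L &&
        length(intersect(consensus$gene_id, per_gene$gene_id)) == 0L &&
        nrow(dplyr::filter(consensus, .data$status != "contradictory")) > 0L) {
    abort("no gene id shared between DEG tables and SNP gene index: gene namespaces do not match")
  }
  consensus |>
    filter(.data$status %in% c("up", "down")) |>
    inner_join(per_gene, by = "gene_id") |>
    mutate(direction = .data$status,
           datasets = ifelse(.data$direction == "up",
                             .data$datasets_up, .data$datasets_down)) |>
    select("gene_id", "direction", "is_reference",
           snp_categories = "categories", "n_snps", "datasets") |>
    arrange(desc(.data$direction), .data$gene_id)
}
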