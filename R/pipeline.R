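#' Run the full candidate-gene discovery pipeline on a study directory
#'
#' Convenience driver that chains every stage on a directory laid out like
#' the output of [simulate_panheat()] (or any study exported in the same
#' formats): PAV matrix and core/variable classification, SNP filtering
#' and consequence annotation, group-specific SNP selection for the target
#' heat classes, DEG consensus and intersection, marker placement, QTL
#' interval construction and the final QTL-resident candidate report.
#'
#' @param dir Study directory containing `genome.fa`, `genes.gff3`,
#'   `meta.tsv`, `variants.vcf.gz`, `deg.tsv`, `markers.tsv` and
#'   `coverage/cov_<accession>.tsv` files.
#' @param target_classes Heat classes whose private alleles define the
#'   screen (default `"HT"`).
#' @param pav [pav_params()].
#' @param flank Flank distance for annotation and SNP scope (bp).
#' @param padj_max,lfc_min DEG thresholds.
#' @param maf_min,max_missing_fraction SNP filter thresholds.
#' @param merge_qtls Union overlapping QTL intervals.
#' @return A list of class `panheat_result` with elements `presence`,
#'   `gene_classes`, `filtered_variants`, `consequences`, `group_snps`,
#'   `consensus`, `candidates`, `markers`, `intervals`, `membership`,
#'   `report`, plus the loaded `models`, `contigs` and `meta`.
#' @export
run_panheat <- function(dir, target_classes = "HT", pav = pav_params(),
                        flank = 2000, padj_max = 0.05, lfc_min = 1,
                        maf_min = 0.05, max_missing_fraction = 0.8,
                        merge_qtls = TRUE) {
  contigs <- read_fasta(file.path(dir, "genome.fa"))
  models <- read_gff3(file.path(dir, "genes.gff3"))
  meta <- read_meta(file.path(dir, "meta.tsv"))
  cov_files <- list.files(file.path(dir, "coverage"), pattern = "^cov_.*\\.tsv$",
                          full.names = TRUE)
  coverages <- setNames(lapply(cov_files, read_coverage),
                        sub("^cov_(.*)\\.tsv$", "\\1", basename(cov_files)))

  presence <- build_matrix(models, coverages, meta, pav)
  gene_classes <- classify_genes(presence)

  variants <- read_vcf(file.path(dir, "variants.vcf.gz"))
  filtered <- filter_variants(variants, maf_min = maf_min,
                              max_missing_fraction = max_missing_fraction)
  consequences <- annotate_variants(filtered, models, contigs, flank = flank)
  group_snps <- select_group_specific(
    filtered, consequences, meta, target_classes = target_classes,
    reference_contigs = contigs$name[contigs$is_reference])

  deg <- read_deg(file.path(dir, "deg.tsv"))
  calls <- call_degs(deg, padj_max = padj_max, lfc_min = lfc_min)
  consensus <- consensus_degs(calls)
  candidates <- intersect_with_snp_genes(consensus, group_snps)

  markers <- place_markers(read_markers(file.path(dir, "markers.tsv")), contigs)
  intervals <- build_intervals(markers, merge = merge_qtls)
  membership <- genes_in_qtls(models, intervals)
  report <- final_candidates(candidates, membership)

  structure(list(
    presence = presence, gene_classes = gene_classes,
    filtered_variants = filtered, consequences = consequences,
    group_snps = group_snps, consensus = consensus,
    candidates = candidates, markers = markers, intervals = intervals,
    membership = membership, report = report,
    models = models, contigs = contigs, meta = meta
  ), class = "panheat_result")
}

#' @export
print.panheat_result <- function(x, ...) {
  gc_tab <- table(x$gene_classes$class)
  cat("panheat pipeline result\n")
  cat(sprintf("  %d genes (%d core, %d variable) x %d accessions\n",
              nrow(x$presence), gc_tab["core"] %||% 0L,
              gc_tab["variable"] %||% 0L,
              length(setdiff(names(x$presence), "gene_id"))))
  cat(sprintf("  %d SNPs after filtering; %d group-specific in %d genes\n",
              nrow(x$filtered_variants), nrow(x$group_snps$variants),
              nrow(x$group_snps$per_gene)))
  cat(sprintf("  %d consensus DEGs (%d contradictory excluded); %d SNP+DE candidates\n",
              sum(x$consensus$status != "contradictory"),
              sum(x$consensus$status == "contradictory"),
              nrow(x$candidates)))
  print(x$report)
  invisible(x)
}

#' Bar plot of a consequence-category tally
#'
#' @param records Consequence tibble (or a `group_snp_result`).
#' @return A ggplot object.
#' @export
plot_category_tally <- function(records) {
  if (inherits(records, "group_snp_result")) records <- records$records
  d <- tally_by_category(records) |>
    mutate(category = factor(.data$category, levels = rev(consequence_categories)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "variant-gene records", y = NULL) +
    ggplot2::theme_minimal()
}

#' Presence/absence heatmap
#'
#' @param presence Presence tibble.
#' @return A ggplot object with genes on the x axis and accessions on y.
#' @export
plot_presence <- function(presence) {
  d <- presence |>
    pivot_longer(-"gene_id", names_to = "accession", values_to = "present")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id, y = .data$accession,
                                  fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
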