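#' Select SNP alleles specific to a phenotype group
#'
#' Implements the heat-tolerance SNP screen: a variant is selected iff
#' * at least one accession of the target heat classes carries at least
#'   one alternate allele (heterozygous carriage counts as presence);
#' * no accession outside the target classes with a *called* genotype
#'   carries an alternate allele (missing genotypes outside the group do
#'   not block selection — specificity is exclusivity of the observed
#'   allele, not fixation within the group);
#' * at least one of its consequence records falls within `scope`:
#'   `"genic_and_flank"` (default) accepts any category other than
#'   intergenic, i.e. genic categories plus upstream/downstream flanks
#'   within the annotation distance; `"high_impact"` accepts only variants
#'   with a HIGH-impact record; `"union"` accepts either.
#'
#' Metadata must cover every sample in the VCF: a sample without a heat
#' class would silently corrupt the specificity predicate, so it is a hard
#' error.
#'
#' @param variants Filtered biallelic variant tibble.
#' @param records Consequence tibble from [annotate_variants()] for the
#'   same variants.
#' @param meta Accession metadata (`accession`, `heat_class`).
#' @param target_classes Heat classes defining the group, e.g. `"HT"` or
#'   `c("HT", "T", "MT")`.
#' @param scope Consequence scope, see above.
#' @param reference_contigs Optional character vector of reference contig
#'   names, used to flag genes on non-reference contigs.
#' @param impact_map Category-to-impact map (for `scope != "genic_and_flank"`).
#' @return An object of class `group_snp_result`: list with `variants`
#'   (selected variant rows), `records` (their gene-linked consequence
#'   records, the variant-gene counting unit), `per_gene` (gene id, SNP
#'   count, categories, `is_reference`), and `tally` (per-category record
#'   counts).
#' @export
select_group_specific <- function(variants, records, meta,
                                  target_classes = "HT",
                                  scope = c("genic_and_flank", "high_impact",
                                            "union"),
                                  reference_contigs = NULL,
                                  impact_map = default_impact_map()) {
  scope <- match.arg(scope)
  bad <- setdiff(target_classes, heat_classes)
  if (length(bad) > 0L) abort(sprintf("unknown heat class: %s",
                                      paste(bad, collapse = ", ")))
  samples <- vcf_samples(variants)
  cls <- meta$heat_class[match(samples, meta$accession)]
  if (anyNA(cls)) {
    abort(sprintf("metadata missing for VCF sample(s): %s",
                  paste(samples[is.na(cls)], collapse = ", ")))
  }
  in_grp <- samples[cls %in% target_classes]
  out_grp <- setdiff(samples, in_grp)
  if (length(in_grp) == 0L) abort("target_classes select no accessions")

  gt <- as.matrix(variants[, samples, drop = FALSE])
  has_alt <- matrix(gt_has_alt(gt), nrow = nrow(gt),
                    dimnames = list(NULL, samples))
  cond_a <- rowSums(has_alt[, in_grp, drop = FALSE]) > 0L
  cond_b <- if (length(out_grp)) {
    rowSums(has_alt[, out_grp, drop = FALSE]) == 0L
  } else TRUE

  key <- function(d) paste(d$contig, d$pos, d$ref, d$alt, sep = ":")
  vkey <- key(variants)
  rkey <- key(records)

  genic <- !records$category %in% c("intergenic", "upstream", "downstream")
  flank <- records$category %in% c("upstream", "downstream")
  high <- impact_of(records$category, impact_map) == "HIGH"
  in_scope <- switch(scope,
                     genic_and_flank = genic | flank,
                     high_impact = high,
                     union = genic | flank | high)
  scoped_keys <- unique(rkey[in_scope])
  cond_c <- vkey %in% scoped_keys

  sel <- cond_a & cond_b & cond_c
  sel_variants <- variants[sel, , drop = FALSE]
  sel_records <- records[rkey %in% vkey[sel] & !is.na(records$gene_id), ,
                         drop = FALSE]

  per_gene <- sel_records |>
    group_by(.data$gene_id) |>
    summarise(contig = first(.data$contig),
              n_snps = dplyr::n_distinct(.data$pos, .data$contig),
              n_records = n(),
              categories = paste(sort(unique(.data$category)),
                                 collapse = ","),
              .groups = "drop") |>
    mutate(is_reference = if (is.null(reference_contigs)) NA else
      .data$contig %in% reference_contigs)

  structure(list(
    variants = sel_variants,
    records = sel_records,
    per_gene = per_gene,
    tally = tally_by_category(sel_records),
    target_classes = target_classes, scope = scope
  ), class = "group_snp_result")
}

#' @export
print.group_snp_result <- function(x, ...) {
  cat(sprintf("Group-specific SNPs for {%s}, scope %s\n",
              paste(x$target_classes, collapse = ","), x$scope))
  cat(sprintf("  %d variants, %d variant-gene records, %d genes\n",
              nrow(x$variants), nrow(x$records), nrow(x$per_gene)))
  invisible(x)
}

#' @export
tidy.group_snp_result <- function(x, ...) x$records

#' @export
glance.group_snp_result <- function(x, ...) {
  imp <- impact_of(x$records$category)
  tibble(
    n_variants = nrow(x$variants),
    n_records = nrow(x$records),
    n_genes = nrow(x$per_gene),
    n_nonref_genes = sum(!x$per_gene$is_reference, na.rm = TRUE),
    high_impact = sum(imp == "HIGH"),
    moderate_impact = sum(imp == "MODERATE"),
    low_impact = sum(imp == "LOW"),
    modifier_impact = sum(imp == "MODIFIER")
  )
}

#' Category tally table for a group-SNP selection
#'
#' Counts the selected variant-gene consequence records per category
#' (so a variant in the flank of two genes contributes twice, which is
#' the additive unit that makes the category column sum to the total) and
#' appends a `total` row. A per-variant unique count is also attached as
#' the `"n_unique_variants"` attribute.
#'
#' @param x A `group_snp_result`, or a consequence-record tibble.
#' @return Tibble of `category`, `n` with a final `total` row.
#' @export
tally_table <- function(x) {
  records <- if (inherits(x, "group_snp_result")) x$records else x
  tl <- tally_by_category(records)
  tl <- tl[tl$category != "intergenic", , drop = FALSE]
  out <- bind_rows(tl, tibble(category = "total", n = sum(tl$n)))
  attr(out, "n_unique_variants") <-
    nrow(distinct(records, .data$contig, .data$pos, .data$ref, .data$alt))
  out
}
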