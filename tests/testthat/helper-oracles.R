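# Independent brute-force oracles. Each re-derives a result by the most
# literal route available (per-record predicate evaluation, exhaustive
# enumeration, whole-CDS rebuild) so the implementation under test is
# never on both sides of a comparison.

oracle_filter_keep <- function(variants, maf_min = 0.05,
                               max_missing_fraction = 0.8) {
  samples <- vcf_samples(variants)
  vapply(seq_len(nrow(variants)), function(i) {
    if (nchar(variants$ref[i]) != 1L || nchar(variants$alt[i]) != 1L ||
          grepl(",", variants$alt[i], fixed = TRUE)) return(FALSE)
    gts <- unlist(variants[i, samples], use.names = FALSE)
    missing <- grepl(".", gts, fixed = TRUE)
    if (mean(missing) >= max_missing_fraction) return(FALSE)
    alleles <- unlist(strsplit(gts[!missing], "/"))
    if (length(alleles) == 0L) return(FALSE)
    f_alt <- mean(alleles == "1")
    min(f_alt, 1 - f_alt) >= maf_min
  }, logical(1))
}

oracle_group_specific_keys <- function(variants, records, meta,
                                       target_classes) {
  samples <- vcf_samples(variants)
  cls <- meta$heat_class[match(samples, meta$accession)]
  keys <- character()
  for (i in seq_len(nrow(variants))) {
    carries <- vapply(samples, function(s) {
      g <- variants[[s]][i]
      any(setdiff(strsplit(g, "/")[[1]], c(".", "0")) != "")
    }, logical(1))
    a <- any(carries[cls %in% target_classes])
    b <- !any(carries[!cls %in% target_classes])
    k <- paste(variants$contig[i], variants$pos[i], variants$ref[i],
               variants$alt[i], sep = ":")
    rk <- paste(records$contig, records$pos, records$ref, records$alt,
                sep = ":")
    cc <- any(rk == k & records$category != "intergenic")
    if (a && b && cc) keys <- c(keys, k)
  }
  keys
}

oracle_consensus <- function(calls) {
  genes <- unique(calls$gene_id)
  status <- vapply(genes, function(g) {
    dirs <- calls$direction[calls$gene_id == g]
    up <- any(dirs == "up"); down <- any(dirs == "down")
    if (up && down) "contradictory" else if (up) "up" else "down"
  }, character(1))
  tibble::tibble(gene_id = genes, status = unname(status))
}

oracle_genes_in_qtls <- function(models, intervals) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    for (j in seq_len(nrow(intervals))) {
      if (models$contig[i] == intervals$contig[j] &&
            models$start[i] <= intervals$end[j] &&
            models$end[i] >= intervals$start[j]) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = models$gene_id[i], qtl_ids = intervals$qtl_ids[j])
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(gene_id = character(), qtl_ids = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), gene_id, qtl_ids)
}

# whole-CDS rebuild-and-translate oracle for coding consequences
oracle_coding_effect <- function(model_row, seq, pos, alt) {
  alt_seq <- seq
  substr(alt_seq, pos, pos) <- alt
  cds <- model_row$cds[[1]]
  get_cds <- function(s) {
    x <- paste(substring(s, cds$start, cds$end), collapse = "")
    if (model_row$strand == "-") {
      x <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    }
    x
  }
  ref_cds <- get_cds(seq)
  alt_cds <- get_cds(alt_seq)
  tr <- function(x) {
    # literal codon-table translation: the initiator position gets no
    # special treatment, so a broken ATG is visible in the protein
    strsplit(as.character(Biostrings::translate(Biostrings::DNAString(x),
                                                no.init.codon = TRUE)),
             "")[[1]]
  }
  pa <- tr(ref_cds); pb <- tr(alt_cds)
  stopifnot(length(pa) == length(pb))
  diff <- which(pa != pb)
  if (length(diff) == 0L) return("synonymous")
  i <- diff[1]
  if (i == 1L && substr(ref_cds, 1, 3) == "ATG" &&
        substr(alt_cds, 1, 3) != "ATG") return("start_lost")
  if (pb[i] == "*" && pa[i] != "*") return("stop_gained")
  if (pa[i] == "*" && pb[i] != "*") return("stop_lost")
  "missense"
}

# exhaustive pan/core growth enumeration (N small)
oracle_growth <- function(presence) {
  acc <- setdiff(names(presence), "gene_id")
  m <- as.matrix(as.data.frame(presence[acc])) * 1L
  n <- length(acc)
  do.call(rbind, lapply(seq_len(n), function(k) {
    combos <- utils::combn(n, k, simplify = FALSE)
    pan <- vapply(combos, function(s) sum(rowSums(m[, s, drop = FALSE]) > 0),
                  numeric(1))
    core <- vapply(combos, function(s) sum(rowSums(m[, s, drop = FALSE]) == k),
                   numeric(1))
    data.frame(k = k, pan_mean = mean(pan), core_mean = mean(core))
  }))
}
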