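#' Construct a gene model row
#'
#' A gene model is one row of the gene-model tibble used throughout the
#' package: gene coordinates plus exon/CDS block structure held in
#' list-columns of `(start, end)` tibbles, all 1-based inclusive. UTRs and
#' introns are derived, never supplied: introns are the gaps between
#' consecutive exons; 5' UTR is the exonic, non-CDS sequence transcribed
#' before the first CDS base (strand-aware) and 3' UTR the remainder.
#'
#' Models whose total CDS length is not divisible by 3 are flagged
#' non-coding (`coding = FALSE`) with a warning, as are models without CDS.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble of exon blocks `(start, end)`, disjoint.
#' @param cds Tibble of CDS blocks, a subset of the exon bases (may be
#'   empty for non-coding models).
#' @return A one-row tibble with columns `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `coding` and list-columns `exons`, `cds`, `utr5`,
#'   `utr3`, `introns`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = interval_tbl()) {
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  exons <- arrange(as_tibble(exons), .data$start)
  cds <- arrange(as_tibble(cds), .data$start)
  if (nrow(exons) == 0L) abort(sprintf("gene '%s' has no exons", gene_id))
  if (any(exons$start > exons$end)) abort("exon with start > end")
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort(sprintf("overlapping exons in gene '%s'", gene_id))
  }
  exon_pos <- intervals_to_positions(exons)
  cds_pos <- intervals_to_positions(cds)
  if (!all(cds_pos %in% exon_pos)) {
    abort(sprintf("CDS outside exons in gene '%s'", gene_id))
  }
  coding <- length(cds_pos) > 0L
  if (coding && length(cds_pos) %% 3L != 0L) {
    warn(sprintf("gene '%s': CDS length %d not divisible by 3; flagged non-coding",
                 gene_id, length(cds_pos)))
    coding <- FALSE
  }
  introns <- if (nrow(exons) > 1L) {
    interval_tbl(exons$end[-nrow(exons)] + 1L, exons$start[-1] - 1L)
  } else interval_tbl()

  utr5 <- utr3 <- interval_tbl()
  if (coding) {
    noncds <- setdiff(exon_pos, cds_pos)
    if (strand == "+") {
      utr5 <- positions_to_intervals(noncds[noncds < min(cds_pos)])
      utr3 <- positions_to_intervals(noncds[noncds > max(cds_pos)])
    } else {
      utr5 <- positions_to_intervals(noncds[noncds > max(cds_pos)])
      utr3 <- positions_to_intervals(noncds[noncds < min(cds_pos)])
    }
  }
  tibble(
    gene_id = gene_id, contig = contig, strand = strand,
    start = min(exons$start), end = max(exons$end), coding = coding,
    exons = list(exons), cds = list(cds), utr5 = list(utr5),
    utr3 = list(utr3), introns = list(introns)
  )
}

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features into one gene model per gene.
#' Single-transcript genes are assumed; when a gene carries several mRNAs
#' the transcript with the longest total CDS is kept with a warning, since
#' the downstream analyses are gene-level and carry no isoform resolution.
#' Records whose exons fall outside the annotated gene span are rejected
#' with a warning. UTRs are always re-derived from exon/CDS structure.
#'
#' @param path GFF3 file.
#' @return Gene-model tibble (see [gene_model()]).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    if (nrow(tx) == 0L) next
    pick <- 1L
    if (nrow(tx) > 1L) {
      cds_len <- vapply(tx$ID, function(tid) {
        blk <- df[df$type == "CDS" & !is.na(df$Parent) & df$Parent == tid, ]
        sum(blk$end - blk$start + 1L)
      }, numeric(1))
      pick <- which.max(cds_len)
      warn(sprintf("gene '%s' has %d mRNAs; keeping the longest CDS ('%s')",
                   g$ID, nrow(tx), tx$ID[pick]))
    }
    tid <- tx$ID[pick]
    ex <- df[df$type == "exon" & !is.na(df$Parent) & df$Parent == tid, ]
    cd <- df[df$type == "CDS" & !is.na(df$Parent) & df$Parent == tid, ]
    if (nrow(ex) == 0L) {  # exon-less annotations: treat mRNA span as one exon
      ex <- tx[pick, ]
    }
    if (any(ex$start < g$start | ex$end > g$end)) {
      warn(sprintf("gene '%s': exon outside gene span; record rejected", g$ID))
      next
    }
    models[[length(models) + 1L]] <- gene_model(
      gene_id = g$ID, contig = as.character(g$seqnames),
      strand = as.character(g$strand),
      exons = interval_tbl(ex$start, ex$end),
      cds = interval_tbl(cd$start, cd$end)
    )
  }
  if (length(models) == 0L) abort("no gene models found in GFF3")
  bind_rows(models)
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` features (UTRs are derivable and
#' not written). CDS phase is computed in transcription order.
#'
#' @param models Gene-model tibble.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  add <- function(contig, type, start, end, strand, phase, attr) {
    rows[[length(rows) + 1L]] <<- sprintf(
      "%s\tpanheat\t%s\t%d\t%d\t.\t%s\t%s\t%s",
      contig, type, start, end, strand, phase, attr)
  }
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    tid <- paste0(m$gene_id, ".t1")
    add(m$contig, "gene", m$start, m$end, m$strand, ".",
        sprintf("ID=%s", m$gene_id))
    add(m$contig, "mRNA", m$start, m$end, m$strand, ".",
        sprintf("ID=%s;Parent=%s", tid, m$gene_id))
    ex <- m$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      add(m$contig, "exon", ex$start[j], ex$end[j], m$strand, ".",
          sprintf("Parent=%s", tid))
    }
    cd <- m$cds[[1]]
    if (nrow(cd) > 0L) {
      ord <- if (m$strand == "+") order(cd$start) else order(-cd$start)
      cum <- 0L
      phase <- integer(nrow(cd))
      for (j in ord) {
        phase[j] <- (3L - cum %% 3L) %% 3L
        cum <- cum + (cd$end[j] - cd$start[j] + 1L)
      }
      for (j in seq_len(nrow(cd))) {
        add(m$contig, "CDS", cd$start[j], cd$end[j], m$strand, phase[j],
            sprintf("Parent=%s", tid))
      }
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}
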