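#' Consequence categories, in severity order
#'
#' Functional categories a SNP can take relative to a gene model, from most
#' to least severe. This order is the precedence used both within a
#' variant-gene pair (a splice-window base in the CDS is called splice, not
#' coding) and across genes when summarising a variant. `exon` is the
#' category for exonic variants of non-coding models (models without CDS,
#' or flagged non-coding); `intergenic` is assigned when no gene lies
#' within the flank distance.
#'
#' @export
consequence_categories <- c(
  "splice_acceptor", "splice_donor", "start_lost", "stop_gained",
  "stop_lost", "missense", "synonymous", "start_gained",
  "utr5", "utr3", "exon", "intronic", "upstream", "downstream", "intergenic"
)

#' Default category-to-impact map
#'
#' Four severity classes over the category taxonomy. HIGH covers the splice
#' acceptor/donor, start-lost and stop-gained calls; MODERATE the missense
#' (non-synonymous) calls; LOW the synonymous, start-gained and stop-lost
#' calls; everything else (UTR, exon, intronic, flanking, intergenic) is
#' MODIFIER. Note stop_lost sits in LOW rather than HIGH so the four
#' classes partition the taxonomy the way the tallies in this pipeline
#' add up; the map is an argument everywhere it is consumed, so a SnpEff
#' style grading (stop_lost HIGH) is one edit away.
#'
#' @return Named character vector mapping category to impact.
#' @export
default_impact_map <- function() {
  c(splice_acceptor = "HIGH", splice_donor = "HIGH", start_lost = "HIGH",
    stop_gained = "HIGH",
    missense = "MODERATE",
    synonymous = "LOW", start_gained = "LOW", stop_lost = "LOW",
    utr5 = "MODIFIER", utr3 = "MODIFIER", exon = "MODIFIER",
    intronic = "MODIFIER", upstream = "MODIFIER", downstream = "MODIFIER",
    intergenic = "MODIFIER")
}

#' Impact class of a consequence category
#'
#' @param category Character vector of categories.
#' @param impact_map Named map from [default_impact_map()].
#' @return Character vector of impact classes.
#' @export
impact_of <- function(category, impact_map = default_impact_map()) {
  unknown <- setdiff(unique(category), names(impact_map))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown consequence category: %s",
                  paste(unknown, collapse = ", ")))
  }
  unname(impact_map[category])
}

rc3 <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# does substituting `alt` at plus-strand position `pos` create an ATG on the
# coding strand in any of the three frames covering pos?
creates_start_codon <- function(seq, pos, alt, strand) {
  n <- nchar(seq)
  for (k in 0:2) {
    a <- pos - k
    if (a < 1L || a + 2L > n) next
    trip_ref <- substr(seq, a, a + 2L)
    trip_alt <- trip_ref
    substr(trip_alt, k + 1L, k + 1L) <- alt
    if (strand == "-") {
      trip_ref <- rc3(trip_ref)
      trip_alt <- rc3(trip_alt)
    }
    if (trip_alt == "ATG" && trip_ref != "ATG") return(TRUE)
  }
  FALSE
}

build_gene_cache <- function(m, seq) {
  cd <- m$cds[[1]]
  cds_pos <- intervals_to_positions(cd)
  cds_seq <- NULL
  if (m$coding) {
    plus <- paste(substring(seq, cd$start, cd$end), collapse = "")
    cds_seq <- if (m$strand == "+") plus else revcomp(plus)
  }
  list(strand = m$strand, coding = m$coding,
       start = m$start, end = m$end,
       exons = m$exons[[1]], cds = cd, cds_pos = cds_pos,
       cds_seq = cds_seq, utr5 = m$utr5[[1]], utr3 = m$utr3[[1]],
       introns = m$introns[[1]])
}

coding_effect <- function(g, pos, alt) {
  L <- length(g$cds_pos)
  i_plus <- match(pos, g$cds_pos)
  i <- if (g$strand == "+") i_plus else L - i_plus + 1L
  alt_base <- if (g$strand == "+") alt else comp_base(alt)
  codon_i <- (i - 1L) %/% 3L + 1L
  off <- (i - 1L) %% 3L + 1L
  ref_codon <- substr(g$cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_base
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[ref_codon])
  aa_alt <- unname(gc[alt_codon])
  category <-
    if (codon_i == 1L && ref_codon == "ATG" && alt_codon != "ATG") "start_lost"
    else if (!is.na(aa_alt) && aa_alt == "*" && aa_ref != "*") "stop_gained"
    else if (!is.na(aa_ref) && aa_ref == "*" && aa_alt != "*") "stop_lost"
    else if (identical(aa_ref, aa_alt)) "synonymous"
    else "missense"
  list(category = category, codon = codon_i, aa_ref = aa_ref, aa_alt = aa_alt)
}

splice_category <- function(g, pos, splice_window) {
  iv <- g$introns
  for (j in seq_len(nrow(iv))) {
    s <- iv$start[j]; e <- iv$end[j]
    if (pos < s || pos > e) next
    w <- min(splice_window, e - s + 1L)
    donor <- if (g$strand == "+") pos <= s + w - 1L else pos >= e - w + 1L
    if (donor) return("splice_donor")
    acceptor <- if (g$strand == "+") pos >= e - w + 1L else pos <= s + w - 1L
    if (acceptor) return("splice_acceptor")
    return("intronic")
  }
  NA_character_
}

classify_variant_gene <- function(g, seq, pos, alt, flank, splice_window) {
  res <- list(category = NA_character_, codon = NA_integer_,
              aa_ref = NA_character_, aa_alt = NA_character_,
              distance = 0L)
  if (pos >= g$start && pos <= g$end) {
    if (pos %in% g$cds_pos) {
      ce <- coding_effect(g, pos, alt)
      res[names(ce)] <- ce
    } else if (in_intervals(pos, g$exons)) {
      if (!g$coding) {
        res$category <- "exon"
      } else if (in_intervals(pos, g$utr5)) {
        res$category <- if (creates_start_codon(seq, pos, alt, g$strand))
          "start_gained" else "utr5"
      } else if (in_intervals(pos, g$utr3)) {
        res$category <- "utr3"
      } else {
        res$category <- "exon"  # exonic but outside the kept transcript's CDS/UTRs
      }
    } else {
      res$category <- splice_category(g, pos, splice_window)
    }
  } else {
    before <- pos < g$start
    res$distance <- if (before) g$start - pos else pos - g$end
    if (res$distance > flank) return(NULL)
    res$category <- if (xor(before, g$strand == "-")) "upstream" else "downstream"
  }
  res
}

#' Annotate SNPs with functional consequences per gene
#'
#' For every variant-gene pair in which the variant lies within the gene
#' span or within `flank` bp of it, one consequence record is emitted. The
#' category is assigned by location with precedence
#' splice > start_lost > stop_gained > stop_lost > missense/synonymous >
#' start_gained > UTR > intronic > upstream/downstream:
#' * CDS variants are classified by rebuilding the affected codon on the
#'   coding strand (reverse-complementing for minus-strand genes) and
#'   translating with the standard genetic code;
#' * intron variants within `splice_window` bases of an exon-intron
#'   boundary are splice donor (5' side of the intron in transcription
#'   order) or splice acceptor (3' side);
#' * 5'-UTR variants whose alternate allele creates an ATG on the coding
#'   strand in a frame overlapping the variant are start_gained;
#' * variants outside the span are upstream on the 5' side and downstream
#'   on the 3' side, strand-aware, measured from the gene span ends;
#' * variants overlapping no gene and no flank get a single `intergenic`
#'   record with `gene_id = NA`.
#'
#' @param variants Filtered biallelic variant tibble (single-base `ref`
#'   and `alt`).
#' @param models Gene-model tibble.
#' @param contigs Contig tibble from [read_fasta()].
#' @param flank Flanking distance in bp (default 2000).
#' @param splice_window Intronic bases at each boundary called splice
#'   (default 2).
#' @param impact_map Category-to-impact map.
#' @return Consequence tibble: `contig`, `pos`, `ref`, `alt`, `gene_id`,
#'   `category`, `impact`, `codon`, `aa_ref`, `aa_alt`, `distance` (bp from
#'   the gene span; 0 inside the span).
#' @export
annotate_variants <- function(variants, models, contigs, flank = 2000,
                              splice_window = 2,
                              impact_map = default_impact_map()) {
  if (flank <= 0) abort("flank must be > 0")
  if (splice_window < 1) abort("splice_window must be >= 1")
  if (nrow(variants) == 0L) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), gene_id = character(),
                  category = character(), impact = character(),
                  codon = integer(), aa_ref = character(),
                  aa_alt = character(), distance = integer()))
  }
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L |
            grepl(",", variants$alt))) {
    abort("annotate_variants expects biallelic single-base SNPs; run filter_variants() first")
  }
  clen <- setNames(nchar(contigs$seq), contigs$name)
  beyond <- variants$pos > clen[variants$contig] | variants$pos < 1L
  if (any(is.na(beyond))) abort("variant on a contig absent from the genome")
  if (any(beyond)) abort("variant position beyond contig end")

  var_gr <- GenomicRanges::GRanges(variants$contig,
                                   IRanges::IRanges(variants$pos, variants$pos))
  gene_gr <- GenomicRanges::GRanges(
    models$contig,
    IRanges::IRanges(pmax(1L, models$start - flank), models$end + flank))
  hits <- GenomicRanges::findOverlaps(var_gr, gene_gr)

  caches <- vector("list", nrow(models))
  seqs <- setNames(contigs$seq, contigs$name)
  rows <- vector("list", length(hits) + nrow(variants))
  nrow_out <- 0L
  annotated <- logical(nrow(variants))
  for (h in seq_along(hits)) {
    vi <- S4Vectors::queryHits(hits)[h]
    gi <- S4Vectors::subjectHits(hits)[h]
    if (is.null(caches[[gi]])) {
      caches[[gi]] <- build_gene_cache(models[gi, ], seqs[[models$contig[gi]]])
    }
    g <- caches[[gi]]
    res <- classify_variant_gene(g, seqs[[variants$contig[vi]]],
                                 variants$pos[vi], variants$alt[vi],
                                 flank, splice_window)
    if (is.null(res)) next
    annotated[vi] <- TRUE
    nrow_out <- nrow_out + 1L
    rows[[nrow_out]] <- tibble(
      contig = variants$contig[vi], pos = variants$pos[vi],
      ref = variants$ref[vi], alt = variants$alt[vi],
      gene_id = models$gene_id[gi], category = res$category,
      codon = res$codon %||% NA_integer_,
      aa_ref = res$aa_ref, aa_alt = res$aa_alt,
      distance = as.integer(res$distance))
  }
  for (vi in which(!annotated)) {
    nrow_out <- nrow_out + 1L
    rows[[nrow_out]] <- tibble(
      contig = variants$contig[vi], pos = variants$pos[vi],
      ref = variants$ref[vi], alt = variants$alt[vi],
      gene_id = NA_character_, category = "intergenic",
      codon = NA_integer_, aa_ref = NA_character_, aa_alt = NA_character_,
      distance = NA_integer_)
  }
  out <- bind_rows(rows[seq_len(nrow_out)])
  out$impact <- impact_of(out$category, impact_map)
  arrange(out, .data$contig, .data$pos, .data$gene_id)
}

#' Per-variant summary: the most severe consequence across genes
#'
#' Severity follows the [consequence_categories] precedence; ties are
#' broken by distance to the gene (nearest first), then lexicographic
#' gene id.
#'
#' @param records Consequence tibble from [annotate_variants()].
#' @return One row per variant: the winning consequence record.
#' @export
summarize_consequences <- function(records) {
  sev <- match(records$category, consequence_categories)
  records |>
    mutate(.sev = sev,
           .dist = replace_na(as.integer(.data$distance), 0L),
           .gene = replace_na(.data$gene_id, "~")) |>
    group_by(.data$contig, .data$pos, .data$ref, .data$alt) |>
    arrange(.data$.sev, .data$.dist, .data$.gene, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select(-".sev", -".dist", -".gene")
}

#' Tally consequence records by category
#'
#' Counts variant-gene consequence records per category; with `by`, counts
#' are additionally split by another record column (for example a
#' reference/non-reference contig flag joined beforehand). All categories
#' of the taxonomy appear, zero-filled, so tallies from different runs are
#' alignable, and the counts sum to the number of records.
#'
#' @param records Consequence tibble.
#' @param by Optional extra grouping column name.
#' @return Tibble of `category`, (optional `by` column,) `n`.
#' @export
tally_by_category <- function(records, by = NULL) {
  cats <- factor(records$category, levels = consequence_categories)
  if (is.null(by)) {
    out <- as_tibble(as.data.frame(table(category = cats),
                                   stringsAsFactors = FALSE))
    names(out) <- c("category", "n")
  } else {
    out <- as_tibble(as.data.frame(
      table(category = cats, by = records[[by]]),
      stringsAsFactors = FALSE))
    names(out) <- c("category", by, "n")
  }
  out$n <- as.integer(out$n)
  out
}
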