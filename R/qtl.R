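#' Place QTL markers on a genome by exact sequence match
#'
#' Marker sequences (>= 15 bp) are searched on both the forward and the
#' reverse-complement strand of every contig. A unique hit yields a
#' forward-coordinate placement; zero hits leave the marker unplaced;
#' several hits make it ambiguous and excluded unless `keep_ambiguous`,
#' in which case the first hit by (contig order, position) is kept.
#' Markers arriving with a `contig` + `pos` already filled are passed
#' through as placed.
#'
#' @param markers Marker tibble (see [read_markers()]).
#' @param contigs Contig tibble.
#' @param keep_ambiguous Keep the first hit of multi-hit markers.
#' @return The marker tibble with `contig`, `pos`, `end`, `status`
#'   (`"placed"`, `"unplaced"`, `"ambiguous"`) filled; a summary of
#'   unplaced/ambiguous markers is messaged.
#' @export
place_markers <- function(markers, contigs, keep_ambiguous = FALSE) {
  assert_cols(markers, c("qtl_id", "marker_id"), "markers")
  if (!"sequence" %in% names(markers)) markers$sequence <- NA_character_
  if (!"contig" %in% names(markers)) markers$contig <- NA_character_
  if (!"pos" %in% names(markers)) markers$pos <- NA_integer_
  out <- as_tibble(markers)
  out$pos <- as.integer(out$pos)
  out$end <- ifelse(!is.na(out$pos) & !is.na(out$sequence),
                    out$pos + nchar(out$sequence) - 1L, out$pos)
  out$status <- ifelse(!is.na(out$contig) & !is.na(out$pos),
                       "placed", NA_character_)

  subject <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$name))
  for (i in which(is.na(out$status))) {
    sq <- out$sequence[i]
    if (is.na(sq) || nchar(sq) < 15L) {
      abort(sprintf("marker '%s' needs a sequence of >= 15 bp or a placement",
                    out$marker_id[i]))
    }
    hits <- list()
    for (ci in seq_along(subject)) {
      fwd <- Biostrings::matchPattern(sq, subject[[ci]])
      rev <- Biostrings::matchPattern(revcomp(sq), subject[[ci]])
      for (s in c(BiocGenerics::start(fwd), BiocGenerics::start(rev))) {
        hits[[length(hits) + 1L]] <- c(ci, s)
      }
    }
    if (length(hits) == 0L) {
      out$status[i] <- "unplaced"
    } else if (length(hits) == 1L || keep_ambiguous) {
      ord <- order(vapply(hits, `[`, numeric(1), 1),
                   vapply(hits, `[`, numeric(1), 2))
      h <- hits[[ord[1]]]
      out$contig[i] <- contigs$name[h[1]]
      out$pos[i] <- as.integer(h[2])
      out$end[i] <- as.integer(h[2] + nchar(sq) - 1L)
      out$status[i] <- if (length(hits) == 1L) "placed" else "ambiguous"
    } else {
      out$status[i] <- "ambiguous"
    }
  }
  n_un <- sum(out$status == "unplaced")
  n_amb <- sum(out$status == "ambiguous" & is.na(out$pos))
  if (n_un + n_amb > 0L) {
    inform(sprintf("%d marker(s) unplaced, %d ambiguous (excluded)",
                   n_un, n_amb))
  }
  out
}

#' Build QTL intervals from placed markers
#'
#' Each QTL's interval spans from its leftmost placed marker start to its
#' rightmost placed marker end (the flanking-marker convention). A QTL
#' whose placed markers land on more than one contig is an error; a QTL
#' with no placed marker is an error. With `merge = TRUE` (default),
#' overlapping intervals on one contig are unioned and their QTL ids
#' concatenated, so the output intervals are pairwise disjoint.
#'
#' @param placed Marker tibble from [place_markers()].
#' @param merge Union overlapping intervals.
#' @return Tibble of intervals: `qtl_ids` (comma-joined when merged),
#'   `contig`, `start`, `end`.
#' @export
build_intervals <- function(placed, merge = TRUE) {
  ok <- placed[!is.na(placed$pos) & placed$status %in% c("placed", "ambiguous"), ]
  all_ids <- unique(placed$qtl_id)
  lost <- setdiff(all_ids, unique(ok$qtl_id))
  if (length(lost) > 0L) {
    abort(sprintf("QTL(s) with no placed marker: %s",
                  paste(lost, collapse = ", ")))
  }
  per_qtl <- ok |>
    group_by(.data$qtl_id) |>
    summarise(n_contig = dplyr::n_distinct(.data$contig),
              contig = first(.data$contig),
              start = min(.data$pos),
              end = max(.data$end),
              .groups = "drop")
  multi <- per_qtl$qtl_id[per_qtl$n_contig > 1L]
  if (length(multi) > 0L) {
    abort(sprintf("QTL(s) with markers on several contigs: %s",
                  paste(multi, collapse = ", ")))
  }
  iv <- per_qtl |> select(qtl_ids = "qtl_id", "contig", "start", "end")
  if (!merge) return(arrange(iv, .data$contig, .data$start))

  merged <- iv |>
    group_by(.data$contig) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                                 default = -Inf))) |>
    group_by(.data$contig, .data$grp) |>
    summarise(qtl_ids = paste(.data$qtl_ids, collapse = ","),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("qtl_ids", "contig", "start", "end")
  arrange(merged, .data$contig, .data$start)
}

#' Map genes into QTL intervals
#'
#' A gene belongs to a QTL interval when its span overlaps the interval by
#' at least 1 bp (both 1-based inclusive); `min_overlap` can raise this or
#' `containment = TRUE` can require the full gene span inside the
#' interval.
#'
#' @param models Gene-model tibble.
#' @param intervals Interval tibble from [build_intervals()].
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param containment Require full containment of the gene span.
#' @return Membership tibble: one row per (gene, interval) pair with
#'   `gene_id`, `qtl_ids`, `contig`, interval `start`/`end`.
#' @export
genes_in_qtls <- function(models, intervals, min_overlap = 1L,
                          containment = FALSE) {
  if (nrow(intervals) == 0L || nrow(models) == 0L) {
    return(tibble(gene_id = character(), qtl_ids = character(),
                  contig = character(), start = integer(), end = integer()))
  }
  gene_gr <- GenomicRanges::GRanges(models$contig,
                                    IRanges::IRanges(models$start, models$end))
  iv_gr <- GenomicRanges::GRanges(intervals$contig,
                                  IRanges::IRanges(intervals$start,
                                                   intervals$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, iv_gr,
                                      minoverlap = as.integer(min_overlap),
                                      type = if (containment) "within" else "any")
  tibble(
    gene_id = models$gene_id[S4Vectors::queryHits(hits)],
    qtl_ids = intervals$qtl_ids[S4Vectors::subjectHits(hits)],
    contig = intervals$contig[S4Vectors::subjectHits(hits)],
    start = intervals$start[S4Vectors::subjectHits(hits)],
    end = intervals$end[S4Vectors::subjectHits(hits)]
  ) |> arrange(.data$gene_id, .data$contig, .data$start)
}

#' Restrict DEG-SNP candidates to QTL residents
#'
#' The final evidence integration: candidate genes (group-SNP-bearing,
#' consistently differentially expressed) that reside in a heat-tolerance
#' QTL interval. Counts are reported as up/down/total with the
#' non-reference subset split out.
#'
#' @param candidates Candidate tibble from [intersect_with_snp_genes()].
#' @param membership Membership tibble from [genes_in_qtls()].
#' @return An object of class `qtl_report`: list with `genes` (candidate
#'   rows restricted to QTL residents, with their QTL ids) and `counts`
#'   (one-row tibble: `up`, `down`, `total`, `nonref_up`, `nonref_down`,
#'   `nonref_total`).
#' @export
final_candidates <- function(candidates, membership) {
  qtl_map <- membership |>
    group_by(.data$gene_id) |>
    summarise(qtl_ids = paste(unique(.data$qtl_ids), collapse = ";"),
              .groups = "drop")
  genes <- inner_join(candidates, qtl_map, by = "gene_id") |>
    arrange(desc(.data$direction), .data$gene_id)
  nonref <- !genes$is_reference
  counts <- tibble(
    up = sum(genes$direction == "up"),
    down = sum(genes$direction == "down"),
    total = nrow(genes),
    nonref_up = sum(genes$direction == "up" & nonref, na.rm = TRUE),
    nonref_down = sum(genes$direction == "down" & nonref, na.rm = TRUE),
    nonref_total = sum(nonref, na.rm = TRUE)
  )
  structure(list(genes = genes, counts = counts), class = "qtl_report")
}

#' @export
print.qtl_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    "QTL-resident candidates: %d (%d up, %d down); non-reference: %d (%d up, %d down)\n",
    c$total, c$up, c$down, c$nonref_total, c$nonref_up, c$nonref_down))
  invisible(x)
}

#' @export
tidy.qtl_report <- function(x, ...) x$genes

#' @export
glance.qtl_report <- function(x, ...) x$counts
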