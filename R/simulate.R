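#' Configuration for the synthetic study generator
#'
#' Defaults emulate, at desk scale, a heat-stress rice panel: a handful of
#' reference chromosomes plus non-reference contigs, ~100 genes with 1-9
#' exons each, a cohort of 15 accessions spanning the five heat classes
#' with 2 highly tolerant members and a couple of low-depth accessions
#' that the PAV stage must exclude, ~2000 background SNPs (some designed
#' to fail the MAF/missingness filters, plus a few multiallelic records),
#' planted group-specific SNPs in every consequence category, four
#' expression datasets with deliberate cross-dataset contradictions, and
#' marker-delimited QTL intervals containing the planted candidates.
#'
#' @param seed Integer seed; the whole simulation is deterministic given
#'   it.
#' @param group_sizes Named counts per heat class (needs >= 2 HT).
#' @param n_low_depth How many non-HT accessions are sequenced below 10x.
#' @param n_contigs_ref,n_contigs_nonref Contig counts.
#' @param n_core_genes,n_variable_genes Gene counts.
#' @param frac_genes_nonref Fraction of genes placed on non-reference
#'   contigs.
#' @param n_noncoding Number of gene models without CDS.
#' @param variable_presence_prob Per-accession presence probability of a
#'   variable gene.
#' @param n_background_snps Background SNP count.
#' @param frac_low_maf,frac_high_missing Fractions of background SNPs
#'   constructed to fail the MAF / missingness filter.
#' @param n_multiallelic Multiallelic records (removed by the biallelic
#'   filter).
#' @param planted_group_snps Named counts of group-specific SNPs per
#'   consequence category.
#' @param n_planted_up,n_planted_down,n_planted_contra SNP-bearing genes
#'   planted as consistently up, consistently down, and contradictory.
#' @param n_de_only Differentially expressed genes without group SNPs.
#' @param datasets Named list: dataset -> character vector of comparisons.
#' @param flank Flank distance used for upstream/downstream planting (bp).
#' @param n_qtl Number of QTL intervals (>= 4; the first four exercise
#'   reference, overlapping and non-reference cases).
#' @param gene_slot_bp Per-gene layout slot on a contig (controls
#'   intergenic spacing; must exceed twice the flank plus the largest
#'   gene).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       group_sizes = c(HT = 2, T = 5, MT = 2, S = 4, HS = 2),
                       n_low_depth = 2,
                       n_contigs_ref = 3, n_contigs_nonref = 2,
                       n_core_genes = 80, n_variable_genes = 20,
                       frac_genes_nonref = 0.16,
                       n_noncoding = 4,
                       variable_presence_prob = 0.8,
                       n_background_snps = 2000,
                       frac_low_maf = 0.08, frac_high_missing = 0.08,
                       n_multiallelic = 15,
                       planted_group_snps = c(
                         missense = 3, synonymous = 2, stop_gained = 1,
                         stop_lost = 1, start_lost = 1, start_gained = 1,
                         splice_donor = 1, splice_acceptor = 1, intronic = 2,
                         utr5 = 1, utr3 = 1, exon = 1,
                         upstream = 2, downstream = 2),
                       n_planted_up = 6, n_planted_down = 3,
                       n_planted_contra = 2, n_de_only = 8,
                       datasets = list(
                         ds1 = c("hs_vs_ctrl_cvA", "hs_vs_ctrl_cvB"),
                         ds2 = "hs_vs_ctrl",
                         ds3 = c("t2_vs_t0", "t4_vs_t0"),
                         ds4 = "hs_vs_ctrl"),
                       flank = 2000, n_qtl = 4,
                       gene_slot_bp = 10000) {
  cfg <- as.list(environment())
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% heat_classes)) {
    abort("group_sizes must be named by heat class")
  }
  if ((group_sizes["HT"] %||% 0) < 2) abort("need >= 2 highly tolerant accessions")
  if (any(group_sizes < 0)) abort("group sizes must be >= 0")
  if (variable_presence_prob < 0 || variable_presence_prob > 1) {
    abort("variable_presence_prob must be in [0, 1]")
  }
  if (n_core_genes + n_variable_genes < 20) abort("need >= 20 genes")
  if (n_qtl < 4) abort("n_qtl must be >= 4")
  unknown <- setdiff(names(planted_group_snps),
                     setdiff(consequence_categories, "intergenic"))
  if (length(unknown) > 0L) {
    abort(sprintf("cannot plant category: %s", paste(unknown, collapse = ", ")))
  }
  if (gene_slot_bp < 2 * flank + 5500) {
    abort("gene_slot_bp too small for the requested flank")
  }
  structure(cfg, class = "sim_config")
}

#' Construct a coverage track realising a target covered fraction
#'
#' Inverse of the presence criterion: emits run-length coverage rows in
#' which exactly `ceiling(target_fraction * gene-body length)` gene-body
#' bases (the 5'-most, by genomic coordinate) are covered at `depth` and
#' all remaining bases are left at depth 0 (no row).
#'
#' @param model_row One-row gene-model tibble.
#' @param target_fraction Fraction of the gene body to cover, in \[0, 1\].
#' @param depth Read depth of the covered bases.
#' @return Coverage tibble (`contig`, `start`, `end`, `depth`).
#' @export
coverage_track <- function(model_row, target_fraction, depth = 5) {
  if (target_fraction < 0 || target_fraction > 1) {
    abort("target_fraction must be in [0, 1]")
  }
  body <- model_row$exons[[1]]
  pos <- intervals_to_positions(body)
  n_cov <- ceiling(target_fraction * length(pos))
  if (n_cov == 0L) {
    return(tibble(contig = character(), start = integer(),
                  end = integer(), depth = double()))
  }
  iv <- positions_to_intervals(pos[seq_len(n_cov)])
  tibble(contig = model_row$contig, start = iv$start, end = iv$end,
         depth = as.double(depth))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sample() that never expands a length-1 vector into 1:x
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3)
  paste0("ATG",
         paste(sample(setdiff(sense_codons(), "ATG"), n_codons - 2L,
                      replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

# --- gene structure ---------------------------------------------------------

sim_gene_structure <- function(gene_id, contig, slot_start, strand, coding) {
  n_exons <- sample(1:9, 1L)
  exon_len <- if (n_exons == 1L) sample(300:450, 1L) else
    c(sample(150:260, 1L),
      if (n_exons > 2L) sample(90:240, n_exons - 2L, replace = TRUE),
      sample(150:260, 1L))
  intron_len <- if (n_exons > 1L) sample(80:300, n_exons - 1L, replace = TRUE)
    else integer()
  gstart <- slot_start + 2600L
  starts <- ends <- integer(n_exons)
  cur <- gstart
  for (i in seq_len(n_exons)) {
    starts[i] <- cur
    ends[i] <- cur + exon_len[i] - 1L
    cur <- ends[i] + 1L + (if (i < n_exons) intron_len[i] else 0L)
  }
  exons <- interval_tbl(starts, ends)
  cds <- interval_tbl()
  if (coding) {
    L <- sum(exon_len)
    u5 <- sample(30:90, 1L)
    u3 <- sample(30:90, 1L)
    cds_len <- L - u5 - u3
    u3 <- u3 + cds_len %% 3L
    cds_len <- cds_len - cds_len %% 3L
    stopifnot(cds_len >= 60L)
    pos <- intervals_to_positions(exons)
    cds_pos <- if (strand == "+") pos[(u5 + 1L):(L - u3)] else
      pos[(u3 + 1L):(L - u5)]
    cds <- positions_to_intervals(cds_pos)
  }
  gene_model(gene_id, contig, strand, exons, cds)
}

# write the authored ORF and canonical splice dinucleotides into the genome
imprint_gene <- function(chars, m, orf = NULL) {
  if (!is.null(orf)) {
    cds_pos <- intervals_to_positions(m$cds[[1]])
    bases <- strsplit(orf, "")[[1]]
    if (m$strand == "-") bases <- rev(unname(COMPLEMENT[bases]))
    chars[cds_pos] <- bases
  }
  introns <- m$introns[[1]]
  for (j in seq_len(nrow(introns))) {
    s <- introns$start[j]; e <- introns$end[j]
    if (m$strand == "+") {
      chars[c(s, s + 1L)] <- c("G", "T")
      chars[c(e - 1L, e)] <- c("A", "G")
    } else {
      chars[c(e - 1L, e)] <- c("A", "C")
      chars[c(s, s + 1L)] <- c("C", "T")
    }
  }
  chars
}

# --- SNP planting -----------------------------------------------------------

# find a single-base CDS change realising `category`; returns plus-strand
# (pos, ref, alt) or NULL
find_coding_site <- function(m, orf, category, used) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(orf, seq(1, nchar(orf) - 2, 3), seq(3, nchar(orf), 3))
  n <- length(codons)
  cds_pos <- intervals_to_positions(m$cds[[1]])
  L <- length(cds_pos)
  gpos_of <- function(i) if (m$strand == "+") cds_pos[i] else cds_pos[L - i + 1L]
  try_site <- function(codon_i, off, alt_coding) {
    i <- (codon_i - 1L) * 3L + off
    gp <- gpos_of(i)
    if (gp %in% used) return(NULL)
    alt_plus <- if (m$strand == "+") alt_coding else unname(COMPLEMENT[alt_coding])
    list(pos = gp, alt = alt_plus)
  }
  bases <- c("A", "C", "G", "T")
  scan <- function(range, want) {
    for (ci in range) {
      cod <- codons[ci]
      for (off in sample(1:3)) {
        for (alt in setdiff(bases, substr(cod, off, off))) {
          new <- cod; substr(new, off, off) <- alt
          if (want(cod, new, ci)) {
            s <- try_site(ci, off, alt)
            if (!is.null(s)) return(s)
          }
        }
      }
    }
    NULL
  }
  mid <- if (n > 2L) sample(2:(n - 1L)) else integer()
  switch(category,
    missense = scan(mid, function(cod, new, ci)
      gc[cod] != "*" && gc[new] != "*" && gc[cod] != gc[new]),
    synonymous = scan(mid, function(cod, new, ci)
      gc[cod] != "*" && gc[cod] == gc[new]),
    stop_gained = scan(mid, function(cod, new, ci)
      gc[cod] != "*" && gc[new] == "*"),
    stop_lost = scan(n, function(cod, new, ci)
      gc[cod] == "*" && gc[new] != "*"),
    start_lost = scan(1L, function(cod, new, ci)
      cod == "ATG" && new != "ATG"),
    abort(sprintf("not a coding category: %s", category))
  )
}

interval_interior <- function(iv, margin = 3L, min_width = 2L * 3L + 1L) {
  wide <- iv[iv$end - iv$start + 1L >= min_width, , drop = FALSE]
  if (nrow(wide) == 0L) return(NULL)
  r <- wide[sample.int(nrow(wide), 1L), ]
  resample(seq.int(r$start + margin, r$end - margin), 1L)
}

# pick a genomic site for a non-coding category in gene m; may edit the
# genome chars (context for start_gained / utr5); returns list(pos, ref,
# alt, chars) or NULL
find_noncoding_site <- function(m, chars, category, used, flank) {
  pick <- function(p) if (!is.null(p) && !any((p - 2L):(p + 2L) %in% used)) p else NULL
  alt_not <- function(ref) sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  minus <- m$strand == "-"
  p <- switch(category,
    upstream = {
      d <- sample(200:(flank - 100L), 1L)
      pick(if (minus) m$end + d else m$start - d)
    },
    downstream = {
      d <- sample(200:(flank - 100L), 1L)
      pick(if (minus) m$start - d else m$end + d)
    },
    intronic = {
      iv <- m$introns[[1]]
      iv <- iv[iv$end - iv$start + 1L >= 20L, , drop = FALSE]
      if (nrow(iv) == 0L) NULL else {
        r <- iv[sample.int(nrow(iv), 1L), ]
        pick((r$start + r$end) %/% 2L)
      }
    },
    splice_donor = {
      iv <- m$introns[[1]]
      if (nrow(iv) == 0L) NULL else {
        r <- iv[sample.int(nrow(iv), 1L), ]
        pick(if (minus) r$end else r$start)
      }
    },
    splice_acceptor = {
      iv <- m$introns[[1]]
      if (nrow(iv) == 0L) NULL else {
        r <- iv[sample.int(nrow(iv), 1L), ]
        pick(if (minus) r$start else r$end)
      }
    },
    utr5 = pick(interval_interior(m$utr5[[1]])),
    utr3 = pick(interval_interior(m$utr3[[1]])),
    start_gained = pick(interval_interior(m$utr5[[1]])),
    exon = if (m$coding) NULL else pick(interval_interior(m$exons[[1]])),
    abort(sprintf("unknown category: %s", category))
  )
  if (is.null(p)) return(NULL)
  if (category == "utr5") {
    chars[(p - 2L):(p + 2L)] <- "C"      # no ATG creatable in any frame
    ref <- "C"; alt <- "G"
  } else if (category == "start_gained") {
    if (!minus) {                         # alt T at p makes A-T-G
      chars[(p - 2L):(p + 2L)] <- c("C", "A", "C", "G", "C")
      ref <- "C"; alt <- "T"
    } else {                              # alt A at p makes plus-strand CAT
      chars[(p - 2L):(p + 2L)] <- c("C", "C", "G", "T", "C")
      ref <- "G"; alt <- "A"
    }
  } else {
    ref <- chars[p]
    alt <- alt_not(ref)
  }
  list(pos = p, ref = ref, alt = alt, chars = chars)
}

# --- main generator ---------------------------------------------------------

#' Simulate a complete toy heat-tolerance study with planted ground truth
#'
#' Writes a genome FASTA (reference + non-reference contigs), GFF3 gene
#' models, per-accession coverage TSVs realising a known presence/absence
#' matrix, a multi-sample VCF with background SNPs plus group-specific
#' SNPs of every requested consequence category, per-dataset DEG tables
#' with planted directions and deliberate contradictions, a QTL marker
#' table whose intervals contain the planted candidate genes, and the
#' accession metadata — then returns the ground truth needed to verify
#' every downstream stage. Deterministic given `config$seed`; each stage
#' draws from its own seed substream so adding one stage does not perturb
#' another.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (list: `presence` tibble over retained accessions,
#'   `group_snps` tibble with category and host gene, `deg` tibble of
#'   planted gene directions, `qtl_genes` character vector,
#'   `expected_candidates` tibble of gene id + direction, `meta`,
#'   `reference_contigs`), and `models`, `contigs` for convenience.
#' @export
simulate_panheat <- function(config = sim_config(), out_dir) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "coverage"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  cfg <- config

  ## stage 1: genome and gene models -----------------------------------------
  set.seed(stage_seed(cfg$seed, 1L))
  n_genes <- cfg$n_core_genes + cfg$n_variable_genes
  n_nonref_genes <- max(4L, round(cfg$frac_genes_nonref * n_genes))
  n_ref_genes <- n_genes - n_nonref_genes
  ref_names <- paste0("chr", seq_len(cfg$n_contigs_ref))
  nonref_names <- paste0("ctg", seq_len(cfg$n_contigs_nonref))
  gene_contig <- c(
    ref_names[1L + (seq_len(n_ref_genes) - 1L) %% cfg$n_contigs_ref],
    nonref_names[1L + (seq_len(n_nonref_genes) - 1L) %% cfg$n_contigs_nonref]
  )
  gene_contig <- sort(gene_contig)  # genes laid out contig by contig
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  noncoding <- rep(FALSE, n_genes)
  nc_idx <- seq(5L, by = max(3L, n_genes %/% max(1L, cfg$n_noncoding)),
                length.out = cfg$n_noncoding)
  noncoding[nc_idx[nc_idx <= n_genes]] <- TRUE
  strands <- rep(c("+", "-"), length.out = n_genes)

  models <- vector("list", n_genes)
  orfs <- vector("list", n_genes)
  slot_of <- integer(n_genes)
  for (ct in unique(gene_contig)) {
    idx <- which(gene_contig == ct)
    for (k in seq_along(idx)) {
      i <- idx[k]
      slot_of[i] <- (k - 1L) * cfg$gene_slot_bp
      models[[i]] <- sim_gene_structure(gene_ids[i], ct, slot_of[i],
                                        strands[i], !noncoding[i])
      if (!noncoding[i]) {
        orfs[[i]] <- random_orf(interval_len(models[[i]]$cds[[1]]) %/% 3L)
      }
    }
  }
  models <- bind_rows(models)

  contig_names <- unique(gene_contig)
  contig_lens <- vapply(contig_names, function(ct) {
    max(models$end[models$contig == ct]) + 3000L
  }, integer(1))
  chars_by_contig <- lapply(seq_along(contig_names), function(ci) {
    sample(c("A", "C", "G", "T"), contig_lens[ci], replace = TRUE)
  })
  names(chars_by_contig) <- contig_names
  for (i in seq_len(n_genes)) {
    ct <- models$contig[i]
    chars_by_contig[[ct]] <- imprint_gene(chars_by_contig[[ct]], models[i, ],
                                          orfs[[i]])
  }

  ## stage 2: cohort metadata -------------------------------------------------
  set.seed(stage_seed(cfg$seed, 2L))
  classes <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n_acc <- length(classes)
  acc <- sprintf("ACC%02d", seq_len(n_acc))
  fert_range <- list(HT = c(66, 95), T = c(50.5, 65), MT = c(35.5, 50),
                     S = c(15.5, 35), HS = c(2, 15))
  fertility <- round(vapply(classes, function(cl) {
    runif(1, fert_range[[cl]][1], fert_range[[cl]][2])
  }, numeric(1)), 1)
  depth <- round(runif(n_acc, 12, 40), 1)
  non_ht <- which(classes != "HT")
  low_idx <- resample(non_ht, min(cfg$n_low_depth, length(non_ht)))
  depth[low_idx] <- round(runif(length(low_idx), 4, 9.5), 1)
  meta <- tibble(
    accession = acc,
    subpopulation = sample(c("Indica", "Japonica", "Aus", "Admix"), n_acc,
                           replace = TRUE, prob = c(0.5, 0.33, 0.07, 0.1)),
    fertility = fertility,
    heat_class = classify_heat_response(fertility),
    depth = depth
  )
  stopifnot(identical(meta$heat_class, unname(classes)))
  retained <- acc[depth > 10]
  ht_acc <- acc[classes == "HT"]

  ## stage 3: presence truth and coverage -------------------------------------
  set.seed(stage_seed(cfg$seed, 3L))
  variable_ids <- sort(sample(gene_ids, cfg$n_variable_genes))
  pres <- matrix(TRUE, n_genes, length(retained),
                 dimnames = list(gene_ids, retained))
  for (g in variable_ids) {
    pres[g, ] <- runif(length(retained)) < cfg$variable_presence_prob
    if (all(pres[g, ])) pres[g, sample.int(length(retained), 1L)] <- FALSE
    if (!any(pres[g, ])) pres[g, sample.int(length(retained), 1L)] <- TRUE
  }
  presence_truth <- tibble(gene_id = gene_ids)
  presence_truth[retained] <- lapply(retained, function(a) unname(pres[, a]))

  low_acc <- setdiff(acc, retained)
  cov_paths <- setNames(character(n_acc), acc)
  for (a in acc) {
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      present <- if (a %in% retained) pres[gene_ids[i], a] else
        runif(1) < cfg$variable_presence_prob
      frac <- if (present) runif(1, 0.85, 0.98) else runif(1, 0.30, 0.70)
      rows[[i]] <- coverage_track(models[i, ], frac,
                                  depth = sample(5:30, 1L))
    }
    cov_paths[a] <- file.path(out_dir, "coverage", paste0("cov_", a, ".tsv"))
    write_coverage(bind_rows(rows), cov_paths[a])
  }

  ## stage 4: variants ---------------------------------------------------------
  set.seed(stage_seed(cfg$seed, 4L))
  used_pos <- setNames(vector("list", length(contig_names)), contig_names)
  take <- function(ct, p) {
    used_pos[[ct]] <<- c(used_pos[[ct]], as.integer(p))
  }
  taken <- function(ct, p) p %in% used_pos[[ct]]

  planted <- list()
  host_rows <- list()
  eligible_for <- function(category) {
    ok <- vapply(seq_len(n_genes), function(i) {
      m <- models[i, ]
      switch(category,
        missense = , synonymous = , stop_gained = , stop_lost = ,
        start_lost = m$coding,
        splice_donor = , splice_acceptor = m$coding && nrow(m$introns[[1]]) > 0L,
        intronic = any(m$introns[[1]]$end - m$introns[[1]]$start + 1L >= 20L),
        utr5 = , start_gained = m$coding && nrow(m$utr5[[1]]) > 0L &&
          any(m$utr5[[1]]$end - m$utr5[[1]]$start + 1L >= 7L),
        utr3 = m$coding && nrow(m$utr3[[1]]) > 0L &&
          any(m$utr3[[1]]$end - m$utr3[[1]]$start + 1L >= 7L),
        exon = !m$coding,
        upstream = , downstream = TRUE)
    }, logical(1))
    which(ok)
  }
  is_nonref_gene <- models$contig %in% nonref_names
  hosted <- rep(FALSE, n_genes)
  nonref_hosted <- 0L
  plant_queue <- rep(names(cfg$planted_group_snps), cfg$planted_group_snps)
  for (category in plant_queue) {
    elig <- eligible_for(category)
    if (length(elig) == 0L) {
      abort(sprintf("infeasible config: no gene can host a %s SNP", category))
    }
    # prefer fresh host genes, non-reference first until 4 are hosted there
    tier1 <- if (nonref_hosted < 4L) elig[is_nonref_gene[elig] & !hosted[elig]]
      else integer()
    tier2 <- setdiff(elig[!hosted[elig]], tier1)
    tier3 <- setdiff(elig, c(tier1, tier2))
    order_try <- c(resample(tier1), resample(tier2), resample(tier3))
    site <- NULL
    for (i in order_try) {
      m <- models[i, ]
      ct <- m$contig
      if (category %in% c("missense", "synonymous", "stop_gained",
                          "stop_lost", "start_lost")) {
        s <- find_coding_site(m, orfs[[i]], category, used = integer())
        if (!is.null(s) && !taken(ct, s$pos)) {
          site <- list(gene = i, pos = s$pos,
                       ref = chars_by_contig[[ct]][s$pos], alt = s$alt)
        }
      } else {
        s <- find_noncoding_site(m, chars_by_contig[[ct]], category,
                                 used = used_pos[[ct]] %||% integer(),
                                 flank = cfg$flank)
        if (!is.null(s) && !taken(ct, s$pos)) {
          chars_by_contig[[ct]] <- s$chars
          site <- list(gene = i, pos = s$pos, ref = s$ref, alt = s$alt)
        }
      }
      if (!is.null(site)) break
    }
    if (is.null(site)) {
      abort(sprintf("infeasible config: could not place a %s SNP", category))
    }
    ct <- models$contig[site$gene]
    take(ct, site$pos)
    hosted[site$gene] <- TRUE
    if (is_nonref_gene[site$gene]) nonref_hosted <- nonref_hosted + 1L
    planted[[length(planted) + 1L]] <- tibble(
      contig = ct, pos = site$pos, ref = site$ref, alt = site$alt,
      category = category, gene_id = gene_ids[site$gene])
  }
  planted <- bind_rows(planted)
  stopifnot(!anyDuplicated(paste(planted$contig, planted$pos)))

  planted_gt <- matrix("0/0", nrow(planted), n_acc,
                       dimnames = list(NULL, acc))
  planted_gt[, ht_acc] <- "1/1"

  n_bg <- cfg$n_background_snps
  bg <- tibble(
    contig = sample(contig_names, n_bg, replace = TRUE,
                    prob = contig_lens / sum(contig_lens)),
    pos = NA_integer_, ref = NA_character_, alt = NA_character_)
  for (i in seq_len(n_bg)) {
    repeat {
      p <- sample.int(contig_lens[bg$contig[i]], 1L)
      if (!taken(bg$contig[i], p)) break
    }
    take(bg$contig[i], p)
    bg$pos[i] <- p
    bg$ref[i] <- chars_by_contig[[bg$contig[i]]][p]
    bg$alt[i] <- sample(setdiff(c("A", "C", "G", "T"), bg$ref[i]), 1L)
  }
  bg_gt <- matrix("0/0", n_bg, n_acc, dimnames = list(NULL, acc))
  n_lowmaf <- round(cfg$frac_low_maf * n_bg)
  n_himiss <- round(cfg$frac_high_missing * n_bg)
  kind <- c(rep("lowmaf", n_lowmaf), rep("himiss", n_himiss),
            rep("normal", n_bg - n_lowmaf - n_himiss))
  non_ht_acc <- setdiff(acc, ht_acc)
  for (i in seq_len(n_bg)) {
    if (kind[i] == "lowmaf") {
      # below-threshold MAF: a singleton het outside the HT group when the
      # cohort is large enough for 1/(2n) < 0.05, else a monomorphic site
      if (1 / (2 * n_acc) < 0.05) bg_gt[i, sample(non_ht_acc, 1L)] <- "0/1"
    } else if (kind[i] == "himiss") {
      p_alt <- runif(1, 0.2, 0.5)
      bg_gt[i, ] <- c("0/0", "0/1", "1/1")[
        rbinom(n_acc, 2, p_alt) + 1L]
      miss <- sample.int(n_acc, ceiling(0.85 * n_acc))
      bg_gt[i, miss] <- "./."
    } else {
      p_alt <- runif(1, 0.15, 0.6)
      bg_gt[i, ] <- c("0/0", "0/1", "1/1")[rbinom(n_acc, 2, p_alt) + 1L]
      bg_gt[i, runif(n_acc) < 0.03] <- "./."
    }
    carriers <- acc[gt_has_alt(bg_gt[i, ])]
    if (length(carriers) > 0L && all(carriers %in% ht_acc)) {
      bg_gt[i, sample(non_ht_acc, 1L)] <- "0/1"   # break group specificity
    }
  }
  # brute-force guarantee: no background SNP is HT-exclusive
  bg_excl <- apply(bg_gt, 1L, function(g) {
    carriers <- acc[gt_has_alt(g)]
    length(carriers) > 0L && all(carriers %in% ht_acc)
  })
  stopifnot(!any(bg_excl))

  multi <- NULL
  if (cfg$n_multiallelic > 0L) {
    multi <- tibble(contig = sample(contig_names, cfg$n_multiallelic,
                                    replace = TRUE),
                    pos = NA_integer_, ref = NA_character_,
                    alt = NA_character_)
    for (i in seq_len(cfg$n_multiallelic)) {
      repeat {
        p <- sample.int(contig_lens[multi$contig[i]], 1L)
        if (!taken(multi$contig[i], p)) break
      }
      take(multi$contig[i], p)
      multi$pos[i] <- p
      multi$ref[i] <- chars_by_contig[[multi$contig[i]]][p]
      alts <- sample(setdiff(c("A", "C", "G", "T"), multi$ref[i]), 2L)
      multi$alt[i] <- paste(alts, collapse = ",")
    }
    multi_gt <- matrix(sample(c("0/0", "0/1", "1/1", "1/2", "0/2"),
                              cfg$n_multiallelic * n_acc, replace = TRUE,
                              prob = c(0.5, 0.2, 0.1, 0.1, 0.1)),
                       cfg$n_multiallelic, n_acc, dimnames = list(NULL, acc))
  }

  fixed <- bind_rows(
    planted |> select("contig", "pos", "ref", "alt"),
    bg,
    if (!is.null(multi)) multi
  )
  gt_all <- rbind(planted_gt, bg_gt, if (!is.null(multi)) multi_gt)
  ord <- order(match(fixed$contig, contig_names), fixed$pos)
  variants <- dplyr::bind_cols(
    tibble(contig = fixed$contig[ord], pos = fixed$pos[ord], id = ".",
           ref = fixed$ref[ord], alt = fixed$alt[ord]),
    as_tibble(as.data.frame(gt_all[ord, , drop = FALSE],
                            stringsAsFactors = FALSE))
  )

  ## stage 5: DEG tables -------------------------------------------------------
  set.seed(stage_seed(cfg$seed, 5L))
  hosts <- unique(planted$gene_id)
  nonref_hosts <- hosts[hosts %in% gene_ids[is_nonref_gene]]
  if (length(nonref_hosts) < 3L) {
    abort("infeasible config: need >= 3 non-reference SNP host genes")
  }
  by_ct <- split(nonref_hosts, models$contig[match(nonref_hosts, gene_ids)])
  ct4 <- names(by_ct)[which.max(lengths(by_ct))]
  if (length(by_ct[[ct4]]) < 2L) {
    abort("infeasible config: need 2 non-reference hosts on one contig")
  }
  up_nonref <- sort(by_ct[[ct4]])[1:2]
  pool <- setdiff(hosts, up_nonref)
  ref_pool <- setdiff(pool, nonref_hosts)
  need <- cfg$n_planted_up - 2L + cfg$n_planted_down + cfg$n_planted_contra
  if (length(pool) < need || length(ref_pool) < need - 1L) {
    abort("infeasible config: too few SNP host genes for the DE plant")
  }
  up_ref <- resample(ref_pool, cfg$n_planted_up - 2L)
  pool <- setdiff(pool, up_ref)
  down_nonref <- intersect(pool, nonref_hosts)   # a non-reference down gene when available
  down_genes <- c(
    if (length(down_nonref) > 0L) resample(down_nonref, 1L),
    resample(setdiff(pool, nonref_hosts),
             cfg$n_planted_down - min(1L, length(down_nonref))))
  pool <- setdiff(pool, down_genes)
  contra_genes <- resample(pool, cfg$n_planted_contra)
  up_genes <- c(up_nonref, up_ref)

  de_only <- resample(setdiff(gene_ids, hosts), cfg$n_de_only)
  de_only_up <- de_only[seq_len(ceiling(cfg$n_de_only / 2))]
  de_only_down <- setdiff(de_only, de_only_up)

  comparisons <- tibble(
    dataset = rep(names(cfg$datasets), lengths(cfg$datasets)),
    comparison = unlist(cfg$datasets, use.names = FALSE))
  n_cmp <- nrow(comparisons)
  sig_in <- function() sort(sample.int(n_cmp, sample(1:2, 1L)))

  deg_rows <- vector("list", n_cmp)
  plan_up <- c(setNames(lapply(c(up_genes, de_only_up), function(g) sig_in()),
                        c(up_genes, de_only_up)))
  plan_down <- c(setNames(lapply(c(down_genes, de_only_down),
                                 function(g) sig_in()),
                          c(down_genes, de_only_down)))
  plan_contra <- setNames(lapply(contra_genes, function(g) {
    k <- sample.int(n_cmp, 2L)
    list(up = k[1], down = k[2])
  }), contra_genes)

  for (k in seq_len(n_cmp)) {
    lfc <- stats::rnorm(n_genes, 0, 0.4)
    padj <- runif(n_genes, 0.2, 1)
    padj[runif(n_genes) < 0.02] <- NA
    for (g in names(plan_up)) if (k %in% plan_up[[g]]) {
      i <- match(g, gene_ids)
      lfc[i] <- runif(1, 1.2, 4); padj[i] <- runif(1, 1e-8, 0.02)
    }
    for (g in names(plan_down)) if (k %in% plan_down[[g]]) {
      i <- match(g, gene_ids)
      lfc[i] <- -runif(1, 1.2, 4); padj[i] <- runif(1, 1e-8, 0.02)
    }
    for (g in names(plan_contra)) {
      i <- match(g, gene_ids)
      if (k == plan_contra[[g]]$up) {
        lfc[i] <- runif(1, 1.2, 4); padj[i] <- runif(1, 1e-8, 0.02)
      } else if (k == plan_contra[[g]]$down) {
        lfc[i] <- -runif(1, 1.2, 4); padj[i] <- runif(1, 1e-8, 0.02)
      }
    }
    deg_rows[[k]] <- tibble(
      dataset = comparisons$dataset[k], comparison = comparisons$comparison[k],
      gene_id = gene_ids, log2fc = round(lfc, 4), padj = signif(padj, 4))
  }
  deg <- bind_rows(deg_rows)

  ## stage 6: QTL markers ------------------------------------------------------
  set.seed(stage_seed(cfg$seed, 6L))
  span_of <- function(gs) {
    i <- match(gs, gene_ids)
    c(min(models$start[i]), max(models$end[i]))
  }
  qtls <- list()
  add_qtl <- function(contig, start, end) {
    qtls[[length(qtls) + 1L]] <<- tibble(
      qtl_id = sprintf("qHT%02d", length(qtls) + 1L),
      contig = contig, start = max(1L, as.integer(start)),
      end = min(contig_lens[contig], as.integer(end)))
  }
  g_up_ref <- up_ref[1]
  sp <- span_of(g_up_ref); ct1 <- models$contig[match(g_up_ref, gene_ids)]
  add_qtl(ct1, sp[1] - 400L, sp[2] + 400L)
  g_down <- down_genes[!down_genes %in% nonref_hosts][1]
  sp <- span_of(g_down); ct2 <- models$contig[match(g_down, gene_ids)]
  add_qtl(ct2, sp[1] - 400L, sp[2] + 400L)
  add_qtl(ct2, sp[1] + 1000L, sp[2] + 6000L)   # overlaps the previous QTL
  sp <- span_of(up_nonref)
  add_qtl(ct4, sp[1] - 300L, sp[2] + 300L)
  extra <- cfg$n_qtl - 4L
  if (extra > 0L) {
    for (g in resample(setdiff(gene_ids, c(up_genes, down_genes)), extra)) {
      sp <- span_of(g); ct <- models$contig[match(g, gene_ids)]
      add_qtl(ct, sp[1] - 200L, sp[2] + 200L)
    }
  }
  qtls <- bind_rows(qtls)

  genome_str <- vapply(chars_by_contig, paste, character(1), collapse = "")
  count_hits <- function(seqv, pat) {
    sum(vapply(seqv, function(s) {
      f <- gregexpr(pat, s, fixed = TRUE)[[1]]
      r <- gregexpr(rc3_long(pat), s, fixed = TRUE)[[1]]
      sum(f > 0) + sum(r > 0)
    }, numeric(1)))
  }
  marker_rows <- list()
  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, ]
    s <- q$start
    for (try in 1:50) {
      m1 <- substr(genome_str[[q$contig]], s, s + 19L)
      if (count_hits(genome_str, m1) == 1L) break
      s <- s + 7L
      if (try == 50L) abort("could not derive a unique left marker")
    }
    e <- q$end
    for (try in 1:50) {
      m2raw <- substr(genome_str[[q$contig]], e - 19L, e)
      if (count_hits(genome_str, m2raw) == 1L) break
      e <- e - 7L
      if (try == 50L) abort("could not derive a unique right marker")
    }
    qtls$start[i] <- s; qtls$end[i] <- e
    marker_rows[[length(marker_rows) + 1L]] <- tibble(
      qtl_id = q$qtl_id,
      marker_id = paste0(q$qtl_id, c("_L", "_R")),
      sequence = c(m1, rc3_long(m2raw)))  # right marker stored as revcomp
  }
  markers <- bind_rows(marker_rows)

  qtl_genes <- sort(unique(unlist(lapply(seq_len(nrow(qtls)), function(i) {
    q <- qtls[i, ]
    gene_ids[models$contig == q$contig & models$start <= q$end &
               models$end >= q$start]
  }))))

  ## ground truth --------------------------------------------------------------
  deg_truth <- bind_rows(
    tibble(gene_id = up_genes, direction = "up", planted = "snp+de"),
    tibble(gene_id = down_genes, direction = "down", planted = "snp+de"),
    tibble(gene_id = contra_genes, direction = "contradictory",
           planted = "snp+contra"),
    tibble(gene_id = de_only_up, direction = "up", planted = "de-only"),
    tibble(gene_id = de_only_down, direction = "down", planted = "de-only"))
  consistent <- deg_truth$gene_id[deg_truth$direction %in% c("up", "down")]
  expected <- tibble(gene_id = intersect(intersect(hosts, consistent),
                                         qtl_genes)) |>
    left_join(deg_truth |> select("gene_id", "direction"), by = "gene_id") |>
    arrange(.data$gene_id)

  truth <- list(
    presence = presence_truth,
    group_snps = planted,
    deg = deg_truth,
    qtl_genes = qtl_genes,
    expected_candidates = expected,
    meta = meta,
    reference_contigs = ref_names,
    retained_accessions = retained
  )

  ## write everything ----------------------------------------------------------
  contigs <- tibble(name = contig_names,
                    seq = unname(genome_str[contig_names]),
                    is_reference = contig_names %in% ref_names)
  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    meta = file.path(out_dir, "meta.tsv"),
    vcf = file.path(out_dir, "variants.vcf.gz"),
    deg = file.path(out_dir, "deg.tsv"),
    markers = file.path(out_dir, "markers.tsv"),
    coverage = cov_paths
  )
  write_fasta(contigs, paths$fasta)
  write_gff3(models, paths$gff3)
  write_meta(meta, paths$meta)
  paths$vcf <- write_vcf(variants, paths$vcf)
  write_deg(deg, paths$deg)
  write_markers(markers, paths$markers)
  write_presence(presence_truth, file.path(out_dir, "truth", "presence_truth.tsv"))
  readr::write_tsv(planted, file.path(out_dir, "truth", "group_snps.tsv"))
  readr::write_tsv(deg_truth, file.path(out_dir, "truth", "deg_truth.tsv"))
  readr::write_tsv(expected, file.path(out_dir, "truth", "expected_candidates.tsv"))
  writeLines(qtl_genes, file.path(out_dir, "truth", "qtl_genes.txt"))

  invisible(list(paths = paths, truth = truth, models = models,
                 contigs = contigs, config = cfg))
}

# reverse complement for plain character scalars of any length
rc3_long <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}
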