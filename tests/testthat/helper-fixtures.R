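# Shared fixtures, built in code at test time.

# cache simulated studies per (seed, size) within the session
.sim_cache <- new.env(parent = emptyenv())

get_sim <- function(seed = 1, small = TRUE) {
  key <- paste0("s", seed, if (small) "_small" else "_full")
  if (is.null(.sim_cache[[key]])) {
    cfg <- if (small) {
      sim_config(
        seed = seed,
        group_sizes = c(HT = 2, T = 3, MT = 1, S = 2, HS = 1),
        n_low_depth = 1,
        n_core_genes = 40, n_variable_genes = 10,
        n_background_snps = 300, n_multiallelic = 6,
        n_planted_up = 4, n_planted_down = 3, n_planted_contra = 1,
        n_de_only = 4
      )
    } else {
      sim_config(seed = seed)
    }
    dir <- file.path(tempdir(), paste0("panheat_fix_", key))
    sim <- simulate_panheat(cfg, dir)
    sim$dir <- dir
    .sim_cache[[key]] <- sim
  }
  .sim_cache[[key]]
}

get_pipeline <- function(seed = 1, small = TRUE) {
  key <- paste0("p", seed, if (small) "_small" else "_full")
  if (is.null(.sim_cache[[key]])) {
    sim <- get_sim(seed, small = small)
    .sim_cache[[key]] <- suppressMessages(run_panheat(sim$dir))
  }
  .sim_cache[[key]]
}

variant_key <- function(d) paste(d$contig, d$pos, d$ref, d$alt, sep = ":")

# deterministic random presence tibble
random_presence <- function(n_genes, n_acc, seed, p = 0.7) {
  set.seed(seed)
  out <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes)))
  for (a in sprintf("a%02d", seq_len(n_acc))) {
    out[[a]] <- stats::runif(n_genes) < p
  }
  out
}

# --- hand-built annotation fixture ----------------------------------------
# One coding gene with engineered codons on a random contig:
#   exons (1001-1200), (1501-1800), (2101-2400)
#   CDS   (1101-1200), (1501-1800), (2101-2300); 600 bp = 200 codons
#   codon  2 = AAA (Lys; AAA->AAG synonymous, AAA->ACA missense)
#   codon  3 = TGG (Trp; TGG->TGA stop gained)
#   codon 200 = TAA (stop; TAA->GAA stop lost)
#   utr5 context at 1050 primed so C->T creates an ATG (start gained)
annot_fixture <- function(seed = 42) {
  set.seed(seed)
  L <- 10000L
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  exons <- tibble::tibble(start = c(1001L, 1501L, 2101L),
                          end = c(1200L, 1800L, 2400L))
  cds <- tibble::tibble(start = c(1101L, 1501L, 2101L),
                        end = c(1200L, 1800L, 2300L))
  m <- gene_model("gx", "chrT", "+", exons, cds)
  orf <- paste0("ATG", "AAA", "TGG",
                paste(rep("GCT", 196), collapse = ""), "TAA")
  stopifnot(nchar(orf) == 600L)
  cds_pos <- unlist(Map(seq.int, cds$start, cds$end))
  chars[cds_pos] <- strsplit(orf, "")[[1]]
  # canonical splice dinucleotides
  chars[c(1201L, 1202L)] <- c("G", "T"); chars[c(1499L, 1500L)] <- c("A", "G")
  chars[c(1801L, 1802L)] <- c("G", "T"); chars[c(2099L, 2100L)] <- c("A", "G")
  # start-gained context at 1050 (utr5 1001-1100): ref CACGC, alt T at 1050
  chars[1048:1052] <- c("C", "A", "C", "G", "C")
  # plain utr5 site at 1070 with no ATG creatable
  chars[1068:1072] <- "C"
  contigs <- tibble::tibble(name = "chrT",
                            seq = paste(chars, collapse = ""),
                            is_reference = TRUE)
  list(contigs = contigs, models = m, chars = chars)
}

# genomic position of coding-strand CDS index i (1-based)
cds_genomic_pos <- function(model_row, i) {
  cds <- model_row$cds[[1]]
  pos <- unlist(Map(seq.int, cds$start, cds$end))
  if (model_row$strand == "+") pos[i] else pos[length(pos) - i + 1L]
}

# --- strand mirror ---------------------------------------------------------
flip_pos <- function(pos, L) L - pos + 1L

flip_intervals <- function(iv, L) {
  tibble::tibble(start = flip_pos(iv$end, L), end = flip_pos(iv$start, L)) |>
    dplyr::arrange(start)
}

flip_study <- function(contigs, models, variants = NULL) {
  stopifnot(nrow(contigs) == 1L)
  L <- nchar(contigs$seq[[1]])
  contigs2 <- contigs
  contigs2$seq <- revcomp(contigs$seq)
  models2 <- do.call(rbind, lapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    gene_model(m$gene_id, m$contig,
               if (m$strand == "+") "-" else "+",
               flip_intervals(m$exons[[1]], L),
               flip_intervals(m$cds[[1]], L))
  }))
  out <- list(contigs = contigs2, models = models2)
  if (!is.null(variants)) {
    v2 <- variants
    v2$pos <- flip_pos(variants$pos, L)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    v2$ref <- unname(comp[variants$ref])
    v2$alt <- unname(comp[variants$alt])
    out$variants <- v2
  }
  out
}

# small wide variant table from a genotype matrix
make_variants <- function(contig, pos, ref, alt, gt) {
  out <- tibble::tibble(contig = contig, pos = as.integer(pos), id = ".",
                        ref = ref, alt = alt)
  dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(gt,
                                                        stringsAsFactors = FALSE)))
}
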