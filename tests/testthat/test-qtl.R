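qtl_genome <- function(seed = 8, len = 6000L) {
  set.seed(seed)
  tibble::tibble(name = "chrQ",
                 seq = paste(sample(c("A", "C", "G", "T"), len, TRUE),
                             collapse = ""),
                 is_reference = TRUE)
}

test_that("markers place by exact match on both strands, or are logged", {
  contigs <- qtl_genome()
  seq <- contigs$seq[[1]]
  m1 <- substr(seq, 101, 120)
  m2 <- revcomp(substr(seq, 4981, 5000))   # reverse-complement occurrence
  markers <- tibble::tibble(
    qtl_id = c("q1", "q1", "q2"),
    marker_id = c("m1", "m2", "m3"),
    sequence = c(m1, m2, strrep("ACGT", 5)))
  # the absent 20-mer may in principle occur by chance; rebuild if so
  stopifnot(!grepl(markers$sequence[3], seq, fixed = TRUE))
  placed <- suppressMessages(place_markers(markers, contigs))
  expect_equal(placed$status, c("placed", "placed", "unplaced"))
  expect_equal(placed$pos[1], 101L)
  expect_equal(placed$pos[2], 4981L)   # forward coordinates of the rc match
  expect_equal(placed$end[2], 5000L)

  # a repeated motif is ambiguous unless keep_ambiguous is set
  seq2 <- paste0(substr(seq, 1, 3000), substr(seq, 1, 3000))
  contigs2 <- tibble::tibble(name = "chrQ", seq = seq2, is_reference = TRUE)
  amb <- tibble::tibble(qtl_id = "q1", marker_id = "m1", sequence = m1)
  out <- suppressMessages(place_markers(amb, contigs2))
  expect_equal(out$status, "ambiguous")
  expect_true(is.na(out$pos))
  out2 <- suppressMessages(place_markers(amb, contigs2,
                                         keep_ambiguous = TRUE))
  expect_equal(out2$pos, 101L)         # first hit by position
})

test_that("QTL intervals span flanking markers and merge when overlapping", {
  placed <- tibble::tibble(
    qtl_id = c("q1", "q1", "q2", "q2", "q3", "q3"),
    marker_id = paste0("m", 1:6),
    sequence = NA_character_,
    contig = "chrQ",
    pos = c(100L, 4981L, 4000L, 8981L, 20000L, 24981L),
    end = c(120L, 5000L, 4020L, 9000L, 20020L, 25000L),
    status = "placed")
  iv <- build_intervals(placed, merge = FALSE)
  expect_equal(iv$start, c(100L, 4000L, 20000L))
  expect_equal(iv$end, c(5000L, 9000L, 25000L))   # [min start, max end]
  merged <- build_intervals(placed, merge = TRUE)
  expect_equal(nrow(merged), 2L)                  # 3 QTLs -> 2 regions
  expect_equal(merged$start[1], 100L)
  expect_equal(merged$end[1], 9000L)
  expect_equal(merged$qtl_ids[1], "q1,q2")
  # merged intervals are disjoint and cover the union of inputs
  expect_true(all(merged$start[-1] > merged$end[-nrow(merged)]))

  lost <- placed
  lost$status[lost$qtl_id == "q1"] <- "unplaced"
  lost$pos[lost$qtl_id == "q1"] <- NA_integer_
  expect_error(build_intervals(lost), "q1")
  bad <- placed
  bad$contig[2] <- "chrZ"
  expect_error(build_intervals(bad), "several contigs")
})

test_that("gene-QTL membership obeys 1-based inclusive overlap and the quadratic oracle", {
  mk_model <- function(id, s, e) {
    gene_model(id, "chrQ", "+", tibble::tibble(start = s, end = e))
  }
  models <- dplyr::bind_rows(
    mk_model("gIn", 2000, 2500),
    mk_model("gOut", 5001, 5600),
    mk_model("gEdge", 4900, 5000))
  iv <- tibble::tibble(qtl_ids = "q1", contig = "chrQ",
                       start = 100L, end = 5000L)
  mem <- genes_in_qtls(models, iv)
  expect_setequal(mem$gene_id, c("gIn", "gEdge"))  # 5001 does not touch 5000

  # random fixtures vs the brute-force all-pairs oracle
  for (s in 1:5) {
    set.seed(300 + s)
    models_r <- dplyr::bind_rows(lapply(1:50, function(i) {
      st <- sample.int(100000L, 1L)
      gene_model(sprintf("g%02d", i), sample(c("c1", "c2"), 1), "+",
                 tibble::tibble(start = st, end = st + sample(200:3000, 1)))
    }))
    iv_r <- tibble::tibble(
      qtl_ids = sprintf("q%02d", 1:10),
      contig = sample(c("c1", "c2"), 10, TRUE),
      start = sample.int(90000L, 10))
    iv_r$end <- iv_r$start + sample(1000:20000, 10)
    got <- genes_in_qtls(models_r, iv_r) |>
      dplyr::select(gene_id, qtl_ids) |>
      dplyr::arrange(gene_id, qtl_ids)
    expect_equal(as.data.frame(got),
                 as.data.frame(oracle_genes_in_qtls(models_r, iv_r)))
  }
})

test_that("the final report restricts candidates to QTL residents monotonically", {
  sim <- get_sim(1)
  res <- get_pipeline(1)
  rep <- res$report
  expect_true(all(rep$genes$gene_id %in% res$candidates$gene_id))
  expect_equal(rep$counts$total, rep$counts$up + rep$counts$down)
  expect_equal(nrow(rep$genes), rep$counts$total)
  # shrinking intervals never adds candidates
  iv <- res$intervals
  shrunk <- iv[1, , drop = FALSE]
  rep2 <- final_candidates(res$candidates, genes_in_qtls(res$models, shrunk))
  expect_true(all(rep2$genes$gene_id %in% rep$genes$gene_id))
  # no overlap anywhere -> empty report
  none <- final_candidates(res$candidates,
                           genes_in_qtls(res$models, iv[0, , drop = FALSE]))
  expect_equal(none$counts$total, 0L)
})
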