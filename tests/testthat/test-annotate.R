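# The engineered gene (see helper-fixtures.R) places known codons at known
# genomic positions, so every coding call can be asserted by hand and then
# cross-checked against the rebuild-and-translate oracle.

expected_plus_calls <- function() {
  tibble::tribble(
    ~pos,  ~alt, ~category,
    1106L, "G", "synonymous",      # AAA -> AAG (Lys)
    1105L, "C", "missense",        # AAA -> ACA (Thr)
    1109L, "A", "stop_gained",     # TGG -> TGA
    2298L, "G", "stop_lost",       # TAA -> GAA
    1102L, "C", "start_lost",      # ATG -> ACG
    1201L, "A", "splice_donor",    # first intron base
    1500L, "C", "splice_acceptor", # last intron base
    1350L, "T", "intronic",
    1050L, "T", "start_gained",    # utr5 allele creating an ATG
    1070L, "G", "utr5",
    2350L, "C", "utr3",
    801L,  "A", "upstream",        # 200 bp 5' of the span
    4400L, "T", "downstream",      # exactly flank bp 3' of the span
    4401L, "T", "intergenic",      # one base past the flank
    8000L, "C", "intergenic"
  )
}

fixture_variants <- function(fx, calls) {
  chars <- strsplit(fx$contigs$seq[[1]], "")[[1]]
  make_variants("chrT", calls$pos, chars[calls$pos], calls$alt,
                matrix("0/1", nrow(calls), 1, dimnames = list(NULL, "s1")))
}

test_that("every consequence category is called correctly on the plus strand", {
  fx <- annot_fixture()
  calls <- expected_plus_calls()
  v <- fixture_variants(fx, calls)
  rec <- annotate_variants(v, fx$models, fx$contigs)
  got <- rec$category[match(calls$pos, rec$pos)]
  expect_equal(got, calls$category)
  # impact classes follow the map
  expect_equal(rec$impact[rec$category == "stop_gained"], "HIGH")
  expect_equal(rec$impact[rec$category == "missense"], "MODERATE")
  expect_equal(rec$impact[rec$category == "synonymous"], "LOW")
  expect_equal(rec$impact[rec$category == "upstream"], "MODIFIER")
  # amino-acid change is reported for coding calls
  mis <- rec[rec$category == "missense", ]
  expect_equal(mis$aa_ref, "K")
  expect_equal(mis$aa_alt, "T")
  expect_equal(mis$codon, 2L)
})

test_that("annotation is strand-symmetric under reverse complement", {
  fx <- annot_fixture()
  calls <- expected_plus_calls()
  v <- fixture_variants(fx, calls)
  flipped <- flip_study(fx$contigs, fx$models, v)
  rec <- annotate_variants(flipped$variants, flipped$models, flipped$contigs)
  L <- nchar(fx$contigs$seq[[1]])
  got <- rec$category[match(flip_pos(calls$pos, L), rec$pos)]
  expect_equal(got, calls$category)
})

test_that("coding calls agree with the rebuild-and-translate oracle on both strands", {
  fx <- annot_fixture()
  coding <- dplyr::filter(expected_plus_calls(),
                          category %in% c("synonymous", "missense",
                                          "stop_gained", "stop_lost",
                                          "start_lost"))
  v <- fixture_variants(fx, coding)
  rec <- annotate_variants(v, fx$models, fx$contigs)
  for (i in seq_len(nrow(v))) {
    expect_equal(rec$category[rec$pos == v$pos[i]],
                 oracle_coding_effect(fx$models[1, ], fx$contigs$seq[[1]],
                                      v$pos[i], v$alt[i]),
                 info = paste("pos", v$pos[i]))
  }
  flipped <- flip_study(fx$contigs, fx$models, v)
  rec2 <- annotate_variants(flipped$variants, flipped$models, flipped$contigs)
  for (i in seq_len(nrow(v))) {
    p2 <- flipped$variants$pos[i]
    expect_equal(rec2$category[rec2$pos == p2],
                 oracle_coding_effect(flipped$models[1, ],
                                      flipped$contigs$seq[[1]],
                                      p2, flipped$variants$alt[i]),
                 info = paste("flipped pos", p2))
  }
})

test_that("a variant in two flanks yields two records and the summary picks the nearest gene", {
  fx <- annot_fixture()
  m2 <- gene_model("gy", "chrT", "+",
                   exons = tibble::tibble(start = 5001, end = 5400),
                   cds = tibble::tibble(start = 5101, end = 5400))
  models <- dplyr::bind_rows(fx$models, m2)
  chars <- strsplit(fx$contigs$seq[[1]], "")[[1]]
  v <- make_variants("chrT", 4000L, chars[4000], "A",
                     matrix("0/1", 1, 1, dimnames = list(NULL, "s1")))
  rec <- annotate_variants(v, models, fx$contigs)
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$gene_id, c("gx", "gy"))
  expect_equal(sort(rec$category), c("downstream", "upstream"))
  smry <- summarize_consequences(rec)
  expect_equal(smry$gene_id, "gy")   # 1001 bp away vs 1600 bp
})

test_that("the per-variant summary equals a brute-force severity maximisation", {
  sim <- get_sim(1)
  res <- get_pipeline(1)
  rec <- res$consequences
  smry <- summarize_consequences(rec)
  key <- paste(rec$contig, rec$pos, rec$ref, rec$alt)
  for (k in unique(key)[seq_len(200)]) {   # spot-check a block of variants
    rows <- rec[key == k, ]
    sev <- match(rows$category, consequence_categories)
    best <- rows[order(sev, rows$distance,
                       ifelse(is.na(rows$gene_id), "~", rows$gene_id)), ][1, ]
    got <- smry[paste(smry$contig, smry$pos, smry$ref, smry$alt) == k, ]
    expect_equal(got$category, best$category)
    expect_equal(got$gene_id, best$gene_id)
  }
})

test_that("impact mapping and category tallies behave structurally", {
  expect_equal(impact_of(c("splice_acceptor", "splice_donor", "start_lost",
                           "stop_gained")),
               rep("HIGH", 4))
  expect_equal(impact_of("missense"), "MODERATE")
  expect_equal(impact_of(c("synonymous", "start_gained", "stop_lost")),
               rep("LOW", 3))
  expect_equal(impact_of("upstream"), "MODIFIER")
  expect_error(impact_of("frameshift"), "unknown")
  # custom map overrides the default grading
  custom <- default_impact_map()
  custom["stop_lost"] <- "HIGH"
  expect_equal(impact_of("stop_lost", custom), "HIGH")

  rec <- tibble::tibble(category = c(rep("upstream", 3), rep("missense", 2)))
  tl <- tally_by_category(rec)
  expect_equal(tl$n[tl$category == "upstream"], 3L)
  expect_equal(tl$n[tl$category == "missense"], 2L)
  expect_equal(sum(tl$n), 5L)
})

test_that("planted consequence categories are recovered exactly from the VCF", {
  sim <- get_sim(1)
  res <- get_pipeline(1)
  truth <- sim$truth$group_snps
  joined <- dplyr::inner_join(
    truth, res$consequences,
    by = c("contig", "pos", "ref", "alt", "gene_id"),
    suffix = c("_truth", "_got"))
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$category_got, joined$category_truth)
})
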