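group_fixture <- function(seed = 1, n_var = 40) {
  set.seed(seed)
  acc <- sprintf("s%02d", 1:12)
  meta <- tibble::tibble(
    accession = acc,
    heat_class = c("HT", "HT", "T", "T", "T", "MT", "MT",
                   "S", "S", "S", "HS", "HS"))
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n_var * 12, TRUE,
                      prob = c(0.55, 0.2, 0.1, 0.15)),
               n_var, 12, dimnames = list(NULL, acc))
  # force a few HT-exclusive rows
  for (i in 1:6) {
    gt[i, ] <- "0/0"
    gt[i, c("s01", "s02")] <- c("1/1", "0/1")
  }
  v <- make_variants("c", seq_len(n_var) * 10, "A", "G", gt)
  cats <- sample(c("missense", "upstream", "intronic", "intergenic",
                   "synonymous", "downstream"), n_var, TRUE)
  rec <- tibble::tibble(
    contig = "c", pos = v$pos, ref = "A", alt = "G",
    gene_id = ifelse(cats == "intergenic", NA_character_,
                     sample(sprintf("g%02d", 1:8), n_var, TRUE)),
    category = cats,
    impact = impact_of(cats),
    distance = ifelse(cats %in% c("upstream", "downstream"),
                      sample(100:1900, n_var, TRUE), 0L))
  list(variants = v, records = rec, meta = meta)
}

test_that("group specificity selects exclusive alleles in scope", {
  acc <- c("h1", "h2", "t1", "s1")
  meta <- tibble::tibble(accession = acc,
                         heat_class = c("HT", "HT", "T", "S"))
  gt <- rbind(c("1/1", "1/1", "0/0", "0/0"),   # HT-exclusive
              c("1/1", "0/1", "0/0", "0/1"),   # alt also in a susceptible
              c("1/1", "1/1", "./.", "0/0"))   # missing outside does not block
  colnames(gt) <- acc
  v <- make_variants("c", c(10, 20, 30), "A", "G", gt)
  rec <- tibble::tibble(contig = "c", pos = c(10L, 20L, 30L),
                        ref = "A", alt = "G",
                        gene_id = "g1", category = "missense",
                        impact = "MODERATE", distance = 0L)
  res <- select_group_specific(v, rec, meta, target_classes = "HT")
  expect_equal(res$variants$pos, c(10L, 30L))
  # a missing metadata row is a hard error, not a silent exclusion
  expect_error(select_group_specific(v, rec, meta[-1, ], "HT"),
               "metadata missing")
})

test_that("selection matches the exhaustive predicate oracle", {
  for (s in 1:4) {
    fx <- group_fixture(seed = 40 + s)
    res <- select_group_specific(fx$variants, fx$records, fx$meta, "HT")
    expect_setequal(variant_key(res$variants),
                    oracle_group_specific_keys(fx$variants, fx$records,
                                               fx$meta, "HT"))
  }
})

test_that("out-of-scope variants are never selected", {
  fx <- group_fixture(seed = 77)
  res <- select_group_specific(fx$variants, fx$records, fx$meta, "HT")
  sel_keys <- variant_key(res$variants)
  rec_keys <- variant_key(fx$records)
  for (k in sel_keys) {
    cats <- fx$records$category[rec_keys == k]
    expect_true(any(cats != "intergenic"), info = k)
  }
  # high-impact scope is a subset of the genic screen
  hi <- select_group_specific(fx$variants, fx$records, fx$meta, "HT",
                              scope = "high_impact")
  expect_true(all(variant_key(hi$variants) %in% sel_keys))
})

test_that("widening the target group keeps HT-exclusive alleles selected", {
  # when every HT carrier set is unchanged, {HT} selection is nested in
  # {HT,T,MT}: verified against the oracle on each fixture
  for (s in 1:4) {
    fx <- group_fixture(seed = 90 + s)
    k_ht <- oracle_group_specific_keys(fx$variants, fx$records, fx$meta, "HT")
    k_res <- oracle_group_specific_keys(fx$variants, fx$records, fx$meta,
                                        c("HT", "T", "MT"))
    got_ht <- variant_key(
      select_group_specific(fx$variants, fx$records, fx$meta, "HT")$variants)
    got_res <- variant_key(
      select_group_specific(fx$variants, fx$records, fx$meta,
                            c("HT", "T", "MT"))$variants)
    expect_setequal(got_ht, k_ht)
    expect_setequal(got_res, k_res)
    expect_true(all(k_ht %in% k_res))
  }
})

test_that("tally table counts variant-gene records and totals add up", {
  rec <- tibble::tibble(
    contig = "c", pos = c(1L, 1L, 2L, 3L, 4L, 5L),
    ref = "A", alt = "G",
    gene_id = c("g1", "g2", "g1", "g3", "g1", "g2"),
    category = c("upstream", "downstream", "missense", "missense",
                 "upstream", "upstream"),
    impact = NA_character_, distance = 0L)
  tl <- tally_table(rec)
  expect_equal(tl$n[tl$category == "missense"], 2L)
  expect_equal(tl$n[tl$category == "upstream"], 3L)
  expect_equal(tl$n[tl$category == "total"], 6L)   # variant-gene unit
  expect_equal(attr(tl, "n_unique_variants"), 5L)  # per-variant unit
  expect_equal(sum(tl$n[tl$category != "total"]),
               tl$n[tl$category == "total"])

  empty <- tally_table(rec[0, ])
  expect_true(all(empty$n == 0L))
})

test_that("planted group SNPs are recovered exactly with per-gene indexing", {
  sim <- get_sim(1)
  res <- get_pipeline(1)
  gs <- res$group_snps
  expect_setequal(variant_key(gs$variants),
                  variant_key(sim$truth$group_snps))
  expect_setequal(gs$per_gene$gene_id, unique(sim$truth$group_snps$gene_id))
  # non-reference flag follows the contig class
  nonref <- gs$per_gene$gene_id[!gs$per_gene$is_reference]
  truth_nonref <- unique(sim$truth$group_snps$gene_id[
    !sim$truth$group_snps$contig %in% sim$truth$reference_contigs])
  expect_setequal(nonref, truth_nonref)
  gl <- glance(gs)
  expect_equal(gl$n_variants, nrow(sim$truth$group_snps))
})
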