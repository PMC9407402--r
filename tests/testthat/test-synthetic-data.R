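test_that("coverage_track realises the requested covered fraction exactly", {
  m <- gene_model("g", "c", "+",
                  exons = tibble::tibble(start = c(1001, 2001),
                                         end = c(1500, 2500)))  # 1000 bp body
  cov <- coverage_track(m, 0.85, depth = 5)
  expect_equal(sum(cov$end - cov$start + 1), 850)
  expect_true(all(cov$depth >= 5))
  expect_equal(nrow(coverage_track(m, 0)), 0L)        # all-zero track
  full <- coverage_track(m, 1)
  expect_equal(sum(full$end - full$start + 1), 1000)  # uniformly covered
  # 0.8 covers exactly 800 bases, which the strict > criterion calls absent
  expect_false(call_presence(m, coverage_track(m, 0.8)))
  expect_true(call_presence(m, coverage_track(m, 0.85)))
})

test_that("simulation is deterministic and writes every advertised file", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 7, group_sizes = c(HT = 2, T = 2, MT = 1, S = 2,
                                              HS = 1),
                    n_low_depth = 1, n_core_genes = 40, n_variable_genes = 10,
                    n_background_snps = 200, n_multiallelic = 4,
                    n_planted_up = 4, n_planted_down = 3,
                    n_planted_contra = 1, n_de_only = 4)
  s1 <- simulate_panheat(cfg, d1)
  s2 <- simulate_panheat(cfg, d2)
  for (p in c("genome.fa", "genes.gff3", "meta.tsv", "deg.tsv",
              "markers.tsv", "truth/expected_candidates.tsv")) {
    expect_true(file.exists(file.path(d1, p)), info = p)
    expect_identical(readLines(file.path(d1, p)),
                     readLines(file.path(d2, p)), info = p)
  }
  for (a in s1$truth$meta$accession) {
    p <- file.path("coverage", paste0("cov_", a, ".tsv"))
    expect_identical(readLines(file.path(d1, p)), readLines(file.path(d2, p)))
  }
  # VCF is gzipped; compare decompressed records
  v1 <- read_vcf(s1$paths$vcf)
  v2 <- read_vcf(s2$paths$vcf)
  expect_identical(v1, v2)
  expect_identical(s1$truth, s2$truth)
})

test_that("core genes are present everywhere and variable genes absent somewhere", {
  sim <- get_sim(1)
  pres <- sim$truth$presence
  m <- as.matrix(as.data.frame(pres[-1]))
  cls <- classify_genes(pres)
  expect_equal(sum(cls$class == "core"), 40L)
  expect_equal(sum(cls$class == "variable"), 10L)
  expect_true(all(rowSums(m) >= 1))   # every gene somewhere in the panel
})

test_that("background SNPs never satisfy the group-specificity predicate", {
  sim <- get_sim(1)
  variants <- read_vcf(sim$paths$vcf)
  meta <- sim$truth$meta
  ht <- meta$accession[meta$heat_class == "HT"]
  planted_keys <- variant_key(sim$truth$group_snps)
  bg <- variants[!variant_key(variants) %in% planted_keys, ]
  samples <- vcf_samples(bg)
  exclusive <- vapply(seq_len(nrow(bg)), function(i) {
    g <- unlist(bg[i, samples], use.names = FALSE)
    carriers <- samples[panheat:::gt_has_alt(g)]
    length(carriers) > 0 && all(carriers %in% ht)
  }, logical(1))
  expect_false(any(exclusive))
})

test_that("planted group-specific SNPs survive the variant filters", {
  sim <- get_sim(1)
  variants <- read_vcf(sim$paths$vcf)
  kept <- filter_variants(variants)
  expect_true(all(variant_key(sim$truth$group_snps) %in% variant_key(kept)))
  # and the filter had actual work to do
  log <- attr(kept, "removal_log")
  expect_true(any(grepl("MAF", log$reason)))
  expect_true(any(grepl("missing", log$reason)))
  expect_true(any(grepl("biallelic", log$reason)))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(group_sizes = c(HT = 1, T = 2, S = 2)),
               "highly tolerant")
  expect_error(sim_config(variable_presence_prob = 1.2), "presence_prob")
  expect_error(sim_config(planted_group_snps = c(frameshift = 1)),
               "cannot plant")
  expect_error(sim_config(flank = 4000), "gene_slot_bp")
})
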