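test_that("presence calling applies the strict >80% coverage rule", {
  m <- gene_model("g", "c", "+",
                  exons = tibble::tibble(start = 1, end = 1000))
  cov_n <- function(n, depth = 5) {
    tibble::tibble(contig = "c", start = 1L, end = as.integer(n),
                   depth = depth)
  }
  expect_true(call_presence(m, cov_n(850)))      # 850/1000 covered
  expect_false(call_presence(m, cov_n(800)))     # exactly 80%: absent
  expect_true(call_presence(m, cov_n(801)))
  expect_false(call_presence(m, cov_n(1000, depth = 4)))  # below min_cov
  expect_false(call_presence(m, cov_n(0)[0, ]))  # all-zero coverage
})

test_that("build_matrix excludes low-depth accessions and recovers the truth", {
  sim <- get_sim(1)
  cov_files <- list.files(file.path(sim$dir, "coverage"), full.names = TRUE)
  coverages <- setNames(lapply(cov_files, read_coverage),
                        sub("^cov_(.*)\\.tsv$", "\\1", basename(cov_files)))
  expect_message(
    presence <- build_matrix(sim$models, coverages, sim$truth$meta),
    "excluding")
  excl <- attr(presence, "excluded")
  expect_equal(sort(excl$accession),
               sort(setdiff(sim$truth$meta$accession,
                            sim$truth$retained_accessions)))
  expect_true(all(excl$depth <= 10))
  expect_setequal(names(presence),
                  c("gene_id", sim$truth$retained_accessions))
  truth <- sim$truth$presence[names(presence)]
  expect_equal(as.data.frame(presence), as.data.frame(truth),
               ignore_attr = TRUE)
})

test_that("classify_genes partitions into core and variable, with private genes", {
  p <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      a = c(TRUE, TRUE, TRUE),
                      b = c(TRUE, FALSE, FALSE),
                      c = c(TRUE, TRUE, FALSE))
  cls <- classify_genes(p)
  expect_equal(cls$class, c("core", "variable", "variable"))
  expect_equal(cls$private, c(FALSE, FALSE, TRUE))
  # partition property on random matrices
  for (s in 1:5) {
    pr <- random_presence(20, 6, seed = s)
    cl <- classify_genes(pr)
    expect_equal(sum(cl$class == "core") + sum(cl$class == "variable"), 20L)
    expect_true(all(cl$private[cl$class == "private"] %in% TRUE))
  }
})

test_that("group-unique genes match a brute-force set comparison", {
  meta <- tibble::tibble(accession = sprintf("a%02d", 1:8),
                         heat_class = c("HT", "HT", "T", "MT",
                                        "S", "S", "HS", "HS"))
  for (s in 1:10) {
    pr <- random_presence(6, 8, seed = 100 + s, p = 0.5)
    got <- group_unique_genes(pr, meta, group = c("HT", "T", "MT"))
    m <- as.matrix(as.data.frame(pr[-1]))
    grp <- meta$accession[meta$heat_class %in% c("HT", "T", "MT")]
    expected <- pr$gene_id[vapply(seq_len(6), function(i) {
      any(m[i, grp]) && !any(m[i, setdiff(colnames(m), grp)])
    }, logical(1))]
    expect_setequal(got$gene_id, expected)
  }
  # a core gene can never be group-unique
  pr_all <- random_presence(5, 8, seed = 3, p = 1)
  expect_equal(nrow(group_unique_genes(pr_all, meta, "HT")), 0L)
  expect_error(group_unique_genes(pr_all, meta, character()), "at least one")
})

test_that("Jaccard similarities match direct set counting", {
  p <- tibble::tibble(gene_id = paste0("g", 1:4),
                      a = c(TRUE, TRUE, TRUE, FALSE),   # {g1,g2,g3}
                      b = c(FALSE, TRUE, TRUE, TRUE),   # {g2,g3,g4}
                      c = c(TRUE, TRUE, TRUE, FALSE),   # identical to a
                      d = c(FALSE, FALSE, FALSE, FALSE))
  j <- jaccard_matrix(p)
  expect_equal(j["a", "b"], 0.5)       # 2 shared / 4 in union
  expect_equal(j["a", "c"], 1)         # identical profiles
  expect_equal(j["a", "d"], 0)         # empty accession vs non-empty
  expect_equal(j["d", "d"], 1)
  expect_equal(j, t(j))
  expect_true(all(j >= 0 & j <= 1))
  expect_equal(pav_distance(p), 1 - j)
  # disjoint presence sets
  p2 <- tibble::tibble(gene_id = paste0("g", 1:4),
                       x = c(TRUE, TRUE, FALSE, FALSE),
                       y = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(jaccard_matrix(p2)["x", "y"], 0)
})
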