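test_that("rpkm matches its definition and rejects degenerate inputs", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 2000, 5e6), 0)
  expect_equal(rpkm(250, 2500, 5e6), 20)  # 250 / 2.5 / 5
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 1000, 0), "library")
  expect_error(rpkm(-1, 1000, 1e6), "non-negative")
})

test_that("fold change handles pseudocounts and zero denominators", {
  expect_equal(fold_change(10, 10, 0), 1)
  expect_equal(fold_change(3, 2, 0), 1.5)
  expect_equal(fold_change(0, 0, 0.01), 1)
  expect_error(fold_change(5, 0, 0), "pseudocount")
})

test_that("classification respects the printed boundary conventions", {
  # low-read rule fires first, needs both counts under the floor
  expect_equal(classify_target(3.0, 4, 7), "low_read_excluded")
  expect_equal(classify_target(3.0, 4, 70), "increased")
  # > 1.5 strict, <= 0.5 inclusive
  expect_equal(classify_target(1.5, 50, 80), "unchanged")
  expect_equal(classify_target(1.5 + 1e-9, 50, 80), "increased")
  expect_equal(classify_target(0.5, 50, 30), "repressed")
  expect_equal(classify_target(0.5 + 1e-9, 50, 30), "unchanged")
  # read floor is strict: 10 reads is enough
  expect_equal(classify_target(2, 10, 10), "increased")
  expect_equal(classify_target(2, 9, 9), "low_read_excluded")
})

test_that("filter_scope = increased_only read-filters only the increased set", {
  fold <- c(0.3, 1.0, 2.0)
  lab <- classify_target(fold, c(4, 4, 4), c(4, 4, 4),
                         filter_scope = "increased_only")
  expect_equal(lab, c("repressed", "unchanged", "low_read_excluded"))
  lab_all <- classify_target(fold, c(4, 4, 4), c(4, 4, 4))
  expect_equal(lab_all, rep("low_read_excluded", 3))
})

test_that("class labels partition the gene universe", {
  set.seed(3)
  n <- 500
  counts <- data.frame(gene = sprintf("g%03d", 1:n),
                       count_vector = rpois(n, 40),
                       count_mir155 = rpois(n, 40),
                       exon_length_bp = sample(500:3000, n, TRUE))
  rec <- quantify_expression(counts, pseudocount = 0.5)
  expect_equal(nrow(rec), n)
  expect_true(all(rec$class_label %in%
                  c("repressed", "increased", "unchanged", "low_read_excluded")))
  expect_equal(sum(table(rec$class_label)), n)
})

test_that("fold changes are invariant to a common scaling of counts and libraries", {
  set.seed(9)
  counts <- data.frame(gene = letters[1:10],
                       count_vector = rpois(10, 200) + 1,
                       count_mir155 = rpois(10, 300) + 1,
                       exon_length_bp = sample(800:2000, 10))
  libs <- c(vector = 2e6, mir155 = 3e6)
  base <- quantify_expression(counts, library_sizes = libs)
  scaled <- counts
  scaled$count_vector <- scaled$count_vector * 7
  scaled$count_mir155 <- scaled$count_mir155 * 7
  res <- quantify_expression(scaled, library_sizes = libs * 7)
  expect_equal(res$fold_change, base$fold_change)
})

test_that("class transition unchanged -> increased sits exactly at the upper bound", {
  flip <- function(f) classify_target(f, 100, 100) == "increased"
  lo <- 1; hi <- 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (flip(mid)) hi <- mid else lo <- mid
  }
  expect_equal(hi, 1.5, tolerance = 1e-12)
})

test_that("fold histogram bins right-open, sums to the selection, validates edges", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    fold_change = c(0.2, 0.8, 1.2, 2.0))
  h <- fold_histogram(rec, c(0, 1, 2, 3))
  expect_equal(h$n_genes, c(2L, 1L, 1L))  # frozen from the [a,b) convention
  expect_equal(sum(h$n_genes), nrow(rec))
  # highest edge is inclusive
  expect_equal(fold_histogram(data.frame(gene = "x", fold_change = 3),
                              c(0, 1, 2, 3))$n_genes, c(0L, 0L, 1L))
  expect_equal(fold_histogram(rec[0, ], c(0, 1, 2))$n_genes, c(0L, 0L))
  expect_equal(fold_histogram(data.frame(gene = "x", fold_change = 1),
                              c(0, 5))$n_genes, 1L)
  expect_error(fold_histogram(rec, c(1, 0, 2)), "increasing")
  expect_error(fold_histogram(rec, c(0.5, 1)), "range")
})

test_that("fold histogram filters genes by seed-site class", {
  rec <- data.frame(gene = c("a", "b", "c"),
                    fold_change = c(0.4, 1.2, 2.5))
  sc <- data.frame(gene = c("a", "b", "c"),
                   n_7mer = c(1L, 0L, 0L), n_8mer = c(0L, 1L, 0L))
  edges <- c(0, 1, 3)
  expect_equal(sum(fold_histogram(rec, edges, sc, "any")$n_genes), 2L)
  expect_equal(sum(fold_histogram(rec, edges, sc, "8mer")$n_genes), 1L)
  expect_equal(sum(fold_histogram(rec, edges, sc, "7mer")$n_genes), 1L)
  expect_error(fold_histogram(rec, edges, seed_filter = "8mer"), "site_counts")
})

test_that("isoform-level counts sum to gene level before quantification", {
  counts <- data.frame(gene = c("g1", "g1", "g2"),
                       isoform = c("g1.1", "g1.2", "g2.1"),
                       count_vector = c(30L, 20L, 100L),
                       count_mir155 = c(60L, 40L, 100L),
                       exon_length_bp = c(1000L, 1500L, 1200L))
  rec <- quantify_expression(counts, library_sizes = c(vector = 1e6, mir155 = 1e6))
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$count_vector[rec$gene == "g1"], 50)
  expect_equal(rec$fold_change[rec$gene == "g1"], 2)
})
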