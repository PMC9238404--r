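# Data model, file round-trips, normalization, genus pooling, and the
# shared statistics primitives.

test_that("count table construction validates counts and metadata", {
  t <- make_tiny_counts()
  expect_s3_class(t, "count_table")
  expect_equal(dim(t$counts), c(4, 3))

  bad <- matrix(c(-1L, 2L, 3L, 4L), 2, 2,
                dimnames = list(c("a", "b"), c("x", "y")))
  meta <- data.frame(sample_id = c("a", "b"), experiment_id = "e",
                     surface_type = "desk", owner = "P01", timepoint = "post")
  expect_error(count_table(bad, meta), "negative count")
  expect_error(count_table(abs(bad) + 0.5, meta), "non-integer")
  expect_error(count_table(abs(bad), meta[1, ]), "missing from metadata.*b")
})

test_that("unknown surface types map to other_public with a warning", {
  counts <- matrix(1L, 1, 1, dimnames = list("a", "x"))
  meta <- data.frame(sample_id = "a", experiment_id = "e",
                     surface_type = "window_sill", owner = "public",
                     timepoint = "post")
  expect_warning(t <- count_table(counts, meta), "other_public")
  expect_equal(t$meta$surface_type, "other_public")
})

test_that("count table TSV round-trip is bit-identical", {
  t <- make_tiny_counts()
  cpath <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(t, cpath, mpath)
  t2 <- read_count_table(cpath, mpath)
  expect_identical(t2$counts, t$counts)
  expect_identical(t2$meta$surface_type, t$meta$surface_type)

  # 2x2 identity case
  m2 <- matrix(c(5L, 0L, 1L, 3L), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("x", "y")))
  meta2 <- data.frame(sample_id = c("a", "b"), experiment_id = "e",
                      surface_type = "desk", owner = "P01",
                      timepoint = "post")
  write_count_table(count_table(m2, meta2), cpath, mpath)
  expect_identical(read_count_table(cpath, mpath)$counts, m2)
})

test_that("relative abundance normalizes rows and drops zero-sum samples", {
  t <- make_tiny_counts()
  a <- relative_abundance(t)
  expect_equal(unname(rowSums(a$values)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(a$values["s2", ]), c(0.25, 0.75, 0))

  counts <- matrix(c(2L, 2L, 0L, 0L), 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("x", "y")))
  meta <- data.frame(sample_id = c("a", "b"), experiment_id = "e",
                     surface_type = "desk", owner = "P01",
                     timepoint = "post")
  expect_warning(a2 <- relative_abundance(count_table(counts, meta)),
                 "zero-sum")
  expect_equal(nrow(a2$values), 1)
  expect_equal(unname(a2$values[1, ]), c(0.5, 0.5))

  zero <- matrix(0L, 1, 2, dimnames = list("a", c("x", "y")))
  expect_error(relative_abundance(count_table(zero, meta[1, ])),
               "empty table")
  # idempotent on already-normalized rows
  expect_equal(relative_abundance(a$values)$values, a$values)
})

test_that("genus pooling sums same-genus ASVs and keeps the invader apart", {
  vals <- matrix(c(0.2, 0.3, 0.4, 0.1,
                   0.1, 0.1, 0.5, 0.3), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), paste0("asv", 1:4)))
  a <- abundance_table(vals)
  tax <- taxonomy_map(paste0("asv", 1:4),
                      genus = c("G", "G", "H", "Lactobacillus"),
                      species = c("unassigned", "unassigned", "unassigned",
                                  "Lb_invader"),
                      invader = c(FALSE, FALSE, FALSE, TRUE))
  g <- collapse_to_genus(a, tax)
  expect_setequal(colnames(g$values), c("G", "H", "Lb_invader"))
  expect_equal(unname(g$values["a", "G"]), 0.5)
  expect_equal(unname(g$values["a", "Lb_invader"]), 0.1)

  # unassigned removal triggers re-normalization
  tax2 <- taxonomy_map(paste0("asv", 1:4),
                       genus = c("G", "unassigned", "H", "unassigned"),
                       species = rep("unassigned", 4),
                       invader = rep(FALSE, 4))
  g2 <- collapse_to_genus(a, tax2)
  expect_false("unassigned" %in% colnames(g2$values))
  expect_equal(rowSums(g2$values), c(a = 1, b = 1))
  expect_equal(unname(g2$values["a", "G"]), 0.2 / 0.6)

  tax3 <- taxonomy_map(paste0("asv", 1:4), genus = rep("unassigned", 4),
                       species = rep("unassigned", 4), invader = rep(FALSE, 4))
  expect_error(collapse_to_genus(a, tax3), "no genera")
})

test_that("top_taxa ranks by mean abundance with deterministic ties", {
  vals <- matrix(c(0.5, 0.3, 0.2,
                   0.5, 0.3, 0.2), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("A", "B", "C")))
  a <- abundance_table(vals)
  expect_equal(top_taxa(a, 2), c("A", "B"))
  # tie broken lexicographically
  tied <- abundance_table(matrix(c(0.5, 0.5), 1,
                                 dimnames = list("a", c("B", "A"))))
  expect_equal(top_taxa(tied, 1), "A")
  # invader appended when outside top k
  expect_equal(top_taxa(a, 2, include = "C"), c("A", "B", "C"))
  expect_warning(res <- top_taxa(a, 5), "exceeds")
  expect_length(res, 3)
})

test_that("bray_curtis matches hand values and the brute-force oracle", {
  m <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0),
             c = c(0, 0, 1), d = c(1, 0, 0))
  d <- bray_curtis(m)
  expect_equal(unname(d["a", "b"]), 0)          # identical rows
  expect_equal(unname(d["a", "c"]), 1)          # disjoint support
  expect_equal(unname(d["a", "d"]), 0.5)        # 1 - sum(min)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))

  set.seed(7)
  for (i in 1:25) {
    x <- stats::runif(12); x <- x / sum(x)
    y <- stats::runif(12); y <- y / sum(y)
    d2 <- bray_curtis(rbind(x, y))
    expect_equal(d2[1, 2], oracle_bray(x, y), tolerance = 1e-12)
  }
  # cross-check against vegan's reference implementation
  set.seed(8)
  mm <- matrix(stats::runif(60), 5, 12)
  mm <- mm / rowSums(mm)
  expect_equal(unname(bray_curtis(mm)[lower.tri(diag(5))]),
               as.numeric(vegan::vegdist(mm, method = "bray")),
               tolerance = 1e-12)
  expect_error(bray_curtis(m[1, , drop = FALSE]), "at least 2")
})

test_that("bh_adjust reproduces the step-up rule and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:300) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("wilson_interval matches the closed form and its boundaries", {
  ci <- wilson_interval(0.5, 100, 0.95)
  expect_equal(unname(ci), c(0.4038315, 0.5961685), tolerance = 1e-6)
  expect_equal(unname(wilson_interval(0, 10)["lo"]), 0)
  expect_equal(unname(wilson_interval(1, 10)["hi"]), 1)
  expect_error(wilson_interval(0.5, 0), "n must be")
  ci2 <- wilson_interval(stats::runif(5), 30)
  expect_true(all(ci2[, "lo"] <= ci2[, "hi"]))
})

test_that("wilson_interval has ~95% coverage for a uniform proportion", {
  set.seed(3)
  n <- 200
  p <- stats::runif(10000)
  k <- stats::rbinom(10000, n, p)
  ci <- wilson_interval(k / n, n, 0.95)
  coverage <- mean(p >= ci[, "lo"] & p <= ci[, "hi"])
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

test_that("spearman_test agrees with cor.test's rho and handles degeneracy", {
  set.seed(5)
  for (i in 1:20) {
    x <- stats::rnorm(30)
    y <- stats::rnorm(30)
    res <- spearman_test(x, y)
    expect_equal(res$rho,
                 unname(stats::cor.test(x, y, method = "spearman")$estimate),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_test(c(1, 1, 1), c(1, 2, 3))$rho))
  expect_true(is.na(spearman_test(c(1, 2), c(3, 4))$rho))
  expect_equal(spearman_test(1:6, 6:1)$rho, -1)
  expect_equal(spearman_test(1:6, 6:1)$p, 0)
})

test_that("dunn_test matches the textbook Kruskal-Wallis statistic", {
  set.seed(9)
  x <- c(stats::rnorm(10, 0), stats::rnorm(12, 1), stats::rnorm(9, 2))
  g <- rep(c("a", "b", "c"), c(10, 12, 9))
  res <- dunn_test(x, g)
  expect_equal(unname(res$kruskal$statistic), oracle_kruskal_h(x, g),
               tolerance = 1e-10)
  expect_equal(nrow(res$pairs), 3)
  expect_true(all(res$pairs$p_adj >= res$pairs$p))
  # strongly separated groups give significant adjacent comparisons
  y <- c(rep(10, 8) + stats::runif(8, 0, 0.1),
         rep(5, 8) + stats::runif(8, 0, 0.1),
         rep(1, 8) + stats::runif(8, 0, 0.1))
  res2 <- dunn_test(y, rep(c("a", "b", "c"), each = 8))
  expect_true(all(res2$pairs$p_adj < 0.05))
})
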