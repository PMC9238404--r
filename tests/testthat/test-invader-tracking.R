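# Invader quantification, carrier ranking, proximity statistics,
# eigencentrality correlation, and the homogenization test.

inv_tax <- function() {
  taxonomy_map(c("a1", "a2", "a3", "i1", "i2"),
               genus = c("G", "G", "H", "Lactobacillus", "Lactobacillus"),
               species = c(rep("unassigned", 3), "Lb", "Lb"),
               invader = c(FALSE, FALSE, FALSE, TRUE, TRUE))
}

test_that("invader abundance sums the invader ASVs and stays in [0, 1]", {
  vals <- rbind(s1 = c(0.4, 0.3, 0.15, 0.1, 0.05),
                s2 = c(0.5, 0.5, 0, 0, 0))
  colnames(vals) <- c("a1", "a2", "a3", "i1", "i2")
  a <- abundance_table(vals)
  prof <- invader_abundance(a, inv_tax())
  expect_equal(unname(prof), c(0.15, 0))
  expect_true(all(prof >= 0 & prof <= 1))
  tax0 <- taxonomy_map("a1", "G", "unassigned", FALSE)
  expect_error(invader_abundance(a, tax0), "empty invader")
})

rank_fixture <- function(perm = NULL) {
  owners <- rep(c("P01", "P02", "P03"), each = 3)
  prof <- c(0.5, 0.4, 0.3,   # P01 surfaces: clear carrier
            0.05, 0.04, 0.03,
            0.01, 0.01, 0.02)
  ids <- paste0("s", 1:9)
  names(prof) <- ids
  meta <- data.frame(sample_id = ids, experiment_id = "e",
                     surface_type = rep(c("hand", "desk", "cup"), 3),
                     owner = owners, timepoint = "post",
                     stringsAsFactors = FALSE)
  if (!is.null(perm)) {
    prof <- prof[perm]
  }
  list(prof = prof, meta = meta)
}

test_that("participants rank by mean invader abundance over owned surfaces", {
  fx <- rank_fixture()
  rk <- rank_participants(fx$prof, fx$meta)
  expect_equal(rk$ranking$participant[1], "P01")
  expect_equal(rk$ranking$mean_abundance[1], mean(c(0.5, 0.4, 0.3)))
  expect_equal(rk$ranking$band, 0.2 * rk$ranking$sd_abundance)
  # rank curves are non-increasing
  for (cv in rk$curves) expect_true(all(diff(cv) <= 0))
  # permutation invariance of sample order
  perm <- sample(9)
  rk2 <- rank_participants(fx$prof[perm], fx$meta)
  expect_equal(rk$ranking, rk2$ranking)
})

test_that("degenerate equal contamination is flagged as tied", {
  prof <- stats::setNames(rep(0.1, 4), paste0("s", 1:4))
  meta <- data.frame(sample_id = paste0("s", 1:4), experiment_id = "e",
                     surface_type = "desk",
                     owner = rep(c("P02", "P01"), each = 2),
                     timepoint = "post", stringsAsFactors = FALSE)
  rk <- rank_participants(prof, meta)
  expect_equal(rk$ranking$participant, c("P01", "P02"))  # id tie-break
  expect_true(all(rk$ranking$tied))
})

prox_fixture <- function(means = c(0.3, 0.1, 0.01), sd = 0.005, n = 15,
                         seed = 61) {
  set.seed(seed)
  surf <- paste0("s", seq_len(3 * n))
  prof <- stats::setNames(
    pmax(0, stats::rnorm(3 * n, rep(means, each = n), sd)), surf)
  meta <- data.frame(sample_id = surf, experiment_id = "e",
                     surface_type = "desk",
                     owner = rep(paste0("P", 2:7), length.out = 3 * n),
                     timepoint = "post", surface_id = surf,
                     stringsAsFactors = FALSE)
  dist <- stats::setNames(rep(c(1, 2, 3), each = n), surf)
  list(prof = prof, meta = meta, dist = dist)
}

test_that("proximity effect detects decreasing contamination with distance", {
  fx <- prox_fixture()
  res <- proximity_effect(fx$prof, fx$dist, fx$meta, carrier = "P01")
  expect_equal(res$buckets$bucket, c("1", "2", ">=3"))
  expect_true(all(diff(res$buckets$mean) < 0))
  adj <- res$dunn
  d12 <- adj$p_adj[adj$group1 == "1" & adj$group2 == "2"]
  d23 <- adj$p_adj[adj$group1 == "2" & adj$group2 == ">=3"]
  expect_lt(d12, 0.05)
  expect_lt(d23, 0.05)
  expect_lt(res$kruskal$p.value, 0.001)
})

test_that("proximity analysis excludes carrier and public surfaces", {
  fx <- prox_fixture()
  fx$meta$owner[1:5] <- "P01"    # carrier-owned, must drop
  res <- proximity_effect(fx$prof, fx$dist, fx$meta, carrier = "P01")
  expect_equal(sum(res$buckets$n), 40)
  one_bucket <- prox_fixture()
  one_bucket$dist[] <- 1
  expect_error(proximity_effect(one_bucket$prof, one_bucket$dist,
                                one_bucket$meta, carrier = "P01"),
               "fewer than 2")
})

ec_fixture <- function() {
  surf <- paste0("d", 1:10)
  log <- data.frame(
    time_s = 1:40,
    surface_u = rep("P01_hand", 40),
    surface_v = c(rep("d1", 6), rep(surf[-1], length.out = 34)),
    stringsAsFactors = FALSE)
  other <- data.frame(
    time_s = 41:140,
    surface_u = rep(paste0("P", 2:6, "_hand"), each = 20),
    surface_v = rep(surf, 10), stringsAsFactors = FALSE)
  net <- build_stn(rbind(log, other))
  meta <- data.frame(sample_id = surf, experiment_id = "e",
                     surface_type = "desk",
                     owner = rep(paste0("P", 2:6), 2),
                     timepoint = "post", surface_id = surf,
                     stringsAsFactors = FALSE)
  list(net = net, meta = meta, surf = surf)
}

test_that("eigencentrality correlation applies the stated exclusions", {
  fx <- ec_fixture()
  ec <- eigencentrality(fx$net)
  prof <- stats::setNames(seq(0.01, 0.1, length.out = 10), fx$surf)
  res <- eigencentrality_correlation(prof, ec, fx$meta, fx$net, "P01",
                                     max_carrier_touches = 5)
  # d1 was touched 6 times by the carrier's hand and must be excluded
  expect_false("d1" %in% res$surface_id)
  expect_equal(res$n, 9)
  # perfectly monotone association
  prof2 <- stats::setNames(rank(ec[fx$surf]) / 100, fx$surf)
  res2 <- eigencentrality_correlation(prof2, ec, fx$meta, fx$net, "P01")
  expect_equal(res2$rho, 1)
  # constant centrality is degenerate
  ec3 <- stats::setNames(rep(0.5, 10), fx$surf)
  res3 <- eigencentrality_correlation(prof, ec3, fx$meta, fx$net, "P01")
  expect_true(is.na(res3$rho))
})

test_that("homogenization test detects paired decreases in dissimilarity", {
  pairs <- c("P1|P2", "P1|P3", "P2|P3", "P1|P4", "P2|P4", "P3|P4")
  pre <- stats::setNames(c(0.8, 0.7, 0.75, 0.72, 0.68, 0.8), pairs)
  same <- homogenization_test(pre, pre)
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")

  post <- pre - 0.2
  res <- homogenization_test(pre, post)
  expect_equal(res$direction, "homogenized")
  expect_lt(res$p_value, 0.05)

  post_up <- pre + 0.2
  res2 <- homogenization_test(pre, post_up)
  expect_equal(res2$direction, "diversified")

  expect_error(homogenization_test(pre, post[-1]), "do not match")
  expect_error(homogenization_test(unname(pre), unname(post)), "named")
})

test_that("hand dissimilarities exclude the invader and pair by owner", {
  sim <- generate_office(office_config(n_participants = 5, n_asvs = 40,
                                       seq_depth = 3000), seed = 3)
  d <- hand_dissimilarity(sim$counts_post, sim$taxonomy, "post")
  expect_length(d, choose(5, 2))
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(grepl("^P[0-9]+\\|P[0-9]+$", names(d))))
  d_pre <- hand_dissimilarity(sim$counts_pre, sim$taxonomy, "pre")
  expect_setequal(names(d_pre), names(d))
})

test_that("touching homogenizes hands; no touching does not", {
  p_touch <- p_none <- numeric(0)
  for (s in 1:8) {
    active <- generate_office(office_config(n_participants = 10,
                                            n_asvs = 60, seq_depth = 8000),
                              seed = s)
    still_cfg <- office_config(n_participants = 10, n_asvs = 60,
                               seq_depth = 8000, touch_rate_own = 0,
                               touch_rate_public = 0, touch_rate_social = 0)
    still <- generate_office(still_cfg, seed = s)
    for (sim in list(active, still)) {
      pre <- hand_dissimilarity(sim$counts_pre, sim$taxonomy, "pre")
      post <- hand_dissimilarity(sim$counts_post, sim$taxonomy, "post")
      shared <- intersect(names(pre), names(post))
      h <- homogenization_test(pre[shared], post[shared])
      p <- if (h$direction == "homogenized") h$p_value else 1
      if (identical(sim, active)) p_touch[s] <- p else p_none[s] <- p
    }
  }
  expect_gte(mean(p_touch < 0.05), 0.75)
  expect_lte(mean(p_none < 0.05), 0.25)
})
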