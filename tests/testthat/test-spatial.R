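test_that("pairwise distance summary separates same- and cross-label pairs", {
  # two A events 100 um apart; one B event 300 um from each
  ev <- data.frame(x = c(0, 100, 50, 50),
                   y = c(0, 0, sqrt(300^2 - 50^2), -sqrt(300^2 - 50^2)),
                   z = 0, label = c("A", "A", "B", "B"))
  res <- pairwise_distance_summary(ev, "A", radius = 500)
  expect_equal(res$same$mean, 100)
  expect_equal(res$cross$mean, 300)
  expect_equal(res$same$n_pairs, 1)
  expect_equal(res$cross$n_pairs, 4)
  expect_true(is.na(res$p))  # a single same-label pair supports no t-test
  # all one label -> cross side empty
  ev1 <- data.frame(x = c(0, 10, 20), y = 0, z = 0, label = "A")
  expect_error(pairwise_distance_summary(ev1, "A"), "cross-label")
  # radius truncates
  far <- rbind(ev, data.frame(x = 5000, y = 0, z = 0, label = "B"))
  res2 <- pairwise_distance_summary(far, "A", radius = 500)
  expect_equal(res2$cross$n_pairs, 4)
  # planar mode ignores the rostrocaudal coordinate
  ev_z <- ev; ev_z$z <- c(0, 4000, 8000, 12000)
  res3 <- pairwise_distance_summary(ev_z, "A", radius = 500, planar = TRUE)
  expect_equal(res3$same$mean, 100)
  expect_equal(res3$cross$mean, 300)
})

test_that("spatially segregated labels have shorter same-label distances", {
  set.seed(33)
  a <- simulate_csr(80, cuboid(c(0, 200), c(0, 200), c(0, 200)))
  b <- simulate_csr(80, cuboid(c(300, 500), c(0, 200), c(0, 200)))
  ev <- data.frame(rbind(a, b), label = rep(c("A", "B"), each = 80))
  res <- pairwise_distance_summary(ev, "A", radius = 500)
  expect_lt(res$same$mean, res$cross$mean)
  expect_lt(res$p, 0.001)
})

test_that("kNN origin proportions match brute-force enumeration", {
  # collinear: A(0), A(10), B(20), B(30), B(40), B(50), B(60); k = 5
  ev <- data.frame(x = c(0, 10, 20, 30, 40, 50, 60), y = 0, z = 0,
                   label = c("A", "A", rep("B", 5)))
  pr <- knn_origin_proportions(ev, k = 5)
  expect_equal(pr["A", "A"], 0.2)   # each A seed: 1 A + 4 B neighbors
  expect_equal(pr["A", "B"], 0.8)
  # all same label
  ev2 <- data.frame(x = 1:6, y = 0, z = 0, label = "A")
  expect_equal(unname(knn_origin_proportions(ev2, k = 5)["A", "A"]), 1)
  expect_error(knn_origin_proportions(ev2[1:5, ], k = 5), "k \\+ 1")
  # well-separated clusters: own-label proportion 1
  set.seed(1)
  a <- simulate_csr(30, cuboid(c(0, 100), c(0, 100), c(0, 100)))
  b <- simulate_csr(30, cuboid(c(5000, 5100), c(0, 100), c(0, 100)))
  ev3 <- data.frame(rbind(a, b), label = rep(c("A", "B"), each = 30))
  pr3 <- knn_origin_proportions(ev3, k = 5)
  expect_equal(unname(pr3["A", "A"]), 1)
  expect_equal(unname(pr3["B", "B"]), 1)
  # proportions sum to one per seed label; input order irrelevant
  expect_true(all(abs(rowSums(pr3) - 1) < 1e-9))
  shuf <- ev3[sample(nrow(ev3)), ]
  expect_equal(knn_origin_proportions(shuf, k = 5), pr3,
               ignore_attr = "counts")
})

test_that("two-sample t-test handles edge cases and both variants", {
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  sep <- two_sample_ttest(c(1, 2, 3), c(11, 12, 13))
  expect_lt(sep$p, 0.01)
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "zero variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "n >= 2")
  pooled <- two_sample_ttest(c(1, 2, 3, 9), c(2, 4, 6), "pooled")
  welch <- two_sample_ttest(c(1, 2, 3, 9), c(2, 4, 6), "welch")
  expect_equal(pooled$df, 5)
  expect_false(isTRUE(all.equal(pooled$df, welch$df)))
})

test_that("stripe enrichment tests against the area expectation", {
  map <- stripe_map(stripe_entry("CrusI", c(0, 100, 200), "AldoC+"))
  # all terminals AldoC+ with expected share 0.5 -> tiny p
  t_all <- data.frame(origin = "S1", lobule = "CrusI",
                      x = runif(100, 0, 99), z = 0)
  res <- stripe_enrichment(t_all, map)
  expect_lt(res$p, 1e-6)
  expect_equal(res$observed_share, 1)
  expect_equal(res$expected_share, 0.5)
  # uniform placement: observed share within 3 binomial se of expected
  set.seed(5)
  t_unif <- data.frame(origin = "S1", lobule = "CrusI",
                       x = runif(2000, 0, 200), z = 0)
  res2 <- stripe_enrichment(t_unif, map)
  expect_lt(abs(res2$observed_share - 0.5), 3 * sqrt(0.25 / 2000))
  # single stripe covering everything: degenerate, flagged, no p
  map1 <- stripe_map(stripe_entry("CrusI", c(0, 200), "AldoC+"))
  res3 <- stripe_enrichment(t_all, map1)
  expect_equal(res3$flag, "degenerate_expectation")
  expect_true(is.na(res3$p))
  # unmapped lobule flagged and excluded from testing
  t_pm <- data.frame(origin = "S1", lobule = "PM", x = 1, z = 0)
  res4 <- stripe_enrichment(t_pm, map)
  expect_equal(res4$flag, "unmapped_lobule")
})
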