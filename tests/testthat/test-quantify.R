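test_that("injection volume follows V = pi a b h", {
  expect_lt(abs(injection_volume(0.2, 0.4, 0.5) - pi * 0.04), 1e-5)
  expect_equal(injection_volume(0.4, 0.4, 0.5),
               2 * injection_volume(0.2, 0.4, 0.5))  # linearity
  expect_error(injection_volume(0.2, 0, 0.5), "positive")
  expect_error(injection_volume(-1, 1, 1), "positive")
})

test_that("terminal counting is an exact multiset count", {
  empty <- count_terminals(data.frame(animal = character(0),
                                      origin = character(0),
                                      side = character(0),
                                      lobule = character(0)))
  expect_equal(nrow(empty), 0)
  pts <- make_points(data.frame(animal = "a1", origin = "M1",
                                side = "contralateral", lobule = "CrusI",
                                n = 3))
  cm <- count_terminals(pts)
  expect_equal(cm$n, 3L)
  expect_equal(sum(cm$n), nrow(pts))
  # generator allocation is reproduced exactly
  st <- simulate_study(small_config(), 2, seed = 8)
  cm <- count_terminals(st$terminals)
  expect_equal(sum(cm$n), nrow(st$terminals))
  # row-order permutation invariance
  shuf <- st$terminals[sample(nrow(st$terminals)), ]
  expect_equal(count_terminals(shuf), cm)
  # invalid labels are rejected with row numbers
  bad <- st$terminals; bad$side[5] <- "left"
  expect_error(count_terminals(bad), "rows: 5")
})

test_that("percentage tables sum to 100 within each row scope", {
  pts <- rbind(
    make_points(data.frame(animal = "a1", origin = "S1",
                           side = "ipsilateral", lobule = "CrusI", n = 30)),
    make_points(data.frame(animal = "a1", origin = "S1",
                           side = "contralateral", lobule = "CrusI", n = 70)))
  cm <- count_terminals(pts)
  p <- side_percentages(cm, "side")
  expect_equal(sort(p$per_animal$pct), c(30, 70))
  # one lobule only: that lobule 100, all others 0
  pl <- side_percentages(cm, "lobule")
  expect_equal(pl$per_animal$pct[pl$per_animal$category == "CrusI"], 100)
  expect_equal(sum(pl$per_animal$pct), 100)
  # property: simulated study, all levels, both normalizations
  st <- simulate_study(small_config(), 3, seed = 4)
  cm <- count_terminals(st$terminals)
  for (lv in c("side", "division", "lobule")) {
    pa <- side_percentages(cm, lv)$per_animal
    sums <- tapply(pa$pct, paste(pa$animal, pa$origin), sum)
    expect_true(all(abs(sums - 100) < 1e-9))
  }
  ps <- side_percentages(cm, "lobule", normalization = "per_side")$per_animal
  sums <- tapply(ps$pct, paste(ps$animal, ps$origin, ps$side), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(side_percentages(count_terminals(
    data.frame(animal = character(0), origin = character(0),
               side = character(0), lobule = character(0))), "side"),
    "empty")
})

test_that("pooled percentage split reproduces the retrograde worked example", {
  split <- percent_of_total(c(pontine = 6429, `extra-pontine` = 2378))
  expect_equal(round(unname(split)), c(73, 27))
  expect_equal(sum(split), 100)
  cells <- data.frame(animal = c("a", "a", "b"),
                      category = c("pontine", "extra-pontine", "pontine"),
                      n_cells = c(4000, 2378, 2429))
  expect_equal(cell_category_split(cells),
               percent_of_total(c(pontine = 6429, `extra-pontine` = 2378)))
  expect_error(percent_of_total(c(0, 0)), "positive total")
})

test_that("density divides by half the lobule volume and round-trips", {
  pts <- make_points(data.frame(animal = "a1", origin = "S1",
                                side = "contralateral", lobule = "Cop",
                                n = 100))
  d <- terminal_density(count_terminals(pts))
  expect_equal(d$density_mm3, 100)  # 100 / (2 * 0.5)
  # doubling N doubles D
  d2 <- terminal_density(count_terminals(rbind(pts, pts)))
  expect_equal(d2$density_mm3, 200)
  # round trip D * V/2 = N over a full study
  st <- simulate_study(small_config(), 2, seed = 14)
  atl <- st$atlas
  dd <- terminal_density(count_terminals(st$terminals), atl)
  expect_equal(dd$density_mm3 * atlas_volume(atl, dd$lobule) * 0.5,
               as.numeric(dd$n))
  expect_error(terminal_density(structure(
    data.frame(animal = "a", origin = "M1", side = "ipsilateral",
               lobule = "Zed", n = 1L),
    class = c("count_matrix", "data.frame"))), "unknown lobule")
})

test_that("laterality ratios and the group contrast behave", {
  pts <- rbind(
    make_points(data.frame(animal = "a1", origin = "M1",
                           side = "ipsilateral", lobule = "CrusI", n = 50)),
    make_points(data.frame(animal = "a1", origin = "M1",
                           side = "contralateral", lobule = "CrusI", n = 50)))
  lr <- laterality_ratio(count_terminals(pts))
  expect_equal(lr$per_animal$ratio, 1)
  # zero contralateral -> undefined
  ipsi_only <- make_points(data.frame(animal = "a1", origin = "M1",
                                      side = "ipsilateral",
                                      lobule = "CrusI", n = 10))
  expect_error(laterality_ratio(count_terminals(ipsi_only)),
               "contralateral")
  # group recovery from generator ground truth (primary contra 0.74 vs
  # association 0.58 => ratios 0.35 vs 0.72)
  st <- simulate_study(small_config(), 3, seed = 31)
  lr <- laterality_ratio(count_terminals(st$terminals))
  prim <- lr$by_group[lr$by_group$group == "primary", ]
  assoc <- lr$by_group[lr$by_group$group == "association", ]
  expect_lt(abs(prim$mean_ratio - 0.26 / 0.74), 3 * prim$sem_ratio + 0.05)
  expect_lt(abs(assoc$mean_ratio - 0.42 / 0.58), 3 * assoc$sem_ratio + 0.05)
  expect_true(is.finite(lr$test$p))
})

test_that("symmetry score is 1 for mirrored patterns, negative for reversed", {
  spec <- expand.grid(animal = "a1", origin = "M1",
                      side = c("ipsilateral", "contralateral"),
                      lobule = c("CrusI", "CrusII", "PM", "Sim"),
                      stringsAsFactors = FALSE)
  spec$n <- rep(c(40, 30, 20, 10), each = 2)
  sym <- symmetry_score(count_terminals(make_points(spec)))
  expect_equal(sym$symmetry, 1)
  # reversed high/low blocks across sides -> negative
  spec$n <- c(40, 5, 40, 5, 5, 40, 5, 40)
  sym <- symmetry_score(count_terminals(make_points(spec)))
  expect_lt(sym$symmetry, 0)
  # mirror-symmetric generator scores high at n = 1e3 per side
  cfg <- simulation_config(
    n_terminals = c(M1 = 2000, S1 = 2000, PPC = 2000, V1 = 2000,
                    A1 = 2000, AuD = 2000),
    contra_fraction = c(M1 = 0.5, S1 = 0.5, PPC = 0.5, V1 = 0.5,
                        A1 = 0.5, AuD = 0.5),
    concentration = Inf)
  st <- simulate_study(cfg, 1, seed = 2)
  sym <- symmetry_score(count_terminals(st$terminals))
  expect_true(all(sym$symmetry > 0.9))
})

test_that("pearson correlation matches hand computation and cor.test", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  pc <- pearson_cor(x, c(2, 1, 4, 3))
  expect_equal(pc$r, 0.6)   # hand product-moment: 3 / sqrt(5 * 5)
  ct <- cor.test(x, c(2, 1, 4, 3))
  expect_equal(pc$p, ct$p.value)
  expect_equal(pc$r, unname(ct$estimate))
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("mossy-fibers-per-cell ratio respects scope", {
  cells <- data.frame(animal = rep(c("a1", "a2"), each = 2),
                      category = rep(c("pontine", "extra-pontine"), 2),
                      n_cells = c(4, 6, 3, 7))
  expect_equal(mf_per_cell(500, cells, "all")$ratio, 25)
  expect_gt(mf_per_cell(500, cells, "pontine_only")$ratio,
            mf_per_cell(500, cells, "all")$ratio)
  per <- mf_per_cell(c(a1 = 500, a2 = 500), cells, "all")
  expect_equal(unname(per$per_animal), c(50, 50))
  expect_equal(per$mean, 50)
  expect_error(mf_per_cell(500, cells[cells$category == "none", ], "all"),
               "no cells")
})

test_that("cross-animal consistency flags outlier animals", {
  # low animal-to-animal variability: same-config animals correlate highly
  st <- simulate_study(small_config(concentration = 300), 3, seed = 6)
  cc <- cross_animal_consistency(count_terminals(st$terminals),
                                 threshold = 0.5)
  expect_true(all(cc$pairs$r[cc$pairs$origin %in% c("M1", "S1")] > 0.8))
  # identical frequency vectors -> r = 1
  pts <- rbind(
    make_points(data.frame(animal = "a1", origin = "M1",
                           side = "contralateral",
                           lobule = c("CrusI", "PM", "VI"), n = c(5, 3, 2))),
    make_points(data.frame(animal = "a2", origin = "M1",
                           side = "contralateral",
                           lobule = c("CrusI", "PM", "VI"),
                           n = c(10, 6, 4))))
  cc <- cross_animal_consistency(count_terminals(pts))
  expect_equal(cc$pairs$r, 1)
  # an animal from a very different profile gets flagged
  pts2 <- rbind(pts, make_points(data.frame(
    animal = "a3", origin = "M1", side = "contralateral",
    lobule = c("Fl", "X", "I"), n = c(10, 6, 4))))
  cc2 <- cross_animal_consistency(count_terminals(pts2), threshold = 0.5)
  expect_true(any(cc2$pairs$flagged))
})
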