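# Counts are built through count_terminals so the classifier sees the
# same container the pipeline produces.
coin_counts <- function(alloc) {
  # alloc: named list side -> lobule -> origin -> n
  rows <- list()
  for (sd_ in names(alloc)) for (lb in names(alloc[[sd_]]))
    for (org in names(alloc[[sd_]][[lb]]))
      rows[[length(rows) + 1L]] <- data.frame(
        animal = "a1", origin = org, side = sd_, lobule = lb,
        n = alloc[[sd_]][[lb]][[org]])
  count_terminals(make_points(do.call(rbind, rows)))
}

test_that("two-threshold rule reproduces hand-computed labels", {
  # one side; CrusI: dominant 60/25/15 -> high (S = 40 > 15);
  # Cop: 96/2/2 -> moderate (S = 4 < 15, two minor origins);
  # Sim: 2% of side total -> excluded
  cts <- coin_counts(list(contralateral = list(
    CrusI = c(M1 = 600, S1 = 250, PPC = 150),
    Cop = c(S1 = 960, M1 = 20, PPC = 20),
    Sim = c(M1 = 41))))
  # side total 2041; Sim share 2% < 4%
  cl <- classify_coinnervation(cts)
  lab <- setNames(cl$label, cl$lobule)
  expect_equal(lab[["CrusI"]], "high")
  expect_equal(lab[["Cop"]], "moderate")
  expect_equal(lab[["Sim"]], "excluded")
  expect_equal(cl$reason[cl$lobule == "Sim"], "below_floor")
  expect_equal(cl$dominant_origin[cl$lobule == "Cop"], "S1")
  expect_equal(cl$nondominant_share[cl$lobule == "Cop"], 4)
})

test_that("single-origin input yields no moderate or high lobules", {
  cts <- coin_counts(list(contralateral = list(
    CrusI = c(M1 = 900), PM = c(M1 = 100))))
  cl <- classify_coinnervation(cts)
  expect_false(any(cl$label %in% c("moderate", "high")))
  expect_true("too_few_origins" %in% cl$reason)
})

test_that("uniform six-origin mixing makes every above-floor lobule high", {
  alloc <- list(contralateral = list())
  for (lb in c("CrusI", "CrusII", "PM", "Sim"))
    alloc$contralateral[[lb]] <-
      setNames(rep(100, 6), c("M1", "S1", "PPC", "V1", "A1", "AuD"))
  cl <- classify_coinnervation(coin_counts(alloc))
  expect_true(all(cl$label == "high"))  # S ~ 83% everywhere, shares 25% > 4%
})

test_that("threshold monotonicity and scale invariance hold", {
  st <- simulate_study(small_config(), 3, seed = 17)
  cts <- count_terminals(st$terminals)
  base <- classify_coinnervation(cts, multimodal_threshold = 15)
  up <- classify_coinnervation(cts, multimodal_threshold = 30)
  # raising the threshold never promotes moderate -> high
  expect_true(all(!(base$label == "moderate" & up$label == "high")))
  expect_true(all(up$label != "high" | base$label == "high"))
  # raising the floor never adds lobules to the classified set
  floor_up <- classify_coinnervation(cts, input_floor = 8)
  classified <- function(x) paste(x$lobule, x$side)[x$label != "excluded"]
  expect_true(all(classified(floor_up) %in% classified(base)))
  # uniform count rescaling leaves labels unchanged
  st10 <- st$terminals[rep(seq_len(nrow(st$terminals)), 3), ]
  scaled <- classify_coinnervation(count_terminals(st10))
  expect_equal(scaled$label, base$label)
})

test_that("strict inequalities and tie handling are deterministic", {
  # lobule share exactly 4% -> excluded (strict >)
  cts <- coin_counts(list(contralateral = list(
    CrusI = c(M1 = 480, S1 = 480), Cop = c(M1 = 20, S1 = 20))))
  cl <- classify_coinnervation(cts)
  expect_equal(cl$label[cl$lobule == "Cop"], "excluded")
  # S exactly 15 -> moderate (strict >): dominant 85, minors 10 + 5
  cts2 <- coin_counts(list(contralateral = list(
    CrusI = c(M1 = 850, S1 = 100, PPC = 50),
    PM = c(M1 = 500, S1 = 400, PPC = 100))))
  cl2 <- classify_coinnervation(cts2)
  expect_equal(cl2$label[cl2$lobule == "CrusI"], "moderate")
  # dominant tie broken lexicographically and flagged
  expect_true(cl$tie[cl$lobule == "CrusI"])
  expect_equal(cl$dominant_origin[cl$lobule == "CrusI"], "M1")
})

test_that("the 'each origin above threshold' reading is available", {
  cts <- coin_counts(list(contralateral = list(
    CrusI = c(M1 = 600, S1 = 250, PPC = 150),   # minors 25% and 15%
    PM = c(M1 = 500, S1 = 300, PPC = 200))))    # minors 30% and 20%
  comb <- classify_coinnervation(cts, share_mode = "combined")
  each <- classify_coinnervation(cts, share_mode = "each")
  expect_equal(comb$label[comb$lobule == "CrusI"], "high")   # S = 40
  expect_equal(each$label[each$lobule == "CrusI"], "moderate") # 15 not > 15
  expect_equal(each$label[each$lobule == "PM"], "high")
})

test_that("report partitions lobule-sides by label", {
  st <- simulate_study(small_config(), 2, seed = 9)
  cl <- classify_coinnervation(count_terminals(st$terminals))
  rep_ <- coinnervation_report(cl)
  expect_setequal(names(rep_), c("high", "moderate", "excluded"))
  expect_equal(sum(vapply(rep_, nrow, 1L)), nrow(cl))
})
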