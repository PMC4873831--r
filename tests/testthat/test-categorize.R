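test_that("detection filter keeps genes present in one full group", {
  means <- list(parentA = c(8, 3, 8), parentB = c(3, 3, 8),
                mix = c(6, 3, 8), polyploid = list(S5 = c(6, 3, 8)))
  ds <- make_dataset(means, sd = 0)
  filt <- suppressMessages(detection_filter(ds, threshold = 5))
  # g002 below threshold everywhere -> removed; g001 present only in
  # parentA -> retained; g003 present everywhere -> retained
  expect_equal(filt$dataset$gene_ids, c("g001", "g003"))
  expect_equal(filt$removed, "g002")
})

test_that("detection filter removes exactly the planted-absent genes", {
  set.seed(21)
  n <- 100
  absent <- sample(n, 30)
  mu <- rep(9, n); mu[absent] <- 2
  means <- list(parentA = mu, parentB = mu, mix = mu,
                polyploid = list(S5 = mu))
  ds <- make_dataset(means, sd = 0.3, seed = 22)
  filt <- suppressMessages(detection_filter(ds, threshold = 5))
  expect_equal(length(filt$dataset$gene_ids), 70L)
  expect_setequal(filt$removed, sprintf("g%03d", sort(absent)))
})

test_that("computed MPV is the linear-scale parental average", {
  means <- list(parentA = c(7, 3), parentB = c(7, 5), mix = c(7, 4.32),
                polyploid = list(S5 = c(7, 4.32)))
  ds <- make_dataset(means, sd = 0)
  mpv <- compute_mpv(ds, mode = "computed")
  expect_equal(unname(mpv$mpv[1]), 7)
  expect_equal(unname(mpv$mpv[2]), log2((2^3 + 2^5) / 2), tolerance = 1e-12)
  expect_equal(unname(mpv$mpv[2]), log2(20), tolerance = 1e-12)

  mm <- compute_mpv(ds, mode = "measured_mix")
  mix_ids <- ds$samples$sample_id[ds$samples$role == "mix"]
  expect_identical(colnames(mm$values), mix_ids)

  no_mix <- subset_dataset(ds, roles = c("parentA", "parentB"))
  expect_error(compute_mpv(no_mix, mode = "measured_mix"), "mix")
})

test_that("parental classification recovers planted divergence", {
  set.seed(23)
  n <- 60
  lfc <- c(rep(0, 30), rep(2, 15), rep(-2, 15))
  base <- runif(n, 6, 10)
  means <- list(parentA = base + lfc / 2, parentB = base - lfc / 2,
                mix = base, polyploid = list(S5 = base))
  ds <- make_dataset(means, sd = 0.2, seed = 24)
  res <- classify_parental(ds, "leaf")
  expect_equal(res$parental_status, c(rep("PEC", 30), rep("PED", 30)))
  expect_equal(res$ped_direction[31:45], rep("A_higher", 15))
  expect_equal(res$ped_direction[46:60], rep("B_higher", 15))

  # identical parents -> all PEC
  ds0 <- make_dataset(list(parentA = base, parentB = base, mix = base,
                           polyploid = list(S5 = base)), sd = 0.2, seed = 25)
  expect_true(all(classify_parental(ds0, "leaf")$parental_status == "PEC"))
})

test_that("the pattern decision tree recovers a constructed expression space", {
  # genes laid out to hit every branch; parents 2 log2 units apart for
  # the PED genes, polyploid at the planted position, low noise
  base <- rep(8, 7)
  lfc <- c(0, 0, 2, 2, 2, 2, 0)
  a <- base + lfc / 2; b <- base - lfc / 2
  mix <- log2((2^a + 2^b) / 2)
  poly <- c(8,            # PEC at parents -> constant
            11,           # PEC above both -> over_tre
            mix[3],       # PED at mix -> additive
            a[4],         # PED at higher parent -> eld_high_parentA
            b[5],         # PED at lower parent -> eld_low_parentB
            12,           # PED above both -> over_tre
            5)            # PEC below both -> under_tre
  ds <- make_dataset(list(parentA = a, parentB = b, mix = mix,
                          polyploid = list(S5 = poly)), sd = 0.1, seed = 26)
  calls <- classify_pattern(ds, "leaf", "S5")
  expect_equal(calls$pattern,
               c("constant", "over_tre", "additive", "eld_high_parentA",
                 "eld_low_parentB", "over_tre", "under_tre"))
  expect_equal(calls$additivity,
               ifelse(calls$pattern %in% c("constant", "additive"),
                      "additive", "nonadditive"))
  expect_error(classify_pattern(ds, "leaf", "S9"), "S9")
})

test_that("identical groups give constant additive calls", {
  base <- rep(7, 5)
  ds <- make_dataset(list(parentA = base, parentB = base, mix = base,
                          polyploid = list(S5 = base)), sd = 0)
  calls <- suppressWarnings(classify_pattern(ds, "leaf", "S5"))
  expect_true(all(calls$pattern == "constant"))
  expect_true(all(calls$additivity == "additive"))
})

test_that("every gene gets exactly one pattern and PEC never yields ELD", {
  for (seed in c(31, 32, 33)) {
    cfg <- small_sim_config(n_genes = 120, seed = seed)
    sim <- simulate_expression(cfg)
    calls <- classify_pattern(sim$dataset, "leaf", "S5")
    expect_equal(nrow(calls), length(sim$dataset$gene_ids))
    expect_true(all(calls$pattern %in% c(
      "constant", "additive", "eld_high_parentA", "eld_high_parentB",
      "eld_low_parentA", "eld_low_parentB", "over_tre", "under_tre",
      "ambiguous")))
    pec <- calls[calls$parental_status == "PEC", ]
    expect_false(any(grepl("^eld_", pec$pattern)))
    expect_true(all((calls$additivity == "additive") ==
                      (calls$pattern %in% c("constant", "additive"))))
  }
})

test_that("raising alpha never moves a gene from nonadditive to additive", {
  cfg <- small_sim_config(n_genes = 150, seed = 35)
  sim <- simulate_expression(cfg)
  calls_strict <- classify_pattern(sim$dataset, "leaf", "S5", alpha = 0.01)
  calls_loose <- classify_pattern(sim$dataset, "leaf", "S5", alpha = 0.10)
  was_nonadd <- calls_strict$additivity == "nonadditive"
  expect_true(all(calls_loose$additivity[was_nonadd] == "nonadditive"))
})

test_that("category summaries partition the classified genes", {
  cfg <- small_sim_config(n_genes = 100, seed = 37)
  sim <- simulate_expression(cfg)
  calls <- rbind(classify_pattern(sim$dataset, "leaf", "S5"),
                 classify_pattern(sim$dataset, "leaf", "S6"))
  summ <- summarize_categories(calls)
  for (g in c("S5", "S6")) {
    pc <- summ$pattern_counts[summ$pattern_counts$generation == g, ]
    expect_equal(sum(pc$n), 100L)
    expect_equal(sum(pc$proportion), 1)
    pa <- summ$parental_additivity[summ$parental_additivity$generation == g, ]
    expect_equal(sum(pa$n_additive + pa$n_nonadditive), 100L)
  }
  expect_true(all(summ$propensity_tests$p_value >= 0 &
                    summ$propensity_tests$p_value <= 1))
})

test_that("recovered category proportions track the planted mix", {
  cfg <- sim_config(n_genes = 1200, seed = 39, tissues = "leaf",
                    homeolog = list(n_genes = 10))
  sim <- simulate_expression(cfg)
  calls <- classify_pattern(sim$dataset, "leaf", "S5")
  sc <- score_pattern_recovery(calls, sim$truth)
  expect_gt(sc$recovery, 0.9)
  planted <- table(sim$truth$patterns$pattern[
    sim$truth$patterns$generation == "S5"]) / 1200
  got <- table(calls$pattern) / 1200
  add_planted <- sum(planted[c("additive", "constant")], na.rm = TRUE)
  add_got <- sum(got[c("additive", "constant")], na.rm = TRUE)
  expect_lt(abs(add_planted - add_got), 0.05)
})
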