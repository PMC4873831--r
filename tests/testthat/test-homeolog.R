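make_part_fixture <- function(mix_fracs, poly_fracs, additivity = "additive") {
  manifest <- make_manifest(c("mix", "polyploid"), n_reps = 3,
                            generations = "S5")
  h <- rbind(
    data.frame(gene_id = "g1",
               sample_id = manifest$sample_id[manifest$role == "mix"],
               a_fraction = mix_fracs),
    data.frame(gene_id = "g1",
               sample_id = manifest$sample_id[manifest$role == "polyploid"],
               a_fraction = poly_fracs))
  calls <- data.frame(gene_id = "g1", tissue = "leaf", generation = "S5",
                      parental_status = "PED", ped_direction = "A_higher",
                      additivity = additivity,
                      pattern = if (additivity == "additive") "additive"
                                else "over_tre",
                      mpv = 8, stringsAsFactors = FALSE)
  list(homeolog = homeolog_table(h), samples = manifest, calls = calls)
}

test_that("partitioning outcomes follow the calling rules", {
  # biased mix returning to 50:50 -> erasure
  fx <- make_part_fixture(c(0.74, 0.75, 0.76), c(0.49, 0.50, 0.51))
  pc <- call_partitioning(fx$homeolog, fx$samples, fx$calls, "leaf")
  expect_true(pc$altered)
  expect_equal(pc$outcome, "erasure")
  expect_true(pc$mix_biased)
  expect_false(pc$poly_biased)

  # balanced throughout -> stable
  fx <- make_part_fixture(c(0.50, 0.50, 0.50), c(0.50, 0.50, 0.50))
  pc <- call_partitioning(fx$homeolog, fx$samples, fx$calls, "leaf")
  expect_false(pc$altered)
  expect_equal(pc$outcome, "stable")

  # balanced mix gaining bias -> novel_bias, matching a direct Welch t
  fx <- make_part_fixture(c(0.49, 0.50, 0.51), c(0.69, 0.70, 0.71))
  pc <- call_partitioning(fx$homeolog, fx$samples, fx$calls, "leaf")
  oracle <- t.test(c(0.69, 0.70, 0.71), c(0.49, 0.50, 0.51))
  expect_equal(pc$p_altered, oracle$p.value, tolerance = 1e-12)
  expect_true(pc$altered)
  expect_equal(pc$outcome, "novel_bias")

  # bias retained in the same direction -> shifted_bias
  fx <- make_part_fixture(c(0.89, 0.90, 0.91), c(0.69, 0.70, 0.71))
  pc <- call_partitioning(fx$homeolog, fx$samples, fx$calls, "leaf")
  expect_equal(pc$outcome, "shifted_bias")
})

test_that("genes without category calls are skipped with a log record", {
  fx <- make_part_fixture(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  h2 <- rbind(as.data.frame(fx$homeolog),
              within(as.data.frame(fx$homeolog), gene_id <- "orphan"))
  expect_message(
    pc <- call_partitioning(homeolog_table(h2), fx$samples, fx$calls, "leaf"),
    "orphan")
  expect_equal(pc$gene_id, "g1")
})

test_that("A/B label swap mirrors bias calls and keeps altered status", {
  cfg <- sim_config(n_genes = 120, seed = 51, tissues = "leaf",
                    homeolog = list(n_genes = 120, n_natural = 0))
  sim <- simulate_expression(cfg)
  h <- simulate_homeolog(cfg, sim$truth, sim$dataset)
  calls <- classify_pattern(sim$dataset, "leaf", "S5")
  pc <- call_partitioning(h$homeolog, sim$dataset, calls, "leaf")
  flipped <- h$homeolog
  flipped$a_fraction <- 1 - flipped$a_fraction
  pc_f <- call_partitioning(homeolog_table(flipped), sim$dataset, calls,
                            "leaf")
  expect_equal(pc_f$altered, pc$altered)
  expect_equal(pc_f$p_altered, pc$p_altered, tolerance = 1e-9)
  expect_equal(pc_f$mix_biased, pc$mix_biased)
  expect_equal(pc_f$poly_biased, pc$poly_biased)
  expect_equal(pc_f$mix_mean_fraction, 1 - pc$mix_mean_fraction,
               tolerance = 1e-12)
  # stable stays stable; erasure/novel_bias swap roles only via direction,
  # not category
  expect_equal(pc_f$outcome, pc$outcome)
})

test_that("comparable-data-point tabulation counts and compares tissues", {
  fake <- data.frame(
    gene_id = sprintf("g%03d", 1:(159 + 208)),
    generation = "S5",
    tissue = c(rep("leaf", 159), rep("inflorescence", 208)),
    expression_class = "additive",
    altered = c(rep(TRUE, 46), rep(FALSE, 113), rep(TRUE, 126),
                rep(FALSE, 82)),
    outcome = "stable", mix_mean_fraction = 0.5, poly_mean_fraction = 0.5,
    p_altered = 0.5, mix_biased = FALSE, poly_biased = FALSE,
    stringsAsFactors = FALSE)
  tab <- tabulate_comparable(fake, "additive")
  expect_equal(tab$n_altered, 172L)
  expect_equal(tab$n_total, 367L)
  leaf <- tab$by_tissue[tab$by_tissue$tissue == "leaf", ]
  expect_equal(leaf$proportion, 46 / 159)
  expect_equal(round(100 * leaf$proportion, 1), 28.9)
  expect_lt(tab$tissue_comparison$p_value, 0.05)

  none <- tabulate_comparable(fake[fake$altered == FALSE, ][1:10, ],
                              "additive")
  expect_equal(none$proportion, 0)
  empty <- tabulate_comparable(fake, "nonadditive")
  expect_true(is.na(empty$proportion))
})

test_that("partitioning outcomes partition the comparable points", {
  cfg <- sim_config(n_genes = 150, seed = 53, tissues = "leaf",
                    homeolog = list(n_genes = 100, n_natural = 0))
  sim <- simulate_expression(cfg)
  h <- simulate_homeolog(cfg, sim$truth, sim$dataset)
  calls <- do.call(rbind, lapply(cfg$generations, function(g)
    classify_pattern(sim$dataset, "leaf", g)))
  pc <- call_partitioning(h$homeolog, sim$dataset, calls, "leaf")
  expect_true(all(pc$outcome %in% c("stable", "erasure", "novel_bias",
                                    "shifted_bias")))
  expect_true(all((pc$outcome == "stable") == (!pc$altered)))
  add <- tabulate_comparable(pc, "additive")
  nonadd <- tabulate_comparable(pc, "nonadditive")
  expect_equal(add$n_total + nonadd$n_total, nrow(pc))
  expect_equal(add$n_altered + nonadd$n_altered, sum(pc$altered))
})

test_that("dominance summary detects a planted natural A-shift", {
  cfg <- sim_config(n_genes = 200, seed = 55, tissues = "leaf",
                    homeolog = list(n_genes = 120, n_natural = 3,
                                    natural_shift = 0.08))
  sim <- simulate_expression(cfg)
  h <- simulate_homeolog(cfg, sim$truth, sim$dataset)
  dom <- summarize_dominance(h$homeolog, sim$dataset, tissue = "leaf")
  expect_equal(dom$n_a_biased + dom$n_b_biased + dom$n_unbiased, dom$n_genes)
  nat <- dom[dom$role == "natural", ]
  expect_equal(nrow(nat), 3L)
  expect_true(all(nat$shift_vs_mix > 0.05))
  expect_true(all(nat$p_shift < 0.01))
  mix_mean <- dom$mean_a_fraction[dom$genotype == "mix"]
  expect_true(all(nat$mean_a_fraction > mix_mean))
})

test_that("uniform 50:50 fractions give a null dominance summary", {
  manifest <- make_manifest(c("mix", "polyploid"), n_reps = 3,
                            generations = "S5")
  h <- homeolog_table(expand.grid(gene_id = paste0("g", 1:5),
                                  sample_id = manifest$sample_id,
                                  stringsAsFactors = FALSE) |>
                        transform(a_fraction = 0.5))
  dom <- summarize_dominance(h, manifest, tissue = "leaf")
  expect_true(all(dom$mean_a_fraction == 0.5))
  expect_true(all(dom$n_a_biased == 0 & dom$n_b_biased == 0))
  s5 <- dom[dom$genotype == "S5", ]
  expect_equal(s5$shift_vs_mix, 0)
  expect_equal(s5$p_shift, 1)
})
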