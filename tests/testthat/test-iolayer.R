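test_that("expression matrix and manifest round through validation", {
  dir <- withr::local_tempdir()
  manifest <- make_manifest(c("parentA", "parentB"), n_reps = 3)
  vals <- matrix(seq(5, 8.5, length.out = 18), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), manifest$sample_id))
  paths <- write_expr_fixture(dir, vals, manifest)
  ds <- read_expression(paths$matrix, paths$manifest)
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(dim(ds$values), c(3L, 6L))
  expect_equal(ds$gene_ids, c("g1", "g2", "g3"))
  expect_equal(ds$values, vals, tolerance = 1e-12)
})

test_that("sample mismatches are reported with the offending ids", {
  dir <- withr::local_tempdir()
  manifest <- make_manifest(c("parentA", "parentB"), n_reps = 3)
  vals <- matrix(6, nrow = 2, ncol = 6,
                 dimnames = list(c("g1", "g2"), manifest$sample_id))
  extra <- rbind(manifest,
                 data.frame(sample_id = "P1_r4", role = "parentA",
                            tissue = "leaf", generation = "", replicate = 4))
  paths <- write_expr_fixture(dir, vals, extra)
  expect_error(read_expression(paths$matrix, paths$manifest), "P1_r4")
})

test_that("gene rows with missing cells are dropped and logged", {
  dir <- withr::local_tempdir()
  manifest <- make_manifest(c("parentA", "parentB"), n_reps = 2)
  vals <- matrix(as.character(6:17), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), manifest$sample_id))
  vals["g2", 2] <- "NA"
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE)
  write.table(df, file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_message(
    ds <- read_expression(file.path(dir, "expr.tsv"),
                          file.path(dir, "manifest.tsv")),
    "g2")
  expect_equal(ds$gene_ids, c("g1", "g3"))
  expect_equal(nrow(ds$values), 2L)
})

test_that("malformed inputs raise targeted errors", {
  dir <- withr::local_tempdir()
  manifest <- make_manifest(c("parentA", "parentB"), n_reps = 2)
  vals <- matrix("6.5", nrow = 2, ncol = 4,
                 dimnames = list(c("g1", "g1"), manifest$sample_id))
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE)
  write.table(df, file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_expression(file.path(dir, "expr.tsv"),
                               file.path(dir, "manifest.tsv")),
               "duplicate gene_id")

  vals2 <- matrix(c("6.5", "oops", "7", "7", "7", "7", "7", "7"), nrow = 2,
                  dimnames = list(c("g1", "g2"), manifest$sample_id))
  df2 <- data.frame(gene_id = rownames(vals2), vals2, check.names = FALSE)
  write.table(df2, file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_expression(file.path(dir, "expr.tsv"),
                               file.path(dir, "manifest.tsv")),
               "oops")

  bad_manifest <- manifest
  bad_manifest$role[1] <- "stranger"
  write.table(bad_manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  vals3 <- matrix("6.5", nrow = 2, ncol = 4,
                  dimnames = list(c("g1", "g2"), manifest$sample_id))
  df3 <- data.frame(gene_id = rownames(vals3), vals3, check.names = FALSE)
  write.table(df3, file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_expression(file.path(dir, "expr.tsv"),
                               file.path(dir, "manifest.tsv")),
               "unknown role token")
})

test_that("homeolog fractions are scale-detected and validated", {
  dir <- withr::local_tempdir()
  write_h <- function(fracs) {
    path <- file.path(dir, "h.tsv")
    write.table(data.frame(gene_id = paste0("g", seq_along(fracs)),
                           sample_id = "AT2_S5_r1", a_fraction = fracs),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  expect_message(h <- read_homeolog(write_h(c(62.0, 45.5, 30.1))), "percent")
  expect_equal(h$a_fraction, c(0.62, 0.455, 0.301))

  h2 <- read_homeolog(write_h(c(0.62, 0.455)))
  expect_equal(h2$a_fraction, c(0.62, 0.455))

  expect_error(read_homeolog(write_h(c(101, 50))), "out of range")
  expect_error(read_homeolog(write_h(c(0.62, 62.0))), "ambiguous")
})

test_that("call tables round-trip exactly and deterministically", {
  set.seed(9)
  calls <- data.frame(
    gene_id = sprintf("g%02d", 10:1),
    tissue = rep(c("leaf", "inflorescence"), 5),
    generation = rep(c("S6", "S5"), each = 5),
    parental_status = sample(c("PEC", "PED"), 10, replace = TRUE),
    ped_direction = sample(c("none", "A_higher", "B_higher"), 10,
                           replace = TRUE),
    additivity = sample(c("additive", "nonadditive"), 10, replace = TRUE),
    pattern = sample(c("constant", "over_tre", "additive"), 10,
                     replace = TRUE),
    mpv = round(runif(10, 4, 12), 6),
    stringsAsFactors = FALSE)
  path1 <- withr::local_tempfile(fileext = ".tsv")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  sorted <- write_calls(calls, path1)
  back <- read_calls(path1)
  expect_equal(back, sorted, ignore_attr = TRUE)
  # re-reading and re-writing reproduces the bytes: determinism
  write_calls(back, path2)
  expect_identical(unname(tools::md5sum(path1)), unname(tools::md5sum(path2)))
  # sorted by tissue, generation, gene within tissue
  expect_equal(back$tissue, sort(back$tissue))

  empty <- calls[0, ]
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_calls(empty, path3)
  expect_equal(length(readLines(path3)), 1L)
  expect_equal(nrow(read_calls(path3)), 0L)
})
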