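# Fixture builders shared across the test files. Everything is built in
# code; nothing is read from disk except files the tests write first.

make_manifest <- function(roles, tissue = "leaf", n_reps = 3,
                          generations = "S5") {
  rows <- list()
  for (role in roles) {
    gens <- if (role %in% c("polyploid", "natural")) generations else ""
    for (g in gens) {
      for (r in seq_len(n_reps)) {
        prefix <- if (nzchar(g)) paste0(role, "_", g) else role
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(prefix, "_", tissue, "_r", r), role = role,
          tissue = tissue, generation = g, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Dataset with per-role (optionally per-generation) true means and
# optional replicate noise. `means` is a list: parentA/parentB/mix are
# vectors over genes; polyploid is a list keyed by generation.
make_dataset <- function(means, tissue = "leaf", n_reps = 3,
                         generations = "S5", sd = 0, seed = 42) {
  set.seed(seed)
  n <- length(means$parentA)
  gene_ids <- sprintf("g%03d", seq_len(n))
  manifest <- make_manifest(intersect(c("parentA", "parentB", "mix",
                                        "polyploid"), names(means)),
                            tissue = tissue, n_reps = n_reps,
                            generations = generations)
  vals <- sapply(seq_len(nrow(manifest)), function(k) {
    s <- manifest[k, ]
    mu <- if (s$role == "polyploid") means$polyploid[[s$generation]]
          else means[[s$role]]
    mu + if (sd > 0) rnorm(n, 0, sd) else 0
  })
  dimnames(vals) <- list(gene_ids, manifest$sample_id)
  expression_dataset(vals, manifest, gene_ids = gene_ids)
}

write_expr_fixture <- function(dir, values, manifest) {
  mpath <- file.path(dir, "expr.tsv")
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- file.path(dir, "manifest.tsv")
  write.table(manifest, spath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mpath, manifest = spath)
}

# Independent classical pooled-variance t-test, computed from textbook
# formulas (oracle for the moderated t with d0 = 0).
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Independent Benjamini-Yekutieli step-up (oracle for adjust_by).
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- p[o] * m * cm / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Independent continuity-corrected chi-square on the 2x2 table
# (oracle for prop_test); the correction is capped at |O - E| as in the
# conventional test.
oracle_yates_chisq <- function(x1, n1, x2, n2) {
  tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  yates <- min(0.5, abs(tab - E))
  chi <- sum((abs(tab - E) - yates)^2 / E)
  list(chi_sq = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
}

small_sim_config <- function(n_genes = 150, seed = 11, ...) {
  sim_config(n_genes = n_genes, seed = seed, tissues = "leaf",
             homeolog = list(n_genes = min(60, n_genes), n_natural = 2), ...)
}
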