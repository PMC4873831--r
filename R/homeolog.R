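# Homeolog expression partitioning: altered-partitioning calls per
# comparable data point, qualitative outcomes (stable / erasure /
# novel bias / shifted bias), and subgenome dominance summaries.

PARTITIONING_OUTCOMES <- c("stable", "erasure", "novel_bias", "shifted_bias")

resolve_samples <- function(samples) {
  if (inherits(samples, "ExpressionDataset")) samples <- samples$samples
  validate_manifest(samples)
}

#' Call homeolog partitioning changes per comparable data point
#'
#' A comparable data point is a gene x generation combination with a
#' total-expression category call and at least 2 replicate A-subgenome
#' fractions in both the polyploid generation and the parental 1:1 mix.
#' Partitioning is altered when a two-sample t-test of polyploid vs mix
#' fractions gives p below `alpha`; each group's bias is a one-sample t
#' against 0.5. Qualitative outcome: `stable` (unaltered), `erasure`
#' (altered, mix biased, polyploid not), `novel_bias` (altered, mix not
#' biased, polyploid biased), `shifted_bias` (altered with bias in both
#' or neither state, including reversals).
#'
#' @param homeolog A `HomeologTable` (see [read_homeolog()]).
#' @param samples Sample manifest data frame or an `ExpressionDataset`.
#' @param calls Gene-category calls from [classify_pattern()].
#' @param tissue Tissue to analyze.
#' @param alpha Raw p threshold (default 0.05).
#' @param var_equal Use pooled instead of Welch two-sample t.
#' @param adjust_bias If `TRUE`, Benjamini-Hochberg-adjust the bias
#'   p-values across genes within each group before calling bias.
#' @param transform `"none"` (default, raw fractions) or
#'   `"arcsine_sqrt"` to test transformed fractions.
#' @return Data frame of partitioning calls: `gene_id`, `generation`,
#'   `tissue`, `expression_class`, `altered`, `outcome`,
#'   `mix_mean_fraction`, `poly_mean_fraction`, `p_altered`,
#'   `mix_biased`, `poly_biased`.
#' @export
call_partitioning <- function(homeolog, samples, calls, tissue,
                              alpha = 0.05, var_equal = FALSE,
                              adjust_bias = FALSE,
                              transform = c("none", "arcsine_sqrt")) {
  transform <- match.arg(transform)
  samples <- resolve_samples(samples)
  h <- merge(as.data.frame(homeolog), samples, by = "sample_id")
  h <- h[h$tissue == tissue, , drop = FALSE]
  calls <- calls[calls$tissue == tissue, , drop = FALSE]
  tfun <- if (transform == "arcsine_sqrt") function(x) asin(sqrt(x)) else identity
  null_val <- tfun(0.5)

  mix <- h[h$role == "mix", , drop = FALSE]
  poly <- h[h$role == "polyploid", , drop = FALSE]
  skipped <- setdiff(unique(poly$gene_id), unique(calls$gene_id))
  if (length(skipped)) {
    message("call_partitioning: skipped ", length(skipped),
            " gene(s) with no category call: ",
            paste(utils::head(skipped, 10L), collapse = ", "),
            if (length(skipped) > 10L) ", ...")
  }

  points <- unique(poly[poly$gene_id %in% calls$gene_id,
                        c("gene_id", "generation")])
  rows <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    g <- points$gene_id[i]; gen <- points$generation[i]
    call_row <- calls[calls$gene_id == g & calls$generation == gen, ]
    if (nrow(call_row) == 0L) next
    fm <- mix$a_fraction[mix$gene_id == g]
    fp <- poly$a_fraction[poly$gene_id == g & poly$generation == gen]
    if (length(fm) < 2L || length(fp) < 2L) next
    tt <- two_sample_t(tfun(fp), tfun(fm), var_equal = var_equal)
    bm <- one_sample_t(tfun(fm), null_val)
    bp <- one_sample_t(tfun(fp), null_val)
    rows[[i]] <- data.frame(
      gene_id = g, generation = gen, tissue = tissue,
      expression_class = call_row$additivity[1L],
      p_altered = tt$p_value,
      mix_mean_fraction = mean(fm), poly_mean_fraction = mean(fp),
      p_mix_bias = bm$p_value, p_poly_bias = bp$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(gene_id = character(0), generation = character(0),
                      tissue = character(0), expression_class = character(0),
                      altered = logical(0), outcome = character(0),
                      mix_mean_fraction = numeric(0),
                      poly_mean_fraction = numeric(0),
                      p_altered = numeric(0), mix_biased = logical(0),
                      poly_biased = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  p_mix <- out$p_mix_bias
  p_poly <- out$p_poly_bias
  if (adjust_bias) {
    p_mix <- stats::p.adjust(p_mix, method = "BH")
    p_poly <- stats::p.adjust(p_poly, method = "BH")
  }
  out$altered <- out$p_altered < alpha
  out$mix_biased <- p_mix < alpha
  out$poly_biased <- p_poly < alpha
  out$outcome <- ifelse(!out$altered, "stable",
                 ifelse(out$mix_biased & !out$poly_biased, "erasure",
                 ifelse(!out$mix_biased & out$poly_biased, "novel_bias",
                        "shifted_bias")))
  out$p_mix_bias <- NULL
  out$p_poly_bias <- NULL
  out[, c("gene_id", "generation", "tissue", "expression_class", "altered",
          "outcome", "mix_mean_fraction", "poly_mean_fraction", "p_altered",
          "mix_biased", "poly_biased")]
}

#' Tabulate altered partitioning among comparable data points
#'
#' Counts altered vs total comparable data points within one
#' total-expression class (additive or nonadditive). When the calls
#' span two tissues the per-tissue proportions are compared with a
#' two-proportion test.
#'
#' @param pcalls Partitioning calls from [call_partitioning()] (any
#'   number of tissues row-bound).
#' @param expression_class `"additive"` or `"nonadditive"`.
#' @return List with `n_altered`, `n_total`, `proportion` (`NA` when
#'   `n_total` is 0), `by_tissue` (data frame) and, with exactly two
#'   tissues, `tissue_comparison` (`chi_sq`, `p_value`).
#' @export
tabulate_comparable <- function(pcalls,
                                expression_class = c("additive",
                                                     "nonadditive")) {
  expression_class <- match.arg(expression_class)
  d <- pcalls[pcalls$expression_class == expression_class, , drop = FALSE]
  n_total <- nrow(d)
  n_altered <- sum(d$altered)
  by_tissue <- do.call(rbind, lapply(unique(d$tissue), function(tt) {
    s <- d[d$tissue == tt, ]
    data.frame(tissue = tt, n_altered = sum(s$altered), n_total = nrow(s),
               proportion = if (nrow(s) > 0) sum(s$altered) / nrow(s)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res <- list(n_altered = n_altered, n_total = n_total,
              proportion = if (n_total > 0) n_altered / n_total else NA_real_,
              by_tissue = by_tissue)
  if (!is.null(by_tissue) && nrow(by_tissue) == 2L) {
    res$tissue_comparison <- prop_test(by_tissue$n_altered[1L],
                                       by_tissue$n_total[1L],
                                       by_tissue$n_altered[2L],
                                       by_tissue$n_total[2L])
  }
  res
}

#' Summarize subgenome expression dominance
#'
#' Per genotype — the mix, each polyploid generation, and each natural
#' accession — computes per-gene mean A-subgenome fractions, the
#' genotype mean across genes, counts of A-biased / B-biased / unbiased
#' genes (one-sample t of each gene's replicate fractions against 0.5),
#' and the genotype-level shift against the mix baseline (paired t-test
#' on per-gene means, paired by gene).
#'
#' @param homeolog A `HomeologTable`.
#' @param samples Sample manifest data frame or an `ExpressionDataset`.
#' @param tissue Tissue to analyze.
#' @param genotypes Optional character vector restricting which
#'   genotypes to summarize (labels as in the output `genotype` column).
#' @param alpha Raw p threshold for per-gene bias calls (default 0.05).
#' @return Data frame with one row per genotype: `genotype`, `role`,
#'   `n_genes`, `mean_a_fraction`, `n_a_biased`, `n_b_biased`,
#'   `n_unbiased`, `shift_vs_mix`, `p_shift`.
#' @export
summarize_dominance <- function(homeolog, samples, tissue,
                                genotypes = NULL, alpha = 0.05) {
  samples <- resolve_samples(samples)
  h <- merge(as.data.frame(homeolog), samples, by = "sample_id")
  h <- h[h$tissue == tissue & h$role %in% c("mix", "polyploid", "natural"), ,
         drop = FALSE]
  h$genotype <- ifelse(h$role == "mix", "mix", h$generation)
  gts <- unique(h[, c("genotype", "role")])
  if (!is.null(genotypes)) {
    absent <- setdiff(genotypes, gts$genotype)
    if (length(absent)) {
      warning("no data for genotype(s): ", paste(absent, collapse = ", "),
              "; omitted")
    }
    gts <- gts[gts$genotype %in% genotypes, , drop = FALSE]
  }
  per_gene_mean <- function(sub) {
    means <- tapply(sub$a_fraction, sub$gene_id, mean)
    data.frame(gene_id = names(means), mean_fraction = as.numeric(means),
               stringsAsFactors = FALSE)
  }
  mix_means <- per_gene_mean(h[h$genotype == "mix", , drop = FALSE])
  out <- do.call(rbind, lapply(seq_len(nrow(gts)), function(i) {
    gt <- gts$genotype[i]
    sub <- h[h$genotype == gt, , drop = FALSE]
    # bias calls need replicates; keep only genes with >= 2 fractions so
    # the A-/B-/unbiased counts partition n_genes exactly
    reps <- table(sub$gene_id)
    sub <- sub[sub$gene_id %in% names(reps)[reps >= 2L], , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(genotype = gt, role = gts$role[i], n_genes = 0L,
                        mean_a_fraction = NA_real_, n_a_biased = 0L,
                        n_b_biased = 0L, n_unbiased = 0L,
                        shift_vs_mix = NA_real_, p_shift = NA_real_,
                        stringsAsFactors = FALSE))
    }
    gm <- per_gene_mean(sub)
    bias <- vapply(gm$gene_id, function(g) {
      f <- sub$a_fraction[sub$gene_id == g]
      if (length(f) < 2L) return(NA_character_)
      bt <- one_sample_t(f, 0.5)
      if (bt$p_value >= alpha) "unbiased"
      else if (mean(f) > 0.5) "A" else "B"
    }, character(1))
    shift <- NA_real_; p_shift <- NA_real_
    if (gt != "mix" && nrow(mix_means) > 0) {
      paired <- merge(gm, mix_means, by = "gene_id",
                      suffixes = c("_gt", "_mix"))
      if (nrow(paired) >= 2L) {
        diffs <- paired$mean_fraction_gt - paired$mean_fraction_mix
        shift <- mean(diffs)
        pt <- one_sample_t(diffs, 0)
        p_shift <- pt$p_value
      }
    }
    data.frame(genotype = gt, role = gts$role[i], n_genes = nrow(gm),
               mean_a_fraction = mean(gm$mean_fraction),
               n_a_biased = sum(bias == "A", na.rm = TRUE),
               n_b_biased = sum(bias == "B", na.rm = TRUE),
               n_unbiased = sum(bias == "unbiased", na.rm = TRUE),
               shift_vs_mix = shift, p_shift = p_shift,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
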