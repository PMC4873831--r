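# Total-expression classification: detection filtering, parental
# divergence (PEC/PED), additivity against the mid-parent value, and
# the ELD/TRE pattern decision tree.

ADDITIVE_PATTERNS <- c("constant", "additive")
NONADDITIVE_PATTERNS <- c("eld_high_parentA", "eld_high_parentB",
                          "eld_low_parentA", "eld_low_parentB",
                          "over_tre", "under_tre", "ambiguous")
ALL_PATTERNS <- c(ADDITIVE_PATTERNS, NONADDITIVE_PATTERNS)

# Genotype-group key per sample: diploids and the mix form one group
# each per tissue; polyploid and natural samples form one group per
# generation/accession per tissue.
genotype_group <- function(samples) {
  gen_part <- ifelse(samples$role %in% c("polyploid", "natural"),
                     paste0(":", samples$generation), "")
  paste0(samples$tissue, ":", samples$role, gen_part)
}

#' Detection filter
#'
#' A gene is called present in a genotype group when every replicate in
#' that group is at or above the detection threshold (log2 scale); a
#' gene is retained when it is present in all replicates of at least one
#' genotype group, a reproducibility rule standing in for array
#' present/absent flags. Genes present in no group are removed.
#'
#' @param dataset An `ExpressionDataset`.
#' @param threshold Detection threshold on the log2 scale (default 5).
#' @param tissue Optional tissue; if given, only that tissue's samples
#'   are considered (and returned).
#' @return List with `dataset` (filtered), `flags` (genes x groups
#'   logical presence matrix over the input genes) and `removed`
#'   (dropped gene identifiers).
#' @export
detection_filter <- function(dataset, threshold = 5, tissue = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!is.null(tissue)) dataset <- subset_dataset(dataset, tissue = tissue)
  groups <- genotype_group(dataset$samples)
  ug <- unique(groups)
  flags <- vapply(ug, function(g) {
    cols <- which(groups == g)
    rowSums(dataset$values[, cols, drop = FALSE] >= threshold) == length(cols)
  }, logical(length(dataset$gene_ids)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L,
                                           dimnames = list(dataset$gene_ids, ug))
  keep <- rowSums(flags) > 0L
  removed <- dataset$gene_ids[!keep]
  if (length(removed)) {
    message("detection_filter: removed ", length(removed),
            " gene(s) present in no genotype group")
  }
  list(dataset = subset_dataset(dataset, genes = dataset$gene_ids[keep]),
       flags = flags, removed = removed)
}

#' Mid-parent value group
#'
#' Builds the replicate set representing the mid-parent value (MPV),
#' the expectation under perfectly additive expression. In
#' `measured_mix` mode the MPV group is the 1:1 parental RNA pool
#' hybridized as its own samples; in `computed` mode parental replicates
#' are paired by index and averaged on the linear scale,
#' `MPV_i = log2((2^a_i + 2^b_i) / 2)`.
#'
#' @param dataset An `ExpressionDataset` (single tissue, or pass
#'   `tissue`).
#' @param mode `"measured_mix"` or `"computed"`.
#' @param tissue Optional tissue to subset to.
#' @return List with `values` (genes x replicates matrix on the log2
#'   scale), `mpv` (per-gene mean of that matrix) and `mode`.
#' @export
compute_mpv <- function(dataset, mode = c("measured_mix", "computed"),
                        tissue = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  mode <- match.arg(mode)
  if (!is.null(tissue)) dataset <- subset_dataset(dataset, tissue = tissue)
  if (mode == "measured_mix") {
    mix_ids <- dataset$samples$sample_id[dataset$samples$role == "mix"]
    if (length(mix_ids) == 0L) {
      stop("measured_mix mode requires role=mix samples")
    }
    vals <- dataset$values[, mix_ids, drop = FALSE]
  } else {
    sa <- dataset$samples[dataset$samples$role == "parentA", , drop = FALSE]
    sb <- dataset$samples[dataset$samples$role == "parentB", , drop = FALSE]
    if (nrow(sa) == 0L || nrow(sb) == 0L) {
      stop("computed mode requires parentA and parentB samples")
    }
    sa <- sa[order(sa$replicate), , drop = FALSE]
    sb <- sb[order(sb$replicate), , drop = FALSE]
    k <- min(nrow(sa), nrow(sb))
    if (nrow(sa) != nrow(sb)) {
      warning("unequal parental replicate counts (", nrow(sa), " vs ",
              nrow(sb), "); pairing the first ", k, " by replicate index")
    }
    a <- dataset$values[, sa$sample_id[seq_len(k)], drop = FALSE]
    b <- dataset$values[, sb$sample_id[seq_len(k)], drop = FALSE]
    vals <- log2((2^a + 2^b) / 2)
    colnames(vals) <- paste0("MPV_r", seq_len(k))
  }
  list(values = vals, mpv = rowMeans(vals), mode = mode)
}

#' Classify parental divergence (PEC vs PED)
#'
#' Contrasts the two diploid parents with the moderated t-test and
#' Benjamini-Yekutieli adjustment; genes with adjusted p below `alpha`
#' are parental expression-differential (PED), the rest parental
#' expression-conserved (PEC). The PED direction is the sign of the
#' parentA-minus-parentB log2 fold change.
#'
#' @param dataset An `ExpressionDataset` (detection-filtered).
#' @param tissue Tissue to analyze.
#' @param alpha FDR threshold (default 0.05).
#' @param method Passed to [moderated_t()].
#' @return Data frame with `gene_id`, `parental_status` (`PEC`/`PED`),
#'   `ped_direction` (`A_higher`/`B_higher`/`none`), `log_fc`,
#'   `p_adjusted`.
#' @export
classify_parental <- function(dataset, tissue, alpha = 0.05,
                              method = "moderated") {
  ds <- subset_dataset(dataset, tissue = tissue)
  ga <- sample_ids_for(ds, "parentA")
  gb <- sample_ids_for(ds, "parentB")
  res <- moderated_t(ds, ga, gb, method = method)
  ped <- res$p_adjusted < alpha
  data.frame(gene_id = res$gene_id,
             parental_status = ifelse(ped, "PED", "PEC"),
             ped_direction = ifelse(!ped, "none",
                                    ifelse(res$log_fc > 0, "A_higher",
                                           "B_higher")),
             log_fc = res$log_fc, p_adjusted = res$p_adjusted,
             stringsAsFactors = FALSE)
}

#' Classify expression patterns against parents and the MPV
#'
#' Runs three moderated-t contrasts per gene — polyploid vs the MPV
#' group, polyploid vs each parent — each Benjamini-Yekutieli adjusted
#' across genes, and applies the pattern decision tree:
#'
#' 1. No MPV difference: additive; pattern `constant` for PEC genes,
#'    `additive` for PED genes.
#' 2. MPV difference (nonadditive): significantly above both parents is
#'    `over_tre`, below both `under_tre`; for PED genes, matching the
#'    higher (lower) parent while differing from the other is expression
#'    level dominance `eld_high_*` (`eld_low_*`), named for the matched
#'    parent; anything else is `ambiguous`.
#'
#' PEC genes can only be `constant`, `over_tre`, `under_tre` or
#' `ambiguous`: ELD requires diverged parents.
#'
#' @param dataset An `ExpressionDataset` (detection-filtered).
#' @param tissue Tissue to analyze.
#' @param generation Polyploid generation label (e.g. `"S5"`).
#' @param parental Optional result of [classify_parental()] for this
#'   tissue; computed if omitted.
#' @param alpha FDR threshold for all three contrasts (default 0.05).
#' @param mpv_mode Passed to [compute_mpv()].
#' @param method Passed to [moderated_t()].
#' @return Data frame of gene-category calls: `gene_id`, `tissue`,
#'   `generation`, `parental_status`, `ped_direction`, `additivity`,
#'   `pattern`, `mpv`.
#' @export
classify_pattern <- function(dataset, tissue, generation, parental = NULL,
                             alpha = 0.05, mpv_mode = "measured_mix",
                             method = "moderated") {
  ds <- subset_dataset(dataset, tissue = tissue)
  poly_ids <- sample_ids_for(ds, "polyploid", generation = generation)
  if (length(poly_ids) == 0L) {
    stop("no polyploid samples for generation ", generation,
         " in tissue ", tissue)
  }
  if (is.null(parental)) {
    parental <- classify_parental(dataset, tissue, alpha = alpha,
                                  method = method)
  }
  if (!identical(parental$gene_id, ds$gene_ids)) {
    parental <- parental[match(ds$gene_ids, parental$gene_id), , drop = FALSE]
    if (any(is.na(parental$gene_id))) {
      stop("parental classification does not cover all genes in the dataset")
    }
  }
  d0 <- if (identical(method, "ordinary")) 0 else NULL
  poly <- ds$values[, poly_ids, drop = FALSE]
  mpv <- compute_mpv(ds, mode = mpv_mode)
  pa <- ds$values[, sample_ids_for(ds, "parentA"), drop = FALSE]
  pb <- ds$values[, sample_ids_for(ds, "parentB"), drop = FALSE]
  t_m <- moderated_t_mat(poly, mpv$values, gene_ids = ds$gene_ids, d0 = d0)
  t_a <- moderated_t_mat(poly, pa, gene_ids = ds$gene_ids, d0 = d0)
  t_b <- moderated_t_mat(poly, pb, gene_ids = ds$gene_ids, d0 = d0)

  sig_m <- t_m$p_adjusted < alpha
  sig_a <- t_a$p_adjusted < alpha
  sig_b <- t_b$p_adjusted < alpha
  is_ped <- parental$parental_status == "PED"
  a_higher <- parental$ped_direction == "A_higher"

  n <- length(ds$gene_ids)
  pattern <- character(n)
  for (i in seq_len(n)) {
    if (!sig_m[i]) {
      pattern[i] <- if (is_ped[i]) "additive" else "constant"
    } else if (sig_a[i] && sig_b[i] && t_a$log_fc[i] > 0 && t_b$log_fc[i] > 0) {
      pattern[i] <- "over_tre"
    } else if (sig_a[i] && sig_b[i] && t_a$log_fc[i] < 0 && t_b$log_fc[i] < 0) {
      pattern[i] <- "under_tre"
    } else if (is_ped[i]) {
      sig_high <- if (a_higher[i]) sig_a[i] else sig_b[i]
      sig_low <- if (a_higher[i]) sig_b[i] else sig_a[i]
      if (!sig_high && sig_low) {
        pattern[i] <- if (a_higher[i]) "eld_high_parentA" else "eld_high_parentB"
      } else if (!sig_low && sig_high) {
        pattern[i] <- if (a_higher[i]) "eld_low_parentB" else "eld_low_parentA"
      } else {
        pattern[i] <- "ambiguous"
      }
    } else {
      pattern[i] <- "ambiguous"
    }
  }
  data.frame(gene_id = ds$gene_ids, tissue = tissue, generation = generation,
             parental_status = parental$parental_status,
             ped_direction = parental$ped_direction,
             additivity = ifelse(pattern %in% ADDITIVE_PATTERNS,
                                 "additive", "nonadditive"),
             pattern = pattern, mpv = mpv$mpv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize category calls
#'
#' Tabulates pattern counts and proportions per tissue x generation,
#' cross-tabulates parental status against additivity, and tests per
#' stratum whether PEC and PED genes have equal propensities for
#' nonadditive expression (two-proportion test).
#'
#' @param calls Gene-category calls from [classify_pattern()] (any
#'   number of tissues/generations row-bound).
#' @return List with `pattern_counts` (tissue, generation, pattern,
#'   n, proportion), `parental_additivity` (tissue, generation,
#'   parental_status, n_additive, n_nonadditive) and `propensity_tests`
#'   (per stratum chi-square and p for PEC vs PED nonadditive shares).
#' @export
summarize_categories <- function(calls) {
  strata <- unique(calls[, c("tissue", "generation")])
  pattern_counts <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- calls[calls$tissue == strata$tissue[i] &
                 calls$generation == strata$generation[i], ]
    tab <- table(factor(sub$pattern, levels = ALL_PATTERNS))
    data.frame(tissue = strata$tissue[i], generation = strata$generation[i],
               pattern = names(tab), n = as.integer(tab),
               proportion = as.integer(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  parental_additivity <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sub <- calls[calls$tissue == strata$tissue[i] &
                 calls$generation == strata$generation[i], ]
    do.call(rbind, lapply(c("PEC", "PED"), function(ps) {
      s2 <- sub[sub$parental_status == ps, ]
      data.frame(tissue = strata$tissue[i], generation = strata$generation[i],
                 parental_status = ps,
                 n_additive = sum(s2$additivity == "additive"),
                 n_nonadditive = sum(s2$additivity == "nonadditive"),
                 stringsAsFactors = FALSE)
    }))
  }))
  propensity_tests <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    pa <- parental_additivity[parental_additivity$tissue == strata$tissue[i] &
                              parental_additivity$generation ==
                                strata$generation[i], ]
    pec <- pa[pa$parental_status == "PEC", ]
    ped <- pa[pa$parental_status == "PED", ]
    n_pec <- pec$n_additive + pec$n_nonadditive
    n_ped <- ped$n_additive + ped$n_nonadditive
    if (n_pec == 0 || n_ped == 0) {
      return(data.frame(tissue = strata$tissue[i],
                        generation = strata$generation[i],
                        chi_sq = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    pt <- prop_test(pec$n_nonadditive, n_pec, ped$n_nonadditive, n_ped)
    data.frame(tissue = strata$tissue[i], generation = strata$generation[i],
               chi_sq = pt$chi_sq, p_value = pt$p_value,
               stringsAsFactors = FALSE)
  }))
  list(pattern_counts = pattern_counts,
       parental_additivity = parental_additivity,
       propensity_tests = propensity_tests)
}
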