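# Transgenerational consistency of nonadditive expression and its
# decomposition into PEC/PED x ELD/TRE sources.

SOURCE_BINS <- c("PEC_over_tre", "PEC_under_tre", "PED_over_tre",
                 "PED_under_tre", "PED_eld_high_A", "PED_eld_high_B",
                 "PED_eld_low_A", "PED_eld_low_B")

#' Find transgenerationally consistent nonadditive genes
#'
#' A gene is transgenerationally consistent when it is nonadditive in
#' every generation and, under the default `exact_pattern` mode, carries
#' the identical pattern label throughout; `nonadditive_only` only
#' requires persistent nonadditivity. Genes classified `ambiguous` in
#' any generation are excluded: no pattern identity can be asserted for
#' them.
#'
#' @param calls Gene-category calls for one tissue across generations.
#' @param generations Generation labels that must all be present;
#'   defaults to the generations found in `calls`.
#' @param match_mode `"exact_pattern"` (default) or `"nonadditive_only"`.
#' @return A `transgen_summary` list: `tissue`, `match_mode`,
#'   `consistent_genes` (identifier vector), `per_generation` (data
#'   frame of nonadditive counts and consistent shares) and
#'   `n_consistent`.
#' @export
find_consistent <- function(calls, generations = NULL,
                            match_mode = c("exact_pattern",
                                           "nonadditive_only")) {
  match_mode <- match.arg(match_mode)
  tissues <- unique(calls$tissue)
  if (length(tissues) != 1L) {
    stop("find_consistent expects calls for a single tissue; got: ",
         paste(tissues, collapse = ", "))
  }
  if (is.null(generations)) generations <- sort(unique(calls$generation))
  missing_gen <- setdiff(generations, unique(calls$generation))
  if (length(missing_gen)) {
    stop("missing generation: ", paste(missing_gen, collapse = ", "))
  }
  calls <- calls[calls$generation %in% generations, , drop = FALSE]

  # genes x generations pattern table (drop genes not called everywhere)
  wide <- split(calls, calls$generation)
  common <- Reduce(intersect, lapply(wide, function(d) d$gene_id))
  pat <- vapply(generations, function(g) {
    d <- wide[[g]]
    d$pattern[match(common, d$gene_id)]
  }, character(length(common)))
  if (is.null(dim(pat))) pat <- matrix(pat, nrow = 1L)
  nonadd <- !(pat %in% ADDITIVE_PATTERNS)
  dim(nonadd) <- dim(pat)
  all_nonadd <- rowSums(nonadd) == length(generations)
  any_ambiguous <- rowSums(pat == "ambiguous") > 0L
  if (match_mode == "exact_pattern") {
    same <- rowSums(pat == pat[, 1L]) == length(generations)
    consistent <- all_nonadd & same & !any_ambiguous
  } else {
    consistent <- all_nonadd & !any_ambiguous
  }
  consistent_genes <- common[consistent]
  per_generation <- do.call(rbind, lapply(generations, function(g) {
    d <- wide[[g]]
    n_nonadd <- sum(d$additivity == "nonadditive")
    data.frame(generation = g, n_nonadditive = n_nonadd,
               consistent_share = if (n_nonadd > 0)
                 length(consistent_genes) / n_nonadd else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(tissue = tissues, match_mode = match_mode,
                 consistent_genes = consistent_genes,
                 per_generation = per_generation,
                 n_consistent = length(consistent_genes)),
            class = "transgen_summary")
}

#' @export
print.transgen_summary <- function(x, ...) {
  cat("Transgenerational consistency (", x$tissue, ", ", x$match_mode,
      "): ", x$n_consistent, " consistent nonadditive gene(s)\n", sep = "")
  print(x$per_generation, row.names = FALSE)
  invisible(x)
}

#' Decompose consistent nonadditive genes by source
#'
#' Assigns each transgenerationally consistent gene one source bin
#' combining its parental status with its (generation-invariant)
#' pattern — PEC or PED crossed with over/under-TRE, plus the four ELD
#' arms for PED genes — and compares the TRE vs ELD contributions by a
#' two-proportion test.
#'
#' @param summary A `transgen_summary` computed under `exact_pattern`.
#' @param calls The calls the summary was computed from.
#' @return List with `source_counts` (bin, n), `n_tre`, `n_eld`,
#'   `tre_share`, and `tre_vs_eld` (`chi_sq`, `p_value`; `NA` when the
#'   consistent set is empty).
#' @export
decompose_sources <- function(summary, calls) {
  stopifnot(inherits(summary, "transgen_summary"))
  if (summary$match_mode != "exact_pattern") {
    stop("source decomposition requires an exact_pattern summary: ",
         "the bin depends on the pattern label being generation-invariant")
  }
  first_gen <- summary$per_generation$generation[1L]
  d <- calls[calls$generation == first_gen &
             calls$gene_id %in% summary$consistent_genes, , drop = FALSE]
  bin <- character(nrow(d))
  for (i in seq_len(nrow(d))) {
    ps <- d$parental_status[i]
    bin[i] <- switch(d$pattern[i],
      over_tre = paste0(ps, "_over_tre"),
      under_tre = paste0(ps, "_under_tre"),
      eld_high_parentA = "PED_eld_high_A",
      eld_high_parentB = "PED_eld_high_B",
      eld_low_parentA = "PED_eld_low_A",
      eld_low_parentB = "PED_eld_low_B",
      stop("unexpected pattern in consistent set: ", d$pattern[i]))
  }
  tab <- table(factor(bin, levels = SOURCE_BINS))
  n <- nrow(d)
  n_tre <- sum(tab[grepl("_tre$", names(tab))])
  n_eld <- sum(tab[grepl("_eld_", names(tab))])
  tve <- if (n > 0) prop_test(n_tre, n, n_eld, n)
         else list(chi_sq = NA_real_, p_value = NA_real_)
  list(source_counts = data.frame(bin = names(tab), n = as.integer(tab),
                                  stringsAsFactors = FALSE),
       n_tre = n_tre, n_eld = n_eld,
       tre_share = if (n > 0) n_tre / n else NA_real_,
       tre_vs_eld = tve)
}
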