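# Scoring classification output against the generator's planted truth.

#' Expected call patterns implied by the planted truth
#'
#' Translates generator labels into the labels the classifier emits:
#' planted `eld_parentX` becomes `eld_high_parentX` or
#' `eld_low_parentX` depending on whether X is the higher or lower
#' parent for that gene; other labels map to themselves.
#'
#' @param truth A `ground_truth` from [simulate_expression()].
#' @return The `patterns` data frame with an `expected_pattern` column.
#' @export
expected_call_pattern <- function(truth) {
  pat <- truth$patterns
  dir <- truth$genes$ped_direction[match(pat$gene_id, truth$genes$gene_id)]
  expected <- pat$pattern
  is_eld_a <- pat$pattern == "eld_parentA"
  is_eld_b <- pat$pattern == "eld_parentB"
  expected[is_eld_a] <- ifelse(dir[is_eld_a] == "A_higher",
                               "eld_high_parentA", "eld_low_parentA")
  expected[is_eld_b] <- ifelse(dir[is_eld_b] == "B_higher",
                               "eld_high_parentB", "eld_low_parentB")
  pat$expected_pattern <- expected
  pat
}

#' Score pattern recovery against the planted truth
#'
#' @param calls Gene-category calls (any tissues/generations).
#' @param truth A `ground_truth` from [simulate_expression()].
#' @return List with `n` (scored calls), `n_correct`, `recovery`
#'   (fraction of calls whose pattern equals the planted label, with
#'   `ambiguous` always counting as a miss) and `by_pattern` (per
#'   planted label recovery).
#' @export
score_pattern_recovery <- function(calls, truth) {
  exp_pat <- expected_call_pattern(truth)
  key <- function(d) paste(d$gene_id, d$tissue, d$generation, sep = "\r")
  idx <- match(key(calls), key(exp_pat))
  scored <- !is.na(idx)
  expected <- exp_pat$expected_pattern[idx[scored]]
  got <- calls$pattern[scored]
  correct <- got == expected
  by_pattern <- stats::aggregate(correct,
                                 by = list(planted = expected), FUN = mean)
  names(by_pattern)[2L] <- "recovery"
  list(n = sum(scored), n_correct = sum(correct),
       recovery = mean(correct), by_pattern = by_pattern)
}

#' Score transgenerational-consistency recovery
#'
#' Compares the recovered consistent gene set against the realized
#' planted truth: genes whose planted pattern labels are identical and
#' nonadditive in every generation (a gene re-drawn per generation can
#' land on the same pattern throughout and is then genuinely
#' consistent).
#'
#' @param summary A `transgen_summary` from [find_consistent()].
#' @param truth A `ground_truth`.
#' @return List with `n_planted`, `n_recovered`, `jaccard`,
#'   `sensitivity`, `precision`.
#' @export
score_transgen_recovery <- function(summary, truth) {
  pat <- truth$patterns[truth$patterns$tissue == summary$tissue, ]
  wide <- split(pat$pattern, pat$gene_id)
  planted <- names(wide)[vapply(wide, function(p) {
    length(unique(p)) == 1L && !(p[1L] %in% c("additive", "constant"))
  }, logical(1))]
  got <- summary$consistent_genes
  inter <- length(intersect(planted, got))
  list(n_planted = length(planted), n_recovered = length(got),
       jaccard = if (length(union(planted, got)) > 0)
         inter / length(union(planted, got)) else NA_real_,
       sensitivity = if (length(planted) > 0) inter / length(planted)
                     else NA_real_,
       precision = if (length(got) > 0) inter / length(got) else NA_real_)
}

#' Score homeolog-partitioning recovery
#'
#' Planted outcomes map onto call outcomes as `unaltered -> stable`,
#' `erasure -> erasure`, `novel_bias -> novel_bias`.
#'
#' @param pcalls Partitioning calls from [call_partitioning()].
#' @param truth_homeolog The `truth_homeolog` data frame from
#'   [simulate_homeolog()].
#' @return List with `n`, `n_correct`, `recovery`, `by_outcome`.
#' @export
score_partitioning_recovery <- function(pcalls, truth_homeolog) {
  key <- function(d) paste(d$gene_id, d$generation, sep = "\r")
  idx <- match(key(pcalls), key(truth_homeolog))
  scored <- !is.na(idx)
  planted <- truth_homeolog$outcome[idx[scored]]
  expected <- c(unaltered = "stable", erasure = "erasure",
                novel_bias = "novel_bias")[planted]
  correct <- pcalls$outcome[scored] == expected
  by_outcome <- stats::aggregate(correct, by = list(planted = planted),
                                 FUN = mean)
  names(by_outcome)[2L] <- "recovery"
  list(n = sum(scored), n_correct = sum(correct),
       recovery = mean(correct), by_outcome = by_outcome)
}
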