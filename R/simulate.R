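# Synthetic-data generator: replicated log2 expression for two diploid
# parents, their 1:1 RNA mix, polyploid generations with planted
# additive/ELD/TRE patterns and planted transgenerational consistency,
# plus allele-fraction tables with planted partitioning outcomes.
# Every classification the pipeline makes has a planted truth here.

EXPRESSION_PATTERNS <- c("additive", "constant", "eld_parentA",
                         "eld_parentB", "over_tre", "under_tre")

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator.
#' Defaults emulate the study design the package analyzes: two diploid
#' parents with ~70% diverged orthologs, a 1:1 parental RNA mix, four
#' consecutive polyploid selfing generations with 3 biological
#' replicates each, and pyrosequencing-style allele fractions for a
#' subset of genes.
#'
#' @param n_genes Number of genes.
#' @param n_reps Biological replicates per genotype group (default 3).
#' @param generations Polyploid generation labels (default S5..S8).
#' @param tissues Tissue labels (default leaf and inflorescence).
#' @param frac_ped Fraction of genes with diverged parental expression
#'   (default 0.70).
#' @param ped_lfc_range Interval for the absolute log2 parental
#'   difference of PED genes (default c(1.5, 4)).
#' @param category_mix Named nonnegative weights over planted polyploid
#'   patterns `additive`, `constant`, `eld_parentA`, `eld_parentB`,
#'   `over_tre`, `under_tre`; renormalized per gene over the admissible
#'   set (constant only for PEC genes; additive and ELD only for PED).
#' @param frac_transgen_consistent Share of first-draw nonadditive genes
#'   whose pattern is held fixed across all generations (default 0.4);
#'   the rest re-draw a pattern independently per generation.
#' @param replicate_sd Replicate noise SD on the log2 scale
#'   (default 0.25).
#' @param baseline_range Interval for baseline parental log2 means
#'   (default c(4, 12)).
#' @param tre_sep_factor TRE offsets are drawn at least
#'   `2 * replicate_sd * tre_sep_factor` above/below the outer parent
#'   (default 4).
#' @param tre_min_delta Floor on the TRE offset so transgressive genes
#'   remain separated even as `replicate_sd` approaches 0
#'   (default 1.5 log2 units).
#' @param homeolog List of allele-fraction settings: `n_genes` (genes
#'   pyrosequenced, default 150), `reps` (default `n_reps`),
#'   `frac_unaltered`, `frac_erasure`, `frac_novel_bias` (outcome
#'   weights, defaults 0.40/0.35/0.25), `bias_shift` (novel-bias
#'   magnitude, default 0.20, must be < 0.5), `baseline_bias` (parental
#'   ortholog bias magnitude for biased-baseline genes, default 0.25),
#'   `beta_precision` (Beta concentration of biased gene baselines;
#'   `Inf` pins the baseline at its mean; balanced baselines are always
#'   exactly 0.5), `logit_sd` (replicate noise SD on the logit scale,
#'   default 0.12, about a 3-percentage-point SD at a 50:50 ratio,
#'   pyrosequencing-like precision), `n_natural` (natural accessions,
#'   default 4) and `natural_shift` (planted A-ward shift of natural
#'   accessions relative to the mix, default 0.08).
#' @param seed Integer seed; all draws flow from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps = 3,
                       generations = c("S5", "S6", "S7", "S8"),
                       tissues = c("leaf", "inflorescence"),
                       frac_ped = 0.70,
                       ped_lfc_range = c(1.5, 4),
                       category_mix = c(additive = 0.30, constant = 0.25,
                                        eld_parentA = 0.08,
                                        eld_parentB = 0.07,
                                        over_tre = 0.20, under_tre = 0.10),
                       frac_transgen_consistent = 0.40,
                       replicate_sd = 0.25,
                       baseline_range = c(4, 12),
                       tre_sep_factor = 4,
                       tre_min_delta = 1.5,
                       homeolog = list(),
                       seed = 1) {
  hdef <- list(n_genes = 150, reps = n_reps, frac_unaltered = 0.40,
               frac_erasure = 0.35, frac_novel_bias = 0.25,
               bias_shift = 0.20, baseline_bias = 0.25,
               beta_precision = 150, logit_sd = 0.12,
               n_natural = 4, natural_shift = 0.08)
  unknown <- setdiff(names(homeolog), names(hdef))
  if (length(unknown)) {
    stop("unknown homeolog config keys: ", paste(unknown, collapse = ", "))
  }
  hdef[names(homeolog)] <- homeolog
  cfg <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              generations = as.character(generations),
              tissues = as.character(tissues),
              frac_ped = frac_ped, ped_lfc_range = ped_lfc_range,
              category_mix = category_mix,
              frac_transgen_consistent = frac_transgen_consistent,
              replicate_sd = replicate_sd,
              baseline_range = baseline_range,
              tre_sep_factor = tre_sep_factor,
              tre_min_delta = tre_min_delta,
              homeolog = hdef, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_reps >= 2,
            length(cfg$generations) >= 1, length(cfg$tissues) >= 1)
  if (cfg$frac_ped < 0 || cfg$frac_ped > 1) stop("frac_ped must be in [0, 1]")
  if (cfg$frac_transgen_consistent < 0 || cfg$frac_transgen_consistent > 1) {
    stop("frac_transgen_consistent must be in [0, 1]")
  }
  if (length(cfg$ped_lfc_range) != 2L || any(cfg$ped_lfc_range <= 0) ||
      diff(cfg$ped_lfc_range) < 0) {
    stop("ped_lfc_range must be a positive increasing interval")
  }
  mix_names <- setdiff(EXPRESSION_PATTERNS, names(cfg$category_mix))
  if (length(mix_names)) {
    stop("category_mix is missing weights for: ",
         paste(mix_names, collapse = ", "))
  }
  if (any(cfg$category_mix < 0) || sum(cfg$category_mix) <= 0) {
    stop("category_mix weights must be nonnegative with a positive sum")
  }
  if (cfg$replicate_sd < 0) stop("replicate_sd must be nonnegative")
  h <- cfg$homeolog
  w <- c(h$frac_unaltered, h$frac_erasure, h$frac_novel_bias)
  if (any(w < 0) || sum(w) <= 0) {
    stop("homeolog outcome weights must be nonnegative with a positive sum")
  }
  invisible(cfg)
}

draw_pattern <- function(weights, admissible) {
  w <- weights[admissible]
  if (sum(w) <= 0) w <- stats::setNames(rep(1, length(admissible)), admissible)
  sample(admissible, 1L, prob = w / sum(w))
}

#' Simulate an expression dataset with planted ground truth
#'
#' Parents get baseline log2 means drawn uniformly from
#' `baseline_range`; PED genes receive a parental offset of magnitude in
#' `ped_lfc_range` with random sign, PEC genes offset 0. Mix samples are
#' the linear-scale average of the parental true means (the physical
#' 1:1 RNA pool), `log2((2^a + 2^b) / 2)`. Polyploid true means follow
#' the planted pattern: `additive` = mix mean, `constant` = the common
#' parental mean, `eld_parentX` = that parent's mean (PED genes only),
#' `over_tre` = max(parents) + delta and `under_tre` = min(parents) -
#' delta with delta at least `max(tre_min_delta, 2 * replicate_sd *
#' tre_sep_factor)`. A `frac_transgen_consistent` share of first-draw
#' nonadditive genes keeps its pattern across all generations; the rest
#' re-draw independently per generation. Replicates are the true mean
#' plus Normal(0, `replicate_sd`) noise. Natural accessions (for the
#' dominance analysis) are given expression at the mix mean.
#' Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (an `ExpressionDataset`) and `truth`
#'   (class `ground_truth`): `genes` (per-gene PEC/PED status,
#'   direction, log2 offset) and `patterns` (per gene x tissue x
#'   generation planted label plus the consistency flag).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  eld_w <- sum(config$category_mix[c("eld_parentA", "eld_parentB")])
  if (eld_w > 0 && config$frac_ped == 0) {
    stop("ELD weights require PED genes: set frac_ped > 0 or zero the ",
         "eld_parentA/eld_parentB weights")
  }
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  ped <- stats::runif(n) < config$frac_ped
  lfc <- ifelse(ped,
                stats::runif(n, config$ped_lfc_range[1L],
                             config$ped_lfc_range[2L]) *
                  sample(c(-1, 1), n, replace = TRUE),
                0)
  genes <- data.frame(gene_id = gene_ids,
                      parental_status = ifelse(ped, "PED", "PEC"),
                      ped_direction = ifelse(!ped, "none",
                                             ifelse(lfc > 0, "A_higher",
                                                    "B_higher")),
                      parental_lfc = lfc, stringsAsFactors = FALSE)

  delta_min <- max(config$tre_min_delta,
                   2 * config$replicate_sd * config$tre_sep_factor)
  gens <- config$generations
  n_gen <- length(gens)

  manifest_list <- list()
  value_list <- list()
  pattern_list <- list()

  natural_ids <- if (config$homeolog$n_natural > 0)
    sprintf("NAT%02d", seq_len(config$homeolog$n_natural)) else character(0)

  for (tt in config$tissues) {
    base <- stats::runif(n, config$baseline_range[1L],
                         config$baseline_range[2L])
    mean_a <- base + lfc / 2
    mean_b <- base - lfc / 2
    mean_mix <- log2((2^mean_a + 2^mean_b) / 2)

    admissible <- lapply(seq_len(n), function(i) {
      if (ped[i]) c("additive", "eld_parentA", "eld_parentB",
                    "over_tre", "under_tre")
      else c("constant", "over_tre", "under_tre")
    })
    first <- vapply(seq_len(n), function(i)
      draw_pattern(config$category_mix, admissible[[i]]), character(1))
    nonadd_first <- !(first %in% c("additive", "constant"))
    consistent <- nonadd_first &
      stats::runif(n) < config$frac_transgen_consistent

    # additive first draws stay additive; consistent nonadditive genes
    # keep their pattern; the rest re-draw in every generation
    # (including the first) so generations are exchangeable
    pat <- matrix("", nrow = n, ncol = n_gen,
                  dimnames = list(gene_ids, gens))
    for (j in seq_len(n_gen)) {
      redraw <- vapply(seq_len(n), function(i)
        draw_pattern(config$category_mix, admissible[[i]]), character(1))
      pat[, j] <- ifelse(!nonadd_first | consistent, first, redraw)
    }

    pattern_mean <- function(p, i, gen_idx) {
      switch(p,
        additive = mean_mix[i],
        constant = base[i],
        eld_parentA = mean_a[i],
        eld_parentB = mean_b[i],
        over_tre = max(mean_a[i], mean_b[i]) + delta[[gen_idx]][i],
        under_tre = min(mean_a[i], mean_b[i]) - delta[[gen_idx]][i])
    }
    delta <- lapply(seq_len(n_gen), function(j)
      delta_min + stats::runif(n, 0, 1))

    add_group <- function(true_means, role, generation, n_reps, prefix) {
      for (r in seq_len(n_reps)) {
        sid <- paste0(prefix, "_", tt, "_r", r)
        manifest_list[[length(manifest_list) + 1L]] <<- data.frame(
          sample_id = sid, role = role, tissue = tt,
          generation = generation, replicate = r, stringsAsFactors = FALSE)
        noise <- if (config$replicate_sd > 0)
          stats::rnorm(n, 0, config$replicate_sd) else 0
        value_list[[sid]] <<- true_means + noise
      }
    }
    add_group(mean_a, "parentA", "", config$n_reps, "parentA")
    add_group(mean_b, "parentB", "", config$n_reps, "parentB")
    add_group(mean_mix, "mix", "", config$n_reps, "mix")
    for (j in seq_len(n_gen)) {
      tm <- vapply(seq_len(n), function(i) pattern_mean(pat[i, j], i, j),
                   numeric(1))
      add_group(tm, "polyploid", gens[j], config$n_reps,
                paste0("poly_", gens[j]))
    }
    for (acc in natural_ids) {
      add_group(mean_mix, "natural", acc, config$n_reps,
                paste0("nat_", acc))
    }

    pattern_list[[tt]] <- data.frame(
      gene_id = rep(gene_ids, times = n_gen),
      tissue = tt,
      generation = rep(gens, each = n),
      pattern = as.vector(pat),
      consistent = rep(consistent, times = n_gen),
      stringsAsFactors = FALSE)
  }

  manifest <- do.call(rbind, manifest_list)
  values <- do.call(cbind, value_list)
  rownames(values) <- gene_ids
  dataset <- expression_dataset(values, manifest, gene_ids = gene_ids)
  truth <- structure(list(genes = genes,
                          patterns = do.call(rbind, pattern_list),
                          config = config),
                     class = "ground_truth")
  rownames(truth$patterns) <- NULL
  list(dataset = dataset, truth = truth)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate a homeolog allele-fraction table with planted outcomes
#'
#' For a subset of genes, each gene gets a mix-baseline A-fraction
#' (Beta-distributed around 0.5 for balanced-baseline genes or around
#' `0.5 +/- baseline_bias` for biased-baseline genes) and a planted
#' partitioning outcome drawn from the configured weights: `unaltered`
#' keeps the mix mean in the polyploid, `erasure` (only planted on
#' biased baselines) sets it to 0.5, `novel_bias` (only on balanced
#' baselines) sets it to `0.5 +/- bias_shift`. The planted outcome is a
#' gene-level property applied to every generation. Natural accessions
#' get the mix baseline shifted A-ward by `natural_shift`. Replicate
#' noise is Normal on the logit scale; fractions are clamped to
#' \[0.01, 0.99\]. Requires the manifest/truth from
#' [simulate_expression()] under the same config (the draw consumes the
#' same seeded stream; call it after simulate_expression or reseed).
#'
#' @param config A [sim_config()].
#' @param truth The `ground_truth` from [simulate_expression()].
#' @param dataset The `ExpressionDataset` from [simulate_expression()]
#'   (supplies the sample manifest).
#' @return List with `homeolog` (a `HomeologTable` covering mix,
#'   polyploid and natural samples in every tissue) and `truth_homeolog`
#'   (per gene x generation planted outcome plus the baseline type and
#'   planted means).
#' @export
simulate_homeolog <- function(config, truth, dataset) {
  validate_sim_config(config)
  h <- config$homeolog
  if (h$bias_shift >= 0.5) stop("bias_shift must be below 0.5")
  if (h$baseline_bias <= 0 || h$baseline_bias >= 0.5) {
    stop("baseline_bias must lie in (0, 0.5)")
  }
  set.seed(config$seed + 1L)
  n_h <- min(h$n_genes, length(truth$genes$gene_id))
  gene_ids <- truth$genes$gene_id[seq_len(n_h)]

  w <- c(unaltered = h$frac_unaltered, erasure = h$frac_erasure,
         novel_bias = h$frac_novel_bias)
  outcome <- sample(names(w), n_h, replace = TRUE, prob = w / sum(w))
  baseline_biased <- ifelse(outcome == "erasure", TRUE,
                     ifelse(outcome == "novel_bias", FALSE,
                            stats::runif(n_h) < 0.5))
  bias_sign <- sample(c(-1, 1), n_h, replace = TRUE)
  m0 <- ifelse(baseline_biased, 0.5 + bias_sign * h$baseline_bias, 0.5)
  # balanced baselines are pinned at exactly 0.5 so the planted
  # balanced/biased dichotomy stays self-consistent; only biased
  # baselines get gene-level Beta spread around their mean
  p0 <- if (is.infinite(h$beta_precision)) m0
        else ifelse(baseline_biased,
                    stats::rbeta(n_h, m0 * h$beta_precision,
                                 (1 - m0) * h$beta_precision),
                    m0)
  novel_sign <- sample(c(-1, 1), n_h, replace = TRUE)
  poly_mean <- ifelse(outcome == "unaltered", p0,
               ifelse(outcome == "erasure", 0.5,
                      0.5 + novel_sign * h$bias_shift))
  nat_mean <- pmin(0.99, pmax(0.01, p0 + h$natural_shift))

  samples <- dataset$samples
  samples <- samples[samples$role %in% c("mix", "polyploid", "natural"), ,
                     drop = FALSE]
  # per sample group use the first `reps` replicates
  samples <- samples[samples$replicate <= h$reps, , drop = FALSE]

  rows <- vector("list", nrow(samples))
  for (k in seq_len(nrow(samples))) {
    s <- samples[k, ]
    mean_frac <- switch(s$role,
      mix = p0,
      polyploid = poly_mean,
      natural = nat_mean)
    x <- logit(pmin(0.99, pmax(0.01, mean_frac)))
    if (h$logit_sd > 0) x <- x + stats::rnorm(n_h, 0, h$logit_sd)
    rows[[k]] <- data.frame(gene_id = gene_ids, sample_id = s$sample_id,
                            a_fraction = pmin(0.99, pmax(0.01,
                                                         inv_logit(x))),
                            stringsAsFactors = FALSE)
  }
  homeolog <- homeolog_table(do.call(rbind, rows))

  gens <- config$generations
  truth_homeolog <- data.frame(
    gene_id = rep(gene_ids, times = length(gens)),
    generation = rep(gens, each = n_h),
    outcome = rep(outcome, times = length(gens)),
    baseline_biased = rep(baseline_biased, times = length(gens)),
    mix_mean = rep(p0, times = length(gens)),
    poly_mean = rep(poly_mean, times = length(gens)),
    stringsAsFactors = FALSE)
  list(homeolog = homeolog, truth_homeolog = truth_homeolog)
}
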