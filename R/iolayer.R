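SAMPLE_ROLES <- c("parentA", "parentB", "mix", "polyploid", "natural")
MANIFEST_COLS <- c("sample_id", "role", "tissue", "generation", "replicate")

#' Construct an expression dataset
#'
#' Bundles a genes x samples log2 expression matrix with its sample
#' manifest. This is the substrate of every total-expression
#' classification in the package: parental divergence, additivity
#' against the mid-parent value, and the ELD/TRE decision tree.
#'
#' @param values Numeric matrix, genes in rows and samples in columns,
#'   on the log2 scale. Row names are gene identifiers and column names
#'   sample identifiers; both may instead be supplied explicitly.
#' @param samples Data frame with columns `sample_id`, `role`
#'   (`parentA`, `parentB`, `mix`, `polyploid`, `natural`), `tissue`,
#'   `generation` (may be empty for diploids and the mix) and
#'   `replicate` (positive integer).
#' @param gene_ids Character vector of gene identifiers; defaults to
#'   `rownames(values)`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `gene_ids`, `samples` and `values`.
#' @export
expression_dataset <- function(values, samples, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) {
    stop("gene identifiers are required (rownames of `values` or `gene_ids`)")
  }
  gene_ids <- as.character(gene_ids)
  samples <- validate_manifest(samples)
  if (nrow(values) != length(gene_ids)) {
    stop("`values` has ", nrow(values), " rows but ", length(gene_ids),
         " gene identifiers were supplied")
  }
  if (ncol(values) != nrow(samples)) {
    stop("`values` has ", ncol(values), " columns but the manifest lists ",
         nrow(samples), " samples")
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene_id: ", paste(dup, collapse = ", "))
  }
  if (!is.null(colnames(values))) {
    if (!identical(colnames(values), samples$sample_id)) {
      # align matrix columns to manifest order; identity of the sets was
      # checked upstream by read_expression or is checked here
      missing_m <- setdiff(samples$sample_id, colnames(values))
      extra_m <- setdiff(colnames(values), samples$sample_id)
      if (length(missing_m) || length(extra_m)) {
        stop("sample mismatch between matrix and manifest; ",
             if (length(missing_m)) paste0("absent from matrix: ",
                                           paste(missing_m, collapse = ", ")),
             if (length(missing_m) && length(extra_m)) "; ",
             if (length(extra_m)) paste0("absent from manifest: ",
                                         paste(extra_m, collapse = ", ")))
      }
      values <- values[, samples$sample_id, drop = FALSE]
    }
  }
  dimnames(values) <- list(gene_ids, samples$sample_id)
  if (any(!is.finite(values))) {
    stop("expression values must be finite after ingestion; ",
         "use read_expression() for the drop-and-log missing-value policy")
  }
  structure(list(gene_ids = gene_ids, samples = samples, values = values),
            class = "ExpressionDataset")
}

validate_manifest <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLS, names(samples))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  samples <- samples[, MANIFEST_COLS]
  samples$sample_id <- as.character(samples$sample_id)
  samples$role <- as.character(samples$role)
  samples$tissue <- as.character(samples$tissue)
  samples$generation <- as.character(samples$generation)
  samples$generation[is.na(samples$generation)] <- ""
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id in manifest: ", paste(dup, collapse = ", "))
  }
  bad_role <- setdiff(unique(samples$role), SAMPLE_ROLES)
  if (length(bad_role)) {
    stop("unknown role token: ", paste(bad_role, collapse = ", "),
         " (expected one of ", paste(SAMPLE_ROLES, collapse = ", "), ")")
  }
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1)) {
    stop("replicate must be a positive integer for every sample")
  }
  samples
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", length(x$gene_ids), "genes x",
      nrow(x$samples), "samples\n")
  cat("tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  tab <- table(x$samples$role)
  cat("roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix and its sample manifest
#'
#' Reads a TSV expression matrix (first column `gene_id`, remaining
#' columns one per sample) together with a TSV sample manifest, checks
#' that the two agree, and returns a validated [expression_dataset()].
#' Gene rows containing any missing value are dropped and reported via
#' a message; non-numeric cells that are not missing raise an error
#' naming the offending row and column.
#'
#' @param matrix_path Path to the expression TSV. Values are assumed to
#'   be on the log2 scale unless `log2_transform = TRUE`.
#' @param manifest_path Path to the manifest TSV with columns
#'   `sample_id`, `role`, `tissue`, `generation`, `replicate`.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to linear-scale
#'   input values.
#' @return An `ExpressionDataset`.
#' @export
read_expression <- function(matrix_path, manifest_path, log2_transform = FALSE) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (ncol(raw) < 2L) stop("expression matrix needs a gene_id column plus samples")
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene_id: ", paste(dup, collapse = ", "))
  }
  sample_ids <- names(raw)[-1L]
  manifest <- utils::read.delim(manifest_path, header = TRUE, sep = "\t",
                                colClasses = "character", check.names = FALSE)
  manifest <- validate_manifest(manifest)

  missing_from_matrix <- setdiff(manifest$sample_id, sample_ids)
  missing_from_manifest <- setdiff(sample_ids, manifest$sample_id)
  if (length(missing_from_matrix) || length(missing_from_manifest)) {
    stop("sample mismatch; ",
         if (length(missing_from_matrix))
           paste0("in manifest but absent from matrix: ",
                  paste(missing_from_matrix, collapse = ", ")),
         if (length(missing_from_matrix) && length(missing_from_manifest)) "; ",
         if (length(missing_from_manifest))
           paste0("in matrix but absent from manifest: ",
                  paste(missing_from_manifest, collapse = ", ")))
  }

  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  missing_tokens <- c("", "NA", "na", "NaN", "nan")
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    is_missing <- col %in% missing_tokens
    parsed <- suppressWarnings(as.numeric(col))
    bad <- !is_missing & is.na(parsed)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric value '", col[i], "' at gene ", gene_ids[i],
           ", sample ", sample_ids[j])
    }
    vals[, j] <- parsed
  }
  keep <- stats::complete.cases(vals)
  if (any(!keep)) {
    dropped <- gene_ids[!keep]
    message("read_expression: dropped ", length(dropped),
            " gene(s) with missing values: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ...")
    vals <- vals[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  if (log2_transform) vals <- log2(vals + 1)
  expression_dataset(vals, manifest, gene_ids = gene_ids)
}

#' Read a homeolog allele-fraction table
#'
#' Reads a TSV with columns `gene_id`, `sample_id`, `a_fraction` giving
#' the A-subgenome share of a gene's transcript pool per sample, the
#' quantity measured by locus-specific cDNA pyrosequencing. The scale is
#' auto-detected: if any value exceeds 1 the column is taken to be
#' percent and divided by 100 (detection is recorded via a message).
#' A file whose values straddle 1 is rejected as ambiguous.
#'
#' @param path Path to the TSV.
#' @return A data frame of class `HomeologTable` with columns `gene_id`,
#'   `sample_id`, `a_fraction` (proportion in \[0, 1\]).
#' @export
read_homeolog <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("gene_id", "sample_id", "a_fraction")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("homeolog table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  frac <- suppressWarnings(as.numeric(raw$a_fraction))
  if (any(is.na(frac))) {
    i <- which(is.na(frac))[1L]
    stop("non-numeric a_fraction '", raw$a_fraction[i], "' at row ", i)
  }
  if (any(frac < 0 | frac > 100)) {
    i <- which(frac < 0 | frac > 100)[1L]
    stop("a_fraction out of range [0, 100]: ", frac[i], " at row ", i)
  }
  if (max(frac) > 1) {
    if (min(frac) <= 1) {
      stop("ambiguous a_fraction scale: values both above and at-or-below 1 ",
           "(mixing percent and proportion conventions?)")
    }
    message("read_homeolog: values interpreted as percent (max ",
            format(max(frac)), " > 1); divided by 100")
    frac <- frac / 100
  }
  homeolog_table(data.frame(gene_id = raw$gene_id, sample_id = raw$sample_id,
                            a_fraction = frac, stringsAsFactors = FALSE))
}

#' @rdname read_homeolog
#' @param records Data frame with columns `gene_id`, `sample_id`,
#'   `a_fraction` already on the proportion scale.
#' @export
homeolog_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "a_fraction")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("homeolog table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  records$gene_id <- as.character(records$gene_id)
  records$sample_id <- as.character(records$sample_id)
  records$a_fraction <- as.numeric(records$a_fraction)
  if (any(!is.finite(records$a_fraction)) ||
      any(records$a_fraction < 0 | records$a_fraction > 1)) {
    stop("a_fraction must lie in [0, 1]")
  }
  class(records) <- c("HomeologTable", "data.frame")
  records
}

# Column order and type registry for the call tables, so that
# write_calls/read_calls are an exact round trip.
CALL_SCHEMAS <- list(
  gene_category = list(
    cols = c("tissue", "generation", "gene_id", "parental_status",
             "ped_direction", "additivity", "pattern", "mpv"),
    numeric = "mpv", logical = character(0)
  ),
  partitioning = list(
    cols = c("tissue", "generation", "gene_id", "expression_class", "altered",
             "outcome", "mix_mean_fraction", "poly_mean_fraction", "p_altered",
             "mix_biased", "poly_biased"),
    numeric = c("mix_mean_fraction", "poly_mean_fraction", "p_altered"),
    logical = c("altered", "mix_biased", "poly_biased")
  )
)

call_schema_for <- function(calls) {
  for (nm in names(CALL_SCHEMAS)) {
    if (all(CALL_SCHEMAS[[nm]]$cols %in% names(calls))) return(CALL_SCHEMAS[[nm]])
  }
  stop("unrecognized call table: expected the columns of a gene-category ",
       "or partitioning call")
}

#' Write classification calls to a deterministic TSV
#'
#' Calls are sorted by tissue, generation and gene identifier and
#' written with fixed column order and 6-decimal reals, so that two
#' writes of the same collection are byte-identical and
#' [read_calls()] reproduces the collection exactly.
#'
#' @param calls A data frame of gene-category calls (from
#'   [classify_pattern()]) or partitioning calls (from
#'   [call_partitioning()]).
#' @param path Output path.
#' @return Invisibly, the sorted data frame as written.
#' @export
write_calls <- function(calls, path) {
  schema <- call_schema_for(calls)
  out <- as.data.frame(calls, stringsAsFactors = FALSE)[, schema$cols]
  ord <- order(out$tissue, out$generation, out$gene_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  txt <- out
  for (cc in schema$numeric) txt[[cc]] <- sprintf("%.6f", out[[cc]])
  for (cc in schema$logical) txt[[cc]] <- ifelse(out[[cc]], "TRUE", "FALSE")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(schema$cols, collapse = "\t"), con, sep = "\n")
  if (nrow(txt)) {
    lines <- do.call(paste, c(unname(as.list(txt)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  rownames(out) <- NULL
  invisible(out)
}

#' Read back a call table written by [write_calls()]
#'
#' @param path Path to a TSV written by [write_calls()].
#' @return The call data frame with its original column types.
#' @export
read_calls <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  schema <- call_schema_for(raw)
  for (cc in schema$numeric) raw[[cc]] <- as.numeric(raw[[cc]])
  for (cc in schema$logical) raw[[cc]] <- raw[[cc]] == "TRUE"
  raw
}

#' Subset an expression dataset
#'
#' @param dataset An `ExpressionDataset`.
#' @param tissue Optional tissue to retain.
#' @param roles Optional roles to retain.
#' @param genes Optional gene identifiers to retain (input order kept).
#' @return An `ExpressionDataset` restricted to the selection.
#' @export
subset_dataset <- function(dataset, tissue = NULL, roles = NULL, genes = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  keep_s <- rep(TRUE, nrow(dataset$samples))
  if (!is.null(tissue)) keep_s <- keep_s & dataset$samples$tissue %in% tissue
  if (!is.null(roles)) keep_s <- keep_s & dataset$samples$role %in% roles
  keep_g <- if (is.null(genes)) rep(TRUE, length(dataset$gene_ids))
            else dataset$gene_ids %in% genes
  structure(list(gene_ids = dataset$gene_ids[keep_g],
                 samples = dataset$samples[keep_s, , drop = FALSE],
                 values = dataset$values[keep_g, keep_s, drop = FALSE]),
            class = "ExpressionDataset")
}

sample_ids_for <- function(dataset, role, tissue = NULL, generation = NULL) {
  s <- dataset$samples
  keep <- s$role == role
  if (!is.null(tissue)) keep <- keep & s$tissue == tissue
  if (!is.null(generation)) keep <- keep & s$generation == generation
  s$sample_id[keep]
}
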