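#' Paired compartment expression experiment
#'
#' Container for an FPKM-like expression matrix over two tumor compartments
#' — tumor cells (`TC`) and tumor-associated macrophages (`TAM`) — profiled
#' from the same animals, with treatment groups `Veh` (vehicle), `Ep`
#' (endpoint, drug-sensitive) and `Reb` (rebound, drug-resistant). Each
#' animal contributes one TC column and one TAM column linked by a pairing
#' identifier; the pairing is what makes intercellular (TC-TAM) correlations
#' well defined.
#'
#' @param expression Numeric matrix, rows = gene symbols, columns = sample IDs.
#'   Values must be finite and non-negative.
#' @param samples Data frame with one row per column of `expression`:
#'   `sample_id`, `compartment` ("TC"/"TAM"), `group` ("Veh"/"Ep"/"Reb"),
#'   `pair_id` linking each TC column to its TAM counterpart.
#' @param normalized Logical; `TRUE` once values are ratios to the vehicle
#'   group mean (see [vehicle_normalize()]).
#'
#' @return An object of class `compartment_experiment`.
#' @seealso [read_expression_table()], [simulate_mouse_experiment()]
#' @export
compartment_experiment <- function(expression, samples, normalized = FALSE) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    abort("compartment_experiment: expression must be a numeric matrix")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    abort("compartment_experiment: expression needs gene rownames and sample colnames")
  }
  samples <- tibble::as_tibble(samples)
  required <- c("sample_id", "compartment", "group", "pair_id")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("compartment_experiment: samples is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("compartment_experiment: duplicated sample IDs: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!setequal(colnames(expression), samples$sample_id) ||
      ncol(expression) != nrow(samples)) {
    abort("compartment_experiment: expression columns and samples$sample_id must match")
  }
  samples <- samples[match(colnames(expression), samples$sample_id), ]
  if (!all(samples$compartment %in% c("TC", "TAM"))) {
    abort("compartment_experiment: compartment must be 'TC' or 'TAM'")
  }
  if (!all(samples$group %in% c("Veh", "Ep", "Reb"))) {
    abort("compartment_experiment: group must be 'Veh', 'Ep' or 'Reb'")
  }
  if (anyNA(expression) || any(!is.finite(expression))) {
    abort("compartment_experiment: expression values must be finite")
  }
  if (any(expression < 0)) {
    abort("compartment_experiment: expression values must be non-negative")
  }
  # each pairing id must resolve to exactly one TC and one TAM column
  tab <- table(samples$pair_id, samples$compartment)
  if (!all(tab %in% c(0L, 1L)) || any(rowSums(tab) != 2L)) {
    abort("compartment_experiment: every pair_id needs exactly one TC and one TAM column")
  }
  structure(
    list(expression = expression, samples = samples, normalized = normalized),
    class = "compartment_experiment"
  )
}

#' @export
print.compartment_experiment <- function(x, ...) {
  grp <- table(x$samples$group[x$samples$compartment == "TC"])
  cat(sprintf(
    "<compartment_experiment> %d genes x %d samples (%d animals)%s\n",
    nrow(x$expression), ncol(x$expression), nrow(x$samples) / 2,
    if (isTRUE(x$normalized)) ", vehicle-normalized" else ""
  ))
  cat("  animals per group: ",
      paste(names(grp), unname(grp), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# columns of one compartment, optionally restricted to groups, ordered by pair_id
compartment_columns <- function(exp, compartment, groups = NULL) {
  s <- exp$samples
  keep <- s$compartment == compartment
  if (!is.null(groups)) keep <- keep & s$group %in% groups
  s <- s[keep, ]
  s[order(s$pair_id), ]
}

normalize_symbols <- function(x) toupper(trimws(x))

# collapse duplicate gene symbols by mean, preserving first-seen order
collapse_duplicate_genes <- function(mat) {
  sym <- normalize_symbols(rownames(mat))
  if (!anyDuplicated(sym)) {
    rownames(mat) <- sym
    return(mat)
  }
  n_dup <- sum(duplicated(sym))
  mcg_log("collapsing ", n_dup, " duplicate gene symbol rows by mean")
  out <- rowsum(mat, group = sym, reorder = FALSE) /
    as.vector(table(factor(sym, levels = unique(sym))))
  out
}

#' Read an expression table with sample metadata
#'
#' Reads a delimited (TSV/CSV, inferred from the extension) gene-by-sample
#' expression table whose first column holds gene symbols and whose header
#' row holds sample IDs. For `schema = "compartment-experiment"` a `groups`
#' table (columns `sample_id`, `compartment`, `group`, `pair_id`) describes
#' the columns; for `schema = "cohort"` see [read_cohort()]. Gene symbols are
#' uppercased and whitespace-stripped; duplicate symbols are collapsed by
#' mean with a logged count.
#'
#' @param path Path to the delimited expression table.
#' @param schema Either `"compartment-experiment"` or `"matrix"` (the bare
#'   validated matrix, used internally by [read_cohort()]).
#' @param groups Data frame or path to a delimited table of per-sample
#'   metadata (required for the compartment-experiment schema).
#'
#' @return A [compartment_experiment()] or a numeric matrix.
#' @export
read_expression_table <- function(path,
                                  schema = c("compartment-experiment", "matrix"),
                                  groups = NULL) {
  schema <- match.arg(schema)
  mat <- read_gene_matrix(path)
  if (schema == "matrix") return(mat)
  if (is.null(groups)) {
    abort("read_expression_table: a groups table is required for schema 'compartment-experiment'")
  }
  if (is.character(groups)) groups <- read_delim_table(groups)
  compartment_experiment(mat, groups)
}

read_delim_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tibble::as_tibble(utils::read.table(
    path, header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\""
  ))
}

read_gene_matrix <- function(path) {
  df <- read_delim_table(path)
  if (ncol(df) < 2) abort(paste0("expression table has no sample columns: ", path))
  ids <- names(df)[-1]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicated sample column ID(s) in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  genes <- as.character(df[[1]])
  vals <- df[-1]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("non-numeric expression column(s) in ", path, ": ",
                 paste(non_num, collapse = ", ")))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes
  collapse_duplicate_genes(mat)
}

#' Write an expression matrix (or experiment) to TSV
#'
#' Inverse of [read_expression_table()]: a `gene` first column, one column
#' per sample. For a [compartment_experiment()] the sample metadata can be
#' written alongside.
#'
#' @param x Matrix or `compartment_experiment`.
#' @param path Output TSV path.
#' @param groups_path Optional path for the sample-metadata TSV (experiment
#'   input only).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, groups_path = NULL) {
  mat <- if (inherits(x, "compartment_experiment")) x$expression else x
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    if (!inherits(x, "compartment_experiment")) {
      abort("write_expression_table: groups_path requires a compartment_experiment")
    }
    utils::write.table(x$samples, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
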