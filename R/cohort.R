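#' Patient survival cohort
#'
#' Container for a gene-by-patient expression matrix joined to clinical
#' follow-up: survival time, event indicator, age, gender, grade, therapy
#' flags and optional mutation/subtype annotations. Patients are kept only
#' if they appear in both the expression and the clinical table (matching by
#' patient ID), and patients missing survival time or event status are
#' dropped with a logged count.
#'
#' @param expression Numeric matrix, rows = gene symbols, columns = patient
#'   IDs.
#' @param clinical Data frame with `patient_id`, `time` (> 0, in `time_unit`),
#'   `event` (1 = death, 0 = censored) and any of: `age`, `gender`
#'   ("Male"/"Female"), `grade` ("low"/"high"), `targeted_therapy`,
#'   `pharmaceutical`, `radiotherapy` ("yes"/"no"/"unknown"), plus optional
#'   annotation columns (e.g. `idh1_status`, `cimp_status`, `egfr_status`,
#'   `pten_status`, `subtype`).
#' @param time_unit Unit of `time`: "years", "months" or "days". Horizons
#'   given in years are converted internally.
#'
#' @return An object of class `cohort`.
#' @seealso [read_cohort()], [simulate_cohort()]
#' @export
cohort <- function(expression, clinical, time_unit = c("years", "months", "days")) {
  time_unit <- match.arg(time_unit)
  if (!is.matrix(expression) || !is.numeric(expression)) {
    abort("cohort: expression must be a numeric matrix")
  }
  expression <- collapse_duplicate_genes(expression)
  clinical <- tibble::as_tibble(clinical)
  for (col in c("patient_id", "time", "event")) {
    if (!col %in% names(clinical)) {
      abort(paste0("cohort: clinical table is missing column '", col, "'"))
    }
  }
  dup <- unique(clinical$patient_id[duplicated(clinical$patient_id)])
  if (length(dup) > 0) {
    abort(paste0("cohort: duplicated patient ID(s): ", paste(dup, collapse = ", ")))
  }

  ids_expr <- colnames(expression)
  ids_clin <- clinical$patient_id
  shared <- intersect(ids_expr, ids_clin)
  n_drop_expr <- length(setdiff(ids_expr, shared))
  n_drop_clin <- length(setdiff(ids_clin, shared))
  if (length(shared) == 0) {
    abort("cohort: no patient IDs shared between expression and clinical tables")
  }
  if (n_drop_expr + n_drop_clin > 0) {
    mcg_log("cohort: keeping ", length(shared), " patients present in both tables (",
            n_drop_expr, " expression-only, ", n_drop_clin, " clinical-only dropped)")
  }
  clinical <- clinical[match(shared, clinical$patient_id), ]
  expression <- expression[, shared, drop = FALSE]

  usable <- is.finite(clinical$time) & clinical$time > 0 &
    clinical$event %in% c(0, 1)
  if (any(!usable)) {
    mcg_log("cohort: dropping ", sum(!usable),
            " patients with missing/invalid survival time or event")
    clinical <- clinical[usable, ]
    expression <- expression[, usable, drop = FALSE]
  }
  if (nrow(clinical) == 0) abort("cohort: no patients with usable follow-up")

  structure(
    list(expression = expression, clinical = clinical, time_unit = time_unit,
         dropped = c(expression_only = n_drop_expr, clinical_only = n_drop_clin,
                     bad_followup = sum(!usable))),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d genes x %d patients, %d events, time in %s\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$clinical$event), x$time_unit))
  invisible(x)
}

n_patients <- function(ch) ncol(ch$expression)

# horizons are expressed in years throughout the user API
horizon_in_unit <- function(horizon_years, time_unit) {
  switch(time_unit,
         years = horizon_years,
         months = horizon_years * 12,
         days = horizon_years * 365.25)
}

#' Read a patient cohort from expression + clinical tables
#'
#' The expression table follows the gene-by-patient layout of
#' [read_expression_table()]; the clinical sidecar is keyed by `patient_id`.
#' The cohort keeps exactly the patient-ID intersection of the two tables
#' and logs dropped counts.
#'
#' @param expression_path Path to the delimited expression table.
#' @param clinical_path Path to the delimited clinical table.
#' @param time_unit Unit of the clinical `time` column.
#' @return A [cohort()].
#' @export
read_cohort <- function(expression_path, clinical_path,
                        time_unit = c("years", "months", "days")) {
  mat <- read_expression_table(expression_path, schema = "matrix")
  clin <- read_delim_table(clinical_path)
  cohort(mat, clin, time_unit = match.arg(time_unit))
}

#' Write a cohort to a pair of TSV files
#'
#' @param ch A [cohort()].
#' @param expression_path,clinical_path Output TSV paths.
#' @return `expression_path`, invisibly.
#' @export
write_cohort <- function(ch, expression_path, clinical_path) {
  write_expression_table(ch$expression, expression_path)
  utils::write.table(ch$clinical, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expression_path)
}

# restrict a cohort to a patient subset (character ids or logical/integer index)
subset_cohort <- function(ch, which) {
  if (is.character(which)) which <- match(which, ch$clinical$patient_id)
  structure(
    list(expression = ch$expression[, which, drop = FALSE],
         clinical = ch$clinical[which, ],
         time_unit = ch$time_unit,
         dropped = ch$dropped),
    class = "cohort"
  )
}
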