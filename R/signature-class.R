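#' Gene signature: a gene-to-coefficient risk score
#'
#' A signature is an ordered set of (gene, coefficient) terms defining the
#' linear risk score RS = sum over genes of beta_g * expression_g, plus fit
#' metadata (the penalty lambda when the signature came from a penalized Cox
#' fit, and the learning-set label). An optional per-gene compartment tag
#' records whether the gene entered the differential network through the
#' macrophage or the tumor-cell compartment.
#'
#' @param terms Data frame with columns `gene`, `beta` and optionally
#'   `compartment`; or a named numeric vector of coefficients.
#' @param name Signature label.
#' @param lambda Optimal penalty, if penalized fitting produced the terms.
#' @param learning_set Label of the cohort the coefficients were fit on.
#'
#' @return An object of class `gene_signature`.
#' @export
#' @examples
#' sig <- gene_signature(c(FANCA = 1.18, SCN3A = -0.88), name = "toy")
#' sig
gene_signature <- function(terms, name = "signature", lambda = NULL,
                           learning_set = NULL) {
  if (is.numeric(terms) && !is.null(names(terms))) {
    terms <- tibble::tibble(gene = names(terms), beta = unname(terms))
  }
  terms <- tibble::as_tibble(terms)
  if (!all(c("gene", "beta") %in% names(terms))) {
    abort("gene_signature: terms need columns 'gene' and 'beta'")
  }
  if (nrow(terms) == 0) abort("gene_signature: a signature needs at least one term")
  terms$gene <- normalize_symbols(terms$gene)
  dup <- unique(terms$gene[duplicated(terms$gene)])
  if (length(dup) > 0) {
    abort(paste0("gene_signature: duplicate gene(s): ", paste(dup, collapse = ", ")))
  }
  if (!all(is.finite(terms$beta))) abort("gene_signature: coefficients must be finite")
  if (!is.null(lambda)) {
    if (!is.numeric(lambda) || lambda <= 0) abort("gene_signature: lambda must be > 0")
  }
  structure(
    list(name = name, terms = terms, lambda = lambda,
         log_lambda = if (is.null(lambda)) NULL else log(lambda),
         learning_set = learning_set),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s': %d terms", x$name, nrow(x$terms)))
  if (!is.null(x$lambda)) {
    cat(sprintf(" (lambda = %.8g, ln lambda = %.6g)", x$lambda, x$log_lambda))
  }
  cat("\n")
  print(x$terms, n = 12)
  invisible(x)
}

#' @method tidy gene_signature
#' @export
#' @rdname gene_signature
#' @param x A `gene_signature`.
#' @param ... Unused.
tidy.gene_signature <- function(x, ...) x$terms

#' Write / read a gene signature as JSON
#'
#' Lossless round-trip of a [gene_signature()] through JSON; coefficients are
#' serialized at full double precision.
#'
#' @param sig A [gene_signature()].
#' @param path File path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   returns the signature.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  payload <- list(
    name = sig$name,
    terms = sig$terms,
    lambda = sig$lambda,
    log_lambda = sig$log_lambda,
    learning_set = sig$learning_set
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("read_signature: cannot parse ", path,
                                     ": ", conditionMessage(e)))
  )
  if (is.null(payload$terms)) {
    abort(paste0("read_signature: no 'terms' field in ", path))
  }
  gene_signature(tibble::as_tibble(payload$terms),
                 name = payload$name %||% "signature",
                 lambda = payload$lambda,
                 learning_set = payload$learning_set)
}

#' Published reference signatures
#'
#' `signature_macrophage()` returns the fixed 12-gene macrophage-related
#' signature with its published Cox coefficients (five macrophage-compartment
#' genes, seven tumor-cell genes). The remaining reference sets are shipped
#' as gene lists without coefficients — `signature_genes_cheng()` (an
#' 8-gene immune-related signature), `signature_genes_egfr()` (the
#' single-gene EGFR signature) and `signature_genes_igf1()` (22 genes from
#' IGF1/IGF1R-mediated macrophage-glioma signaling) — their coefficients are
#' conventionally obtained by an unpenalized Cox refit on a learning cohort
#' via [refit_signature()].
#'
#' @return `signature_macrophage()`: a [gene_signature()]; the `signature_genes_*()`
#'   helpers: character vectors of gene symbols.
#' @export
signature_macrophage <- function() {
  terms <- tibble::tibble(
    gene = c("ANPEP", "DPP4", "PRRG1", "GPNMB", "TMEM26",
             "PXDN", "CDH6", "SCN3A", "SEMA6B", "CCDC37", "FANCA", "NETO2"),
    beta = c(0.001695826, 0.001351164, 0.828492221, 0.002693736, 0.572250065,
             0.011112329, 0.000861924, -0.877296902, -0.042307865,
             0.019673956, 1.184362541, 0.101032334),
    compartment = c(rep("MP", 5), rep("TC", 7))
  )
  gene_signature(terms, name = "macrophage_12gene", lambda = 0.06226413,
                 learning_set = "published")
}

#' @rdname signature_macrophage
#' @export
signature_genes_cheng <- function() {
  c("FOXO3", "IL6", "IL10", "ZBTB16", "CCL18", "AIMP1", "FCGR2B", "MMP9")
}

#' @rdname signature_macrophage
#' @export
signature_genes_egfr <- function() "EGFR"

#' @rdname signature_macrophage
#' @export
signature_genes_igf1 <- function() {
  c("PIK3R1", "PIK3R2", "PIK3R3", "PIK3R4", "PIK3R5", "PIK3R6", "PIK3AP1",
    "AKT1", "AKT2", "AKT3", "IGF1", "IGF1R", "IL4", "IL4R",
    "NFATC1", "NFATC2", "NFATC3", "NFATC4", "NFAT5", "STAT6", "CSF1", "CSF1R")
}
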