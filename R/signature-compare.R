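#' Weighted module score of a gene signature
#'
#' The module score of a signature in one sample is
#' `sum(w_i * e_i) / sum(w_i)` over the signature genes present in the
#' sample. Genes absent from the sample are dropped (a message reports the
#' count). For signatures with signed weights the literal denominator can
#' vanish; `denominator = "abs"` divides by `sum(|w_i|)` instead.
#'
#' @param sample_expr Named numeric vector: one sample's expression.
#' @param sig Data frame with columns `gene_id` and `weight` (a
#'   `SignatureDefinition`).
#' @param denominator `"literal"` (default, the printed formula) or
#'   `"abs"`.
#' @return A single number.
#' @export
#' @examples
#' module_score(c(a = 2, b = 4), data.frame(gene_id = c("a", "b"), weight = c(1, 1)))
module_score <- function(sample_expr, sig, denominator = c("literal", "abs")) {
  denominator <- match.arg(denominator)
  if (!is.data.frame(sig) || !all(c("gene_id", "weight") %in% names(sig))) {
    abort("`sig` must have columns gene_id and weight.")
  }
  if (nrow(sig) == 0L) abort("Signature has no entries.")
  if (any(!is.finite(sig$weight))) abort("Signature weights must be finite.")
  if (is.null(names(sample_expr))) abort("`sample_expr` must be named by gene id.")
  present <- sig$gene_id %in% names(sample_expr)
  n_missing <- sum(!present)
  if (!any(present)) abort("No signature gene is present in the sample.")
  if (n_missing > 0L) {
    inform(sprintf("module_score: %d of %d signature genes missing; dropped.",
                   n_missing, nrow(sig)))
  }
  w <- sig$weight[present]
  e <- unname(sample_expr[sig$gene_id[present]])
  den <- if (denominator == "abs") sum(abs(w)) else sum(w)
  if (den == 0) {
    abort("Zero weight sum for this signature; use denominator = 'abs' for signed weights.")
  }
  sum(w * e) / den
}

#' Unweighted mean expression of a gene list
#'
#' Used by comparator signatures defined as the average expression of a
#' fixed gene list (for example a 9-gene cell-cycle list or a 48-gene
#' stromal list). Missing genes are dropped with a warning.
#'
#' @param sample_expr Named numeric vector.
#' @param gene_list Character vector of gene ids.
#' @return A single number.
#' @export
mean_expression_score <- function(sample_expr, gene_list) {
  if (length(gene_list) == 0L) abort("`gene_list` is empty.")
  present <- gene_list %in% names(sample_expr)
  if (!any(present)) abort("No listed gene is present in the sample.")
  if (any(!present)) {
    warn(sprintf("mean_expression_score: %d of %d genes missing; dropped.",
                 sum(!present), length(gene_list)))
  }
  mean(unname(sample_expr[gene_list[present]]))
}

# (x - median) / IQR with a type-2 quantile convention, so the rescaled
# vector has median 0 and inter-quartile range 1.
rescale_iqr <- function(x, what = "component") {
  if (length(x) < 4L) abort("At least 4 samples are needed to define the IQR.")
  q <- unname(quantile(x, c(0.25, 0.75), type = 2, names = FALSE))
  iqr <- q[2L] - q[1L]
  if (iqr == 0) abort(sprintf("Zero IQR in %s; cannot rescale.", what))
  (x - median(x)) / iqr
}

#' Consensus signature score (immune + proliferation + regulator)
#'
#' Combines a STAT1 immune module score with TOP2A and LAPTM4B expression:
#' each cohort-level vector is rescaled to median 0 and inter-quartile
#' range 1, and the per-sample score is the sum of the three rescaled
#' values.
#'
#' @param cohort_module Numeric vector of module scores across samples.
#' @param top2a,laptm4b Numeric expression vectors across the same samples.
#' @return Numeric vector of per-sample consensus scores.
#' @export
consensus_score <- function(cohort_module, top2a, laptm4b) {
  n <- length(cohort_module)
  if (length(top2a) != n || length(laptm4b) != n) {
    abort("All three component vectors must have the same length.")
  }
  rescale_iqr(cohort_module, "the module-score component") +
    rescale_iqr(top2a, "TOP2A expression") +
    rescale_iqr(laptm4b, "LAPTM4B expression")
}

#' Microenvironment-module composite score with Her2-dependent terms
#'
#' Sums an immune-response module and a stromal module; for Her2-positive
#' samples a TOP2A (proliferation) module is added as a third term. Each
#' module is evaluated with [module_score()].
#'
#' @param sample_expr Named numeric vector.
#' @param her2_status `"positive"` or `"negative"` (anything else errors).
#' @param immune_sig,stroma_sig,top2a_sig Signature data frames
#'   (`gene_id`, `weight`).
#' @param ... Passed on to [module_score()].
#' @return A single number.
#' @export
desmedt_score <- function(sample_expr, her2_status, immune_sig, stroma_sig,
                          top2a_sig, ...) {
  if (!her2_status %in% c("positive", "negative")) {
    abort(sprintf("her2_status must be 'positive' or 'negative', got '%s'.", her2_status))
  }
  s <- module_score(sample_expr, immune_sig, ...) +
    module_score(sample_expr, stroma_sig, ...)
  if (her2_status == "positive") {
    s <- s + module_score(sample_expr, top2a_sig, ...)
  }
  s
}

#' Metagene-difference score (mitotic minus ceramide)
#'
#' The paclitaxel-response-style metagene: the difference between a mitotic
#' module score and a ceramide-metabolism module score.
#'
#' @param sample_expr Named numeric vector.
#' @param mitotic_sig,ceramide_sig Signature data frames (`gene_id`,
#'   `weight`).
#' @param ... Passed on to [module_score()].
#' @return A single number.
#' @export
metagene_difference_score <- function(sample_expr, mitotic_sig, ceramide_sig, ...) {
  module_score(sample_expr, mitotic_sig, ...) -
    module_score(sample_expr, ceramide_sig, ...)
}

#' Read signature definitions from TSV
#'
#' @param path TSV with columns `name`, `gene_id`, `weight`.
#' @return A named list of signature tibbles (`gene_id`, `weight`).
#' @export
read_signature_definitions <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(), gene_id = readr::col_character(),
    weight = readr::col_double()), progress = FALSE, show_col_types = FALSE)
  if (!all(c("name", "gene_id", "weight") %in% names(df))) {
    abort(sprintf("'%s' must have columns name, gene_id, weight.", path))
  }
  split(tibble::as_tibble(df[c("gene_id", "weight")]), df$name)
}

#' Module scores for a whole cohort
#'
#' @param m Genes x samples numeric matrix.
#' @param signatures Named list of signature data frames (`gene_id`,
#'   `weight`), e.g. from [read_signature_definitions()].
#' @param ... Passed on to [module_score()].
#' @return A tibble: `sample_id` plus one column per signature.
#' @export
cohort_module_scores <- function(m, signatures, ...) {
  check_expression_matrix(m)
  if (is.null(names(signatures)) || any(names(signatures) == "")) {
    abort("`signatures` must be a named list.")
  }
  out <- tibble::tibble(sample_id = colnames(m))
  for (nm in names(signatures)) {
    out[[nm]] <- unname(suppressMessages(
      vapply(colnames(m), function(s) module_score(m[, s], signatures[[nm]], ...),
             numeric(1))
    ))
  }
  out
}
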