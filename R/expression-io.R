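#' Read a gene- or probe-level expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene (or probe) ids
#' and whose remaining columns are samples, with a header row of sample ids.
#' Values are log2-scale intensities (RMA-style); no re-logging is performed.
#'
#' @param path Path to a TSV file.
#' @param dialect `"gene_level"` (default; duplicate ids are an error) or
#'   `"probe_level"` (duplicate probe ids are still an error, but the ids are
#'   interpreted as probes to be collapsed later with [collapse_probes()]).
#' @return A numeric matrix (rows = genes or probes, columns = samples) with
#'   dimnames set.
#' @seealso [collapse_probes()], [quantile_normalize()], [adjust_batches()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "TP53\t5.1\t6.2", "MKI67\t7.0\t7.4"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path, dialect = c("gene_level", "probe_level")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  if (nrow(df) == 0L) abort(sprintf("'%s' has no data rows.", path))
  if (ncol(df) < 2L) abort(sprintf("'%s' has no sample columns (malformed header?).", path))
  ids <- as.character(df[[1L]])
  vals <- df[-1L]
  not_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(not_num)) {
    abort(sprintf("Non-numeric expression values in column '%s' of '%s'.",
                  not_num[1L], path))
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    kind <- if (dialect == "gene_level") "gene" else "probe"
    abort(sprintf("Duplicated %s id '%s' in '%s'.", kind, dup, path))
  }
  if (anyDuplicated(names(vals))) {
    abort(sprintf("Duplicated sample id '%s' in '%s'.",
                  names(vals)[duplicated(names(vals))][1L], path))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) abort(sprintf("Missing expression values in '%s'.", path))
  m
}

#' Write an expression matrix to TSV
#'
#' @param m Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @param id_column Name for the first column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  check_expression_matrix(m)
  df <- tibble::tibble(!!id_column := rownames(m))
  df <- dplyr::bind_cols(df, tibble::as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map from TSV
#'
#' @param path TSV with columns `probe_id` and `gene_id`.
#' @return A tibble with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    abort(sprintf("'%s' must have columns probe_id and gene_id.", path))
  }
  if (anyDuplicated(df$probe_id)) {
    abort(sprintf("Probe '%s' is mapped more than once in '%s'.",
                  df$probe_id[duplicated(df$probe_id)][1L], path))
  }
  tibble::as_tibble(df[c("probe_id", "gene_id")])
}

#' Read a per-sample clinical annotation table from TSV
#'
#' Columns: `sample_id`, `response` (pCR/RD, may be unknown for samples not
#' used in training or evaluation), `er_status`, `pr_status`, `her2_status`
#' (positive/negative/unknown), `stage` (I-IV/unknown), `grade`
#' (I-III/unknown), `age` (years), `batch` (cohort label). Missing
#' categorical entries are encoded as explicit `"unknown"`, never imputed.
#'
#' @param path TSV path.
#' @return A tibble, one row per sample.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  req <- c("sample_id", "response", "er_status", "pr_status", "her2_status",
           "stage", "grade", "age", "batch")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(sprintf("'%s' lacks annotation column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("Duplicated sample_id '%s' in '%s'.",
                  df$sample_id[duplicated(df$sample_id)][1L], path))
  }
  tibble::tibble(
    sample_id = df$sample_id,
    response = enum_or_unknown(df$response, c("pCR", "RD"), "response"),
    er_status = enum_or_unknown(df$er_status, c("positive", "negative"), "er_status"),
    pr_status = enum_or_unknown(df$pr_status, c("positive", "negative"), "pr_status"),
    her2_status = enum_or_unknown(df$her2_status, c("positive", "negative"), "her2_status"),
    stage = enum_or_unknown(df$stage, c("I", "II", "III", "IV"), "stage"),
    grade = enum_or_unknown(df$grade, c("I", "II", "III"), "grade"),
    age = suppressWarnings(as.numeric(df$age)),
    batch = as.character(df$batch)
  )
}

#' Collapse a probe-level matrix to gene level
#'
#' For genes interrogated by several probesets, the probeset with the
#' largest mean expression across samples represents the gene; its values
#' are retained verbatim. Probes without a gene mapping are dropped. Ties in
#' mean expression are broken toward the lexicographically smaller probe id
#' so the collapse is deterministic.
#'
#' @param pm Probes x samples numeric matrix (rownames = probe ids).
#' @param probe_map Data frame with columns `probe_id`, `gene_id`.
#' @return A genes x samples matrix, rows ordered by gene id.
#' @export
collapse_probes <- function(pm, probe_map) {
  check_expression_matrix(pm, arg = "pm")
  if (!is.data.frame(probe_map) || !all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` must have columns probe_id and gene_id.")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    abort("`probe_map` maps some probe to more than one gene.")
  }
  map <- probe_map[probe_map$probe_id %in% rownames(pm), , drop = FALSE]
  if (nrow(map) == 0L) abort("No probe in the matrix has a gene mapping.")
  means <- rowMeans(pm)[map$probe_id]
  picked <- tibble::tibble(probe_id = map$probe_id, gene_id = map$gene_id,
                           mean_expr = unname(means)) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$mean_expr), .data$probe_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  out <- pm[picked$probe_id, , drop = FALSE]
  rownames(out) <- picked$gene_id
  out
}

#' Quantile-normalize an expression matrix
#'
#' Rescales every sample so its empirical distribution equals the
#' across-sample mean of sorted value vectors, preserving within-sample
#' ranks; within-sample ties receive the mean of the reference values at the
#' tied ranks (the limma convention).
#'
#' @param m Genes x samples numeric matrix, at least 2 samples, no missing
#'   values.
#' @return The normalized matrix (same dimnames).
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m, min_samples = 2L)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Remove batch effects from an expression matrix
#'
#' @param m Genes x samples numeric matrix.
#' @param annotations Data frame with `sample_id` and `batch` covering every
#'   sample in `m`.
#' @param method `"eb"` (default) applies the parametric empirical-Bayes
#'   location-scale adjustment of ComBat (via the sva package);
#'   `"center_scale"` applies the direct per-gene location-scale formula
#'   without shrinkage (each batch recentred and rescaled to the pooled
#'   per-gene moments); `"none"` returns the input.
#' @return The adjusted matrix. Dimensions, dimnames, and gene order are
#'   preserved; for balanced batches the per-gene pooled mean is preserved.
#' @details Every batch must contain at least 2 samples and there must be at
#'   least 2 batches; merge or exclude singleton batches first.
#' @export
adjust_batches <- function(m, annotations, method = c("eb", "center_scale", "none")) {
  method <- match.arg(method)
  check_expression_matrix(m, min_samples = 2L)
  if (!all(c("sample_id", "batch") %in% names(annotations))) {
    abort("`annotations` must have columns sample_id and batch.")
  }
  idx <- match(colnames(m), annotations$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("Sample '%s' has no annotation row.", colnames(m)[which(is.na(idx))[1L]]))
  }
  batch <- as.character(annotations$batch[idx])
  if (method == "none") return(m)
  tab <- table(batch)
  if (length(tab) < 2L) {
    abort("Batch adjustment needs at least 2 batches; pass method = 'none' for a single cohort.")
  }
  if (any(tab < 2L)) {
    abort(sprintf(
      "Batch '%s' has a single sample; merge it into another batch or exclude it.",
      names(tab)[tab < 2L][1L]))
  }
  if (method == "eb") {
    out <- suppressMessages(sva::ComBat(dat = m, batch = batch, par.prior = TRUE,
                                        prior.plots = FALSE))
    dimnames(out) <- dimnames(m)
    return(out)
  }
  # center_scale: per gene, map each batch onto the pooled location/scale.
  out <- m
  grand_mean <- rowMeans(m)
  pooled_sd <- apply(m, 1L, sd)
  for (b in names(tab)) {
    cols <- which(batch == b)
    sub <- m[, cols, drop = FALSE]
    b_mean <- rowMeans(sub)
    b_sd <- apply(sub, 1L, sd)
    scale <- ifelse(b_sd > 0 & pooled_sd > 0, pooled_sd / b_sd, 1)
    out[, cols] <- (sub - b_mean) * scale + grand_mean
  }
  out
}
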