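#' Fit a per-gene logistic regression of response on expression
#'
#' Fits `logit P(pCR) = beta0 + beta1 * expr` by maximum likelihood and
#' reports the Wald two-sided p-value for `beta1`. With a univariate
#' predictor, complete or quasi-complete separation (the two classes'
#' expression ranges do not overlap) means the MLE does not exist; such fits
#' are flagged `converged = FALSE` and their coefficients/p-values must not
#' be used. A constant predictor carries no signal and returns
#' `beta1 = 0, p = 1`.
#'
#' @param expr Numeric vector of one gene's expression across samples.
#' @param labels Response labels: `"pCR"`/`"RD"`, or 1/0 (pCR = 1).
#' @param gene_id Optional identifier carried into the result.
#' @return A one-row tibble: `gene_id`, `beta0`, `beta1`, `p_value`,
#'   `converged`.
#' @export
#' @examples
#' fit_gene_logistic(c(3.1, 1.0, 2.2, 2.0, 3.0, 1.2), c(1, 0, 1, 0, 1, 0))
fit_gene_logistic <- function(expr, labels, gene_id = NA_character_) {
  y <- as_response01(labels)
  if (length(expr) != length(y)) abort("`expr` and `labels` differ in length.")
  if (length(y) < 4L) abort("At least 4 samples are required for a per-gene fit.")
  if (length(unique(y)) < 2L) abort("Both response classes (pCR and RD) must be present.")
  if (anyNA(expr)) abort("`expr` contains missing values.")

  row <- function(b0, b1, p, conv) {
    tibble::tibble(gene_id = gene_id, beta0 = b0, beta1 = b1,
                   p_value = p, converged = conv)
  }
  if (isTRUE(all.equal(var(expr), 0)) || var(expr) == 0) {
    # no-signal gene: slope is exactly 0 and the test carries no evidence
    return(row(stats::qlogis(mean(y)), 0, 1, TRUE))
  }
  x1 <- expr[y == 1L]
  x0 <- expr[y == 0L]
  separated <- min(x1) >= max(x0) || max(x1) <= min(x0)

  X <- cbind(`(Intercept)` = 1, expr = expr)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- fit$coefficients
  # Wald SE from the final IRLS weights, as summary.glm computes it
  XtWX <- crossprod(X * sqrt(fit$weights))
  se <- tryCatch(sqrt(diag(chol2inv(chol(XtWX)))), error = function(e) rep(NA_real_, 2L))
  z <- beta[2L] / se[2L]
  p <- 2 * pnorm(-abs(z))
  conv <- isTRUE(fit$converged) && !separated && all(is.finite(se))
  p <- if (conv) max(min(p, 1), .Machine$double.xmin) else NA_real_
  row(unname(beta[1L]), unname(beta[2L]), p, conv)
}

#' Fit per-gene logistic models for every gene in a cohort
#'
#' @param m Genes x samples numeric matrix (log2 expression).
#' @param annotations Data frame with `sample_id` and `response`; only
#'   samples with a pCR/RD label are used.
#' @param subset Optional named character vector of annotation filters
#'   applied before fitting, e.g.
#'   `c(er_status = "negative", pr_status = "negative", her2_status = "negative")`
#'   restricts training to triple-negative samples.
#' @return A tibble with one row per gene: `gene_id`, `beta0`, `beta1`,
#'   `p_value`, `converged`.
#' @export
fit_gene_stats <- function(m, annotations, subset = NULL) {
  check_expression_matrix(m, min_samples = 4L)
  ann <- dplyr::filter(annotations, .data$sample_id %in% colnames(m))
  if (!is.null(subset)) {
    for (field in names(subset)) {
      if (!field %in% names(ann)) abort(sprintf("Unknown subset field '%s'.", field))
      ann <- ann[ann[[field]] == subset[[field]], , drop = FALSE]
    }
  }
  ann <- dplyr::filter(ann, .data$response %in% c("pCR", "RD"))
  if (nrow(ann) < 4L) abort("Fewer than 4 labelled samples after filtering.")
  y <- as.integer(ann$response == "pCR")
  if (length(unique(y)) < 2L) abort("Both response classes (pCR and RD) must be present.")
  sub <- m[, ann$sample_id, drop = FALSE]
  purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    fit_gene_logistic(sub[i, ], y, gene_id = rownames(sub)[i])
  })
}

#' Build paired up/down weight profiles from per-gene statistics
#'
#' Each converged gene receives a raw weight `-log(p)` assigned to the up
#' profile (`w_plus`) when its slope is positive (higher expression in pCR)
#' or the down profile (`w_minus`) when negative; the other side is zero.
#' Raw weights are trimmed at `trim` to avoid extreme values and then
#' min-max rescaled into \[0, 1\] jointly over the pooled raw weights of
#' both profiles (subtract the pooled minimum, divide by the pooled range),
#' so the two sides stay on a shared scale and zeros remain zero.
#' Non-converged genes get weight 0 on both sides.
#'
#' @param stats Tibble from [fit_gene_stats()] (columns `gene_id`, `beta1`,
#'   `p_value`, `converged`).
#' @param trim Cap on raw `-log(p)` weights (default 10; with base-10 logs
#'   the cap corresponds to p = 1e-10).
#' @param log_base Base of the `-log(p)` transform, `10` (default) or
#'   `exp(1)`.
#' @return A tibble: `gene_id`, `w_plus`, `w_minus`.
#' @export
build_weight_profiles <- function(stats, trim = 10, log_base = 10) {
  req <- c("gene_id", "beta1", "p_value", "converged")
  if (!is.data.frame(stats) || !all(req %in% names(stats))) {
    abort("`stats` must have columns gene_id, beta1, p_value, converged.")
  }
  if (!any(stats$converged)) abort("No gene converged; cannot build weight profiles.")
  if (!is.numeric(trim) || trim <= 0) abort("`trim` must be a positive number.")

  usable <- stats$converged & is.finite(stats$p_value) & stats$p_value > 0
  raw <- ifelse(usable, pmin(-log(stats$p_value, base = log_base), trim), 0)
  raw <- pmax(raw, 0)
  up <- usable & stats$beta1 > 0
  down <- usable & stats$beta1 < 0
  raw_plus <- ifelse(up, raw, 0)
  raw_minus <- ifelse(down, raw, 0)

  pooled <- c(raw_plus, raw_minus)
  rng <- range(pooled)
  denom <- rng[2L] - rng[1L]
  if (denom == 0) {
    # every usable gene has p = 1: an all-zero, signal-free signature
    w_plus <- rep(0, nrow(stats))
    w_minus <- rep(0, nrow(stats))
  } else {
    w_plus <- (raw_plus - rng[1L]) / denom
    w_minus <- (raw_minus - rng[1L]) / denom
  }
  tibble::tibble(gene_id = stats$gene_id, w_plus = w_plus, w_minus = w_minus)
}

#' Build a response-probability-score signature from a labelled cohort
#'
#' Convenience wrapper chaining [fit_gene_stats()] and
#' [build_weight_profiles()]. Restricting `subset` to triple-negative
#' samples reproduces the TNBC-specific signature construction.
#'
#' @inheritParams fit_gene_stats
#' @inheritParams build_weight_profiles
#' @return An object of class `rps_signature`: a list with `gene_stats`
#'   (per-gene fits), `weights` (the paired profiles), and the settings
#'   used. `tidy()` returns the weights, `glance()` a one-row summary.
#' @export
build_rps_signature <- function(m, annotations, subset = NULL, trim = 10, log_base = 10) {
  stats <- fit_gene_stats(m, annotations, subset = subset)
  weights <- build_weight_profiles(stats, trim = trim, log_base = log_base)
  structure(
    list(gene_stats = stats, weights = weights, trim = trim, log_base = log_base,
         n_train = sum(annotations$response %in% c("pCR", "RD")), subset = subset),
    class = "rps_signature"
  )
}

#' @export
print.rps_signature <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<rps_signature> %d genes (%d up-weighted, %d down-weighted, %d non-converged)\n",
    g$n_genes, g$n_up, g$n_down, g$n_nonconverged))
  cat(sprintf("  trim = %g, log base = %g\n", x$trim, x$log_base))
  invisible(x)
}

#' @rdname build_rps_signature
#' @param x An `rps_signature`.
#' @param ... Unused.
#' @method tidy rps_signature
#' @export
tidy.rps_signature <- function(x, ...) x$weights

#' @rdname build_rps_signature
#' @method glance rps_signature
#' @export
glance.rps_signature <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$weights),
    n_up = sum(x$weights$w_plus > 0),
    n_down = sum(x$weights$w_minus > 0),
    n_nonconverged = sum(!x$gene_stats$converged),
    trim = x$trim,
    log_base = x$log_base
  )
}

#' Read / write weight-profile TSVs
#'
#' The on-disk format is a TSV with columns `gene_id`, `w_plus`, `w_minus`.
#'
#' @param path TSV path.
#' @return `read_weight_profiles()`: a validated tibble.
#' @export
read_weight_profiles <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE)
  check_weight_profiles(df, arg = path)
  tibble::as_tibble(df)
}

#' @rdname read_weight_profiles
#' @param weights Tibble with `gene_id`, `w_plus`, `w_minus` (or an
#'   `rps_signature`).
#' @export
write_weight_profiles <- function(weights, path) {
  if (inherits(weights, "rps_signature")) weights <- weights$weights
  check_weight_profiles(weights)
  readr::write_tsv(weights[c("gene_id", "w_plus", "w_minus")], path, progress = FALSE)
  invisible(path)
}
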