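#' Median-center an expression matrix
#'
#' Subtracts each gene's across-sample median from its row, converting
#' absolute log2 intensities to relative expression.
#'
#' @param m Genes x samples numeric matrix, at least 2 samples.
#' @return The centered matrix.
#' @export
median_center <- function(m) {
  check_expression_matrix(m, min_samples = 2L)
  m - apply(m, 1L, median)
}

#' Foreground and background cumulative curves
#'
#' Given one sample's relative-expression profile sorted in descending
#' order and a weight profile aligned to it, computes the two cumulative
#' curves of the modified BASE statistic:
#' `f(i) = sum_{k<=i} e_k w_k / sum_{k<=g} e_k w_k` and
#' `b(i) = sum_{k<=i} e_k (1-w_k) / sum_{k<=g} e_k (1-w_k)`.
#' When highly weighted genes sit among the sample's most expressed genes,
#' `f` accumulates faster than `b`.
#'
#' @param e_sorted Numeric vector, descending. Values must be non-negative
#'   (callers shift median-centered profiles by their minimum first; see
#'   [score_sample()]).
#' @param w Weight vector in \[0, 1\], same length and order as `e_sorted`.
#' @return A list with components `f` and `b`, each of length `g` and
#'   ending at 1.
#' @export
#' @examples
#' foreground_background(c(4, 3, 2, 1), c(1, 0, 0, 0))
foreground_background <- function(e_sorted, w) {
  if (length(e_sorted) != length(w)) abort("`e_sorted` and `w` differ in length.")
  if (is.unsorted(rev(e_sorted))) abort("`e_sorted` must be sorted in descending order.")
  if (any(e_sorted < 0)) abort("`e_sorted` must be non-negative; shift the profile first.")
  if (any(w < 0 | w > 1)) abort("Weights must lie in [0, 1].")
  if (all(w == 0)) abort("Empty signature side: all weights are zero.")
  fg <- e_sorted * w
  bg <- e_sorted * (1 - w)
  fg_tot <- sum(fg)
  bg_tot <- sum(bg)
  if (fg_tot <= 0 || bg_tot <= 0) {
    abort("Degenerate profile: a cumulative total is not strictly positive.")
  }
  list(f = cumsum(fg) / fg_tot, b = cumsum(bg) / bg_tot)
}

#' Signed maximum deviation between the two cumulative curves
#'
#' Returns `f(i) - b(i)` at the index maximizing `|f(i) - b(i)|`
#' (sign-preserving, the BASE convention), so depletion of a gene set at
#' the top of the profile yields a negative statistic. Set
#' `mode = "max_signed"` for the plain maximum of the signed difference.
#'
#' @param f,b Numeric curves of equal length (from
#'   [foreground_background()]).
#' @param mode `"max_abs"` (default) or `"max_signed"`.
#' @return A single number in \[-1, 1\].
#' @export
raw_deviation <- function(f, b, mode = c("max_abs", "max_signed")) {
  mode <- match.arg(mode)
  if (length(f) != length(b)) abort("`f` and `b` differ in length.")
  d <- unname(f - b)
  if (mode == "max_signed") return(max(d))
  d[which.max(abs(d))]
}

# Columns needed to score against; exclusivity is NOT required here, so
# arbitrary weightings (e.g. uniform on both sides) can be scored.
check_score_weights <- function(w, arg = "weights") {
  if (!is.data.frame(w) || !all(c("gene_id", "w_plus", "w_minus") %in% names(w))) {
    abort(sprintf("`%s` must be a data frame with columns gene_id, w_plus, w_minus.", arg))
  }
  if (anyDuplicated(w$gene_id)) abort(sprintf("`%s` has duplicated gene ids.", arg))
  if (any(!is.finite(w$w_plus)) || any(!is.finite(w$w_minus))) {
    abort(sprintf("`%s` has non-finite weights.", arg))
  }
  if (any(w$w_plus < 0 | w$w_plus > 1) || any(w$w_minus < 0 | w$w_minus > 1)) {
    abort(sprintf("`%s` weights must lie in [0, 1].", arg))
  }
  invisible(w)
}

# z-transform against the permutation null; a constant null is only legal
# when the observed statistic equals it (then the score is exactly 0).
null_z <- function(raw, mu, s) {
  if (s == 0) {
    if (abs(raw - mu) < 1e-12) return(0)
    abort("Degenerate permutation null (zero standard deviation).")
  }
  (raw - mu) / s
}

# Raw deviations for both weight sides of one already-sorted profile.
# e_shifted: descending, non-negative; w_plus/w_minus aligned to it.
base_raw_pair <- function(e_shifted, w_plus, w_minus, mode = "max_abs") {
  fb_p <- foreground_background(e_shifted, w_plus)
  fb_m <- foreground_background(e_shifted, w_minus)
  c(plus = raw_deviation(fb_p$f, fb_p$b, mode = mode),
    minus = raw_deviation(fb_m$f, fb_m$b, mode = mode))
}

#' Score one sample against a pair of weight profiles
#'
#' Computes the modified BASE statistic for a single median-centered
#' expression profile: the profile is sorted in descending order, shifted
#' by its minimum so cumulative sums stay monotone, and the sign-preserving
#' maximum deviation between foreground and background curves is taken for
#' the up (`w_plus`) and down (`w_minus`) profiles. Each raw deviation is
#' z-normalized against a null distribution built by permuting the
#' expression values across gene labels `n_perm` times, and the final score
#' is `rps = rps_plus - rps_minus`. High scores mean the sample's profile
#' resembles known responders.
#'
#' @param profile Named numeric vector: one sample's median-centered
#'   relative expression (names = gene ids).
#' @param weights Data frame with `gene_id`, `w_plus`, `w_minus`. Genes are
#'   matched by id; at least one shared gene is required and fewer than 50
#'   triggers a warning.
#' @param n_perm Number of null permutations (default 1000).
#' @param seed Integer seed making the permutation null reproducible.
#' @param mode Deviation convention, see [raw_deviation()].
#' @param sample_id Identifier recorded in the output row.
#' @return A one-row tibble (class `rps_scores`): `sample_id`, `rps_plus`,
#'   `rps_minus`, `rps`, `raw_plus`, `raw_minus`, null summaries,
#'   `n_genes_used`, `n_permutations`, `seed`.
#' @export
score_sample <- function(profile, weights, n_perm = 1000, seed = 1L,
                         mode = c("max_abs", "max_signed"),
                         sample_id = "sample") {
  mode <- match.arg(mode)
  if (is.null(names(profile))) abort("`profile` must be named by gene id.")
  check_score_weights(weights)
  if (n_perm < 2L) abort("`n_perm` must be at least 2.")
  shared <- intersect(names(profile), weights$gene_id)
  if (length(shared) == 0L) abort("No gene overlap between profile and weight profiles.")
  if (length(shared) < 50L) {
    warn(sprintf("Only %d genes shared between profile and weights.", length(shared)))
  }
  if (!any(weights$w_plus[match(shared, weights$gene_id)] > 0)) {
    abort("Empty signature side: all shared w_plus weights are zero.")
  }
  if (!any(weights$w_minus[match(shared, weights$gene_id)] > 0)) {
    abort("Empty signature side: all shared w_minus weights are zero.")
  }

  # gene-order invariance + deterministic ties: sort by value, gene id breaking ties
  e <- profile[shared]
  wp <- weights$w_plus[match(shared, weights$gene_id)]
  wm <- weights$w_minus[match(shared, weights$gene_id)]
  ord <- order(-e, names(e), method = "radix")
  e <- e[ord]; wp <- wp[ord]; wm <- wm[ord]
  e_shifted <- e - min(e)

  raw <- base_raw_pair(e_shifted, wp, wm, mode = mode)

  g <- length(e_shifted)
  null_plus <- numeric(n_perm)
  null_minus <- numeric(n_perm)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    for (j in seq_len(n_perm)) {
      # permuting expression across genes == permuting the weights against
      # the fixed sorted expression vector; on tiny profiles a draw can put
      # all of one side's weight on the zero-shifted bottom gene, so redraw
      r <- NULL
      for (attempt in seq_len(100L)) {
        perm <- sample.int(g)
        r <- tryCatch(base_raw_pair(e_shifted, wp[perm], wm[perm], mode = mode),
                      error = function(e) NULL)
        if (!is.null(r)) break
      }
      if (is.null(r)) abort("Could not draw a non-degenerate permutation null.")
      null_plus[j] <- r[["plus"]]
      null_minus[j] <- r[["minus"]]
    }
  })
  mu_p <- mean(null_plus); sd_p <- sd(null_plus)
  mu_m <- mean(null_minus); sd_m <- sd(null_minus)
  rps_plus <- null_z(raw[["plus"]], mu_p, sd_p)
  rps_minus <- null_z(raw[["minus"]], mu_m, sd_m)
  out <- tibble::tibble(
    sample_id = sample_id,
    rps_plus = rps_plus, rps_minus = rps_minus, rps = rps_plus - rps_minus,
    raw_plus = raw[["plus"]], raw_minus = raw[["minus"]],
    null_mean_plus = mu_p, null_sd_plus = sd_p,
    null_mean_minus = mu_m, null_sd_minus = sd_m,
    n_genes_used = g, n_permutations = as.integer(n_perm),
    seed = as.integer(seed)
  )
  class(out) <- c("rps_scores", class(out))
  out
}

#' Score every sample of a cohort
#'
#' Median-centers the matrix internally, then scores each sample with
#' [score_sample()]. Each sample's permutation stream is derived from the
#' master seed plus a content hash of its gene-id-sorted profile, so scores
#' are independent of sample order and gene order, and identical profiles
#' receive identical scores.
#'
#' @param m Genes x samples numeric matrix (absolute log2 expression; it is
#'   median-centered internally).
#' @param weights Data frame with `gene_id`, `w_plus`, `w_minus` (or an
#'   `rps_signature`).
#' @param n_perm Permutations per sample (default 1000).
#' @param seed Master integer seed.
#' @param center Set `FALSE` if `m` is already median-centered.
#' @inheritParams score_sample
#' @return A tibble (class `rps_scores`), one row per sample.
#' @export
score_cohort <- function(m, weights, n_perm = 1000, seed = 1L,
                         mode = c("max_abs", "max_signed"), center = TRUE) {
  mode <- match.arg(mode)
  if (inherits(weights, "rps_signature")) weights <- weights$weights
  check_expression_matrix(m, min_samples = if (center) 2L else 1L)
  centered <- if (center) median_center(m) else m
  gene_order <- order(rownames(centered), method = "radix")
  out <- purrr::map_dfr(colnames(centered), function(s) {
    profile <- centered[, s]
    sample_seed <- stable_seed(seed, unname(profile[gene_order]))
    score_sample(profile, weights, n_perm = n_perm, seed = sample_seed,
                 mode = mode, sample_id = s)
  })
  class(out) <- c("rps_scores", class(out))
  out
}

#' Plot cohort score distributions by response group
#'
#' @param object An `rps_scores` tibble from [score_cohort()].
#' @param annotations Optional data frame with `sample_id` and `response`;
#'   when supplied, scores are grouped by response label.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rps_scores
#' @export
autoplot.rps_scores <- function(object, annotations = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(annotations)) {
    df <- dplyr::left_join(df, annotations[c("sample_id", "response")], by = "sample_id")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$rps,
                                     fill = .data$response)) +
      ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
      ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
      ggplot2::labs(x = NULL, y = "response probability score (RPS)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(legend.position = "none")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$rps)) +
      ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
      ggplot2::labs(x = "response probability score (RPS)", y = "samples") +
      ggplot2::theme_minimal()
  }
}
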