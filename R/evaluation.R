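#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a threshold across every observed score: samples scoring above
#' the threshold are called pCR, those at or below are called RD;
#' sensitivity and specificity are recorded per threshold and the AUC is
#' obtained by trapezoidal integration, which equals the Mann-Whitney
#' concordance probability (ties count one half).
#'
#' @param scores Numeric vector of per-sample scores.
#' @param labels Response labels (`"pCR"`/`"RD"` or 1/0); both classes must
#'   be present.
#' @return An object of class `rps_roc`: `tidy()` gives the per-threshold
#'   curve (`threshold`, `sensitivity`, `specificity`), `glance()` a
#'   one-row summary with `auc`, and `autoplot()` the ROC plot.
#' @export
#' @examples
#' r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' glance(r)$auc
roc_curve <- function(scores, labels) {
  y <- as_response01(labels)
  if (length(scores) != length(y)) abort("`scores` and `labels` differ in length.")
  if (anyNA(scores)) abort("`scores` contains missing values.")
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) abort("Both classes must be present to build a ROC curve.")

  thr <- sort(unique(scores))
  sweep <- purrr::map_dfr(c(-Inf, thr), function(t) {
    pred <- scores > t
    tibble::tibble(
      threshold = t,
      sensitivity = sum(pred & y == 1L) / n_pos,
      specificity = sum(!pred & y == 0L) / n_neg
    )
  })
  # trapezoid over the (1 - specificity, sensitivity) polyline
  fpr <- 1 - sweep$specificity
  tpr <- sweep$sensitivity
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tpr[ord][-1]) / 2)
  structure(
    list(curve = sweep, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "rps_roc"
  )
}

#' @export
print.rps_roc <- function(x, ...) {
  cat(sprintf("<rps_roc> AUC = %.4f (%d pCR vs %d RD, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$curve)))
  invisible(x)
}

#' @rdname roc_curve
#' @param x,object An `rps_roc`.
#' @param ... Unused.
#' @method tidy rps_roc
#' @export
tidy.rps_roc <- function(x, ...) x$curve

#' @rdname roc_curve
#' @method glance rps_roc
#' @export
glance.rps_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pcr = x$n_pos, n_rd = x$n_neg)
}

#' @rdname roc_curve
#' @method autoplot rps_roc
#' @export
autoplot.rps_roc <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Wilcoxon rank-sum comparison of scores between response groups
#'
#' Two-sided test that pCR and RD score distributions differ; exact when
#' the combined sample size is at most 20 and there are no ties, otherwise
#' the normal approximation with tie correction.
#'
#' @param scores_pcr,scores_rd Numeric score vectors for the two groups.
#' @return A one-row tibble: `statistic` (W), `p_value`, `method`.
#' @export
rank_sum_test <- function(scores_pcr, scores_rd) {
  if (length(scores_pcr) == 0L || length(scores_rd) == 0L) {
    abort("Both groups must be non-empty.")
  }
  n <- length(scores_pcr) + length(scores_rd)
  has_ties <- anyDuplicated(c(scores_pcr, scores_rd)) > 0L
  exact <- n <= 20L && !has_ties
  ht <- suppressWarnings(
    wilcox.test(scores_pcr, scores_rd, alternative = "two.sided",
                exact = exact, correct = FALSE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = if (exact) "exact" else "normal approximation")
}

#' Tertile enrichment of responders in score groups
#'
#' Splits samples at the 1/3 and 2/3 score quantiles into low/mid/high
#' groups (scores exactly at a boundary go to the lower tertile) and tests
#' the 2 x 3 response-by-tertile table with Pearson's chi-square (df = 2,
#' no continuity correction).
#'
#' @param scores Numeric per-sample scores.
#' @param labels Response labels (`"pCR"`/`"RD"` or 1/0).
#' @return A list: `counts` (2 x 3 table, rows = RD/pCR), `pcr_rate`
#'   (per-tertile responder fraction), `chi2`, `df`, `p_value`.
#' @export
tertile_enrichment <- function(scores, labels) {
  y <- as_response01(labels)
  if (length(scores) < 6L) abort("At least 6 samples are needed for a tertile split.")
  if (length(unique(y)) < 2L) abort("Both classes must be present.")
  q <- quantile(scores, c(1, 2) / 3, type = 7, names = FALSE)
  tertile <- factor(1L + (scores > q[1L]) + (scores > q[2L]), levels = 1:3,
                    labels = c("low", "mid", "high"))
  if (any(table(tertile) == 0L)) {
    abort("A tertile is empty after tie handling; scores are too discrete.")
  }
  counts <- table(response = factor(y, levels = c(0, 1), labels = c("RD", "pCR")),
                  tertile = tertile)
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(
    counts = counts,
    pcr_rate = counts["pCR", ] / colSums(counts),
    chi2 = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

# stage/grade -> ordered integers; "unknown" -> NA (rows later dropped)
encode_ordinal <- function(x, levels) {
  as.integer(factor(as.character(x), levels = levels))
}

#' Cross-validated random-forest classifier combining a score with
#' clinical predictors
#'
#' Trains a balanced random forest (per-class sampling equalized to the
#' minority class) on per-sample features such as an RPS plus age, stage,
#' and grade, and evaluates it by stratified k-fold cross-validation
#' repeated many times. Held-out predicted probabilities are pooled across
#' the folds of each repeat and one AUC is computed per repeat
#' (`pooling = "fold_average"` averages per-fold AUCs instead). Feature
#' importances (mean decrease in node impurity, averaged over folds) are
#' recorded per repeat. Stage and grade given as roman-numeral categories
#' are encoded as ordered integers; rows with unknown values in any used
#' feature are excluded with a message.
#'
#' @param features Data frame of per-sample predictors (numeric, or
#'   `stage`/`grade` categories).
#' @param labels Response labels aligned with `features` rows.
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of CV repetitions (default 100).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param ntree Trees per forest (default 500).
#' @param pooling `"pooled"` (default) or `"fold_average"`.
#' @return An object of class `rps_cv`: `tidy()` gives per-repeat AUCs,
#'   `glance()` mean/sd AUC, `$importances` per-repeat feature importances.
#' @export
combined_classifier_cv <- function(features, labels, folds = 10, repeats = 100,
                                   seed = 1L, ntree = 500,
                                   pooling = c("pooled", "fold_average")) {
  pooling <- match.arg(pooling)
  if (!is.data.frame(features) || ncol(features) < 1L) {
    abort("`features` must be a data frame with at least one column.")
  }
  y <- as_response01(labels)
  if (nrow(features) != length(y)) abort("`features` and `labels` differ in length.")

  X <- as.data.frame(features)
  if ("stage" %in% names(X) && !is.numeric(X$stage)) {
    X$stage <- encode_ordinal(X$stage, c("I", "II", "III", "IV"))
  }
  if ("grade" %in% names(X) && !is.numeric(X$grade)) {
    X$grade <- encode_ordinal(X$grade, c("I", "II", "III"))
  }
  keep <- complete.cases(X)
  if (!all(keep)) {
    inform(sprintf("combined_classifier_cv: excluding %d sample(s) with unknown features.",
                   sum(!keep)))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(X)
  if (n < 30L) abort("At least 30 usable samples are required.")
  class_sizes <- table(y)
  if (length(class_sizes) < 2L || any(class_sizes < folds)) {
    abort(sprintf("Each class needs at least %d samples for %d-fold stratified CV.",
                  folds, folds))
  }
  yf <- factor(y, levels = c(0, 1), labels = c("RD", "pCR"))

  per_repeat <- vector("list", repeats)
  importances <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    withr::with_seed((as.integer(seed) + r) %% .Machine$integer.max, {
      fold_id <- integer(n)
      for (cl in levels(yf)) {
        idx <- which(yf == cl)
        fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      prob <- numeric(n)
      fold_auc <- numeric(folds)
      imp_acc <- NULL
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        sampsize <- rep(min(table(yf[tr])), 2L)
        rf <- randomForest::randomForest(
          x = X[tr, , drop = FALSE], y = yf[tr],
          ntree = ntree, sampsize = sampsize, strata = yf[tr]
        )
        prob[!tr] <- predict(rf, X[!tr, , drop = FALSE], type = "prob")[, "pCR"]
        if (pooling == "fold_average") {
          fold_auc[k] <- if (length(unique(y[!tr])) == 2L) {
            roc_curve(prob[!tr], y[!tr])$auc
          } else NA_real_
        }
        imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
        imp_acc <- if (is.null(imp_acc)) imp else imp_acc + imp
      }
      auc_r <- if (pooling == "pooled") {
        roc_curve(prob, y)$auc
      } else {
        mean(fold_auc, na.rm = TRUE)
      }
      per_repeat[[r]] <- tibble::tibble(repeat_id = r, auc = auc_r)
      importances[[r]] <- tibble::tibble(
        repeat_id = r, feature = names(imp_acc),
        importance = unname(imp_acc) / folds
      )
    })
  }
  per_repeat <- dplyr::bind_rows(per_repeat)
  importances <- dplyr::bind_rows(importances)
  structure(
    list(
      per_repeat = per_repeat, importances = importances,
      mean_auc = mean(per_repeat$auc), sd_auc = sd(per_repeat$auc),
      folds = folds, repeats = repeats, seed = as.integer(seed),
      ntree = ntree, pooling = pooling, n_samples = n,
      features = names(X)
    ),
    class = "rps_cv"
  )
}

#' @export
print.rps_cv <- function(x, ...) {
  cat(sprintf("<rps_cv> %d-fold CV x %d repeats on %d samples: mean AUC = %.3f (sd %.3f)\n",
              x$folds, x$repeats, x$n_samples, x$mean_auc, x$sd_auc))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  invisible(x)
}

#' @rdname combined_classifier_cv
#' @param x,object An `rps_cv`.
#' @param ... Unused.
#' @method tidy rps_cv
#' @export
tidy.rps_cv <- function(x, ...) x$per_repeat

#' @rdname combined_classifier_cv
#' @method glance rps_cv
#' @export
glance.rps_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = x$sd_auc,
                 folds = x$folds, repeats = x$repeats, n_samples = x$n_samples)
}

#' @rdname combined_classifier_cv
#' @method autoplot rps_cv
#' @export
autoplot.rps_cv <- function(object, ...) {
  ggplot2::ggplot(object$importances,
                  ggplot2::aes(x = stats::reorder(.data$feature, .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean decrease in node impurity",
                  title = sprintf("feature importance over %d CV repeats", object$repeats)) +
    ggplot2::theme_minimal()
}

#' Compare per-repeat feature importances by one-way ANOVA
#'
#' @param report An `rps_cv` from [combined_classifier_cv()].
#' @return A list: `mean_importance` (tibble per feature), `f_statistic`,
#'   `p_value`.
#' @export
importance_comparison <- function(report) {
  if (!inherits(report, "rps_cv")) abort("`report` must be an rps_cv object.")
  imp <- report$importances
  if (length(unique(imp$feature)) < 2L) abort("At least 2 features are required.")
  if (length(unique(imp$repeat_id)) < 2L) abort("At least 2 repeats are required.")
  if (var(imp$importance) == 0) {
    # no variation anywhere: no evidence that features differ
    f_stat <- 0
    p_val <- 1
  } else {
    fit <- aov(importance ~ feature, data = transform(imp, feature = factor(feature)))
    s <- summary(fit)[[1L]]
    f_stat <- s[["F value"]][1L]
    p_val <- s[["Pr(>F)"]][1L]
  }
  list(
    mean_importance = imp |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(mean_importance = mean(.data$importance), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$mean_importance)),
    f_statistic = f_stat,
    p_value = p_val
  )
}

#' Paired t-test on per-dataset AUC differences
#'
#' Compares two signatures' AUCs measured on the same collection of
#' datasets with a paired two-sided t-test.
#'
#' @param auc_a,auc_b Numeric vectors of per-dataset AUCs, equal length of
#'   at least 3, paired by position.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`,
#'   `mean_difference`.
#' @export
paired_auc_comparison <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b)) abort("AUC vectors must have equal length.")
  if (length(auc_a) < 3L) abort("At least 3 paired datasets are required.")
  d <- auc_a - auc_b
  if (var(d) == 0) {
    abort("Zero variance of AUC differences; the paired t-test is undefined.")
  }
  ht <- t.test(auc_a, auc_b, paired = TRUE, alternative = "two.sided")
  tibble::tibble(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_difference = mean(d))
}
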