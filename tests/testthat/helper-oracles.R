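# Independent oracles, written with explicit loops / closed forms so they
# share no code with the package implementation.

# Brute-force modified-BASE deviation: explicit cumulative loops, first
# index of maximal |f - b| wins (sign preserved).
brute_raw_deviation <- function(e, w) {
  g <- length(e)
  f_tot <- 0
  b_tot <- 0
  for (k in seq_len(g)) {
    f_tot <- f_tot + e[k] * w[k]
    b_tot <- b_tot + e[k] * (1 - w[k])
  }
  cf <- 0
  cb <- 0
  best <- 0
  best_abs <- -1
  for (i in seq_len(g)) {
    cf <- cf + e[i] * w[i]
    cb <- cb + e[i] * (1 - w[i])
    d <- cf / f_tot - cb / b_tot
    if (abs(d) > best_abs) {
      best_abs <- abs(d)
      best <- d
    }
  }
  best
}

# Independent IRLS fit of logit P(y=1) = b0 + b1 x with Wald p for b1.
irls_logistic <- function(x, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    z <- eta + (y - p) / w
    beta_new <- as.numeric(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- as.numeric(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  se <- unname(sqrt(diag(solve(crossprod(X, (p * (1 - p)) * X)))))
  list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
       p_value = unname(2 * pnorm(-abs(beta[2] / se[2]))))
}

# Pairwise Mann-Whitney concordance with half-credit ties.
brute_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p by enumeration of all label assignments.
enum_rank_sum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  m <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(m)])
  combos <- utils::combn(n, m)
  sums <- apply(combos, 2L, function(idx) sum(r[idx]))
  ew <- mean(sums)
  mean(abs(sums - ew) >= abs(obs - ew))
}

# Closed-form one-way ANOVA.
closed_form_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lv <- unique(groups)
  k <- length(lv)
  n <- length(values)
  ssb <- 0
  ssw <- 0
  for (g in lv) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# chi-square kernel sum((O - E)^2 / E) from a counts matrix.
chi_square_kernel <- function(counts) {
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - e)^2 / e)
}

# Small shared fixtures ----------------------------------------------------

make_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# A small cohort reused by several scoring tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(n_genes = 300, n_samples = 80, n_de_genes = 60,
                                effect_size = 1.5, seed = 2024)
    }
    cache
  }
})

# Full-scale recovery experiment shared by the acceptance tests: train on
# half of a 2000-gene, 240-sample cohort with a 1-SD planted effect and
# score the held-out half (cached per session; ~1 min).
recovery_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(seed = 20260926)
      train_ids <- sim$annotations$sample_id[seq_len(120)]
      test_ids <- sim$annotations$sample_id[121:240]
      sig <- build_rps_signature(
        sim$expression[, train_ids],
        dplyr::filter(sim$annotations, sample_id %in% train_ids)
      )
      scores <- score_cohort(sim$expression[, test_ids], sig,
                             n_perm = 1000, seed = 4242)
      cache <<- list(sim = sim, sig = sig, scores = scores,
                     train_ids = train_ids, test_ids = test_ids)
    }
    cache
  }
})
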