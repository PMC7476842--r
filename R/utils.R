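# Internal validators shared across the package.

# Checks a genes x samples numeric matrix with unique dimnames.
check_expression_matrix <- function(m, arg = "m", min_samples = 1L) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix.", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must have gene ids as rownames and sample ids as colnames.", arg))
  }
  if (anyDuplicated(rownames(m))) {
    dup <- rownames(m)[duplicated(rownames(m))][1L]
    abort(sprintf("Duplicate gene id in `%s`: '%s'.", arg, dup))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- colnames(m)[duplicated(colnames(m))][1L]
    abort(sprintf("Duplicate sample id in `%s`: '%s'.", arg, dup))
  }
  if (anyNA(m)) {
    abort(sprintf("`%s` contains missing values.", arg))
  }
  if (ncol(m) < min_samples) {
    abort(sprintf("`%s` needs at least %d samples, got %d.", arg, min_samples, ncol(m)))
  }
  invisible(m)
}

check_weight_profiles <- function(w, arg = "weights") {
  if (!is.data.frame(w) || !all(c("gene_id", "w_plus", "w_minus") %in% names(w))) {
    abort(sprintf("`%s` must be a data frame with columns gene_id, w_plus, w_minus.", arg))
  }
  if (anyDuplicated(w$gene_id)) {
    abort(sprintf("`%s` has duplicated gene ids.", arg))
  }
  if (any(!is.finite(w$w_plus)) || any(!is.finite(w$w_minus))) {
    abort(sprintf("`%s` has non-finite weights.", arg))
  }
  if (any(w$w_plus < 0) || any(w$w_minus < 0) || any(w$w_plus > 1) || any(w$w_minus > 1)) {
    abort(sprintf("`%s` weights must lie in [0, 1].", arg))
  }
  if (any(pmin(w$w_plus, w$w_minus) > 0)) {
    abort(sprintf("`%s` must have at most one nonzero side per gene.", arg))
  }
  invisible(w)
}

# Coerces pCR/RD style labels to 0/1 integers (pCR = 1).
as_response01 <- function(labels, arg = "labels") {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("pCR", "RD"))
    if (length(bad)) {
      abort(sprintf("`%s` must be 'pCR'/'RD' (or 0/1); found '%s'.", arg, bad[1L]))
    }
    return(as.integer(labels == "pCR"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      abort(sprintf("Numeric `%s` must be 0 (RD) or 1 (pCR).", arg))
    }
    return(as.integer(labels))
  }
  abort(sprintf("Cannot interpret `%s` as response labels.", arg))
}

# A stable, platform-independent 31-bit integer derived from an R object.
stable_seed <- function(master_seed, x) {
  h <- digest::digest(x, algo = "xxhash32", serialize = TRUE)
  (as.integer(master_seed) + strtoi(substr(h, 1L, 7L), base = 16L)) %% .Machine$integer.max
}

enum_or_unknown <- function(x, allowed, field) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  bad <- setdiff(unique(x), c(allowed, "unknown"))
  if (length(bad)) {
    abort(sprintf("Invalid value '%s' in field '%s' (allowed: %s, unknown).",
                  bad[1L], field, paste(allowed, collapse = ", ")))
  }
  x
}
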