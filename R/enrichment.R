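#' Read a gene-set collection in GMT format
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated fields
#' `name`, `description`, then gene ids. Duplicate genes within a set are
#' deduplicated.
#'
#' @param path GMT file path.
#' @param source Label recorded on the collection (default the file name).
#' @return A named list of character vectors with attribute `source`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn(sprintf("'%s' is empty; returning an empty collection.", path))
    return(structure(list(), source = source))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("Line %d of '%s' has fewer than 3 tab-separated fields.", i, path))
    }
    nm <- fields[1L]
    if (nm %in% names(sets)) {
      abort(sprintf("Duplicate gene-set name '%s' at line %d of '%s'.", nm, i, path))
    }
    genes <- unique(fields[-c(1L, 2L)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) abort(sprintf("Gene set '%s' has no genes.", nm))
    sets[[nm]] <- genes
  }
  structure(sets, source = source)
}

#' Restrict gene sets to a ranked universe and drop small sets
#'
#' Sets are intersected with the ranked gene list; sets retaining fewer
#' than `min_size` genes are removed (the convention excluding sets with
#' less than 20 genes).
#'
#' @param gsc Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param ranked_genes Character vector: the signature's gene universe.
#' @param min_size Minimum post-intersection size (default 20).
#' @return The filtered collection (same structure; sets keep only genes in
#'   `ranked_genes`).
#' @export
filter_gene_sets <- function(gsc, ranked_genes, min_size = 20) {
  if (length(ranked_genes) == 0L) abort("`ranked_genes` is empty.")
  out <- lapply(gsc, function(g) intersect(g, ranked_genes))
  out <- out[vapply(out, length, integer(1)) >= min_size]
  structure(out, source = attr(gsc, "source"))
}

#' Rank signature genes by signed weight
#'
#' Orders genes descending by the signed weight `w_plus - w_minus`, ties
#' broken by gene id, so the top of the ranking holds the most
#' up-regulated (in responders) genes and the bottom the most
#' down-regulated. Zero-weight genes stay in the ranking so the universe
#' size matches the signature.
#'
#' @param weights Data frame with `gene_id`, `w_plus`, `w_minus` (or an
#'   `rps_signature`).
#' @return Character vector of gene ids, most up-weighted first.
#' @export
rank_signature_genes <- function(weights) {
  if (inherits(weights, "rps_signature")) weights <- weights$weights
  check_weight_profiles(weights)
  s <- weights$w_plus - weights$w_minus
  weights$gene_id[order(-s, weights$gene_id, method = "radix")]
}

#' Walking-sum enrichment score of a gene set in a ranked signature
#'
#' With hits of the gene set at ranks `r_1 < ... < r_n` in a ranking of `N`
#' genes, the cumulative hit count `g_i = i` and the rank gap
#' `d_i = r_(i+1) - r_i` (sentinel `r_(n+1) = N + 1`) give
#' `ES = (sum(g_i * d_i) / (n * N) - 0.5) * 2`. Hits concentrated at the
#' top push ES toward +1 (enrichment among up-regulated signature genes),
#' hits at the bottom toward -1.
#'
#' @param gene_set Character vector of gene ids.
#' @param ranked_genes Character vector, descending by signed signature
#'   weight (see [rank_signature_genes()]).
#' @return A one-row tibble: `es` in \[-1, 1\], `n_hits_used`, `n_universe`,
#'   `direction` (`"up"` for positive ES, `"down"` for negative).
#' @export
#' @examples
#' enrichment_score(c("g1", "g2"), paste0("g", 1:10))  # ES = 0.9
enrichment_score <- function(gene_set, ranked_genes) {
  if (anyDuplicated(ranked_genes)) abort("`ranked_genes` contains duplicates.")
  N <- length(ranked_genes)
  hits <- which(ranked_genes %in% unique(gene_set))
  n <- length(hits)
  if (n == 0L) abort("The gene set does not intersect the ranked list.")
  d <- c(hits[-1L], N + 1L) - hits
  es <- (sum(seq_len(n) * d) / (n * N) - 0.5) * 2
  tibble::tibble(
    es = es, n_hits_used = n, n_universe = N,
    direction = if (es >= 0) "up" else "down"
  )
}

#' Enrichment scores for a whole collection
#'
#' Applies [filter_gene_sets()] then [enrichment_score()] to every set.
#'
#' @inheritParams filter_gene_sets
#' @return A tibble: `set_name`, `es`, `n_hits_used`, `n_universe`,
#'   `direction`, sorted by decreasing ES.
#' @export
enrich_collection <- function(gsc, ranked_genes, min_size = 20) {
  kept <- filter_gene_sets(gsc, ranked_genes, min_size = min_size)
  if (length(kept) == 0L) {
    return(tibble::tibble(set_name = character(), es = numeric(),
                          n_hits_used = integer(), n_universe = integer(),
                          direction = character()))
  }
  purrr::imap_dfr(kept, function(g, nm) {
    dplyr::mutate(enrichment_score(g, ranked_genes), set_name = nm, .before = 1L)
  }) |>
    dplyr::arrange(dplyr::desc(.data$es))
}

#' Spearman correlation of scores with microenvironment components
#'
#' Correlates per-sample scores with precomputed tumor-microenvironment
#' component estimates (immune and stromal abundance from an external
#' decomposition such as ESTIMATE, plus a proliferation proxy), using
#' Spearman rank correlation with average-rank ties and a two-sided test.
#'
#' @param scores Named or positional numeric vector of per-sample scores.
#' @param components Data frame of per-sample component values (e.g.
#'   columns `immune`, `stromal`, `proliferation`), rows aligned with
#'   `scores`.
#' @return A tibble: `component`, `rho`, `p_value`, `n`.
#' @export
correlate_components <- function(scores, components) {
  if (!is.data.frame(components) || ncol(components) < 1L) {
    abort("`components` must be a data frame with at least one column.")
  }
  comp <- components[vapply(components, is.numeric, logical(1))]
  if (ncol(comp) == 0L) abort("`components` has no numeric columns.")
  if (nrow(comp) != length(scores)) abort("`scores` and `components` differ in length.")
  purrr::imap_dfr(comp, function(x, nm) {
    ok <- is.finite(scores) & is.finite(x)
    if (sum(ok) < 4L) abort(sprintf("Fewer than 4 paired samples for component '%s'.", nm))
    if (var(x[ok]) == 0 || var(scores[ok]) == 0) {
      abort(sprintf("Component '%s' (or the scores) is constant.", nm))
    }
    ht <- suppressWarnings(cor.test(scores[ok], x[ok], method = "spearman",
                                    alternative = "two.sided"))
    tibble::tibble(component = nm, rho = unname(ht$estimate),
                   p_value = ht$p.value, n = sum(ok))
  })
}

#' Proliferation proxy from a marker gene
#'
#' The per-sample median-centered expression of a proliferation marker
#' (MKI67 by default), used as the tumor-cell proliferation component of
#' the microenvironment decomposition.
#'
#' @param m Genes x samples numeric matrix.
#' @param gene Marker gene symbol (default `"MKI67"`).
#' @return Named numeric vector of per-sample values.
#' @export
proliferation_proxy <- function(m, gene = "MKI67") {
  check_expression_matrix(m, min_samples = 2L)
  if (!gene %in% rownames(m)) {
    abort(sprintf("Gene '%s' is absent from the expression matrix.", gene))
  }
  v <- m[gene, ]
  v - median(v)
}
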