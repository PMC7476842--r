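#' Simulate a labelled two-class expression cohort
#'
#' Generates an Affymetrix-style log2-intensity cohort with the structure
#' the scoring framework assumes: Gaussian baseline gene means, a planted
#' set of differentially expressed (DE) genes shifted up or down in
#' responders, per-batch location shifts, and clinical covariates (stage,
#' grade) tilted toward response. The defaults mirror the scale at which
#' the framework is exercised end to end: 2000 genes, 240 samples (a
#' 120-sample training and 120-sample validation split), a one-third
#' responder rate, 200 DE genes (half up, half down) at a 1-SD effect.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_samples Number of samples (default 240).
#' @param pcr_fraction Responder (pCR) probability per sample (default 1/3,
#'   the typical neoadjuvant response rate).
#' @param n_de_genes Number of DE genes, split half up-/half down-regulated
#'   in responders (default 200).
#' @param effect_size Mean shift of DE genes in responders, in units of
#'   `noise_sd` (default 1).
#' @param noise_sd Within-gene residual SD on the log2 scale (default 1).
#' @param n_batches Number of cohort batches (default 2).
#' @param batch_shift_sd SD of per-gene, per-batch location shifts
#'   (default 0.3).
#' @param clinical_effect Log-odds tilt of stage/grade toward response
#'   (default 0.5; more advanced stage/grade leans pCR).
#' @param seed Integer seed; output is bit-identical for a given seed.
#' @return A list with components `expression` (genes x samples matrix,
#'   log2 scale), `annotations` (tibble in the clinical-annotation layout),
#'   and `truth` (list: `de_genes` tibble with `gene_id`/`direction`,
#'   `gene_ids`, `propensity`, `config`).
#' @export
#' @examples
#' sim <- simulate_cohort(n_genes = 100, n_samples = 40, seed = 1)
#' dim(sim$expression)
simulate_cohort <- function(n_genes = 2000, n_samples = 240, pcr_fraction = 1 / 3,
                            n_de_genes = 200, effect_size = 1, noise_sd = 1,
                            n_batches = 2, batch_shift_sd = 0.3,
                            clinical_effect = 0.5, seed = 1L) {
  if (n_genes < 1L || n_samples < 1L) abort("Counts must be positive.")
  if (pcr_fraction <= 0 || pcr_fraction >= 1) abort("`pcr_fraction` must lie in (0, 1).")
  if (n_de_genes > n_genes) abort("`n_de_genes` cannot exceed `n_genes`.")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (n_batches < 1L) abort("`n_batches` must be at least 1.")

  withr::with_seed(as.integer(seed), {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    sample_ids <- sprintf("s%04d", seq_len(n_samples))

    propensity <- rep(pcr_fraction, n_samples)
    response01 <- rbinom(n_samples, 1L, propensity)
    # guarantee both classes so downstream fits are always defined
    if (sum(response01) == 0L) response01[sample.int(n_samples, 1L)] <- 1L
    if (sum(response01) == n_samples) response01[sample.int(n_samples, 1L)] <- 0L

    de_idx <- sort(sample.int(n_genes, n_de_genes))
    n_up <- ceiling(n_de_genes / 2)
    direction <- rep(c(1, -1), c(n_up, n_de_genes - n_up))

    mu <- rnorm(n_genes, mean = 7, sd = 1.5)
    expr <- matrix(rnorm(n_genes * n_samples, sd = noise_sd),
                   nrow = n_genes, ncol = n_samples,
                   dimnames = list(gene_ids, sample_ids)) + mu

    shift <- effect_size * noise_sd
    if (n_de_genes > 0L && any(response01 == 1L)) {
      expr[de_idx, response01 == 1L] <-
        expr[de_idx, response01 == 1L] + direction * shift
    }

    batch <- sprintf("batch%d", sample(rep_len(seq_len(n_batches), n_samples)))
    if (n_batches > 1L && batch_shift_sd > 0) {
      batch_shift <- matrix(rnorm(n_genes * n_batches, sd = batch_shift_sd),
                            nrow = n_genes)
      for (b in seq_len(n_batches)) {
        cols <- batch == sprintf("batch%d", b)
        expr[, cols] <- expr[, cols] + batch_shift[, b]
      }
    }

    # ordinal clinical covariates tilted toward response: responders lean
    # toward higher stage/grade with log-odds slope `clinical_effect`
    sample_ordinal <- function(levels_chr) {
      k <- length(levels_chr)
      centered <- seq_len(k) - (k + 1) / 2
      vapply(response01, function(y) {
        logits <- clinical_effect * centered * (2 * y - 1)
        p <- exp(logits) / sum(exp(logits))
        levels_chr[sample.int(k, 1L, prob = p)]
      }, character(1))
    }
    annotations <- tibble::tibble(
      sample_id = sample_ids,
      response = ifelse(response01 == 1L, "pCR", "RD"),
      er_status = "negative", pr_status = "negative", her2_status = "negative",
      stage = sample_ordinal(c("I", "II", "III", "IV")),
      grade = sample_ordinal(c("I", "II", "III")),
      age = round(rnorm(n_samples, mean = 50, sd = 10), 1),
      batch = batch
    )

    truth <- list(
      de_genes = tibble::tibble(
        gene_id = gene_ids[de_idx],
        direction = ifelse(direction > 0, "up", "down")
      ),
      gene_ids = gene_ids,
      propensity = propensity,
      config = list(
        n_genes = n_genes, n_samples = n_samples, pcr_fraction = pcr_fraction,
        n_de_genes = n_de_genes, effect_size = effect_size, noise_sd = noise_sd,
        n_batches = n_batches, batch_shift_sd = batch_shift_sd,
        clinical_effect = clinical_effect, seed = as.integer(seed)
      )
    )
    list(expression = expr, annotations = annotations, truth = truth)
  })
}

#' Embed gene sets with controlled overlap with the planted DE genes
#'
#' Builds a gene-set collection whose sets contain a controlled fraction of
#' the up- (or down-) regulated planted DE genes, the remainder drawn from
#' non-DE genes; used to test that the walking-sum enrichment recovers
#' planted pathway structure.
#'
#' @param truth The `truth` component of [simulate_cohort()].
#' @param n_sets Number of sets (default 3).
#' @param set_size Genes per set (default 50).
#' @param overlap_with_de Fraction of each set drawn from the DE genes of
#'   the chosen direction (default 1).
#' @param direction `"up"` (default) or `"down"`: which DE arm to overlap.
#' @param seed Integer seed.
#' @return A named list of gene-id vectors with attribute
#'   `source = "synthetic"`.
#' @export
embed_gene_sets <- function(truth, n_sets = 3, set_size = 50,
                            overlap_with_de = 1, direction = c("up", "down"),
                            seed = 1L) {
  direction <- match.arg(direction)
  if (overlap_with_de < 0 || overlap_with_de > 1) {
    abort("`overlap_with_de` must lie in [0, 1].")
  }
  universe <- truth$gene_ids
  if (set_size > length(universe)) abort("`set_size` exceeds the gene universe.")
  de_pool <- truth$de_genes$gene_id[truth$de_genes$direction == direction]
  non_de <- setdiff(universe, truth$de_genes$gene_id)
  n_de <- round(overlap_with_de * set_size)
  if (n_de > length(de_pool)) {
    abort(sprintf("Requested %d %s-DE genes per set but only %d exist.",
                  n_de, direction, length(de_pool)))
  }
  if (set_size - n_de > length(non_de)) {
    abort("Not enough non-DE genes to fill the sets.")
  }
  withr::with_seed(as.integer(seed), {
    sets <- lapply(seq_len(n_sets), function(i) {
      c(sample(de_pool, n_de), sample(non_de, set_size - n_de))
    })
  })
  names(sets) <- sprintf("SYNTHETIC_SET_%s_%02d", toupper(direction), seq_len(n_sets))
  structure(sets, source = "synthetic")
}
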