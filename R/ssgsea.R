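#' Single-sample gene-set enrichment score
#'
#' Rank-weighted running-sum enrichment of one gene set in one expression
#' profile. Genes are ordered by decreasing expression (ties broken by
#' descending gene ID); walking down the list, the score accumulates the gap
#' between the weighted in-set cumulative distribution and the uniform
#' out-of-set step. Weights are integer ranks (N for the top gene) raised to
#' `alpha`, making the score invariant under strictly monotone transforms of
#' the expression values; `weight = "value"` uses the expression values
#' themselves instead.
#'
#' @param expr named numeric vector of per-gene expression for one sample.
#' @param gene_set character vector of member genes.
#' @param alpha rank-weight exponent (default 0.25).
#' @param min_overlap minimum set genes present in the universe (default 5).
#' @param weight `"rank"` (default) or `"value"`.
#' @return scalar enrichment score; `NA` (with a warning) on empty overlap.
#'   A set covering the whole universe scores 0 by convention (the
#'   out-of-set step is degenerate).
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, min_overlap = 5L,
                         weight = c("rank", "value")) {
  weight <- match.arg(weight)
  assert_that(length(expr) >= 2, "need at least 2 genes in the universe")
  genes <- names(expr)
  in_set <- genes %in% gene_set
  n_in <- sum(in_set)
  if (n_in == 0) {
    warning("gene set has no overlap with the expression universe")
    return(NA_real_)
  }
  if (n_in < min_overlap)
    warning(sprintf("gene-set overlap %d below min_overlap %d",
                    n_in, min_overlap))
  N <- length(expr)
  if (n_in == N) return(0)

  # descending expression; ties by descending gene ID (deterministic)
  ord <- order(-expr, -xtfrm(genes))
  in_ord <- in_set[ord]
  w <- if (weight == "rank") (N - seq_len(N) + 1)^alpha else
    abs(expr[ord])^alpha
  w_in <- w * in_ord
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!in_ord) / (N - n_in)
  sum(p_in - p_out)
}

#' Score every sample against every gene set
#'
#' @param expr genes x samples matrix.
#' @param gene_sets named list of gene vectors (see [read_gmt()]).
#' @param normalize divide each set's scores by their range across samples
#'   (for cross-sample heatmaps; off by default).
#' @inheritParams ssgsea_score
#' @return samples x gene-sets numeric matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(expr, gene_sets, alpha = 0.25, min_overlap = 5L,
                          weight = "rank", normalize = FALSE) {
  out <- matrix(NA_real_, ncol(expr), length(gene_sets),
                dimnames = list(colnames(expr), names(gene_sets)))
  for (s in names(gene_sets))
    out[, s] <- apply(expr, 2L, ssgsea_score, gene_set = gene_sets[[s]],
                      alpha = alpha, min_overlap = min_overlap,
                      weight = weight)
  if (normalize) {
    rng <- apply(out, 2L, function(v) diff(range(v, na.rm = TRUE)))
    rng[rng == 0] <- 1
    out <- sweep(out, 2L, rng, "/")
  }
  out
}

#' Correlate diversity with cancer-immunity-cycle step scores
#'
#' Spearman rank correlation of the Shannon index against each gene-set
#' enrichment score across overlapping samples, with Benjamini-Hochberg
#' adjusted p-values alongside the raw ones.
#'
#' @param dt a [diversity_table()] result.
#' @param scores samples x gene-sets matrix from [ssgsea_matrix()].
#' @return data.frame: gene_set, rho, p_value, p_adjusted, n.
#' @export
immunity_cycle_correlation <- function(dt, scores) {
  common <- intersect(dt$sample_id[!dt$degenerate & !is.na(dt$shannon)],
                      rownames(scores))
  assert_that(length(common) >= 10, "need at least 10 overlapping samples")
  H <- dt$shannon[match(common, dt$sample_id)]
  res <- lapply(colnames(scores), function(s) {
    v <- scores[common, s]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("constant score vector for gene set '", s, "'")
      return(data.frame(gene_set = s, rho = NA_real_, p_value = NA_real_,
                        n = length(common)))
    }
    ct <- suppressWarnings(cor.test(H, v, method = "spearman"))
    data.frame(gene_set = s, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(common))
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
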