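#' Shannon diversity index
#'
#' \eqn{H = -\sum_i P_i \ln P_i} over a vector of fractions, with
#' \eqn{0 \cdot \ln 0 \equiv 0}. Natural logarithm throughout.
#'
#' @param p non-negative fractions summing to 1 (tolerance 1e-9).
#' @return non-negative scalar, at most `ln(length(p))`.
#' @export
shannon_index <- function(p) {
  check_simplex(p)
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Gini-Simpson diversity index
#'
#' \eqn{1 - \sum_i P_i^2}: the probability that two independent draws come
#' from different categories.
#'
#' @inheritParams shannon_index
#' @export
gini_simpson_index <- function(p) {
  check_simplex(p)
  1 - sum(p^2)
}

#' Pielou evenness index
#'
#' Shannon diversity normalized by its maximum, \eqn{H / \ln n}. Equals 1
#' exactly for a uniform distribution over `n` categories.
#'
#' @inheritParams shannon_index
#' @param n category count in the denominator (>= 2). By convention this is
#'   the total number of subgroups in the signature, keeping the index
#'   comparable across samples (see vignette).
#' @export
pielou_index <- function(p, n = length(p)) {
  assert_that(is_count(n) && n >= 2, "Pielou's n must be an integer >= 2")
  shannon_index(p) / log(n)
}

#' Per-sample diversity table
#'
#' Computes Shannon (the primary index), Gini-Simpson and Pielou indices for
#' every row of a fraction profile. Degenerate rows (flagged by
#' [to_fractions()] when a sample had all-zero abundance) carry `NA`.
#'
#' @param fractions samples x subgroups matrix of fractions (rows on the
#'   simplex), or a `FractionProfile` from [to_fractions()].
#' @param pielou_n `"signature"` (default: n = number of subgroup columns,
#'   constant across samples) or `"observed"` (per-sample richness).
#' @return data.frame: sample_id, shannon, gini_simpson, pielou, n,
#'   degenerate.
#' @export
diversity_table <- function(fractions, pielou_n = c("signature", "observed")) {
  pielou_n <- match.arg(pielou_n)
  degenerate <- NULL
  if (inherits(fractions, "myelodiv_fractions")) {
    degenerate <- fractions$degenerate
    fractions <- fractions$fractions
  }
  degenerate <- degenerate %||% rep(FALSE, nrow(fractions))
  ids <- rownames(fractions) %||% sprintf("S%04d", seq_len(nrow(fractions)))
  K <- ncol(fractions)
  assert_that(K >= 2, "need at least 2 subgroups")

  out <- data.frame(sample_id = ids, shannon = NA_real_,
                    gini_simpson = NA_real_, pielou = NA_real_,
                    n = NA_integer_, degenerate = degenerate,
                    stringsAsFactors = FALSE)
  for (i in which(!degenerate)) {
    p <- fractions[i, ]
    n_i <- if (pielou_n == "signature") K else max(sum(p > 0), 2L)
    out$shannon[i] <- shannon_index(p)
    out$gini_simpson[i] <- gini_simpson_index(p)
    out$pielou[i] <- out$shannon[i] / log(n_i)
    out$n[i] <- as.integer(n_i)
  }
  out
}

#' Stratify a cohort by diversity quantiles
#'
#' Labels samples `high` / `low` (and `middle-excluded` under the
#' quartile-extremes scheme) by their Shannon index. Ties at a threshold are
#' resolved toward nominal group sizes, breaking remaining ties by sample-ID
#' order. Degenerate samples are excluded.
#'
#' @param dt a [diversity_table()] result.
#' @param q tail fraction per side, in (0, 0.5] (default 0.25: the top and
#'   bottom quarter of patients).
#' @param scheme `"quartile-extremes"` (middle excluded) or `"median-split"`.
#' @return data.frame: sample_id, stratum; with attributes `thresholds` and
#'   `scheme`.
#' @export
stratify_by_quantile <- function(dt, q = 0.25,
                                 scheme = c("quartile-extremes",
                                            "median-split")) {
  scheme <- match.arg(scheme)
  assert_that(q > 0 && q <= 0.5, "q must lie in (0, 0.5]")
  use <- dt[!dt$degenerate & !is.na(dt$shannon), , drop = FALSE]
  assert_that(nrow(use) >= 8, "need at least 8 non-degenerate samples")
  if (diff(range(use$shannon)) == 0) stop("no variation to stratify")

  ord <- order(use$shannon, use$sample_id)        # ascending; ties by ID
  n <- nrow(use)
  if (scheme == "median-split") {
    n_low <- floor(n / 2)
    stratum <- rep("high", n)
    stratum[seq_len(n_low)] <- "low"
  } else {
    n_tail <- max(1L, floor(q * n))
    stratum <- rep("middle-excluded", n)
    stratum[seq_len(n_tail)] <- "low"
    stratum[seq(n - n_tail + 1L, n)] <- "high"
  }
  out <- data.frame(sample_id = use$sample_id[ord], stratum = stratum,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(
    low = unname(quantile(use$shannon, if (scheme == "median-split") 0.5 else q)),
    high = unname(quantile(use$shannon,
                           if (scheme == "median-split") 0.5 else 1 - q)))
  attr(out, "scheme") <- scheme
  out
}
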