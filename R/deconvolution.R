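#' Deconvolve bulk expression against a signature matrix
#'
#' Per sample, solves the non-negative least-squares problem
#' \eqn{\min_x \|S x - b\|_2, x \ge 0} on the gene space shared by signature
#' and bulk ("absolute mode": the raw coefficient vector, no sum-to-one
#' constraint). Relative abundances come from [to_fractions()] downstream.
#' Genes are used untransformed (linear space), matching the mixture model.
#'
#' @param bulk genes x samples matrix.
#' @param sig a `myelodiv_signature` or a plain markers x subgroups matrix.
#' @param min_overlap minimum fraction of signature genes that must be
#'   present in the bulk matrix (default 0.5).
#' @return a `myelodiv_abundance`: list with `abundance` (samples x K),
#'   `diagnostics` (residual norm, R2, degenerate flag per sample) and
#'   `genes_used`.
#' @export
deconvolve <- function(bulk, sig, min_overlap = 0.5) {
  S_full <- if (inherits(sig, "myelodiv_signature")) sig$values else sig
  common <- intersect(rownames(S_full), rownames(bulk))
  frac <- length(common) / nrow(S_full)
  if (frac < min_overlap)
    stop(sprintf(paste0("only %d/%d signature genes present in bulk ",
                        "(%.0f%% < %.0f%% required)"),
                 length(common), nrow(S_full), 100 * frac, 100 * min_overlap))
  assert_that(length(common) >= ncol(S_full),
              "fewer overlapping genes than subgroups")
  S <- S_full[common, , drop = FALSE]
  if (qr(S)$rank < ncol(S))
    warning("signature matrix is rank-deficient on the overlap genes; ",
            "NNLS proceeds but estimates may be non-unique")

  B <- bulk[common, , drop = FALSE]
  n <- ncol(B)
  K <- ncol(S)
  ab <- matrix(0, n, K, dimnames = list(colnames(B), colnames(S)))
  resid <- r2 <- numeric(n)
  degenerate <- logical(n)
  for (j in seq_len(n)) {
    b <- B[, j]
    if (all(b == 0)) {
      degenerate[j] <- TRUE
      r2[j] <- NA_real_
      next
    }
    x <- .nnls_cpp(S, b)
    ab[j, ] <- x
    resid[j] <- sqrt(sum((S %*% x - b)^2))
    r2[j] <- 1 - sum((S %*% x - b)^2) / sum(b^2)
    if (all(x == 0)) degenerate[j] <- TRUE
  }
  structure(list(
    abundance = ab,
    diagnostics = data.frame(sample_id = colnames(B), residual_norm = resid,
                             r_squared = r2, degenerate = degenerate,
                             stringsAsFactors = FALSE),
    genes_used = common
  ), class = c("myelodiv_abundance", "list"))
}

#' Convert absolute abundances to fractions
#'
#' Row-normalizes abundances to the simplex: \eqn{P_i = a_i / \sum_k a_k}.
#' All-zero rows cannot be normalized and are flagged degenerate; their
#' diversity is missing downstream rather than imputed. Fractions are
#' invariant to any positive rescaling of the abundances.
#'
#' @param ab a `myelodiv_abundance`, or a samples x K non-negative matrix.
#' @return a `myelodiv_fractions`: list with `fractions` (samples x K, rows
#'   summing to 1) and logical `degenerate`.
#' @export
to_fractions <- function(ab) {
  m <- if (inherits(ab, "myelodiv_abundance")) ab$abundance else ab
  assert_that(all(is.finite(m)), "abundances must be finite")
  assert_that(all(m >= 0), "abundances must be non-negative")
  tot <- rowSums(m)
  degenerate <- tot == 0
  fr <- m
  fr[!degenerate, ] <- m[!degenerate, , drop = FALSE] / tot[!degenerate]
  fr[degenerate, ] <- NA_real_
  structure(list(fractions = fr, degenerate = degenerate),
            class = c("myelodiv_fractions", "list"))
}
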