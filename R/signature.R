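#' Select subgroup marker genes from labelled single-cell expression
#'
#' For each subgroup, ranks genes by one-vs-rest mean log2 fold-change on
#' log1p-transformed expression and keeps up to `top_n` genes with fold
#' change >= `min_fold` that are expressed in at least `min_frac` of the
#' subgroup's cells. The union across subgroups, deduplicated, forms the
#' signature gene set. Ranking ties break lexicographically by gene ID.
#'
#' @param sc genes x cells expression matrix.
#' @param labels named character vector cell -> subgroup.
#' @param top_n maximum markers per subgroup (default 50).
#' @param min_fold minimum one-vs-rest fold change (default 2).
#' @param min_frac minimum expressing fraction within the subgroup
#'   (default 0.25).
#' @param min_cells minimum cells per subgroup (default 10).
#' @param allow_relaxed when a subgroup has no qualifying gene, keep its
#'   best-ranked sub-threshold genes (with a warning) instead of erroring.
#' @return data.frame of markers with provenance columns `gene`, `subgroup`,
#'   `log2_fc`, `pct_expressing`.
#' @export
select_markers <- function(sc, labels, top_n = 50L, min_fold = 2,
                           min_frac = 0.25, min_cells = 10L,
                           allow_relaxed = FALSE) {
  labels <- labels[colnames(sc)]
  assert_that(!anyNA(labels), "every cell in the matrix must be labelled")
  groups <- sort(unique(labels))
  assert_that(length(groups) >= 2, "need at least 2 subgroups")
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small))
    stop("subgroup(s) below min_cells: ", paste(small, collapse = ", "))

  lx <- log1p(sc)
  rows <- list()
  for (g in groups) {
    in_g <- labels == g
    lfc <- (rowMeans(lx[, in_g, drop = FALSE]) -
              rowMeans(lx[, !in_g, drop = FALSE])) / log(2)
    pct <- rowMeans(sc[, in_g, drop = FALSE] > 0)
    ok <- lfc >= log2(min_fold) & pct >= min_frac
    ord <- order(-lfc, rownames(sc))
    picked <- ord[ok[ord]][seq_len(min(top_n, sum(ok)))]
    if (!length(picked)) {
      if (!allow_relaxed)
        stop("subgroup '", g, "' has no qualifying marker gene ",
             "(set allow_relaxed = TRUE to keep its best-ranked genes)")
      warning("subgroup '", g, "' has no gene passing thresholds; ",
              "keeping its best-ranked genes")
      picked <- ord[seq_len(min(top_n, length(ord)))]
    }
    rows[[g]] <- data.frame(gene = rownames(sc)[picked], subgroup = g,
                            log2_fc = unname(lfc[picked]),
                            pct_expressing = unname(pct[picked]),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a signature matrix from markers
#'
#' Entry (g, k) is the arithmetic mean of untransformed expression of marker
#' gene g over cells labelled k (the classic deconvolution-reference
#' convention; not a mean of logs). Column order follows the sorted subgroup
#' vocabulary; deterministic and invariant to cell order and duplication.
#'
#' @param sc genes x cells expression matrix.
#' @param labels named character vector cell -> subgroup.
#' @param markers character vector of marker genes, or a [select_markers()]
#'   provenance data.frame.
#' @return a `myelodiv_signature`: list with `values` (markers x subgroups
#'   matrix) and `provenance`.
#' @export
build_signature <- function(sc, labels, markers) {
  prov <- NULL
  if (is.data.frame(markers)) {
    prov <- markers
    markers <- unique(markers$gene)
  }
  assert_that(length(markers) > 0, "marker list is empty")
  missing <- setdiff(markers, rownames(sc))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  labels <- labels[colnames(sc)]
  groups <- sort(unique(labels))
  markers <- unique(markers)
  vals <- vapply(groups, function(g)
    rowMeans(sc[markers, labels == g, drop = FALSE]), numeric(length(markers)))
  vals <- matrix(vals, nrow = length(markers),
                 dimnames = list(markers, groups))
  if (any(rowSums(vals) == 0)) stop("signature contains all-zero marker rows")
  structure(list(values = vals, provenance = prov),
            class = c("myelodiv_signature", "list"))
}

#' @export
print.myelodiv_signature <- function(x, ...) {
  cat("Signature matrix:", nrow(x$values), "marker genes x",
      ncol(x$values), "subgroups\n")
  invisible(x)
}

#' Write signature (and provenance) TSVs
#' @param sig a [build_signature()] result.
#' @param path signature TSV path; provenance goes to
#'   `<path>.provenance.tsv` when available.
#' @export
write_signature <- function(sig, path) {
  write_expression(sig$values, path)
  if (!is.null(sig$provenance))
    write.table(sig$provenance, paste0(path, ".provenance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
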