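# standard module color vocabulary, assigned by decreasing module size
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white", "skyblue", "saddlebrown",
                   "steelblue", "paleturquoise", "violet", "darkolivegreen",
                   "darkmagenta")

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned network: \eqn{a_{ij} = |cor(g_i, g_j)|^\beta} with unit
#' diagonal. Zero-variance genes are removed (with a message) before the
#' correlation. The signed variant uses \eqn{((1 + cor)/2)^\beta}.
#'
#' @param expr genes x samples matrix (genes become network nodes).
#' @param soft_power soft-threshold exponent beta (default 8).
#' @param signed use the signed network transform (default FALSE).
#' @return genes x genes adjacency matrix.
#' @export
build_adjacency <- function(expr, soft_power = 8L, signed = FALSE) {
  assert_that(ncol(expr) >= 3, "need at least 3 samples")
  assert_that(is_count(soft_power), "soft_power must be a positive integer")
  v <- apply(expr, 1L, var)
  if (any(v == 0)) {
    message("removing ", sum(v == 0), " zero-variance gene(s)")
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- cor(t(expr))
  a <- if (signed) ((1 + r) / 2)^soft_power else abs(r)^soft_power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \eqn{TOM_{ij} = (\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} with \eqn{k_i} the connectivity (row sum
#' minus the diagonal). `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix with unit diagonal.
#' @return TOM matrix in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  assert_that(max(abs(a - t(a))) <= 1e-9, "adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a          # shared-neighbor products plus direct edge
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

module_eigengene <- function(expr_mod) {
  # expr_mod: genes x samples; eigengene = first PC of the standardized
  # expression across samples, zero mean / unit variance, oriented so the
  # mean gene loading is positive
  z <- t(scale(t(expr_mod)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 1, nv = 1)
  e <- sv$v[, 1L]
  if (mean(sv$u[, 1L]) < 0) e <- -e
  e <- (e - mean(e)) / sd(e)
  names(e) <- colnames(expr_mod)
  ve <- sv$d[1L]^2 / sum(sv$d^2)
  list(eigengene = e, variance_explained = ve)
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut statically at
#' `cut_height`; clusters smaller than `min_module_size` fall into `grey`
#' (unassigned). Modules are labelled with color names by decreasing size.
#' An external cutter can be plugged in via `cutter` (a function taking the
#' hclust tree and returning integer cluster labels).
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param expr genes x samples matrix (for eigengenes).
#' @param min_module_size smallest retained module (default 30).
#' @param cut_height static cut height on 1 - TOM (default 0.99).
#' @param cutter optional replacement for the static cut.
#' @return list of modules, each with `label`, `genes`, `eigengene`,
#'   `variance_explained`; attribute `grey` holds unassigned genes.
#' @export
detect_modules <- function(tom, expr, min_module_size = 30L,
                           cut_height = 0.99, cutter = NULL) {
  genes <- rownames(tom)
  tree <- hclust(as.dist(1 - tom), method = "average")
  cl <- if (is.null(cutter)) cutree(tree, h = cut_height) else cutter(tree)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  grey <- genes[!(cl %in% as.integer(keep))]
  keep <- keep[order(-sizes[keep], keep)]
  if (!length(keep)) {
    warning("all genes unassigned (grey); no modules detected")
    out <- list()
    attr(out, "grey") <- genes
    return(out)
  }
  out <- lapply(seq_along(keep), function(i) {
    g <- genes[cl == as.integer(keep[i])]
    eg <- module_eigengene(expr[g, , drop = FALSE])
    list(label = MODULE_COLORS[((i - 1L) %% length(MODULE_COLORS)) + 1L],
         genes = sort(g), eigengene = eg$eigengene,
         variance_explained = eg$variance_explained)
  })
  names(out) <- vapply(out, `[[`, character(1L), "label")
  attr(out, "grey") <- grey
  out
}

#' Correlate module eigengenes with the diversity index
#'
#' Pearson correlation of every module eigengene against the Shannon index;
#' the best module maximizes `|rho|` among those with p < `alpha`, and its
#' eigengene sign is normalized so the selected correlation is positive.
#'
#' @param modules a [detect_modules()] result.
#' @param dt a [diversity_table()] result.
#' @param alpha significance gate for selection (default 0.05).
#' @return list with `table` (module, rho, p_value, n) and `best` (module
#'   name or NA when none is significant).
#' @export
module_trait_correlation <- function(modules, dt, alpha = 0.05) {
  assert_that(length(modules) > 0, "no modules to test")
  ids <- dt$sample_id[!dt$degenerate & !is.na(dt$shannon)]
  common <- intersect(ids, names(modules[[1L]]$eigengene))
  assert_that(length(common) >= 10, "need at least 10 overlapping samples")
  H <- dt$shannon[match(common, dt$sample_id)]
  rows <- lapply(names(modules), function(m) {
    e <- modules[[m]]$eigengene[common]
    ct <- cor.test(e, H)
    data.frame(module = m, rho = unname(ct$estimate), p_value = ct$p.value,
               n = length(common), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sig <- tab[tab$p_value < alpha, , drop = FALSE]
  best <- if (nrow(sig)) sig$module[which.max(abs(sig$rho))] else NA_character_
  if (!is.na(best) && tab$rho[tab$module == best] < 0) {
    modules[[best]]$eigengene <- -modules[[best]]$eigengene
    tab$rho[tab$module == best] <- -tab$rho[tab$module == best]
  }
  list(table = tab, best = best, modules = modules)
}
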