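#' Random-forest importance ranking of module genes
#'
#' Scales and centers the module genes, splits samples 70/30 (seeded),
#' regresses the Shannon index on the training split with a regression
#' random forest (bundled CART implementation; 500 trees, mtry = p/3,
#' variance-reduction splits), and ranks genes by permutation importance on
#' the held-out split: the increase in held-out MSE when a gene's column is
#' permuted, averaged over `n_permutations` shuffles and clipped at zero.
#' Ties in importance break lexicographically by gene ID.
#'
#' @param expr genes x samples matrix restricted (or restrictable via
#'   `genes`) to the module of interest.
#' @param dt a [diversity_table()] result.
#' @param genes optional module gene subset.
#' @param n_trees forest size (default 500).
#' @param train_frac training fraction (default 0.7).
#' @param min_node minimum node size to attempt a split (default 5).
#' @param n_permutations permutations per gene (default 3).
#' @param seed RNG seed for the split, bootstrap and permutations.
#' @param cohort tag recorded in the result.
#' @param holdout_floor warn when held-out predicted-vs-actual correlation
#'   falls below this (default 0.5).
#' @return a `myelodiv_importance`: data.frame (gene, importance, rank) with
#'   attributes `holdout_cor`, `seed`, `cohort`.
#' @export
rank_importance <- function(expr, dt, genes = NULL, n_trees = 500L,
                            train_frac = 0.7, min_node = 5L,
                            n_permutations = 3L, seed = 1L,
                            cohort = NA_character_, holdout_floor = 0.5) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop("module gene(s) absent: ", paste(missing, collapse = ", "))
    expr <- expr[genes, , drop = FALSE]
  }
  ids <- intersect(colnames(expr),
                   dt$sample_id[!dt$degenerate & !is.na(dt$shannon)])
  assert_that(length(ids) >= 30, "need at least 30 samples")
  X <- scale(t(expr[, ids, drop = FALSE]))   # samples x genes, z-scored
  X[!is.finite(X)] <- 0
  y <- dt$shannon[match(ids, dt$sample_id)]
  p <- ncol(X)

  with_seed(derive_seed(seed, "rf"), {
    n <- nrow(X)
    tr <- sort(sample.int(n, floor(train_frac * n)))
    te <- setdiff(seq_len(n), tr)
    forest <- .grow_forest_cpp(X[tr, , drop = FALSE], y[tr], n_trees,
                               max(1L, floor(p / 3)), min_node)
    pred <- .predict_forest_cpp(forest, X[te, , drop = FALSE])
    hold_cor <- suppressWarnings(cor(pred, y[te]))
    imp <- .perm_importance_cpp(forest, X[te, , drop = FALSE], y[te],
                                n_permutations)
  })
  if (is.na(hold_cor) || hold_cor < holdout_floor)
    warning(sprintf("module weakly predictive (held-out cor = %.3f)",
                    hold_cor))
  out <- data.frame(gene = colnames(X), importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "holdout_cor") <- hold_cor
  attr(out, "seed") <- seed
  attr(out, "cohort") <- cohort
  class(out) <- c("myelodiv_importance", "data.frame")
  out
}

#' Combine importance rankings and filter collinearity
#'
#' Takes the union of each cohort's top-`top_k` genes (default 15), orders
#' candidates by their best importance across cohorts, and greedily drops
#' any gene whose training-set |Pearson r| with an already-kept gene reaches
#' `r_threshold` (default 0.75). With `combine = "intersection"` only genes
#' in every cohort's top list are candidates.
#'
#' @param rankings list of [rank_importance()] results (>= 1 cohorts).
#' @param expr genes x samples training expression for the correlations.
#' @param top_k per-cohort depth (default 15).
#' @param r_threshold collinearity cutoff (default 0.75).
#' @param combine `"union"` (default) or `"intersection"`.
#' @return character vector of kept genes (ordered by importance).
#' @export
combine_and_filter <- function(rankings, expr, top_k = 15L,
                               r_threshold = 0.75,
                               combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (inherits(rankings, "myelodiv_importance")) rankings <- list(rankings)
  tops <- lapply(rankings, function(r) r$gene[seq_len(min(top_k, nrow(r)))])
  cand <- if (combine == "union") Reduce(union, tops) else
    Reduce(intersect, tops)
  assert_that(length(cand) > 0, "no candidate genes after combination")
  best <- vapply(cand, function(g)
    max(vapply(rankings, function(r) {
      v <- r$importance[r$gene == g]
      if (length(v)) v else -Inf
    }, numeric(1L))), numeric(1L))
  cand <- cand[order(-best, cand)]

  missing <- setdiff(cand, rownames(expr))
  if (length(missing))
    stop("candidate gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  kept <- character()
  for (g in cand) {
    if (!length(kept)) { kept <- g; next }
    r <- abs(cor(expr[g, ], t(expr[kept, , drop = FALSE])))
    if (all(r < r_threshold, na.rm = TRUE)) kept <- c(kept, g)
  }
  assert_that(length(kept) > 0, "collinearity filter removed every gene")
  kept
}

#' Fit the linear surrogate diversity model
#'
#' Ordinary least squares of the Shannon index on z-scaled expression of the
#' selected genes. The scaler (per-gene training mean and sd) is stored so
#' [score_samples()] reproduces fitted values exactly; an empty gene list
#' yields the intercept-only model (constant prediction at the mean
#' diversity).
#'
#' @param expr genes x samples training expression.
#' @param dt a [diversity_table()] result.
#' @param genes model gene list (e.g. from [combine_and_filter()]).
#' @param r_threshold collinearity invariant asserted on every fit
#'   (default 0.75).
#' @return a `myelodiv_surrogate`: list with `genes`, `intercept`,
#'   `coefficients`, `center`, `scale`, `train_cor` (in-sample Spearman),
#'   `provenance`.
#' @export
fit_surrogate <- function(expr, dt, genes, r_threshold = 0.75) {
  ids <- intersect(colnames(expr),
                   dt$sample_id[!dt$degenerate & !is.na(dt$shannon)])
  y <- dt$shannon[match(ids, dt$sample_id)]
  assert_that(length(ids) > length(genes) + 1,
              "need more samples than genes + 1")
  if (!length(genes)) {
    model <- structure(list(genes = character(), intercept = mean(y),
                            coefficients = numeric(), center = numeric(),
                            scale = numeric(), train_cor = NA_real_,
                            provenance = list(n_train = length(ids))),
                       class = c("myelodiv_surrogate", "list"))
    return(model)
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("model gene(s) absent: ", paste(missing, collapse = ", "))
  X <- t(expr[genes, ids, drop = FALSE])
  if (length(genes) > 1) {
    rr <- abs(cor(X))
    diag(rr) <- 0
    if (any(rr >= r_threshold)) {
      bad <- which(rr >= r_threshold, arr.ind = TRUE)[1L, ]
      stop("collinear gene pair at |r| >= ", r_threshold, ": ",
           genes[bad[1L]], " / ", genes[bad[2L]])
    }
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1) stop("rank-deficient design matrix")
  fit <- lm(y ~ Z)
  beta <- coef(fit)
  structure(list(
    genes = genes,
    intercept = unname(beta[1L]),
    coefficients = setNames(unname(beta[-1L]), genes),
    center = setNames(unname(ctr), genes),
    scale = setNames(unname(scl), genes),
    train_cor = suppressWarnings(
      cor(unname(fitted(fit)), y, method = "spearman")),
    provenance = list(n_train = length(ids), r_threshold = r_threshold)
  ), class = c("myelodiv_surrogate", "list"))
}

#' @export
print.myelodiv_surrogate <- function(x, ...) {
  cat("Surrogate diversity model:", length(x$genes), "genes",
      sprintf("(train Spearman = %.3f)\n", x$train_cor))
  if (length(x$genes))
    print(round(x$coefficients, 4))
  invisible(x)
}

#' Score samples with a surrogate model
#'
#' Applies the stored training scaler and linear predictor. All model genes
#' must be present unless `impute_missing = TRUE`, in which case absent
#' genes sit at their training mean (zero after scaling). Extra genes in the
#' matrix are ignored.
#'
#' @param model a [fit_surrogate()] result.
#' @param expr genes x samples matrix.
#' @param impute_missing mean-impute absent model genes (default FALSE).
#' @return named numeric vector of surrogate diversity scores.
#' @export
score_samples <- function(model, expr, impute_missing = FALSE) {
  if (!length(model$genes))
    return(setNames(rep(model$intercept, ncol(expr)), colnames(expr)))
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) && !impute_missing)
    stop("model gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  Z <- matrix(0, ncol(expr), length(model$genes),
              dimnames = list(colnames(expr), model$genes))
  present <- setdiff(model$genes, missing)
  Z[, present] <- sweep(
    sweep(t(expr[present, , drop = FALSE]), 2L, model$center[present]),
    2L, model$scale[present], "/")
  drop(model$intercept + Z %*% model$coefficients[model$genes])
}

#' Survival validation of the surrogate index
#'
#' Univariate Cox regression of the endpoint on the surrogate score, plus a
#' risk table of samples ranked by score (the risk-plot surface).
#'
#' @param scores named numeric vector from [score_samples()].
#' @param clin clinical table.
#' @inheritParams fit_cox
#' @return list with `cox` (a [fit_cox()] row) and `risk_table`.
#' @export
validate_surrogate <- function(scores, clin, time_col = "time",
                               event_col = "event") {
  ids <- intersect(names(scores), clin$sample_id)
  assert_that(length(ids) >= 10, "need at least 10 overlapping samples")
  d <- clin[match(ids, clin$sample_id), , drop = FALSE]
  d$surrogate_index <- scores[ids]
  cox <- fit_cox(d, "surrogate_index", model = "univariate",
                 time_col = time_col, event_col = event_col)
  risk <- d[order(-d$surrogate_index),
            c("sample_id", "surrogate_index", time_col, event_col)]
  rownames(risk) <- NULL
  list(cox = cox, risk_table = risk)
}

#' Export a surrogate model as JSON
#' @param model a [fit_surrogate()] result.
#' @param path output path.
#' @export
write_surrogate <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a surrogate model from JSON
#' @param path JSON written by [write_surrogate()].
#' @export
read_surrogate <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  l$genes <- as.character(l$genes)
  for (f in c("coefficients", "center", "scale"))
    l[[f]] <- setNames(as.numeric(l[[f]]), l$genes)
  structure(l, class = c("myelodiv_surrogate", "list"))
}
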