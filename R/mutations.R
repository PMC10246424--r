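# presence matrix: one row per sample, one column per gene, after per-sample
# per-gene deduplication (a gene counts once per sample regardless of how
# many variants hit it). Silent-category variants are excluded by default.
mutation_presence <- function(mut, samples, include_silent = FALSE) {
  if (!include_silent)
    mut <- mut[mut$variant_classification %in% NONSYNONYMOUS_CLASSES, ,
               drop = FALSE]
  mut <- unique(mut[, c("sample_id", "gene")])
  mut <- mut[mut$sample_id %in% samples, , drop = FALSE]
  genes <- sort(unique(mut$gene))
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  if (nrow(mut)) m[cbind(mut$sample_id, mut$gene)] <- TRUE
  m
}

#' Differential mutation prevalence between diversity strata
#'
#' Per gene, tests the 2x2 table (stratum x mutated) with the chi-square
#' test (Yates correction off by default, matching the large-sample
#' convention). The odds ratio is oriented as
#' `(high&mutated * low&wildtype) / (high&wildtype * low&mutated)`, so
#' OR > 1 means the gene is more often mutated in the high-diversity
#' stratum; a Haldane-Anscombe +0.5 correction is applied when any cell is
#' zero. Genes passing `p < 0.01` are flagged differential; significance
#' tiers mark p < 0.05 / 0.001 / 0.0001.
#'
#' @param mut mutation table ([read_maf()] layout).
#' @param strata a [stratify_by_quantile()] result.
#' @param min_mutated minimum mutated samples overall for a gene to be
#'   tested (default 3).
#' @param yates apply Yates continuity correction (default FALSE).
#' @param include_silent count Silent-category variants (default FALSE).
#' @return data.frame: gene, count_high, n_high, count_low, n_low,
#'   odds_ratio, continuity_corrected, chi_square, p_value, tier,
#'   differential.
#' @export
differential_prevalence <- function(mut, strata, min_mutated = 3L,
                                    yates = FALSE, include_silent = FALSE) {
  hi <- strata$sample_id[strata$stratum == "high"]
  lo <- strata$sample_id[strata$stratum == "low"]
  assert_that(length(hi) > 0 && length(lo) > 0,
              "both strata must be non-empty")
  pres <- mutation_presence(mut, c(hi, lo), include_silent)
  counts <- colSums(pres)
  genes <- names(counts)[counts >= min_mutated]

  rows <- lapply(genes, function(g) {
    a <- sum(pres[hi, g]); b <- length(hi) - a    # high: mutated / wildtype
    c_ <- sum(pres[lo, g]); d <- length(lo) - c_  # low
    corrected <- any(c(a, b, c_, d) == 0)
    or <- if (corrected) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    ct <- suppressWarnings(
      chisq.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE), correct = yates))
    data.frame(gene = g, count_high = a, n_high = length(hi),
               count_low = c_, n_low = length(lo), odds_ratio = or,
               continuity_corrected = corrected,
               chi_square = unname(ct$statistic),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(gene = character(), count_high = integer(),
               n_high = integer(), count_low = integer(), n_low = integer(),
               odds_ratio = numeric(), continuity_corrected = logical(),
               chi_square = numeric(), p_value = numeric())
  out$tier <- cut(out$p_value, c(-Inf, 1e-4, 1e-3, 0.05, Inf),
                  labels = c("***", "**", "*", ""))
  out$differential <- out$p_value < 0.01
  out[order(out$p_value), , drop = FALSE]
}

#' Pairwise mutation co-occurrence / mutual exclusivity
#'
#' Two-sided Fisher exact test on each gene pair's 2x2 sample-presence
#' table, among the `max_genes` most prevalent genes mutated in at least
#' `floor_n` samples (the reference implementation's default depth is 25
#' genes, which also keeps the pair count tractable). Direction is
#' co-occurring when the sample-level odds ratio exceeds 1, mutually
#' exclusive below 1; `signed_log10_p` is positive for co-occurrence.
#'
#' @param mut mutation table.
#' @param samples sample universe (character vector).
#' @param floor_n prevalence floor (default 5 mutated samples).
#' @param max_genes cap on genes tested, by decreasing prevalence then gene
#'   ID (default 25).
#' @param include_silent count Silent-category variants (default FALSE).
#' @return data.frame: gene1, gene2, p_value, odds_ratio, direction,
#'   signed_log10_p (symmetric pairs listed once, gene1 < gene2).
#' @export
somatic_interactions <- function(mut, samples, floor_n = 5L,
                                 max_genes = 25L, include_silent = FALSE) {
  pres <- mutation_presence(mut, samples, include_silent)
  counts <- colSums(pres)
  genes <- colnames(pres)[counts >= floor_n]
  assert_that(length(genes) >= 2,
              "need at least 2 genes above the prevalence floor")
  genes <- genes[order(-counts[genes], genes)][
    seq_len(min(max_genes, length(genes)))]
  pairs <- utils::combn(sort(genes), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    tab <- table(factor(pres[, g1], levels = c(TRUE, FALSE)),
                 factor(pres[, g2], levels = c(TRUE, FALSE)))
    ft <- fisher.test(tab)
    co <- unname(ft$estimate) > 1
    data.frame(gene1 = g1, gene2 = g2, p_value = ft$p.value,
               odds_ratio = unname(ft$estimate),
               direction = if (co) "co-occurring" else "mutually-exclusive",
               signed_log10_p = (if (co) 1 else -1) *
                 -log10(max(ft$p.value, 1e-300)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tumor mutation burden, overall and panel-restricted
#'
#' TMB is the number of qualifying mutation rows per sample divided by the
#' genome size in megabases. Raw rows are counted (burden is about events),
#' unlike the presence-based prevalence tests. `tmb_signature` restricts the
#' count to a gene panel (see [signature_tmb_panel()]); an empty panel gives
#' zero everywhere.
#'
#' @param mut mutation table.
#' @param samples sample universe.
#' @param genome_size_mb denominator in megabases (default 38, a standard
#'   exome footprint).
#' @param panel optional character vector of panel genes.
#' @param include_silent count Silent-category rows (default FALSE).
#' @return data.frame: sample_id, tmb_all, tmb_signature (NA without panel).
#' @export
compute_tmb <- function(mut, samples, genome_size_mb = 38, panel = NULL,
                        include_silent = FALSE) {
  assert_that(genome_size_mb > 0, "genome_size_mb must be positive")
  if (!include_silent)
    mut <- mut[mut$variant_classification %in% NONSYNONYMOUS_CLASSES, ,
               drop = FALSE]
  mut <- mut[mut$sample_id %in% samples, , drop = FALSE]
  all_counts <- table(factor(mut$sample_id, levels = samples))
  out <- data.frame(sample_id = samples,
                    tmb_all = as.numeric(all_counts) / genome_size_mb,
                    stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    pm <- mut[mut$gene %in% panel, , drop = FALSE]
    pc <- table(factor(pm$sample_id, levels = samples))
    out$tmb_signature <- as.numeric(pc) / genome_size_mb
  } else {
    out$tmb_signature <- NA_real_
  }
  attr(out, "panel") <- panel
  out
}

#' Build the signature-TMB gene panel
#'
#' Union of the top-`k` most prevalent genes of each stratum, the genes in
#' significant pairwise interactions, and the differential-prevalence genes.
#'
#' @param mut mutation table.
#' @param strata a [stratify_by_quantile()] result.
#' @param k per-stratum prevalence depth (default 10).
#' @param alpha significance level for interactions (default 0.05).
#' @param min_mutated,floor_n,include_silent see
#'   [differential_prevalence()] and [somatic_interactions()].
#' @return character vector of panel genes.
#' @export
signature_tmb_panel <- function(mut, strata, k = 10L, alpha = 0.05,
                                min_mutated = 3L, floor_n = 5L,
                                include_silent = FALSE) {
  wf <- mutation_waterfall_summary(mut, strata, k = k,
                                   include_silent = include_silent)
  top_genes <- unlist(lapply(wf, function(w) w$genes))
  dp <- tryCatch(differential_prevalence(mut, strata,
                                         min_mutated = min_mutated,
                                         include_silent = include_silent),
                 error = function(e) NULL)
  diff_genes <- if (is.null(dp)) character() else dp$gene[dp$differential]
  inter <- tryCatch({
    si <- somatic_interactions(
      mut, strata$sample_id[strata$stratum %in% c("high", "low")],
      floor_n = floor_n, include_silent = include_silent)
    unique(c(si$gene1[si$p_value < alpha], si$gene2[si$p_value < alpha]))
  }, error = function(e) character())
  sort(unique(c(top_genes, diff_genes, inter)))
}

#' Top-k mutated genes and presence grids per stratum
#'
#' Per stratum, ranks genes by mutated-sample count (ties broken
#' lexicographically by gene ID) and returns the top-`k` with a
#' gene x sample grid of variant-class labels (the waterfall-plot surface).
#'
#' @param mut mutation table.
#' @param strata a [stratify_by_quantile()] result.
#' @param k genes per stratum (default 10).
#' @param include_silent count Silent-category variants (default FALSE).
#' @return named list (one element per stratum) of lists with `genes`,
#'   `frequency` and `grid` (character matrix, "" where wild-type).
#' @export
mutation_waterfall_summary <- function(mut, strata, k = 10L,
                                       include_silent = FALSE) {
  out <- list()
  for (st in c("high", "low")) {
    ids <- strata$sample_id[strata$stratum == st]
    if (!length(ids)) next
    pres <- mutation_presence(mut, ids, include_silent)
    counts <- colSums(pres)
    ord <- order(-counts, colnames(pres))
    top <- colnames(pres)[ord][seq_len(min(k, ncol(pres)))]
    grid <- matrix("", length(top), length(ids),
                   dimnames = list(top, ids))
    sub <- mut[mut$sample_id %in% ids & mut$gene %in% top, , drop = FALSE]
    if (!include_silent)
      sub <- sub[sub$variant_classification %in% NONSYNONYMOUS_CLASSES, ,
                 drop = FALSE]
    sub <- sub[!duplicated(sub[, c("sample_id", "gene")]), , drop = FALSE]
    if (nrow(sub))
      grid[cbind(sub$gene, sub$sample_id)] <- sub$variant_classification
    out[[st]] <- list(genes = top,
                      frequency = unname(counts[top]) / length(ids),
                      grid = grid)
  }
  assert_that(length(out) > 0, "no non-empty strata")
  out
}
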