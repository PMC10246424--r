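#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#' Defaults describe a breast-cancer-like setting: 15 myeloid subgroups (the
#' granularity of the single-cell reference this pipeline emulates), sparse
#' Dirichlet mixing so per-sample diversity varies, a protective log-hazard
#' of -1 per unit Shannon diversity, and a heavy-tailed per-sample mutation
#' propensity so overall mutation burden dwarfs any single gene panel.
#'
#' @param n_subgroups number of myeloid subgroups K (>= 2).
#' @param n_marker_genes_per_subgroup planted marker genes per subgroup.
#' @param n_background_genes genes with no subgroup specificity.
#' @param n_cells_per_subgroup single-cell library size per subgroup.
#' @param n_bulk_samples bulk cohort size.
#' @param mixture_concentration Dirichlet concentration vector (length K or
#'   scalar, recycled); strictly positive.
#' @param noise_sd log-scale multiplicative noise sd for bulk expression.
#' @param marker_fold fold elevation of a marker in its own subgroup.
#' @param sc_dispersion negative-binomial dispersion of single-cell counts
#'   (variance = mu + dispersion * mu^2); 0 gives deterministic dense means.
#' @param hazard_coefficient log-hazard per unit true Shannon diversity.
#' @param baseline_hazard exponential baseline event rate per time unit.
#' @param censoring_rate expected fraction of censored samples, in [0,1].
#' @param response_intercept,response_slope logistic model for binary
#'   neoadjuvant response on true diversity.
#' @param n_surrogate_genes planted surrogate predictor genes.
#' @param surrogate_effect log-expression shift per SD of true diversity for
#'   planted surrogate genes, on the same natural-log scale as `noise_sd`
#'   (see vignette for the collinearity rationale).
#' @param panel_genes names of the diversity-linked mutation panel.
#' @param mutation_rate_high,mutation_rate_low per-gene mutation probability
#'   for panel genes in the top-quartile-diversity stratum vs all others.
#' @param n_mutation_background_genes,background_mutation_rate background
#'   mutation panel size and common per-gene rate.
#' @param tmb_sdlog sdlog of the per-sample log-normal mutation propensity
#'   (meanlog fixed at -tmb_sdlog^2/2 so the mean factor is 1).
#' @param genome_size_mb exome denominator for mutations-per-megabase.
#' @param seed global seed; fans out to independent per-component substreams.
#' @return a validated `myelodiv_sim_config` list.
#' @export
simulation_config <- function(n_subgroups = 15L,
                              n_marker_genes_per_subgroup = 5L,
                              n_background_genes = 200L,
                              n_cells_per_subgroup = 50L,
                              n_bulk_samples = 200L,
                              mixture_concentration = 0.5,
                              noise_sd = 0.1,
                              marker_fold = 8,
                              sc_dispersion = 0.5,
                              hazard_coefficient = -1,
                              baseline_hazard = 0.1,
                              censoring_rate = 0.3,
                              response_intercept = -2,
                              response_slope = 1,
                              n_surrogate_genes = 5L,
                              surrogate_effect = 0.15,
                              panel_genes = c("PIK3CA", "TTN", "CDH1", "PTEN",
                                              "ACACA", "AKAP11", "ATP9A",
                                              "CAPRIN2", "KIAA1009", "MAP3K1"),
                              mutation_rate_high = 0.4,
                              mutation_rate_low = 0.1,
                              n_mutation_background_genes = 500L,
                              background_mutation_rate = 0.08,
                              tmb_sdlog = 1,
                              genome_size_mb = 38,
                              seed = 1L) {
  cfg <- as.list(environment())
  assert_that(is_count(cfg$n_subgroups) && cfg$n_subgroups >= 2,
              "n_subgroups must be an integer >= 2")
  for (f in c("n_marker_genes_per_subgroup", "n_background_genes",
              "n_cells_per_subgroup", "n_bulk_samples"))
    assert_that(is_count(cfg[[f]]), paste(f, "must be a positive integer"))
  cfg$mixture_concentration <- rep_len(as.numeric(mixture_concentration),
                                       cfg$n_subgroups)
  assert_that(all(cfg$mixture_concentration > 0),
              "Dirichlet concentrations must be strictly positive")
  assert_that(is.finite(cfg$hazard_coefficient),
              "hazard_coefficient must be finite")
  assert_that(cfg$censoring_rate >= 0 && cfg$censoring_rate <= 1,
              "censoring_rate must lie in [0,1]")
  for (f in c("mutation_rate_high", "mutation_rate_low",
              "background_mutation_rate"))
    assert_that(cfg[[f]] >= 0 && cfg[[f]] <= 1,
                paste(f, "must lie in [0,1]"))
  assert_that(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(cfg$genome_size_mb > 0, "genome_size_mb must be positive")
  class(cfg) <- c("myelodiv_sim_config", "list")
  cfg
}

subgroup_names <- function(K) sprintf("M%02d", seq_len(K))

# the published 5-gene surrogate panel, used to name planted surrogate genes
# when exactly 5 are requested so the generated world mirrors the real one
#' Published 5-gene surrogate panel
#'
#' The gene list of the clinically oriented 5-gene surrogate diversity model
#' (C3, CD27, GFPT2, GMFG, HLA-DPB1). Coefficients are cohort-specific and
#' must be refit with [fit_surrogate()] on the user's data.
#' @export
FIVE_GENE_PANEL <- c("C3", "CD27", "GFPT2", "GMFG", "HLA-DPB1")

sim_gene_names <- function(cfg) {
  K <- cfg$n_subgroups
  markers <- unlist(lapply(seq_len(K), function(k)
    sprintf("MK_%s_%02d", subgroup_names(K)[k],
            seq_len(cfg$n_marker_genes_per_subgroup))))
  background <- sprintf("BG_%04d", seq_len(cfg$n_background_genes))
  surrogate <- if (cfg$n_surrogate_genes == 5L) FIVE_GENE_PANEL else
    sprintf("SG_%02d", seq_len(cfg$n_surrogate_genes))
  list(markers = markers, background = background, surrogate = surrogate)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

# subgroup-mean profiles for marker + background genes; surrogate genes get a
# flat baseline (their diversity-dependence is planted at the bulk layer)
sim_profiles <- function(cfg) {
  nm <- sim_gene_names(cfg)
  K <- cfg$n_subgroups
  with_seed(derive_seed(cfg$seed, "profiles"), {
    base <- rlnorm(length(nm$markers) + length(nm$background) +
                     length(nm$surrogate), meanlog = log(5), sdlog = 0.5)
  })
  genes <- c(nm$markers, nm$background, nm$surrogate)
  prof <- matrix(rep(base, K), ncol = K,
                 dimnames = list(genes, subgroup_names(K)))
  for (k in seq_len(K)) {
    own <- sprintf("MK_%s_%02d", subgroup_names(K)[k],
                   seq_len(cfg$n_marker_genes_per_subgroup))
    prof[own, k] <- prof[own, k] * cfg$marker_fold
  }
  prof
}

#' Simulate labelled single-cell expression
#'
#' Draws negative-binomial counts around subgroup-mean profiles in which each
#' subgroup's marker genes sit `marker_fold` (default 8x) above their level
#' in every other subgroup. With `sc_dispersion = 0` the dense means are
#' returned verbatim (noiseless construction).
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (genes x cells), `labels` (named character
#'   vector cell -> subgroup) and `truth` (a `GroundTruth` list holding true
#'   fractions, true Shannon diversity, subgroup profiles and the planted
#'   surrogate genes/coefficients).
#' @export
simulate_single_cell <- function(config) {
  cfg <- config
  assert_that(inherits(cfg, "myelodiv_sim_config"),
              "config must come from simulation_config()")
  K <- cfg$n_subgroups
  prof <- sim_profiles(cfg)
  n_cells <- cfg$n_cells_per_subgroup
  labels <- rep(subgroup_names(K), each = n_cells)
  cell_ids <- sprintf("CELL_%05d", seq_along(labels))
  names(labels) <- cell_ids

  counts <- with_seed(derive_seed(cfg$seed, "single_cell"), {
    mu <- prof[, match(labels, colnames(prof)), drop = FALSE]
    if (cfg$sc_dispersion == 0) {
      mu
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$sc_dispersion),
             nrow(mu), ncol(mu))
    }
  })
  dimnames(counts) <- list(rownames(prof), cell_ids)

  truth <- sim_ground_truth(cfg, prof)
  list(counts = counts, labels = labels, truth = truth)
}

#' Generate ground truth only
#'
#' Produces the `GroundTruth` object (true fractions, true Shannon
#' diversity, subgroup profiles, planted surrogate genes) without sampling
#' single-cell counts — convenient for simulations that go straight to the
#' bulk, clinical or mutation layers.
#'
#' @param config a [simulation_config()].
#' @return a `myelodiv_truth` list.
#' @export
simulate_ground_truth <- function(config) sim_ground_truth(config)

sim_ground_truth <- function(cfg, prof = sim_profiles(cfg)) {
  nm <- sim_gene_names(cfg)
  fr <- with_seed(derive_seed(cfg$seed, "fractions"),
                  rdirichlet(cfg$n_bulk_samples, cfg$mixture_concentration))
  dimnames(fr) <- list(sprintf("S%04d", seq_len(cfg$n_bulk_samples)),
                       subgroup_names(cfg$n_subgroups))
  H <- apply(fr, 1L, shannon_index)
  coefs <- rep(cfg$surrogate_effect, cfg$n_surrogate_genes)
  names(coefs) <- nm$surrogate
  structure(list(
    true_fractions = fr,
    true_diversity = H,
    subgroup_profiles = prof,
    marker_genes = nm$markers,
    planted_surrogate_genes = nm$surrogate,
    planted_coefficients = coefs
  ), class = c("myelodiv_truth", "list"))
}

#' Simulate a bulk expression cohort
#'
#' Marker and background genes are exact convex mixtures of the subgroup
#' profiles (`profiles %*% fractions`), perturbed by multiplicative
#' log-normal noise of sd `noise_sd`. Planted surrogate genes are a separate
#' layer: their log expression shifts by `surrogate_effect` per SD of true
#' Shannon diversity around a flat baseline (see the vignette for why a
#' convex mixture alone cannot carry a diversity signal under a symmetric
#' mixing prior).
#'
#' @param config a [simulation_config()].
#' @param truth `GroundTruth` from [simulate_single_cell()] (or regenerated
#'   internally when omitted).
#' @param plant_surrogate include the surrogate-gene layer (default TRUE).
#' @return genes x samples numeric matrix.
#' @export
simulate_bulk <- function(config, truth = NULL, plant_surrogate = TRUE) {
  cfg <- config
  truth <- truth %||% sim_ground_truth(cfg)
  prof <- truth$subgroup_profiles
  fr <- truth$true_fractions
  assert_that(ncol(prof) == ncol(fr),
              "profile and fraction dimensions disagree")
  bulk <- prof %*% t(fr)                      # genes x samples, exact mixture

  if (plant_surrogate && length(truth$planted_surrogate_genes)) {
    H <- truth$true_diversity
    z <- (H - mean(H)) / max(sd(H), 1e-12)
    for (g in truth$planted_surrogate_genes)
      bulk[g, ] <- bulk[g, ] * exp(truth$planted_coefficients[[g]] * z)
  }
  if (cfg$noise_sd > 0) {
    noise <- with_seed(derive_seed(cfg$seed, "bulk_noise"),
                       matrix(rnorm(length(bulk), 0, cfg$noise_sd),
                              nrow(bulk), ncol(bulk)))
    bulk <- bulk * exp(noise)
  }
  bulk
}

#' Simulate clinical outcomes
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(hazard_coefficient * H)` where H is true Shannon
#' diversity, so the Cox proportional-hazards model holds exactly. Censoring
#' is independent: an exponential censoring time whose rate is solved so the
#' expected censored fraction equals `censoring_rate`. Binary response
#' follows
#' `Bernoulli(plogis(response_intercept + response_slope * H))`. Age and
#' intrinsic-subtype covariates are drawn independently of diversity.
#'
#' @param config a [simulation_config()].
#' @param truth ground truth (regenerated when omitted).
#' @return data.frame: sample_id, time, event, response, age, subtype.
#' @export
simulate_clinical <- function(config, truth = NULL) {
  cfg <- config
  assert_that(is.finite(cfg$hazard_coefficient),
              "hazard_coefficient must be finite")
  truth <- truth %||% sim_ground_truth(cfg)
  H <- truth$true_diversity
  n <- length(H)
  with_seed(derive_seed(cfg$seed, "clinical"), {
    rate <- cfg$baseline_hazard * exp(cfg$hazard_coefficient * H)
    t_event <- rexp(n, rate)
    if (cfg$censoring_rate == 0) {
      time <- t_event
      cens <- rep(FALSE, n)
    } else {
      # independent exponential censoring; rate mu solved so that the
      # expected censored fraction E[mu / (rate_i + mu)] hits the target
      mu <- stats::uniroot(
        function(m) mean(m / (rate + m)) - cfg$censoring_rate,
        lower = 1e-12, upper = 1e12, tol = 1e-12)$root
      t_cens <- rexp(n, mu)
      cens <- t_cens < t_event
      time <- pmin(t_event, t_cens)
    }
    response <- rbinom(n, 1L,
                       plogis(cfg$response_intercept + cfg$response_slope * H))
    data.frame(sample_id = names(H),
               time = time,
               event = as.integer(!cens),
               response = response,
               age = round(rnorm(n, 58, 10)),
               subtype = sample(c("LumA", "LumB", "HER2", "Basal"), n,
                                replace = TRUE,
                                prob = c(0.45, 0.25, 0.15, 0.15)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a somatic mutation table
#'
#' Panel genes mutate with exactly `mutation_rate_high` in samples whose
#' true diversity is in the top quartile and `mutation_rate_low` otherwise.
#' Background genes mutate at a common rate scaled by a per-sample
#' log-normal propensity factor (mean 1, sdlog `tmb_sdlog`), emulating the
#' heavy-tailed mutation-burden distribution of real exomes. Genes that
#' never mutate are absent from the output.
#'
#' @param config a [simulation_config()].
#' @param truth ground truth (regenerated when omitted).
#' @return MAF-style data.frame (`sample_id`, `gene`,
#'   `variant_classification`, `protein_position`).
#' @export
simulate_mutations <- function(config, truth = NULL) {
  cfg <- config
  truth <- truth %||% sim_ground_truth(cfg)
  H <- truth$true_diversity
  high <- H >= quantile(H, 0.75)
  samples <- names(H)
  bg_genes <- sprintf("MBG_%04d", seq_len(cfg$n_mutation_background_genes))
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "Splice_Site", "Silent")
  class_p <- c(0.60, 0.10, 0.10, 0.05, 0.05, 0.10)

  with_seed(derive_seed(cfg$seed, "mutations"), {
    f <- rlnorm(length(samples), meanlog = -cfg$tmb_sdlog^2 / 2,
                sdlog = cfg$tmb_sdlog)
    rows <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      p_panel <- if (high[i]) cfg$mutation_rate_high else
        cfg$mutation_rate_low
      p_bg <- min(cfg$background_mutation_rate * f[i], 1)
      hit_panel <- cfg$panel_genes[runif(length(cfg$panel_genes)) < p_panel]
      hit_bg <- bg_genes[runif(length(bg_genes)) < p_bg]
      hits <- c(hit_panel, hit_bg)
      if (!length(hits)) next
      rows[[i]] <- data.frame(
        sample_id = samples[i],
        gene = hits,
        variant_classification = sample(classes, length(hits),
                                        replace = TRUE, prob = class_p),
        protein_position = sample.int(1000L, length(hits), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  })
}

#' Write a full synthetic cohort to disk
#'
#' Emits every artifact the pipeline consumes: single-cell MTX + labels,
#' bulk TSV, clinical TSV, MAF TSV and ground-truth JSON.
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return invisibly, the list of generated objects.
#' @export
simulate_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulate_single_cell(config)
  bulk <- simulate_bulk(config, sc$truth)
  clin <- simulate_clinical(config, sc$truth)
  mut <- simulate_mutations(config, sc$truth)

  write_mtx(sc$counts, file.path(dir, "single_cell"))
  write.table(data.frame(cell_id = names(sc$labels), subgroup = sc$labels),
              file.path(dir, "cell_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_expression(bulk, file.path(dir, "bulk.tsv"))
  write_clinical(clin, file.path(dir, "clinical.tsv"))
  write_maf(mut, file.path(dir, "mutations.maf"))
  jsonlite::write_json(list(
    true_fractions = sc$truth$true_fractions,
    true_diversity = sc$truth$true_diversity,
    planted_surrogate_genes = sc$truth$planted_surrogate_genes,
    planted_coefficients = sc$truth$planted_coefficients
  ), file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(list(sc = sc, bulk = bulk, clinical = clin, mutations = mut))
}
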