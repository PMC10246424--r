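test_that("config validation enforces invariants", {
  expect_error(simulation_config(n_subgroups = 1L), ">= 2")
  expect_error(simulation_config(n_cells_per_subgroup = 0L), "positive")
  expect_error(simulation_config(mixture_concentration = c(1, -1)),
               "strictly positive")
  expect_error(simulation_config(censoring_rate = 1.2), "0,1")
  expect_error(simulation_config(hazard_coefficient = NaN), "finite")
  expect_error(simulation_config(mutation_rate_high = 1.5), "0,1")
})

test_that("noiseless single-cell construction puts markers at background level elsewhere", {
  cfg <- tiny_config(sc_dispersion = 0, noise_sd = 0,
                     n_marker_genes_per_subgroup = 1L)
  sc <- simulate_single_cell(cfg)
  prof <- sc$truth$subgroup_profiles
  for (k in seq_len(cfg$n_subgroups)) {
    mk <- sprintf("MK_M%02d_01", k)
    other <- setdiff(seq_len(cfg$n_subgroups), k)
    # outside its own subgroup the marker sits exactly at its baseline
    expect_equal(unname(prof[mk, other]),
                 rep(prof[mk, k] / cfg$marker_fold, length(other)),
                 tolerance = 1e-12)
    cells_other <- names(sc$labels)[sc$labels != sprintf("M%02d", k)]
    expect_true(all(sc$counts[mk, cells_other] == prof[mk, other][1]))
  }
})

test_that("generators are bit-reproducible and independent across components", {
  cfg <- tiny_config()
  a <- simulate_single_cell(cfg)
  b <- simulate_single_cell(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(simulate_bulk(cfg, a$truth), simulate_bulk(cfg, b$truth))
  expect_identical(simulate_clinical(cfg, a$truth),
                   simulate_clinical(cfg, a$truth))
  expect_identical(simulate_mutations(cfg, a$truth),
                   simulate_mutations(cfg, a$truth))
  # changing the mutation layer must not perturb the bulk layer
  cfg2 <- tiny_config(mutation_rate_high = 0.2)
  expect_identical(simulate_bulk(cfg2, a$truth), simulate_bulk(cfg, a$truth))
  cfg3 <- tiny_config(seed = 999L)
  expect_false(identical(simulate_bulk(cfg3), simulate_bulk(cfg)))
})

test_that("marker means match configured generator means within 3 SE", {
  cfg <- simulation_config(n_subgroups = 3L, n_cells_per_subgroup = 50L,
                           n_marker_genes_per_subgroup = 3L,
                           n_background_genes = 10L, seed = 21L)
  sc <- simulate_single_cell(cfg)
  prof <- sc$truth$subgroup_profiles
  disp <- cfg$sc_dispersion
  for (k in 1:3) {
    cells <- names(sc$labels)[sc$labels == sprintf("M%02d", k)]
    for (g in sprintf("MK_M%02d_%02d", k, 1:3)) {
      mu <- prof[g, k]
      se <- sqrt((mu + disp * mu^2) / length(cells))
      expect_lt(abs(mean(sc$counts[g, cells]) - mu), 3 * se + 1e-9)
    }
  }
})

test_that("noiseless bulk is an exact convex mixture of profiles", {
  cfg <- tiny_config(noise_sd = 0)
  tr <- myelodiv:::sim_ground_truth(cfg)
  # degenerate fraction rows: unit vector and uniform
  tr$true_fractions[1, ] <- c(1, 0, 0, 0)
  tr$true_fractions[2, ] <- rep(0.25, 4)
  bulk <- simulate_bulk(cfg, tr, plant_surrogate = FALSE)
  expect_equal(bulk[, 1], tr$subgroup_profiles[, 1], tolerance = 1e-12)
  expect_equal(bulk[, 2], rowMeans(tr$subgroup_profiles), tolerance = 1e-12)
  expect_equal(bulk, tr$subgroup_profiles %*% t(tr$true_fractions),
               tolerance = 1e-12)
})

test_that("bulk log-residual sd matches the configured noise level", {
  cfg <- simulation_config(n_bulk_samples = 200L, noise_sd = 0.1,
                           n_background_genes = 50L, seed = 31L)
  tr <- myelodiv:::sim_ground_truth(cfg)
  noiseless <- simulate_bulk(simulation_config(n_bulk_samples = 200L,
                                               noise_sd = 0,
                                               n_background_genes = 50L,
                                               seed = 31L), tr)
  noisy <- simulate_bulk(cfg, tr)
  res_sd <- apply(log(noisy) - log(noiseless), 1L, sd)
  expect_true(all(abs(res_sd - 0.1) / 0.1 < 0.15))
})

test_that("clinical generator plants the survival and response links", {
  # protective diversity: strong single-cohort check
  cfg <- simulation_config(n_bulk_samples = 800L, hazard_coefficient = -1,
                           seed = 41L)
  tr <- myelodiv:::sim_ground_truth(cfg)
  cl <- simulate_clinical(cfg, tr)
  cl$shannon <- tr$true_diversity[cl$sample_id]
  cx <- fit_cox(cl, "shannon")
  expect_lt(cx$hazard_ratio, 1)
  expect_lt(cx$ci_upper, 1)
  expect_equal(mean(cl$event == 0), cfg$censoring_rate, tolerance = 0.2)

  # null hazard: log-rank p not extreme, null response: OR CI covers 1 in
  # most replicates
  cover <- logical(10)
  for (r in 1:10) {
    cfg0 <- simulation_config(n_bulk_samples = 150L, hazard_coefficient = 0,
                              response_slope = 0, seed = 500L + r)
    tr0 <- myelodiv:::sim_ground_truth(cfg0)
    cl0 <- simulate_clinical(cfg0, tr0)
    lg <- fit_logistic_response(cl0, setNames(tr0$true_diversity,
                                              names(tr0$true_diversity)))
    cover[r] <- lg$ci_lower <= 1 && lg$ci_upper >= 1
  }
  expect_gte(sum(cover), 8)
})

test_that("mutation generator honours rates, null case and absent genes", {
  cfg <- tiny_config(n_bulk_samples = 200L, mutation_rate_high = 0.4,
                     mutation_rate_low = 0.4)
  tr <- myelodiv:::sim_ground_truth(cfg)
  mut <- simulate_mutations(cfg, tr)
  dt <- diversity_table(tr$true_fractions)
  st <- stratify_by_quantile(dt)
  dp <- differential_prevalence(mut, st)
  panel <- dp[dp$gene %in% cfg$panel_genes, ]
  expect_gt(nrow(panel), 5)
  expect_lt(abs(mean(log(panel$odds_ratio))), 0.5)  # OR ~ 1 under the null

  cfg0 <- tiny_config(mutation_rate_high = 0, mutation_rate_low = 0,
                      background_mutation_rate = 0.1)
  mut0 <- simulate_mutations(cfg0, myelodiv:::sim_ground_truth(cfg0))
  expect_false(any(cfg0$panel_genes %in% mut0$gene))
})

test_that("simulate_cohort writes all artifacts consistently", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  obj <- simulate_cohort(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("bulk.tsv", "clinical.tsv", "mutations.maf", "ground_truth.json",
           "cell_labels.tsv", "single_cell/matrix.mtx")))))
  bulk <- read_expression(file.path(dir, "bulk.tsv"))
  expect_equal(bulk, obj$bulk, tolerance = 0)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(gt$planted_surrogate_genes),
               sort(obj$sc$truth$planted_surrogate_genes))
})
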