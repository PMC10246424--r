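maf_from_presence <- function(pres, class = "Missense_Mutation") {
  idx <- which(pres, arr.ind = TRUE)
  data.frame(sample_id = rownames(pres)[idx[, 1L]],
             gene = colnames(pres)[idx[, 2L]],
             variant_classification = class,
             protein_position = 1L, stringsAsFactors = FALSE)
}

strata_of <- function(hi, lo) {
  data.frame(sample_id = c(hi, lo),
             stratum = rep(c("high", "low"), c(length(hi), length(lo))))
}

test_that("differential prevalence reproduces the cross-product OR", {
  hi <- sprintf("H%02d", 1:50)
  lo <- sprintf("L%02d", 1:50)
  pres <- matrix(FALSE, 100, 1, dimnames = list(c(hi, lo), "gX"))
  pres[hi[1:20], 1] <- TRUE   # a=20, b=30
  pres[lo[1:5], 1] <- TRUE    # c=5,  d=45
  dp <- differential_prevalence(maf_from_presence(pres), strata_of(hi, lo))
  expect_equal(dp$odds_ratio, (20 * 45) / (30 * 5), tolerance = 1e-12)
  expect_equal(dp$count_high, 20)
  expect_equal(dp$count_low, 5)

  # balanced table: OR = 1, p ~ 1
  pres2 <- matrix(FALSE, 100, 1, dimnames = list(c(hi, lo), "gY"))
  pres2[c(hi[1:10], lo[1:10]), 1] <- TRUE
  dp2 <- differential_prevalence(maf_from_presence(pres2),
                                 strata_of(hi, lo))
  expect_equal(dp2$odds_ratio, 1, tolerance = 1e-12)
  expect_gt(dp2$p_value, 0.95)

  # empty low cell: Haldane-Anscombe correction, flagged
  pres3 <- matrix(FALSE, 100, 1, dimnames = list(c(hi, lo), "gZ"))
  pres3[hi[1:8], 1] <- TRUE
  dp3 <- differential_prevalence(maf_from_presence(pres3),
                                 strata_of(hi, lo))
  expect_true(dp3$continuity_corrected)
  expect_true(is.finite(dp3$odds_ratio) && dp3$odds_ratio > 0)
})

test_that("prevalence is presence-based: duplicates and silent rows ignored", {
  hi <- sprintf("H%02d", 1:10)
  lo <- sprintf("L%02d", 1:10)
  pres <- matrix(FALSE, 20, 1, dimnames = list(c(hi, lo), "gD"))
  pres[c(hi[1:6], lo[1:2]), 1] <- TRUE
  maf <- maf_from_presence(pres)
  dp <- differential_prevalence(maf, strata_of(hi, lo))
  dup <- rbind(maf, maf, maf)  # extra variants in the same sample-gene
  dp_dup <- differential_prevalence(dup, strata_of(hi, lo))
  expect_equal(dp_dup$odds_ratio, dp$odds_ratio)
  expect_equal(dp_dup$count_high, dp$count_high)

  sil <- maf_from_presence(pres, class = "Silent")
  expect_equal(nrow(differential_prevalence(rbind(maf, sil),
                                            strata_of(hi, lo))),
               nrow(dp))
})

test_that("interaction p-values match exact hypergeometric enumeration", {
  samples <- sprintf("S%02d", 1:20)
  # both genes mutated in the same 5 samples: strongly co-occurring
  pres <- matrix(FALSE, 20, 2, dimnames = list(samples, c("gA", "gB")))
  pres[1:5, ] <- TRUE
  si <- somatic_interactions(maf_from_presence(pres), samples, floor_n = 5L)
  expect_equal(si$direction, "co-occurring")
  expect_equal(si$p_value, oracle_fisher(5, 0, 0, 15), tolerance = 1e-9)

  # disjoint sets covering all samples: mutually exclusive
  pres2 <- matrix(FALSE, 20, 2, dimnames = list(samples, c("gA", "gB")))
  pres2[1:9, 1] <- TRUE
  pres2[10:20, 2] <- TRUE
  si2 <- somatic_interactions(maf_from_presence(pres2), samples,
                              floor_n = 5L)
  expect_equal(si2$direction, "mutually-exclusive")
  expect_lt(si2$odds_ratio, 1)
  expect_lt(si2$signed_log10_p, 0)

  # random tables vs enumeration oracle
  set.seed(104)
  for (i in 1:10) {
    pres3 <- matrix(runif(40) < 0.45, 20, 2,
                    dimnames = list(samples, c("gA", "gB")))
    cnt <- colSums(pres3)
    if (any(cnt < 5)) next
    si3 <- somatic_interactions(maf_from_presence(pres3), samples,
                                floor_n = 5L)
    a <- sum(pres3[, 1] & pres3[, 2]); b <- sum(pres3[, 1] & !pres3[, 2])
    c_ <- sum(!pres3[, 1] & pres3[, 2]); d <- sum(!pres3[, 1] & !pres3[, 2])
    expect_equal(si3$p_value, oracle_fisher(a, b, c_, d), tolerance = 1e-7)
  }
})

test_that("null interaction rates give ~5% positives", {
  set.seed(105)
  samples <- sprintf("S%03d", 1:500)
  genes <- sprintf("g%02d", 1:12)
  pres <- matrix(runif(500 * 12) < 0.3, 500, 12,
                 dimnames = list(samples, genes))
  si <- somatic_interactions(maf_from_presence(pres), samples)
  expect_lt(mean(si$p_value < 0.05), 0.12)   # 66 pairs, null ~ 5%
})

test_that("TMB arithmetic, panels and linearity", {
  samples <- c("S1", "S2")
  mut <- data.frame(sample_id = rep("S1", 38), gene = sprintf("g%02d", 1:38),
                    variant_classification = "Missense_Mutation",
                    protein_position = 1L)
  tmb <- compute_tmb(mut, samples, genome_size_mb = 38)
  expect_equal(tmb$tmb_all, c(1, 0))
  expect_equal(compute_tmb(mut, samples, genome_size_mb = 19)$tmb_all,
               c(2, 0))
  # empty panel: signature TMB identically zero
  tmb0 <- compute_tmb(mut, samples, panel = character())
  expect_equal(tmb0$tmb_signature, c(0, 0))
  # burden counts raw rows, even duplicated sample-gene events
  mut2 <- rbind(mut, mut[1, ])
  expect_equal(compute_tmb(mut2, samples, genome_size_mb = 38)$tmb_all[1],
               39 / 38)
})

test_that("waterfall summary ranks by frequency with lexicographic ties", {
  hi <- sprintf("H%02d", 1:20)
  lo <- sprintf("L%02d", 1:20)
  pres <- matrix(FALSE, 40, 3,
                 dimnames = list(c(hi, lo), c("gB", "gA", "gC")))
  pres[, "gB"] <- TRUE                       # everywhere: rank 1
  pres[c(hi[1:5], lo[1:5]), "gA"] <- TRUE    # ties with gC
  pres[c(hi[1:5], lo[1:5]), "gC"] <- TRUE
  wf <- mutation_waterfall_summary(maf_from_presence(pres),
                                   strata_of(hi, lo), k = 3L)
  expect_equal(wf$high$genes, c("gB", "gA", "gC"))
  expect_equal(wf$high$frequency, c(1, 0.25, 0.25))
  expect_equal(dim(wf$low$grid), c(3L, 20L))
  expect_true(all(wf$high$grid["gB", ] == "Missense_Mutation"))

  # planted frequencies recover their order at n = 200
  set.seed(106)
  samp <- sprintf("P%03d", 1:200)
  pres2 <- cbind(p50 = runif(200) < 0.5, p30 = runif(200) < 0.3,
                 p10 = runif(200) < 0.1)
  rownames(pres2) <- samp
  st <- strata_of(samp[1:100], samp[101:200])
  wf2 <- mutation_waterfall_summary(maf_from_presence(pres2), st, k = 3L)
  expect_equal(wf2$high$genes, c("p50", "p30", "p10"))
})

test_that("signature panel unions prevalent, differential and interacting genes", {
  cfg <- tiny_config(n_bulk_samples = 200L)
  tr <- myelodiv:::sim_ground_truth(cfg)
  mut <- simulate_mutations(cfg, tr)
  st <- stratify_by_quantile(diversity_table(tr$true_fractions))
  panel <- signature_tmb_panel(mut, st)
  dp <- differential_prevalence(mut, st)
  expect_true(all(dp$gene[dp$differential] %in% panel))
  wf <- mutation_waterfall_summary(mut, st)
  expect_true(all(unlist(lapply(wf, `[[`, "genes")) %in% panel))
})
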