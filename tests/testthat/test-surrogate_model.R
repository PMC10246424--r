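module_world <- function(n = 120, n_noise = 20, seed = 121) {
  set.seed(seed)
  H <- runif(n, 0.5, 2.5)
  expr <- rbind(sig1 = 2 * H + rnorm(n, 0, 0.05),
                matrix(rnorm(n_noise * n), n_noise, n,
                       dimnames = list(sprintf("nz%02d", 1:n_noise), NULL)))
  colnames(expr) <- sprintf("S%03d", 1:n)
  dt <- data.frame(sample_id = colnames(expr), shannon = H,
                   gini_simpson = NA, pielou = NA, n = 5L,
                   degenerate = FALSE)
  list(expr = expr, dt = dt, H = H)
}

test_that("a planted linear driver dominates the importance ranking", {
  w <- module_world()
  imp <- rank_importance(w$expr, w$dt, n_trees = 200L, seed = 5L)
  expect_equal(imp$gene[1], "sig1")
  expect_gt(imp$importance[1], 10 * max(imp$importance[-1]))
  expect_gt(attr(imp, "holdout_cor"), 0.9)
})

test_that("an all-noise module warns and shows only small importances", {
  w <- module_world()
  noise_only <- w$expr[-1, , drop = FALSE]
  expect_warning(
    imp <- rank_importance(noise_only, w$dt, n_trees = 200L, seed = 5L),
    "weakly predictive")
  expect_lt(max(imp$importance), 0.1 * var(w$H))
})

test_that("collinearity filtering follows the documented greedy trace", {
  # chain with exact sample correlations: r(A,B) = r(B,C) = 0.8,
  # r(A,C) = 0.3, importance A > B > C -> greedy keeps {A, C}
  set.seed(122)
  n <- 60
  E <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  A <- E[, 1]
  B <- 0.8 * E[, 1] + 0.6 * E[, 2]
  cC2 <- (0.8 - 0.8 * 0.3) / 0.6
  C <- 0.3 * E[, 1] + cC2 * E[, 2] + sqrt(1 - 0.09 - cC2^2) * E[, 3]
  expr <- rbind(A = A, B = B, C = C)
  colnames(expr) <- sprintf("S%03d", 1:n)
  stopifnot(abs(cor(A, B) - 0.8) < 1e-9, abs(cor(B, C) - 0.8) < 1e-9,
            abs(cor(A, C) - 0.3) < 1e-9)
  rk <- structure(data.frame(gene = c("A", "B", "C"),
                             importance = c(3, 2, 1), rank = 1:3),
                  class = c("myelodiv_importance", "data.frame"))
  kept <- combine_and_filter(list(rk), expr, r_threshold = 0.75)
  expect_equal(kept, c("A", "C"))

  # exact duplicates: only the higher-ranked survives
  expr2 <- rbind(A = A, Adup = A, C = C)
  colnames(expr2) <- colnames(expr)
  rk2 <- structure(data.frame(gene = c("A", "Adup", "C"),
                              importance = c(3, 2, 1), rank = 1:3),
                   class = c("myelodiv_importance", "data.frame"))
  kept2 <- combine_and_filter(list(rk2), expr2)
  expect_true("A" %in% kept2 && !("Adup" %in% kept2))

  # orthogonal genes all survive
  set.seed(123)
  expr3 <- matrix(rnorm(3 * n), 3, n,
                  dimnames = list(c("A", "B", "C"), colnames(expr)))
  expect_setequal(combine_and_filter(list(rk), expr3), c("A", "B", "C"))

  # union across cohorts
  rkA <- structure(data.frame(gene = c("A", "B"), importance = c(3, 1),
                              rank = 1:2),
                   class = c("myelodiv_importance", "data.frame"))
  rkB <- structure(data.frame(gene = c("C", "B"), importance = c(2.5, 1),
                              rank = 1:2),
                   class = c("myelodiv_importance", "data.frame"))
  expect_setequal(combine_and_filter(list(rkA, rkB), expr3, top_k = 1L),
                  c("A", "C"))
})

test_that("exact linear diversity is recovered to 1e-8 and scored bit-exactly", {
  set.seed(124)
  n <- 100
  expr <- matrix(rexp(3 * n, 0.2), 3, n,
                 dimnames = list(c("gA", "gB", "gC"), sprintf("S%03d", 1:n)))
  beta <- c(0.7, -0.4, 0.2)
  H <- unname(drop(2 + scale(t(expr)) %*% beta))
  dt <- data.frame(sample_id = colnames(expr), shannon = H,
                   gini_simpson = NA, pielou = NA, n = 5L,
                   degenerate = FALSE)
  model <- fit_surrogate(expr, dt, c("gA", "gB", "gC"))
  expect_equal(unname(model$coefficients), beta, tolerance = 1e-8)
  expect_equal(model$train_cor, 1, tolerance = 1e-9)

  scores <- score_samples(model, expr)
  expect_equal(unname(scores), H, tolerance = 1e-8)
  # extra genes in the matrix are ignored; identical columns tie
  expr_big <- rbind(expr, extra = rexp(n))
  expr_big <- cbind(expr_big, Sdup = expr_big[, 1])
  s2 <- score_samples(model, expr_big)
  expect_equal(unname(s2[colnames(expr)]), unname(scores))
  expect_equal(unname(s2["Sdup"]), unname(scores[1]))

  expect_error(score_samples(model, expr[-1, , drop = FALSE]), "gA")
  s3 <- score_samples(model, expr[-1, , drop = FALSE],
                      impute_missing = TRUE)
  expect_length(s3, n)

  # intercept-only degenerate model predicts the mean
  m0 <- fit_surrogate(expr, dt, character())
  expect_equal(unname(score_samples(m0, expr)),
               rep(mean(H), n), tolerance = 1e-12)
})

test_that("noisy coefficients land within 3 SE of the planted values", {
  set.seed(125)
  n <- 300
  Z <- matrix(rnorm(3 * n), n, 3)
  expr <- t(Z)
  dimnames(expr) <- list(c("gA", "gB", "gC"), sprintf("S%03d", 1:n))
  beta <- c(0.5, 0.3, -0.2)
  H <- drop(1 + Z %*% beta + rnorm(n, 0, 0.1))
  dt <- data.frame(sample_id = colnames(expr), shannon = H,
                   gini_simpson = NA, pielou = NA, n = 5L,
                   degenerate = FALSE)
  model <- fit_surrogate(expr, dt, rownames(expr))
  se <- 0.1 / sqrt(n)   # near-orthonormal design
  expect_true(all(abs(unname(model$coefficients) -
                        beta * apply(Z, 2, sd)) < 3 * se + 0.01))
})

test_that("the fitted model never contains a collinear pair", {
  set.seed(126)
  n <- 200
  z <- rnorm(n)
  expr <- rbind(gA = z + rnorm(n, 0, 0.1), gB = z + rnorm(n, 0, 0.1))
  colnames(expr) <- sprintf("S%03d", 1:n)
  dt <- data.frame(sample_id = colnames(expr), shannon = z,
                   gini_simpson = NA, pielou = NA, n = 5L,
                   degenerate = FALSE)
  expect_error(fit_surrogate(expr, dt, c("gA", "gB")), "collinear")
})

test_that("surrogate JSON round-trips and validates against survival", {
  w <- module_world()
  model <- fit_surrogate(w$expr, w$dt, c("sig1", "nz01"))
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(model, path)
  back <- read_surrogate(path)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_equal(unname(score_samples(back, w$expr)),
               unname(score_samples(model, w$expr)), tolerance = 1e-12)

  # constant scores: HR exactly 1
  set.seed(127)
  clin <- data.frame(sample_id = colnames(w$expr),
                     time = rexp(ncol(w$expr)),
                     event = rbinom(ncol(w$expr), 1, 0.8))
  val <- validate_surrogate(setNames(rep(2, ncol(w$expr)),
                                     colnames(w$expr)), clin)
  expect_equal(val$cox$hazard_ratio, 1)

  # permuted scores: null covered in most replicates
  scores <- score_samples(model, w$expr)
  cover <- logical(15)
  for (r in 1:15) {
    set.seed(300 + r)
    v <- validate_surrogate(setNames(sample(scores), names(scores)), clin)
    cover[r] <- v$cox$ci_lower <= 1 && v$cox$ci_upper >= 1
  }
  expect_gte(sum(cover), 12)
})
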