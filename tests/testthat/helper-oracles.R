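# Independent oracles used across the suite. Each is a brute-force or
# closed-form route that never shares code with the implementation it checks.

# term-by-term evaluation of the Shannon formula
oracle_shannon <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

# exhaustive simplex grid search (step 0.01) for the K=3 mixture problem
oracle_nnls_simplex <- function(S, b, step = 0.01) {
  best <- NULL
  best_r <- Inf
  grid <- seq(0, 1, by = step)
  for (x1 in grid) for (x2 in grid) {
    x3 <- 1 - x1 - x2
    if (x3 < -1e-12) next
    x <- c(x1, x2, max(x3, 0))
    r <- sum((S %*% x - b)^2)
    if (r < best_r) { best_r <- r; best <- x }
  }
  best
}

# Breslow partial log-likelihood for a single covariate
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, oracle_breslow_loglik, numeric(1L),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# observed-minus-expected log-rank chi-square for two groups
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1L]
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# spreadsheet-style running-sum evaluation of the ssGSEA statistic
oracle_ssgsea <- function(expr, gene_set, alpha) {
  genes <- names(expr)
  ord <- order(-expr, -xtfrm(genes))
  genes <- genes[ord]
  N <- length(genes)
  w <- (N:1)^alpha
  in_set <- genes %in% gene_set
  score <- 0
  cum_in <- 0
  cum_out <- 0
  tot_in <- sum(w[in_set])
  tot_out <- sum(!in_set)
  for (i in seq_len(N)) {
    if (in_set[i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
    score <- score + cum_in / tot_in - cum_out / tot_out
  }
  score
}

# two-sided Fisher p by full enumeration of tables with fixed margins
oracle_fisher <- function(a, b, c_, d) {
  m <- a + b          # gene1 mutated
  n <- c_ + d         # gene1 wild-type
  k <- a + c_         # gene2 mutated
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random simplex point
rand_simplex <- function(k) {
  g <- rexp(k)
  g / sum(g)
}
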