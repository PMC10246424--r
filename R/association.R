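#' Cox proportional-hazards regression of survival on covariates
#'
#' Fits `survival::coxph` with Breslow tie handling and reports per-term
#' hazard ratios with Wald 95% confidence intervals. Monotone likelihoods
#' (perfect separation: coefficient diverging) are flagged rather than
#' silently reported.
#'
#' @param clin clinical data.frame with `time` and `event` columns (see
#'   [read_clinical()]); the endpoint columns can be remapped via
#'   `time_col` / `event_col` for PFS-style endpoints.
#' @param covariates character vector of column names in `clin` (factors are
#'   expanded by the model matrix). A constant covariate yields HR = 1.
#' @param model tag recorded in the result (`"univariate"` when one
#'   covariate, else `"multivariate"`).
#' @param time_col,event_col endpoint column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame: term, coef, hazard_ratio, ci_lower, ci_upper,
#'   p_value, n, n_events, model, flagged.
#' @export
fit_cox <- function(clin, covariates, model = NULL,
                    time_col = "time", event_col = "event",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  assert_that(all(covariates %in% names(clin)),
              "covariate column(s) missing from clinical table")
  keep <- complete.cases(clin[, c(time_col, event_col, covariates),
                              drop = FALSE])
  d <- clin[keep, , drop = FALSE]
  n_events <- sum(d[[event_col]])
  assert_that(n_events >= 2, "need at least 2 events")
  model <- model %||% if (length(covariates) == 1L) "univariate" else
    "multivariate"

  constant <- vapply(covariates, function(v)
    length(unique(d[[v]])) == 1L, logical(1L))
  vary <- covariates[!constant]
  rows <- list()
  if (length(vary)) {
    fml <- stats::as.formula(paste0(
      "survival::Surv(", time_col, ", ", event_col, ") ~ ",
      paste(sprintf("`%s`", vary), collapse = " + ")))
    monotone <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = d, ties = ties),
      warning = function(w) {
        if (grepl("coefficient may be infinite", conditionMessage(w))) {
          monotone <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    s <- summary(fit)
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    flagged <- monotone | !is.finite(beta) | abs(beta) > 15 | !is.finite(se)
    rows[[1L]] <- data.frame(
      term = names(beta),
      coef = unname(beta),
      hazard_ratio = exp(unname(beta)),
      ci_lower = exp(unname(beta - qnorm(0.975) * se)),
      ci_upper = exp(unname(beta + qnorm(0.975) * se)),
      p_value = unname(s$coefficients[, "Pr(>|z|)"]),
      stringsAsFactors = FALSE)
    rows[[1L]]$flagged <- unname(flagged)
    if (any(flagged))
      warning("monotone likelihood suspected for: ",
              paste(names(beta)[flagged], collapse = ", "))
  }
  if (any(constant))
    rows[[length(rows) + 1L]] <- data.frame(
      term = covariates[constant], coef = 0, hazard_ratio = 1,
      ci_lower = 1, ci_upper = 1, p_value = NA_real_, flagged = FALSE,
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$n <- nrow(d)
  out$n_events <- n_events
  out$model <- model
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves and log-rank test over diversity strata
#'
#' Product-limit survival estimates per stratum plus the log-rank chi-square
#' statistic (1 df for two groups). `middle-excluded` samples are dropped.
#'
#' @param clin clinical table.
#' @param strata a [stratify_by_quantile()] result (or data.frame with
#'   sample_id, stratum).
#' @inheritParams fit_cox
#' @return list with `curves` (data.frame: stratum, time, n_risk, n_event,
#'   survival), `chisq`, `df`, `p_value`, `n`.
#' @export
km_logrank <- function(clin, strata, time_col = "time", event_col = "event") {
  d <- merge(clin, strata, by = "sample_id")
  d <- d[d$stratum %in% c("high", "low"), , drop = FALSE]
  d <- d[complete.cases(d[, c(time_col, event_col)]), , drop = FALSE]
  lv <- unique(d$stratum)
  assert_that(length(lv) >= 2, "need at least 2 non-empty strata")
  for (g in lv)
    assert_that(sum(d[[event_col]][d$stratum == g]) >= 1,
                paste0("stratum '", g, "' has no events"))

  surv <- survival::Surv(d[[time_col]], d[[event_col]])
  fit <- survival::survfit(surv ~ stratum, data = d)
  sm <- summary(fit, censored = TRUE)
  curves <- data.frame(
    stratum = sub("^stratum=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    survival = sm$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(surv ~ stratum, data = d)
  df <- length(sd_$n) - 1L
  list(curves = curves, chisq = unname(sd_$chisq), df = df,
       p_value = pchisq(sd_$chisq, df, lower.tail = FALSE), n = nrow(d))
}

#' Logistic regression of treatment response on diversity
#'
#' The predictor is z-normalized before fitting (the normalization constants
#' are returned), so the odds ratio is per SD of the diversity index.
#' Complete separation is flagged; a single-class response is an error.
#'
#' @param clin clinical table with a binary `response` column.
#' @param predictor named numeric vector (names = sample IDs), e.g. the
#'   Shannon index; or a column name in `clin`.
#' @param arm optional label recorded in the result.
#' @param normalize z-scale the predictor (default TRUE).
#' @return data.frame row: term, coef, odds_ratio, ci_lower, ci_upper,
#'   p_value, n, arm, flagged; attributes `center` and `scale`.
#' @export
fit_logistic_response <- function(clin, predictor, arm = NA_character_,
                                  normalize = TRUE) {
  if (is.character(predictor) && length(predictor) == 1L) {
    x <- clin[[predictor]]
    names(x) <- clin$sample_id
    predictor <- x
  }
  ids <- intersect(clin$sample_id, names(predictor))
  d <- clin[match(ids, clin$sample_id), , drop = FALSE]
  x <- predictor[ids]
  keep <- !is.na(d$response) & !is.na(x)
  d <- d[keep, , drop = FALSE]
  x <- x[keep]
  tab <- table(factor(d$response, levels = c(0, 1)))
  if (any(tab == 0)) stop("response has a single class; cannot fit")
  if (any(tab < 5))
    warning("fewer than 5 samples in a response class; estimates unstable")

  ctr <- if (normalize) mean(x) else 0
  scl <- if (normalize) max(sd(x), 1e-12) else 1
  z <- (x - ctr) / scl
  fit <- suppressWarnings(glm(d$response ~ z, family = binomial()))
  beta <- coef(fit)[["z"]]
  se <- sqrt(diag(vcov(fit)))[["z"]]
  flagged <- !fit$converged || abs(beta) > 15 || se > 100
  if (flagged) warning("possible complete separation; estimate flagged")
  out <- data.frame(
    term = "diversity", coef = beta, odds_ratio = exp(beta),
    ci_lower = exp(beta - qnorm(0.975) * se),
    ci_upper = exp(beta + qnorm(0.975) * se),
    p_value = summary(fit)$coefficients["z", "Pr(>|z|)"],
    n = nrow(d), arm = arm, flagged = flagged, stringsAsFactors = FALSE)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
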