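#' @useDynLib myelodiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test sd var quantile rnorm runif rbinom rexp
#'   rgamma rnbinom rpois rlnorm p.adjust pchisq glm binomial coef vcov lm
#'   predict fisher.test chisq.test wilcox.test prcomp as.dist hclust cutree
#'   setNames complete.cases plogis qnorm median
#' @importFrom utils read.delim write.table head modifyList packageVersion
NULL

# Deterministic fan-out of one global seed into per-component substreams:
# changing what one component draws must not perturb any other component.
# Small FNV-style string hash folded with the seed, kept below 2^31.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 5381
  for (cp in utf8ToInt(tag)) h <- (h * 33 + cp) %% 2147483647
  as.integer((abs(seed) * 1000003 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

check_simplex <- function(p, tol = 1e-9) {
  if (any(!is.finite(p))) stop("fraction vector contains non-finite entries")
  if (any(p < 0)) stop("fraction vector contains negative entries")
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("fractions must sum to 1 (got %.12f)", sum(p)))
  invisible(p)
}
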