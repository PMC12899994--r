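# Internal helpers shared across modules.

#' @useDynLib ictalarm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic sub-seed derived from a base seed and a character key.
# Keeps results invariant to the composition of the surrounding data
# (e.g. which other subjects are present in a LOSO universe).
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Rank-based (Mann-Whitney) AUC of scores for binary labels.
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Rational approximation p/q of a ratio (continued fractions).
rational_approx <- function(x, max_den = 4096L, tol = 1e-9) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) < tol * x || abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = as.integer(p1), q = as.integer(q1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
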