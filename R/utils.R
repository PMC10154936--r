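# internal helpers shared across stages

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed for a named stage. Keeps everything under one
# user-facing seed while decoupling the streams of the different generators.
#' @noRd
stage_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' @noRd
ecosel_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ecosel_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
is_count <- function(x) is.numeric(x) && all(is.na(x) | (x >= 0 & x == round(x)))

# draw n rows from a bivariate normal with sds s and correlation rho
#' @noRd
rbvnorm <- function(n, s1, s2, rho) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(s1 * z1, s2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# split-chain potential scale reduction factor (rank-agnostic, classic form)
# draws: iterations x chains matrix
#' @noRd
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  B <- half * var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
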