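#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG state without disturbing the caller's stream.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed for a named stage from a global seed,
# kept within the 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% .Machine$integer.max
}

stop_arg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Zero-truncated normal draws. `calibrate = TRUE` solves for the parent mean
# so that the mean of the truncated distribution equals `mean` (used for
# generators whose target moments come from reported summaries).
rtruncnorm_pos <- function(n, mean, sd, calibrate = TRUE) {
  stop_arg(mean > 0, "`mean` must be positive")
  stop_arg(sd >= 0, "`sd` must be non-negative")
  if (sd == 0) return(rep(mean, n))
  mu <- if (calibrate) truncnorm_parent_mean(mean, sd) else mean
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mu, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

# Mean of a normal(mu, sd) truncated to (0, Inf).
truncnorm_mean <- function(mu, sd) {
  a <- mu / sd
  mu + sd * stats::dnorm(a) / stats::pnorm(a)
}

truncnorm_parent_mean <- function(target, sd) {
  f <- function(mu) truncnorm_mean(mu, sd) - target
  stats::uniroot(f, lower = target - 6 * sd, upper = target, extendInt = "upX",
                 tol = 1e-10)$root
}

# Quantile with the standard linear-interpolation definition (type 7).
quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
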