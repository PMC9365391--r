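# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. `seed = NULL` leaves
# the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Ordinary least squares y ~ x via closed forms; returns slope, intercept,
# r2 and the two-sided t-test p-value on the slope. Much faster than lm()
# for the window scans, where it is called thousands of times.
linfit <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) return(list(slope = NA_real_, intercept = my,
                            r2 = NA_real_, p = NA_real_, n = n))
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  p <- NA_real_
  if (n > 2L) {
    s2 <- sse / (n - 2L)
    se <- sqrt(s2 / sxx)
    p <- if (se > 0) 2 * stats::pt(abs(slope / se), df = n - 2L,
                                   lower.tail = FALSE) else 0
  }
  list(slope = slope, intercept = intercept, r2 = r2, p = p, n = n)
}

stop_if_not_scalar <- function(x, name, positive = FALSE,
                               nonnegative = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L)
    stop(sprintf("'%s' must be a numeric scalar", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (positive && !(x > 0))
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonnegative && !(x >= 0))
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
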