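# internal helpers shared across modules

# multiplicative log-normal noise with mean exactly 1 and coefficient of
# variation cv; cv = 0 degenerates to the constant 1 (noise-free channel)
.lnorm_noise <- function(n, cv) {
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv < 0)
    stop("noise_cv must be a single nonnegative number", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

.maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("seed must be a single integer", call. = FALSE)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
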