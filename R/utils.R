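# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be a single number", name)
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    stopf("'%s' = %g is outside the allowed range", name, x)
  }
  as.numeric(x)
}

# seeded evaluation that leaves the caller's RNG state untouched
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
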