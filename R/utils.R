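# Internal helpers shared across modules.

# Half-up rounding to integer sample indices. base::round() rounds halves to
# even, which would map the 12.5 ms phase-tag latency to sample 12 on one call
# and 13 on another depending on parity; stimulus timing needs one convention.
round_half_up <- function(x) floor(x + 0.5)

# Wrap angles (degrees) into [0, 360).
wrap_deg <- function(x) ((x %% 360) + 360) %% 360

# Signed angular difference a - b in (-180, 180].
ang_diff_deg <- function(a, b) {
  d <- wrap_deg(a - b)
  ifelse(d > 180, d - 360, d)
}

# Circular mean of angles in degrees, result in [0, 360).
circ_mean_deg <- function(x) {
  z <- mean(exp(1i * x * pi / 180))
  wrap_deg(Arg(z) * 180 / pi)
}

# Circular standard deviation in degrees: sqrt(-2 log R).
circ_sd_deg <- function(x) {
  r <- Mod(mean(exp(1i * x * pi / 180)))
  r <- min(max(r, .Machine$double.eps), 1)
  sqrt(-2 * log(r)) * 180 / pi
}

# Run code under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL leaves the global stream alone.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min) {
    if (x <= min) abort(sprintf("`%s` must be > %s.", name, format(min)))
  } else if (x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  if (x > max) abort(sprintf("`%s` must be <= %s.", name, format(max)))
  invisible(x)
}
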