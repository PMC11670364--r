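# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Positive-preserving interpolation of tabulated physics curves: linear in
# log(E), log(y). Extrapolation is disallowed; callers must stay within the
# tabulated 10 keV - 6 MeV range.
loglog_interp_fun <- function(energy_keV, value) {
  stopifnot(all(diff(energy_keV) > 0), all(value > 0))
  lo <- min(energy_keV); hi <- max(energy_keV)
  f <- stats::approxfun(log(energy_keV), log(value), rule = 1)
  function(E) {
    if (any(!is.finite(E)) || any(E < lo) || any(E > hi)) {
      stop("energy outside tabulated range [", lo, ", ", hi, "] keV",
           call. = FALSE)
    }
    exp(f(log(E)))
  }
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

deg2rad <- function(deg) deg * pi / 180
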