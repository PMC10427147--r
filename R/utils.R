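# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG flow.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Wrap angles (degrees) into [0, 360).
wrap_angle <- function(theta) {
  theta %% 360
}

# Smooth zero-mean Gaussian-like random field over scattered (x, y) points.
# Sum of `n_comp` random-phase plane-wave cosines with wavelengths drawn from
# `wavelength`; the marginal variance is exactly sd^2 (over random phases),
# while values vary smoothly in space with gradients of order sd / wavelength.
# Draws from the current RNG stream; callers control seeding.
smooth_field <- function(x, y, sd = 1, n_comp = 24L, wavelength = c(3, 8)) {
  if (sd == 0) {
    return(numeric(length(x)))
  }
  lam <- stats::runif(n_comp, wavelength[1], wavelength[2])
  dir <- stats::runif(n_comp, 0, 2 * pi)
  phase <- stats::runif(n_comp, 0, 2 * pi)
  amp <- sd * sqrt(2 / n_comp)
  out <- numeric(length(x))
  for (m in seq_len(n_comp)) {
    k <- 2 * pi / lam[m]
    out <- out + amp * cos(k * (x * cos(dir[m]) + y * sin(dir[m])) + phase[m])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nf <- function(...) stop(..., call. = FALSE)
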