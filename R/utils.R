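# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# FWHM of a Gaussian with standard deviation `sigma`.
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert Gaussian standard deviation to full width at half maximum
#'
#' @param sigma standard deviation (any length unit).
#' @return FWHM in the same unit (`2 sqrt(2 log 2) * sigma`).
#' @export
sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma

#' @rdname sigma_to_fwhm
#' @param fwhm full width at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

# Quadratic (3-point parabola) interpolation of an extremum position.
# Returns the sub-sample offset in [-0.5, 0.5] relative to the central sample.
parabolic_offset <- function(ym, y0, yp) {
  denom <- ym - 2 * y0 + yp
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym - yp) / denom
  max(-0.5, min(0.5, off))
}
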