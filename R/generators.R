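#' Synthetic lineal-energy spectrum generators
#'
#' Idealized stand-ins for transport-code microdosimetric histograms, each
#' with closed-form moments used throughout the test suite.
#'
#' `spectrum_delta()` concentrates the dose probability at `y_star` (e.g.
#' the photon reference spectra at 2.3 or 4.3 keV/um), splitting the mass
#' between the two adjacent bins whose representatives bracket `y_star` so
#' the dose-mean lineal energy equals `y_star` exactly.
#'
#' `spectrum_track_segment()` is the classic track-segment chord-length
#' model for spherical sites under mu-randomness: the dose density is
#' d(y) = 3 y^2 / y_max^3 on (0, y_max] with y_max = 3/2 * LET, discretized
#' by exact per-bin integration.  Its moments are yF = LET and
#' yD = 9/8 * LET.
#'
#' `spectrum_lognormal()` builds a log-normal *frequency* distribution of y
#' (parameters `mu`, `sigma` of ln y) and converts it to dose weighting, so
#' yD = exp(mu + 3/2 sigma^2) in closed form.
#'
#' @param y_star Lineal energy (keV/um) of the delta peak; must lie inside
#'   the grid span.
#' @param let LET in water (keV/um), positive; also stored as metadata.
#' @param mu,sigma Mean and standard deviation of ln(y) for the frequency
#'   distribution; `sigma > 0`.
#' @param grid An [le_grid()].
#' @param label Optional text label.
#' @return A normalized [mkm_spectrum()].
#' @examples
#' y_dose_mean(spectrum_delta(2.3))           # ~2.3 (one bin wide)
#' y_dose_mean(spectrum_track_segment(100))   # 112.5
#' y_dose_mean(spectrum_lognormal(0, 1))      # exp(1.5) ~ 4.48
#' @name spectrum_generators
NULL

#' @rdname spectrum_generators
#' @export
spectrum_delta <- function(y_star, grid = le_grid(), label = NULL) {
  stopifnot(is.numeric(y_star), length(y_star) == 1L, is.finite(y_star))
  i <- grid_bin_index(grid, y_star)
  if (is.na(i))
    stop(sprintf("y_star = %g keV/um lies outside the grid span [%g, %g]",
                 y_star, grid$edges[1L], grid$edges[grid$n + 1L]))
  w <- numeric(grid$n)
  # moment-preserving placement: split the mass between the two bins whose
  # representatives bracket y_star so that the dose-mean equals y_star
  # exactly (a single-bin delta would bias it by up to half a bin width)
  j <- if (y_star >= grid$y[i]) i + 1L else i - 1L
  if (j < 1L || j > grid$n || y_star == grid$y[i]) {
    w[i] <- 1
  } else {
    f <- (y_star - grid$y[i]) / (grid$y[j] - grid$y[i])
    w[i] <- 1 - f
    w[j] <- f
  }
  mkm_spectrum(w, grid, normalize = FALSE, label = label)
}

#' @rdname spectrum_generators
#' @export
spectrum_track_segment <- function(let, grid = le_grid(), label = NULL) {
  stopifnot(is.numeric(let), length(let) == 1L)
  if (!is.finite(let) || let <= 0) stop("'let' must be a positive LET in keV/um")
  y_max <- 1.5 * let
  if (y_max <= grid$edges[1L])
    stop(sprintf(
      "track-segment support (0, %g] falls entirely below the grid floor %g",
      y_max, grid$edges[1L]))
  # exact mass per bin: integral of 3 y^2 / y_max^3 over [a, min(b, y_max)]
  lo <- pmin(grid$edges[-(grid$n + 1L)], y_max)
  hi <- pmin(grid$edges[-1L], y_max)
  w <- (hi^3 - lo^3) / y_max^3
  # mass below the grid floor ((ymin/y_max)^3) is dropped; renormalize
  mkm_spectrum(w, grid, normalize = TRUE, label = label, let = let)
}

#' @rdname spectrum_generators
#' @export
spectrum_lognormal <- function(mu, sigma, grid = le_grid(), label = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(sigma),
            length(sigma) == 1L)
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  f <- diff(stats::plnorm(grid$edges, meanlog = mu, sdlog = sigma))
  if (sum(f) <= 0)
    stop("log-normal frequency distribution has no mass inside the grid span")
  spectrum_from_frequency(f, grid, label = label)
}
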