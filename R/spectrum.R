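#' Microdosimetric dose-probability spectrum
#'
#' Container for a binned dose-probability distribution of the lineal energy
#' y: each weight is the probability mass d(y)*dy carried by one bin of a
#' log-uniform [le_grid()].  Storing per-bin mass (not density) makes the
#' model integrals plain weighted sums and the on-disk format independent of
#' the binning.
#'
#' @param weights Non-negative per-bin dose-probability masses, length
#'   `grid$n`; at least one must be positive.
#' @param grid An [le_grid()].
#' @param normalize Normalize the weights to unit sum (default `TRUE`).
#' @param label Optional text label carried into prediction tables.
#' @param let Optional LET in water (keV/um) carried as opaque metadata.
#' @return An object of class `mkm_spectrum` with components `grid`,
#'   `weights` and `y` (per-bin representative lineal energy).
#' @seealso [spectrum_delta()], [spectrum_track_segment()],
#'   [spectrum_lognormal()], [read_spectrum()]
#' @export
mkm_spectrum <- function(weights, grid = le_grid(), normalize = TRUE,
                         label = NULL, let = NULL) {
  stopifnot(is_le_grid(grid))
  if (!is.numeric(weights) || length(weights) != grid$n)
    stop("'weights' must be a numeric vector of length grid$n (", grid$n, ")")
  if (anyNA(weights) || any(weights < 0))
    stop("spectrum weights must be non-negative and non-missing")
  s <- structure(
    list(grid = grid, weights = as.numeric(weights), y = grid$y,
         label = label, let = let),
    class = "mkm_spectrum")
  if (normalize) normalize_spectrum(s) else s
}

is_mkm_spectrum <- function(x) inherits(x, "mkm_spectrum")

assert_spectrum <- function(spectrum) {
  if (!is_mkm_spectrum(spectrum))
    stop("expected an 'mkm_spectrum' object")
  if (sum(spectrum$weights) <= 0)
    stop("degenerate spectrum: total dose-probability weight is zero")
  invisible(spectrum)
}

#' Normalize a spectrum to unit total dose probability
#'
#' Rescales all weights by one constant so they sum to 1; the spectral shape
#' is preserved.
#'
#' @param spectrum An [mkm_spectrum()].
#' @return The spectrum with weights summing to 1.
#' @export
normalize_spectrum <- function(spectrum) {
  assert_spectrum(spectrum)
  spectrum$weights <- spectrum$weights / sum(spectrum$weights)
  spectrum
}

#' Spectral moments of the lineal energy
#'
#' `y_dose_mean()` returns the dose-mean lineal energy, the first moment of
#' the dose-probability distribution d(y):  yD = sum(y_i * w_i).
#' `y_freq_mean()` returns the frequency-mean lineal energy, the harmonic-type
#' moment yF = 1 / sum(w_i / y_i), i.e. the mean of the event-frequency
#' distribution f(y) that underlies d(y) via d(y) proportional to y * f(y).
#'
#' @param spectrum An [mkm_spectrum()]; normalized internally.
#' @return Lineal energy in keV/um.
#' @examples
#' s <- spectrum_track_segment(100)
#' y_dose_mean(s)  # 9/8 * LET = 112.5
#' y_freq_mean(s)  # LET = 100
#' @export
y_dose_mean <- function(spectrum) {
  spectrum <- normalize_spectrum(spectrum)
  sum(spectrum$y * spectrum$weights)
}

#' @rdname y_dose_mean
#' @export
y_freq_mean <- function(spectrum) {
  spectrum <- normalize_spectrum(spectrum)
  if (any(spectrum$y[spectrum$weights > 0] <= 0))
    stop("frequency mean undefined: support contains y <= 0")
  1 / sum(spectrum$weights / spectrum$y)
}

#' Convert a frequency distribution to a dose-probability spectrum
#'
#' Standard microdosimetric weighting d(y) proportional to y * f(y): per-bin
#' dose masses are `y_i * f_i`, renormalized to unit sum.
#'
#' @param f_weights Non-negative per-bin event-frequency masses f(y)*dy.
#' @param grid An [le_grid()].
#' @inheritParams mkm_spectrum
#' @return A normalized [mkm_spectrum()].
#' @export
spectrum_from_frequency <- function(f_weights, grid = le_grid(),
                                    label = NULL, let = NULL) {
  stopifnot(is_le_grid(grid))
  if (!is.numeric(f_weights) || length(f_weights) != grid$n)
    stop("'f_weights' must be a numeric vector of length grid$n (", grid$n, ")")
  if (anyNA(f_weights) || any(f_weights < 0))
    stop("frequency weights must be non-negative and non-missing")
  w <- grid$y * f_weights
  if (sum(w) <= 0)
    stop("degenerate spectrum: total dose-probability weight is zero")
  mkm_spectrum(w, grid, normalize = TRUE, label = label, let = let)
}

#' @export
print.mkm_spectrum <- function(x, ...) {
  tot <- sum(x$weights)
  cat("<mkm_spectrum>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  grid: %d bins, %.3g to %.3g keV/um\n",
              x$grid$n, x$grid$edges[1L], x$grid$edges[x$grid$n + 1L]))
  cat(sprintf("  non-zero bins: %d, total weight: %.6g\n",
              sum(x$weights > 0), tot))
  if (tot > 0)
    cat(sprintf("  yF = %.4g keV/um, yD = %.4g keV/um\n",
                y_freq_mean(x), y_dose_mean(x)))
  if (!is.null(x$let)) cat(sprintf("  LET = %g keV/um (metadata)\n", x$let))
  invisible(x)
}
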