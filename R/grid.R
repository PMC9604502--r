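#' Logarithmic lineal-energy grid
#'
#' Binning convention for lineal-energy spectra: log-uniform bin edges from
#' `ymin` to `ymax` with `bins_per_decade` bins per decade.  The default grid
#' (1e-2 to 1e7 keV/um, 50 bins per decade, 450 bins) matches the scoring
#' convention used for microdosimetric transport histograms.
#'
#' @param ymin,ymax Grid span in keV/um; both must be positive, `ymin < ymax`.
#' @param bins_per_decade Number of bins per decade of lineal energy; need not
#'   be an integer (the bin count is rounded to the nearest integer >= 1).
#' @return An object of class `le_grid` with components `edges` (length
#'   `n + 1`, strictly increasing, log-uniform), `y` (per-bin representative
#'   lineal energy, the geometric mean of the bin edges) and `n`.
#' @examples
#' g <- le_grid()
#' g$n            # 450
#' range(g$edges) # 1e-2, 1e7
#' @export
le_grid <- function(ymin = 1e-2, ymax = 1e7, bins_per_decade = 50) {
  stopifnot(is.numeric(ymin), is.numeric(ymax), length(ymin) == 1L,
            length(ymax) == 1L, ymin > 0, ymax > ymin,
            is.numeric(bins_per_decade), bins_per_decade > 0)
  n <- max(1L, as.integer(round(bins_per_decade * log10(ymax / ymin))))
  edges <- 10^seq(log10(ymin), log10(ymax), length.out = n + 1L)
  structure(
    list(edges = edges, y = sqrt(edges[-(n + 1L)] * edges[-1L]), n = n),
    class = "le_grid")
}

#' @export
print.le_grid <- function(x, ...) {
  cat(sprintf("<le_grid> %d log-uniform bins, %.3g to %.3g keV/um\n",
              x$n, x$edges[1L], x$edges[x$n + 1L]))
  invisible(x)
}

is_le_grid <- function(x) inherits(x, "le_grid")

# bin index containing each y; NA outside the span (right edge inclusive)
grid_bin_index <- function(grid, y) {
  i <- findInterval(y, grid$edges, rightmost.closed = TRUE)
  i[i < 1L | i > grid$n] <- NA_integer_
  i
}
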