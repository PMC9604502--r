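#' Read and write lineal-energy spectra
#'
#' The on-disk format is two-column delimited text: column 1 the lineal
#' energy y in keV/um, column 2 the dose-probability mass d(y)*dy of that
#' bin.  The delimiter is auto-detected among comma, tab and whitespace; an
#' optional header line and `#` comment lines are tolerated.  On reading,
#' each y is snapped to the containing bin of `grid` (mass-conserving), so
#' files written against any binning land on one canonical grid.
#'
#' @param path Path to a spectrum file.
#' @param grid Target [le_grid()] for the imported spectrum.
#' @param label,let Optional metadata attached to the result (see
#'   [mkm_spectrum()]); `label` defaults to the file name.
#' @return `read_spectrum()` returns a normalized [mkm_spectrum()];
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path, grid = le_grid(), label = basename(path),
                          let = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L) stop("empty spectrum file: ", path)

  parse_row <- function(txt) {
    fields <- strsplit(trimws(txt), "[,\t ]+")[[1L]]
    if (length(fields) < 2L) return(NULL)
    suppressWarnings(as.numeric(fields[1:2]))
  }
  rows <- lapply(lines, parse_row)

  # one optional non-numeric header line
  first_bad <- which(vapply(rows, function(r) is.null(r) || anyNA(r), TRUE))
  if (length(first_bad) && first_bad[1L] == 1L) {
    rows <- rows[-1L]
    lines <- lines[-1L]
    lineno <- lineno[-1L]
    first_bad <- which(vapply(rows, function(r) is.null(r) || anyNA(r), TRUE))
  }
  if (length(rows) == 0L) stop("no data rows in spectrum file: ", path)
  if (length(first_bad))
    stop(sprintf("non-numeric spectrum row at line %d of %s: '%s'",
                 lineno[first_bad[1L]], path, lines[first_bad[1L]]))

  m <- do.call(rbind, rows)
  y <- m[, 1L]
  w <- m[, 2L]
  if (any(w < 0))
    stop(sprintf("negative weight at line %d of %s",
                 lineno[which(w < 0)[1L]], path))
  if (is.unsorted(y, strictly = FALSE))
    stop(sprintf("lineal energies not sorted (line %d of %s)",
                 lineno[which(diff(y) < 0)[1L] + 1L], path))
  idx <- grid_bin_index(grid, y)
  if (anyNA(idx))
    stop(sprintf("lineal energy %g keV/um (line %d of %s) outside grid span",
                 y[which(is.na(idx))[1L]], lineno[which(is.na(idx))[1L]], path))
  weights <- numeric(grid$n)
  agg <- tapply(w, idx, sum)
  weights[as.integer(names(agg))] <- agg
  mkm_spectrum(weights, grid, normalize = TRUE, label = label, let = let)
}

#' @param spectrum An [mkm_spectrum()] to write.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  assert_spectrum(spectrum)
  nz <- spectrum$weights > 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# y[keV/um], d(y)dy", con)
  writeLines(sprintf("%.12e,%.12e", spectrum$y[nz], spectrum$weights[nz]), con)
  invisible(path)
}
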