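# Unit-closure constant for the single-event specific energy:
# 1 keV / (1 um^2 * 1 um * 1 g/cm^3) = 1.6022e-16 J / 1e-15 kg = 0.16022 Gy.
.k_specific_energy <- 0.16022

#' Single-event specific energy in a spherical site
#'
#' Mean specific energy z deposited per event of lineal energy y in a
#' spherical site of radius r: z = K * y / (rho * pi * r^2), with
#' K = 0.16022 Gy g um^3 cm^-3 keV^-1 closing the units (y in keV/um, r in
#' um, rho in g/cm^3, z in Gy).
#'
#' @param y Lineal energy in keV/um (vectorized, >= 0).
#' @param r Site radius in um (> 0): the domain radius rd or the nucleus
#'   radius Rn.
#' @param rho Density in g/cm^3, default 1.
#' @return Specific energy in Gy.
#' @examples
#' specific_energy(2.3, 0.294)  # ~1.36 Gy in a domain
#' specific_energy(100, 5.6)    # ~0.16 Gy in a nucleus
#' @export
specific_energy <- function(y, r, rho = 1) {
  stopifnot(is.numeric(y), is.numeric(r), length(r) == 1L,
            is.numeric(rho), length(rho) == 1L)
  if (!is.finite(r) || r <= 0) stop("site radius 'r' must be > 0 (um)")
  if (!is.finite(rho) || rho <= 0) stop("'rho' must be > 0 (g/cm^3)")
  if (any(y < 0, na.rm = TRUE)) stop("'y' must be >= 0")
  .k_specific_energy * y / (rho * pi * r^2)
}

#' Non-Poisson saturation correction factor c(y)
#'
#' Corrects the lethal-lesion yield for the non-Poisson distribution of
#' lesions among nuclei at high lineal energy (the overkill effect).  With
#' z_d and z_n the single-event specific energies in the domain and the
#' nucleus, and
#' `u = (alpha0 + beta0 * z_d) * z_n + beta0 * z_n^2`,
#' the factor is `c = (1 - exp(-u)) / u`, evaluated in the expanded form so
#' that alpha0 = 0 needs no division by alpha0.  c is 1 at y = 0, strictly
#' decreasing in y, and bounded in (0, 1].  For u < 1e-8 the series
#' 1 - u/2 + u^2/6 is used to avoid cancellation.
#'
#' @param y Lineal energy in keV/um (vectorized, >= 0).
#' @param params A `cell_line_params` object (see [build_cell_line()]).
#' @return The dimensionless correction factor, same length as `y`.
#' @export
saturation_correction <- function(y, params) {
  stopifnot(is_cell_line_params(params))
  zd <- specific_energy(y, params$rd_um, params$rho)
  zn <- specific_energy(y, params$Rn_um, params$rho)
  u <- (params$alpha0 + params$beta0 * zd) * zn + params$beta0 * zn^2
  small <- abs(u) < 1e-8
  out <- numeric(length(u))
  out[small] <- 1 - u[small] / 2 + u[small]^2 / 6
  out[!small] <- -expm1(-u[!small]) / u[!small]
  out
}

#' Exposure-specific LQM terms from a microdosimetric spectrum
#'
#' The linear term is the dose-probability-weighted mean of the single-event
#' biological effect, saturation-corrected:
#' `alpha = sum_i (alpha0 + beta0 * z_d(y_i)) * c(y_i) * w_i`,
#' and the quadratic term applies the same correction quadratically as the
#' square of the integral:
#' `beta = beta0 * (sum_i c(y_i) * w_i)^2`,
#' where w_i are the per-bin dose-probability masses d(y)dy.  Both are
#' discrete sums over the binned spectrum (no interpolation), so results are
#' reproducible for a given grid.  beta never exceeds beta0, hence the model
#' always predicts beta/beta_ref <= 1.
#'
#' @param spectrum A normalized [mkm_spectrum()].
#' @param params A `cell_line_params` object.
#' @return `alpha_mkm()` the linear term in Gy^-1; `beta_mkm()` the
#'   quadratic term in Gy^-2.
#' @export
alpha_mkm <- function(spectrum, params) {
  assert_spectrum(spectrum)
  stopifnot(is_cell_line_params(params))
  spectrum <- normalize_spectrum(spectrum)
  zd <- specific_energy(spectrum$y, params$rd_um, params$rho)
  cy <- saturation_correction(spectrum$y, params)
  sum((params$alpha0 + params$beta0 * zd) * cy * spectrum$weights)
}

#' @rdname alpha_mkm
#' @export
beta_mkm <- function(spectrum, params) {
  assert_spectrum(spectrum)
  stopifnot(is_cell_line_params(params))
  spectrum <- normalize_spectrum(spectrum)
  cy <- saturation_correction(spectrum$y, params)
  params$beta0 * sum(cy * spectrum$weights)^2
}

#' Linear-quadratic survival and its inverse
#'
#' `lq_survival()` is the linear-quadratic model
#' S = exp(-alpha D - beta D^2); `lq_dose()` inverts it for a target
#' surviving fraction with the numerically stable root
#' D = -2 ln S / (alpha + sqrt(alpha^2 - 4 beta ln S)), which reduces to
#' -ln S / alpha at beta = 0.
#'
#' @param dose Absorbed dose in Gy (vectorized, >= 0).
#' @param alpha Linear term in Gy^-1 (>= 0).
#' @param beta Quadratic term in Gy^-2 (>= 0).
#' @param survival Target surviving fraction in (0, 1).
#' @return `lq_survival()` the surviving fraction in (0, 1];
#'   `lq_dose()` the dose in Gy.
#' @examples
#' lq_survival(2, 0.5, 0.05)       # exp(-1.2)
#' lq_dose(0.5, 0.05, exp(-1.2))   # 2
#' @export
lq_survival <- function(dose, alpha, beta) {
  stopifnot(is.numeric(dose), is.numeric(alpha), is.numeric(beta))
  if (any(dose < 0)) stop("'dose' must be >= 0")
  exp(-alpha * dose - beta * dose^2)
}

#' @rdname lq_survival
#' @export
lq_dose <- function(alpha, beta, survival) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(survival))
  if (any(survival <= 0 | survival >= 1))
    stop("'survival' must be strictly inside (0, 1)")
  if (any(alpha < 0) || any(beta < 0)) stop("LQM terms must be >= 0")
  if (any(alpha == 0 & beta == 0))
    stop("alpha = beta = 0: no finite dose reaches the target survival")
  lnS <- log(survival)
  -2 * lnS / (alpha + sqrt(alpha^2 - 4 * beta * lnS))
}

#' Relative biological effectiveness at a surviving fraction
#'
#' Closed-form RBE_S, the ratio of the reference-photon dose to the test
#' dose producing the same surviving fraction S under the LQM:
#' `RBE_S = (alpha + sqrt(alpha^2 - 4 beta ln S)) /
#'          (alpha_ref + sqrt(alpha_ref^2 - 4 beta_ref ln S))`.
#' Identical to `lq_dose(alpha_ref, beta_ref, S) / lq_dose(alpha, beta, S)`.
#'
#' @param alpha,beta LQM terms of the radiation under test (Gy^-1, Gy^-2).
#' @param alpha_ref,beta_ref LQM terms of the reference photon exposure.
#' @param survival Surviving fraction in (0, 1) (vectorized).
#' @return RBE (dimensionless, > 0).
#' @examples
#' rbe_s(1, 0, 0.5, 0, 0.1)  # 2
#' @export
rbe_s <- function(alpha, beta, alpha_ref, beta_ref, survival) {
  if (any(survival <= 0 | survival >= 1))
    stop("'survival' must be strictly inside (0, 1)")
  if ((alpha == 0 && beta == 0) || (alpha_ref == 0 && beta_ref == 0))
    stop("degenerate LQM terms: alpha and beta cannot both be zero")
  lnS <- log(survival)
  (alpha + sqrt(alpha^2 - 4 * beta * lnS)) /
    (alpha_ref + sqrt(alpha_ref^2 - 4 * beta_ref * lnS))
}

#' Predict LQM terms and RBE for one spectrum
#'
#' Composes [alpha_mkm()], [beta_mkm()] and [rbe_s()]: derives the
#' exposure-specific (alpha, beta) for the spectrum and the RBE against the
#' cell line's photon reference terms at each requested surviving fraction.
#'
#' @param spectrum A normalized [mkm_spectrum()].
#' @param params A `cell_line_params` object.
#' @param s_levels Surviving fractions in (0, 1) at which to report RBE;
#'   default 0.5, 0.1 and 0.01.  May be empty (alpha and beta only).
#' @return An object of class `mkm_prediction`: a list with `label`, `let`,
#'   `yD` (keV/um), `alpha` (Gy^-1), `beta` (Gy^-2) and `rbe` (named numeric
#'   vector, one element per survival level).
#' @examples
#' hela <- bundled_cell_lines("HeLa")$HeLa
#' p <- mkm_predict(spectrum_track_segment(100), hela)
#' p$rbe[["0.10"]]
#' @export
mkm_predict <- function(spectrum, params, s_levels = c(0.5, 0.1, 0.01)) {
  assert_spectrum(spectrum)
  stopifnot(is_cell_line_params(params))
  if (length(s_levels) && any(s_levels <= 0 | s_levels >= 1))
    stop("'s_levels' must lie strictly inside (0, 1)")
  spectrum <- normalize_spectrum(spectrum)
  a <- alpha_mkm(spectrum, params)
  b <- beta_mkm(spectrum, params)
  rbe <- vapply(s_levels, function(S)
    rbe_s(a, b, params$alpha_ref, params$beta_ref, S), numeric(1))
  names(rbe) <- format(s_levels, trim = TRUE)
  structure(
    list(label = spectrum$label, let = spectrum$let,
         yD = y_dose_mean(spectrum), alpha = a, beta = b, rbe = rbe,
         cell_line = params$name),
    class = "mkm_prediction")
}

#' @export
print.mkm_prediction <- function(x, ...) {
  cat(sprintf("<mkm_prediction> %s | %s\n",
              if (is.null(x$label)) "spectrum" else x$label, x$cell_line))
  if (!is.null(x$let)) cat(sprintf("  LET = %g keV/um\n", x$let))
  cat(sprintf("  yD = %.4g keV/um\n", x$yD))
  cat(sprintf("  alpha = %.4g Gy-1, beta = %.4g Gy-2\n", x$alpha, x$beta))
  for (nm in names(x$rbe))
    cat(sprintf("  RBE at S = %s: %.4g\n", nm, x$rbe[[nm]]))
  invisible(x)
}
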