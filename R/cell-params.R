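#' Species constants: haploid DNA content and normal chromosome count
#'
#' Built-in per-species constants used to derive the mean DNA content of an
#' irradiated population: the haploid (one chromosome set) DNA content gamma
#' in Mbp and the normal chromosome set count x_n.
#'
#' @param species One of `"human"`, `"rat"`, `"chinese hamster"` (also
#'   accepted as `"chinese_hamster"` or `"hamster"`), `"mouse"`.
#' @return A list with components `gamma_mbp` and `x_n`.
#' @examples
#' species_constants("human")  # gamma 3050 Mbp, x_n 23
#' @export
species_constants <- function(species) {
  key <- gsub("[_ ]+", " ", tolower(trimws(species)))
  if (key == "hamster") key <- "chinese hamster"
  tab <- list(
    "human"           = list(gamma_mbp = 3050, x_n = 23L),
    "rat"             = list(gamma_mbp = 2750, x_n = 21L),
    "chinese hamster" = list(gamma_mbp = 2700, x_n = 11L),
    "mouse"           = list(gamma_mbp = 2650, x_n = 20L))
  if (is.null(tab[[key]]))
    stop("unknown species '", species, "'; known: ",
         paste(names(tab), collapse = ", "))
  tab[[key]]
}

#' Ploidy number of an aneuploid population
#'
#' Approximates the ploidy p of an aneuploid cell population as the mean
#' chromosome number divided by the species' normal set count,
#' p = x / x_n.
#'
#' @param x Mean number of chromosomes in the population (> 0).
#' @param species Species name, see [species_constants()].
#' @return Ploidy number (dimensionless).
#' @examples
#' ploidy(78, "human")  # HeLa: 3.391
#' @export
ploidy <- function(x, species) {
  stopifnot(is.numeric(x), length(x) == 1L)
  if (!is.finite(x) || x <= 0) stop("'x' must be a positive chromosome count")
  x / species_constants(species)$x_n
}

#' Mean DNA content of an irradiated population
#'
#' Gamma = gamma * p * xi, where gamma is the species' haploid DNA content,
#' p the ploidy and xi a cell-cycle factor (4/3 for asynchronized
#' populations, in which part of the cells have replicated their DNA).
#'
#' @param species Species name, see [species_constants()].
#' @param p Ploidy number (> 0); 2 for diploid lines.
#' @param xi Cell-cycle factor (> 0), default 4/3.
#' @return Mean DNA content in Mbp.
#' @examples
#' mean_dna_content("human", 2)  # 8133.3 Mbp
#' @export
mean_dna_content <- function(species, p, xi = 4 / 3) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(xi), length(xi) == 1L)
  if (!is.finite(p) || p <= 0) stop("'p' must be > 0")
  if (!is.finite(xi) || xi <= 0) stop("'xi' must be > 0")
  species_constants(species)$gamma_mbp * p * xi
}

#' Mean nucleus radius from morphology or DNA content
#'
#' Three estimators of the mean radius Rn of the (spherical) cell nucleus:
#'
#' * `nucleus_radius_sphere(area)` - from the cross-sectional area A of an
#'   attached nucleus, assuming the nucleus is a sphere of that great-circle
#'   area: Rn = sqrt(A / pi).
#' * `nucleus_radius_spheroid(area)` - same measurement, but treating the
#'   attached nucleus as an oblate spheroid whose vertical semi-axis is a
#'   third of its equatorial radius, and returning the radius of the sphere
#'   of equal volume: Rn = sqrt(A / pi) * 3^(-1/3).
#' * `nucleus_radius_from_dna(Gamma_mbp)` - phenomenological correlation with
#'   the mean DNA content, Rn = 3.5 um + 0.144 um/Gbp * Gamma.  Calibrated on
#'   asynchronized lines with Gamma roughly 5 to 17 Gbp; a warning is issued
#'   outside that window because extrapolating the correlation is
#'   discouraged.
#'
#' @param area Cross-sectional nucleus area in um^2 (> 0).
#' @param Gamma_mbp Mean DNA content in Mbp (> 0); note the correlation
#'   coefficient is per Gbp, conversion is internal.
#' @return Nucleus radius in um.
#' @examples
#' nucleus_radius_sphere(100)          # 5.642
#' nucleus_radius_spheroid(100)        # 3.912
#' nucleus_radius_from_dna(8133.33)    # 4.671
#' @export
nucleus_radius_sphere <- function(area) {
  stopifnot(is.numeric(area), length(area) == 1L)
  if (!is.finite(area) || area <= 0) stop("'area' must be > 0 (um^2)")
  sqrt(area / pi)
}

#' @rdname nucleus_radius_sphere
#' @export
nucleus_radius_spheroid <- function(area) {
  nucleus_radius_sphere(area) * 3^(-1 / 3)
}

#' @rdname nucleus_radius_sphere
#' @export
nucleus_radius_from_dna <- function(Gamma_mbp) {
  stopifnot(is.numeric(Gamma_mbp), length(Gamma_mbp) == 1L)
  if (!is.finite(Gamma_mbp) || Gamma_mbp <= 0) stop("'Gamma_mbp' must be > 0")
  if (Gamma_mbp < 5000 || Gamma_mbp > 17000)
    warning(sprintf(
      "Gamma = %.3g Gbp is outside the calibrated window [5, 17] Gbp; %s",
      Gamma_mbp / 1000,
      "the DNA-radius correlation should not be extrapolated"))
  3.5 + 0.144 * (Gamma_mbp / 1000)
}

#' Mean radius of the subnuclear domains
#'
#' Under the assumption that DNA is homogeneously distributed in the nucleus
#' and that a domain is the average nuclear volume holding `lambda` Mbp of
#' DNA (about 2 Mbp, the size of a giant chromatin loop):
#' rd = Rn * (lambda / Gamma)^(1/3).
#'
#' @param Rn Nucleus radius in um (> 0).
#' @param Gamma_mbp Mean DNA content in Mbp (>= `lambda_mbp`).
#' @param lambda_mbp DNA content of one domain in Mbp, default 2.
#' @return Domain radius in um; `rd <= Rn`, with equality iff
#'   `Gamma_mbp == lambda_mbp`.
#' @examples
#' domain_radius(5.6, 13791.3)  # HeLa: 0.294
#' @export
domain_radius <- function(Rn, Gamma_mbp, lambda_mbp = 2) {
  stopifnot(is.numeric(Rn), length(Rn) == 1L,
            is.numeric(Gamma_mbp), length(Gamma_mbp) == 1L,
            is.numeric(lambda_mbp), length(lambda_mbp) == 1L)
  if (!is.finite(Rn) || Rn <= 0) stop("'Rn' must be > 0 (um)")
  if (!is.finite(lambda_mbp) || lambda_mbp <= 0) stop("'lambda_mbp' must be > 0")
  if (Gamma_mbp < lambda_mbp)
    stop("'Gamma_mbp' must be >= 'lambda_mbp' (domain cannot exceed nucleus)")
  Rn * (lambda_mbp / Gamma_mbp)^(1 / 3)
}

#' Entry-weighted photon reference LQM terms
#'
#' When a cell line's survival entries reference several photon experiments,
#' the reference terms are the arithmetic means of the per-experiment
#' (alpha_ref_i, beta_ref_i) weighted by the number n_i of ion-exposure
#' entries tied to each experiment, so that photon experiments with few ion
#' entries do not bias the average.
#'
#' @param sets A data frame (or list coercible to one) with columns `alpha`
#'   (Gy^-1, > 0), `beta` (Gy^-2, > 0) and `n` (entry counts, >= 1).
#' @return A list with components `alpha_ref` and `beta_ref`.
#' @examples
#' weighted_reference_lqm(data.frame(alpha = c(0.2, 0.4),
#'                                   beta  = c(0.02, 0.04),
#'                                   n     = c(1, 3)))
#' @export
weighted_reference_lqm <- function(sets) {
  sets <- as.data.frame(sets)
  if (nrow(sets) == 0L) stop("empty photon reference set list")
  need <- c("alpha", "beta", "n")
  if (!all(need %in% names(sets)))
    stop("photon reference sets need columns: ", paste(need, collapse = ", "))
  with(sets, {
    if (any(!is.finite(alpha) | alpha <= 0)) stop("all alpha_ref must be > 0")
    if (any(!is.finite(beta) | beta <= 0)) stop("all beta_ref must be > 0")
    if (any(!is.finite(n) | n < 1)) stop("all entry counts n must be >= 1")
    list(alpha_ref = sum(alpha * n) / sum(n),
         beta_ref  = sum(beta * n) / sum(n))
  })
}

#' LQM linear term in the limit of vanishing lineal energy
#'
#' The photon reference alpha_ref already contains the dose-squared-like
#' contribution of single-event specific energy at the reference radiation
#' quality; removing it yields the y -> 0 limit:
#' alpha0 = alpha_ref - beta0 * z_d(yD_ref), with z_d the single-event
#' specific energy in a domain of radius rd.
#'
#' A negative result means beta0 * z_d exceeds alpha_ref - the parameter set
#' is internally inconsistent at the stated reference radiation quality.
#' By default this is an error; `strict = FALSE` downgrades it to a warning
#' and returns the negative value (the model's alpha/beta integrands only
#' ever use the combination alpha0 + beta0 * z_d, which stays positive for
#' y at and above the reference quality).
#'
#' @param alpha_ref Photon reference alpha in Gy^-1.
#' @param beta0 Quadratic LQM term in the y -> 0 limit (equals beta_ref),
#'   Gy^-2.
#' @param yD_ref Dose-mean lineal energy of the reference photon field in
#'   keV/um (2.3 for gamma-rays and 6 MV X-rays, 4.3 for 200 kV X-rays).
#' @param rd Domain radius in um.
#' @param rho Density in g/cm^3, default 1.
#' @param strict Error (default) or warn when the result is negative.
#' @return alpha0 in Gy^-1.
#' @export
alpha0 <- function(alpha_ref, beta0, yD_ref = 2.3, rd, rho = 1,
                   strict = TRUE) {
  stopifnot(is.numeric(alpha_ref), is.numeric(beta0), is.numeric(yD_ref),
            is.numeric(rd))
  if (yD_ref < 0) stop("'yD_ref' must be >= 0")
  a0 <- alpha_ref - beta0 * specific_energy(yD_ref, rd, rho)
  if (a0 < 0) {
    msg <- sprintf(paste0(
      "alpha0 = %.4g Gy^-1 is negative: beta0 * z_d(yD_ref) = %.4g exceeds ",
      "alpha_ref = %.4g; the photon reference parameters are inconsistent ",
      "with the stated reference radiation quality (yD_ref = %g keV/um, ",
      "rd = %.4g um)"),
      a0, beta0 * specific_energy(yD_ref, rd, rho), alpha_ref, yD_ref, rd)
    if (strict) stop(msg) else warning(msg)
  }
  a0
}
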