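---
title: "Methods: a priori microdosimetric kinetic modelling of survival and RBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a priori microdosimetric kinetic modelling of survival and RBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromkm)
```

## Model

`micromkm` predicts the linear-quadratic (LQ) clonogenic survival terms of
a cell population exposed to an arbitrary radiation quality, described
only by its microdosimetric single-event spectrum. The radiation input is
the dose-probability distribution d(y) of the lineal energy y (energy
imparted per event divided by the mean chord length of the site, keV/µm),
stored per bin as the probability mass $w_i = d(y)\,dy$ on a log-uniform
grid. The biological effect of one event in a subnuclear *domain* of
radius $r_d$ is linear-quadratic in the single-event specific energy
$z(y, r) = K\,y/(\rho \pi r^2)$, with $K = 0.16022$ Gy·g·µm³·cm⁻³·keV⁻¹
closing the units and $\rho = 1$ g/cm³. The exposure-specific LQ terms
are the dose-weighted spectrum averages

$$\alpha = \sum_i \left(\alpha_0 + \beta_0\, z_d(y_i)\right) c(y_i)\, w_i,
\qquad
\beta = \beta_0 \left[\sum_i c(y_i)\, w_i\right]^2,$$

where the saturation correction

$$c(y) = \frac{1 - e^{-u}}{u}, \qquad
u = (\alpha_0 + \beta_0 z_d)\, z_n + \beta_0 z_n^2$$

accounts for the non-Poisson distribution of lethal lesions among nuclei
(radius $R_n$) at high lineal energy: as the expected lethal yield per
nucleus traversal $u$ grows, additional energy is increasingly wasted in
already-inactivated cells and $c \to 0$ (the overkill effect). $c$ is 1 at
$y = 0$ and strictly decreasing. Because the same correction enters
$\beta$ quadratically *outside* the integral (the square of the corrected
integral, not the integral of a square), the model always predicts
$\beta/\beta_\mathrm{ref} \le 1$, monotonically decreasing with LET, while
$\alpha$(LET) is unimodal with an interior maximum.

RBE at surviving fraction $S$ is the closed-form iso-survival dose ratio

$$\mathrm{RBE}_S =
\frac{\alpha + \sqrt{\alpha^2 - 4\beta \ln S}}
     {\alpha_\mathrm{ref} + \sqrt{\alpha_\mathrm{ref}^2 -
      4\beta_\mathrm{ref} \ln S}},$$

kept equivalent (to 1e-10, property-tested) to the explicit ratio of
inverted survival curves. Default reporting levels are S = 0.5, 0.1, 0.01.

## A priori cell-line parameters

No ion-exposure data enter the parameter chain; everything derives from
photon dose–response and karyotype/morphology:

| parameter | meaning | source |
|---|---|---|
| $\Gamma = \gamma\, p\, \xi$ | mean DNA content (Mbp) | species constant γ (human 3050, rat 2750, Chinese hamster 2700, mouse 2650 Mbp; normal set counts 23/21/11/20), ploidy p, cell-cycle factor ξ |
| $p$ | ploidy | 2 for normal/pseudodiploid lines, else mean chromosome count / normal set count |
| $\xi$ | cell-cycle factor | 4/3 for asynchronized populations (a quarter of the DNA is duplicated on average); 1 would describe a G1-synchronized population. Free parameter, no cell-cycle model behind it. |
| $R_n$ | nucleus radius (µm) | one of: measured radius; cross-sectional area A via $\sqrt{A/\pi}$ (sphere) or $\sqrt{A/\pi}\cdot 3^{-1/3}$ (equal-volume oblate spheroid with vertical semi-axis a third of the equatorial radius); or the phenomenological correlation $R_n = 3.5 + 0.144\,\Gamma[\mathrm{Gbp}]$ µm |
| $r_d$ | domain radius (µm) | $R_n (\lambda/\Gamma)^{1/3}$, the radius of the average nuclear volume holding λ = 2 Mbp of DNA (one giant chromatin loop), assuming homogeneous DNA packing |
| $\alpha_\mathrm{ref}, \beta_\mathrm{ref}$ | photon reference LQ terms (Gy⁻¹, Gy⁻²) | a single photon experiment, or the entry-count-weighted mean over several ($\sum \alpha_i n_i / \sum n_i$) so photon fits tied to few ion entries do not bias the average |
| $\beta_0$ | quadratic term at $y \to 0$ | $= \beta_\mathrm{ref}$ (the correction integral is ≈ 1 for photons) |
| $\alpha_0$ | linear term at $y \to 0$ | $\alpha_\mathrm{ref} - \beta_0\, z_d(\bar y_{D,\mathrm{ref}})$, with $\bar y_{D,\mathrm{ref}}$ = 2.3 keV/µm (γ-rays, 6 MV X-rays) or 4.3 keV/µm (200 kV X-rays) |

The DNA–radius correlation was calibrated on asynchronized lines with Γ
roughly 5–17 Gbp; `nucleus_radius_from_dna()` warns outside that window
rather than failing, since the exact calibration range is not tabulated —
the window brackets the configurations shipped with the package.

### Negative α₀ and the U-251MG configuration

`alpha0()` errors when $\beta_0 z_d(\bar y_{D,\mathrm{ref}})$ exceeds
$\alpha_\mathrm{ref}$: the photon reference terms are then inconsistent
with the stated reference radiation quality, and a silent negative α₀
usually indicates a data-entry problem. One bundled line, U-251MG, is a
genuine exception — its unusually low $\alpha_\mathrm{ref} = 0.031$ Gy⁻¹
(α/β ≈ 0.56 Gy) puts it below the subtraction at $\bar y_{D,\mathrm{ref}}
= 2.3$ keV/µm, giving α₀ = −0.046 Gy⁻¹. The model remains well defined:
every integrand uses the combination $\alpha_0 + \beta_0 z_d(y)$, which is
positive for all qualities at or above the reference one, and predictions
for such lines are published practice. The config flag
`allow_negative_alpha0` therefore downgrades the error to a warning;
it is set only in the bundled U-251MG configuration. The side effect is
that $c(y)$ may minutely exceed 1 below the reference quality
($u < 0$); this region carries no weight in realistic ion spectra.

A related data note: the published table for C3H10T1/2 prints
β_ref = 0.389 Gy⁻², inconsistent with its printed α/β = 4.44 Gy (which
implies 0.0389) and yielding a negative α₀ as well. The bundled fixture
uses 0.0389 Gy⁻² as the working value and records the printed reading in
`beta_ref_printed` with an explanatory note rather than correcting it
silently.

## Spectra: representation, generators, numerics

**Grid.** Log-uniform edges, default 1e-2–1e7 keV/µm at 50 bins/decade
(450 bins); the representative y of a bin is the geometric mean of its
edges, unbiased for log-uniform binning. Arbitrary file y-values are
snapped mass-conservingly to the containing bin, so all spectra live on
one canonical grid and results are grid-reproducible. The α/β sums are
discrete over bin masses — no interpolation — and halving the bin width
changes moments and LQ terms by well under 0.1% (property-tested at
100 and 500 bins/decade).

**Generators.** Three synthetic sources stand in for transport-code
spectra, chosen for closed-form moments: a delta line (photon references);
the track-segment chord-length spectrum for spherical sites under
µ-randomness, $d(y) = 3y^2/y_\mathrm{max}^3$ with $y_\mathrm{max} =
\tfrac32\,\mathrm{LET}$, hence $\bar y_F = \mathrm{LET}$ and $\bar y_D =
\tfrac98\,\mathrm{LET}$ (exact per-bin integration of $y^3$ differences);
and a log-normal frequency spectrum converted by $d(y) \propto y f(y)$,
with $\bar y_D = e^{\mu + 3\sigma^2/2}$ (accurate to 0.5% on the default
grid for σ ≤ 1.5). The track-segment model is explicitly idealized: no
energy-loss straggling, delta-ray escape, or detector response.

**Delta placement.** The delta generator splits its unit mass between the
two bins whose representatives bracket the requested y\*, so the
dose-mean equals y\* exactly instead of inheriting an up-to-half-bin bias
(~2% at 50 bins/decade). This matters for the self-consistency guarantee
below: for lines with small $\alpha_\mathrm{ref}$ a 2% shift in the
reference y would propagate into a several-percent α error.

**Saturation numerics.** $c(u)$ is evaluated as `-expm1(-u)/u`; for
$|u| < 10^{-8}$ the series $1 - u/2 + u^2/6$ avoids cancellation. The
second-order bound $1 - u/2 \le c \le 1$ is property-tested for
$u \le 0.1$.

## What the tests demonstrate (and what they cannot)

The suite verifies, among others: exact reproduction of all 14 published
parameter sets' nucleus radii (1 d.p.) and domain radii (2 d.p.) from
their stated inputs; photon self-consistency — predicting on a delta at
$\bar y_{D,\mathrm{ref}}$ returns $\alpha_\mathrm{ref}$ and
$\beta_\mathrm{ref}$ within 1.5% for every bundled line; $\beta \le
\beta_0$ always; and
a single interior RBE₁₀% maximum along a 1–10⁴ keV/µm track-segment sweep
for all 14 lines (41 log-spaced LET points).

Synthetic spectra are idealized monoenergetic-segment conditions. Passing
these suites shows internal consistency and correct closed-form limits,
not agreement with in-vitro survival for real beams, which depends on
transport-simulated spectra (secondary electrons, fragmentation tails)
and on the scatter of biological data. LET never enters the physics here;
it is carried as opaque metadata for labelling sweeps.

## Survival-database filtering

`filter_survival_entries()` encodes the consistency rules used before
benchmarking against heterogeneous survival compilations, rejecting in
order: spread-out-Bragg-peak exposures (incompatible with monoenergetic
modelling), ion energies < 1 MeV/n (partial cell traversal, dosimetric
uncertainty), synchronized populations (ξ = 4/3 assumes asynchrony),
entries with no positive photon reference pair, entries with no
non-negative ion β, and entries whose only fit reports α = 0 with β above
a threshold (constrained-fit artifact). The threshold defaults to 0 —
"large β" is not defined quantitatively anywhere authoritative, so any
positive β triggers the rule, and the parameter is exposed rather than
inventing a cutoff. Malformed rows become per-row rejections, never a
crash.

## Problem sizes

All shipped computations are desk-scale: 450-bin spectra, 41-point LET
sweeps, 1000-draw RBE property checks; the complete test suite runs in
about 15 s on one core and the acceptance derivations in milliseconds.
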