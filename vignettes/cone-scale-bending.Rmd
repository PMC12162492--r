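---
title: "Quantifying hygroscopic bending of cone scales: strains, curvature and the arc-bending model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hygroscopic bending of cone scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conebend)
```

## The problem

Mature conifer ovuliferous scales are built entirely of dead tissue, yet
they bend reversibly as humidity changes, opening the cone to release
seeds. The movement is driven by differential swelling of the cell-wall
matrix: the abaxial side of the scale lamina acts as the active tissue,
the adaxial side as the resistance tissue, and the stiff vascular-bundle
(VB) plate sits between them. A puzzle this package is built to dissect
is that scales with very similar anatomy, chemistry and *surface strains*
can nonetheless bend to very different extents. The explanation is
geometric: bending curvature depends not only on the strain contrast
between the two surfaces but also, inversely, on lamina thickness — and
on where the stiff VB plate sits within that thickness.

`conebend` implements the full measurement chain at the desk-analysis
level: landmark-based surface strains, profile curvature from digitized
point sets, an analytic arc-bending laminate model, cross-section
morphometry, and the two-group statistics used to compare bending
phenotypes. Image acquisition and landmark digitization themselves are
out of scope; the package starts from coordinate tables.

## Surface strains from landmark correspondences

Each strip surface carries 8 landmarks (modelled as a 2 × 4 grid),
digitized in dry and wet state. The deformation is estimated as a single
global affine map \(x_i = F X_i + c\) over all paired landmarks of a
surface, by ordinary least squares. This is deliberately the
smallest-assumption estimator of a *homogeneous* surface strain: with 8
landmarks and 6 affine parameters the fit is overdetermined, and the
root-mean-squared landmark residual is reported so that inhomogeneous
deformation shows up as a large residual rather than silently biasing
the strain.

The polar decomposition \(F = R\,U\) separates rigid rotation \(R\) from
the right stretch tensor \(U = \sqrt{F^\top F}\). The principal
engineering strains are \(\varepsilon_{max} = \lambda_1 - 1\) and
\(\varepsilon_{min} = \lambda_2 - 1\) (eigenvalues of \(U\)), matching
the \(\Delta L / L\) strain definition used for segment measurements;
Green–Lagrange strain is intentionally not used. The maximal-strain
direction is the \(\lambda_1\) eigenvector, reported in the *reference*
(dry) configuration relative to a user-declared longitudinal axis and
folded into \((-\pi/2, \pi/2]\). When \(\lambda_1 = \lambda_2\) the
direction is undefined; the package reports 0 and sets an `isotropic`
flag rather than returning an undefined angle.

Degenerate configurations are rejected explicitly: fewer than 3
landmarks, or a centred reference cloud whose smallest singular value is
below \(10^{-6}\) times its RMS size (collinearity), or a fitted
\(\det F \le 0\) (which in practice means a mislabelled dry/wet pairing
or a mirrored image).

Segment strains support both reference conventions —
\(\varepsilon = (L_{wet}-L_{dry})/L_{dry}\) for wetting and
\((L_{dry}-L_{wet})/L_{wet}\) for drying — because the surface-replica
analysis uses the dry reference while the laminate model is formulated
for the wet-to-dry transition. The two are reciprocal,
\((1+\varepsilon_{dry\,ref})(1+\varepsilon_{wet\,ref}) = 1\), and
`flip_strain_reference()` converts between them exactly.

```{r strain-example}
corr <- gen_landmark_pair(diag(c(1.08, 1.02)))  # 8% transverse-free stretch
ps <- principal_strains(fit_deformation(corr))
c(eps_max = ps$eps_max, eps_min = ps$eps_min)
```

## Profile curvature

Profiles are digitized as ordered points along the abaxial side of a
square or strip profile (12–26 points in practice). The pipeline is:

1. **Chord alignment.** The trace is rigidly moved so the chord from the
   first to the last point lies on the x-axis. This makes the fit frame
   independent of how the profile was oriented in the image, and it is a
   precondition for single-valued polynomial fitting: a profile that
   folds back over its chord (an arc beyond a half-turn) is rejected as
   a geometry error rather than silently fitted.
2. **Rank-selected polynomial fit.** Rank-2 and rank-3 polynomials are
   fitted by OLS. Because the models are nested, raw \(R^2\) can never
   prefer the quadratic, so the selection criterion is *adjusted*
   \(R^2\), with ties within \(10^{-9}\) resolved toward the lower rank.
   This is the one place where the procedure as commonly stated ("the
   rank with the higher \(R^2\)") is degenerate, and the adjusted form
   is the minimal fix that makes it meaningful.
3. **Analytic curvature.** \(\kappa(x) = f''(x)/(1+f'(x)^2)^{3/2}\),
   evaluated at the abscissa of every digitized point (not on a uniform
   grid), signed internally, summarised as the mean of \(|\kappa|\).

The sign convention is that convex-toward-abaxial is positive; all
comparisons use absolute values since profiles may be digitized in
either direction.

Numerical behaviour worth knowing: a polynomial can only approximate a
circular arc, so even noise-free arcs carry a small systematic
curvature error that grows with arc span — about 2% at a 30° span and
about 3% at 40°, which is why the cross-module consistency tests are
calibrated at spans up to 30–40° and why comparisons between profiles of
similar span are more accurate than absolute values. Degenerate flat
traces (ordinates numerically zero after alignment) are given
\(R^2 = 1\) by convention so that straight lines return zero curvature
rather than an undefined fit statistic.

```{r curvature-example}
arc <- gen_profile("arc", list(radius = 10, span_deg = 30), n_points = 20)
mean_abs_curvature(arc)$mean_abs_kappa  # truth: 0.1 /mm
```

## The arc-bending laminate model

The model idealises a lamina square as flat in the wet state and bent
into a circular arc in the dry state, with the adaxial surface on the
outside (it contracts less on drying). Both surfaces must fit the same
arc of circle fraction \(p\):

\[(1+\varepsilon_{ad})\,L = 2\pi p\,(r + t_{dry}), \qquad
  (1+\varepsilon_{ab})\,L = 2\pi p\,r,\]

with \(L\) the wet length, \(t_{dry}\) the dry thickness and \(r\) the
radius of the abaxial surface. Subtracting and dividing gives the closed
forms implemented in `forward_bend()`:

\[p = \frac{(\varepsilon_{ad}-\varepsilon_{ab})\,L}{2\pi t_{dry}}, \qquad
  \kappa = \frac{1}{r}
         = \frac{\varepsilon_{ad}-\varepsilon_{ab}}{(1+\varepsilon_{ab})\,t_{dry}},\]

and the strain ratio \(\rho = (1+\varepsilon_{ad})/(1+\varepsilon_{ab})
= (r+t_{dry})/r = 1 + \kappa t_{dry}\), which `invert_to_ratio()` uses to
recover \(\rho\) from a measured curvature and thickness. At fixed
\(\rho\), \(\kappa(t) = (\rho-1)/t\): the theoretical curvature–thickness
curves produced by `curvature_thickness_curve()` never cross for
different \(\rho\).

Model conventions, chosen once:

* Strains are wet→dry reference (both typically negative, with
  \(\varepsilon_{ad} > \varepsilon_{ab}\)); `forward_bend()` rejects
  \(\varepsilon_{ad} < \varepsilon_{ab}\) as a sign-convention error
  rather than silently bending the other way.
* The wet state is exactly flat — no residual wet curvature parameter.
* \(r\) is measured to the abaxial surface, the same surface the
  curvature pipeline digitizes, so model and measurement refer to the
  same quantity.
* \(t_{wet}\) is carried as metadata only; the equations use
  \(t_{dry}\).
* \(p \le 0.5\) is treated as the model's geometric regime; larger arcs
  trigger a warning (and could not be measured by chord-frame
  polynomial fitting anyway).
* The flat case \(\varepsilon_{ad} = \varepsilon_{ab}\) returns
  \(\kappa = 0\), \(p = 0\), \(r = \infty\), and the limit is
  continuous: \(\kappa \to 0\) as the strain difference vanishes.

The model ignores mid-plane longitudinal strain and transverse coupling
(the saddle-shape interplay of the plates); it is a single-direction arc
construction, which is exactly the explanatory level needed for the
thickness effect.

## Morphometry

The VB center is estimated from digitized outline points by the
algebraic (Kåsa) circle fit — linear in its parameters, deterministic,
no initialization — with radial RMS residual reported. The VB-position
asymmetry index is defined as \(A = d_{ad}/(d_{ad}+d_{ab})\) with both
distances measured to the VB center: dimensionless, scale-invariant,
0.5 for a mid-plane VB plate, below 0.5 when the bundles sit closer to
the adaxial surface. (The underlying distance measurements could equally
be taken to the VB margins; the center is used because the circle fit
defines it reproducibly.)

Cell-wall density is wall thickness divided by outer cell radius, per
cell; positions along a cross-section transect are normalized so the
adaxial VB margin is 0 and the abaxial margin 1. Out-of-range samples
are clipped and flagged rather than rejected, since hand-measured
margins do not always bracket every sampled cell. The gradient is
summarised by a Spearman rank correlation.

## Statistics

Group comparisons use the classical pooled-variance Student t-test
(Welch's form is available behind a flag but is not the default, since
the named method is Student's). Significance classes follow the display
convention: `ns` for \(p \ge 0.05\), `moderate` ("dashed") for
\(0.01 < p < 0.05\), `strong` ("solid") for \(p \le 0.01\), with the
boundaries exact. Zero-variance degenerate samples use the convention
\(p = 1\) for identical means and \(p = 0\) otherwise. Boxplot summaries
fix the quartile rule to linear interpolation of the empirical
distribution (`quantile(type = 7)`) so whisker ends (most extreme values
within 1.5 IQR of the box) and outlier lists are bit-for-bit
reproducible. No multiple-testing correction is applied — pairwise tests
are reported individually — which is a known limitation when many
variables are compared.

## The synthetic-data generator and what it does (not) show

All tests run on generated data with known ground truth. The generator
emulates:

* homogeneous planar deformations of 2 × 4 landmark grids with
  anisotropic strain and isotropic Gaussian digitization noise;
* straight, circular-arc and polynomial profiles with Gaussian noise
  along the local normal;
* laminate squares whose wet trace is straight and whose dry trace is
  the model's predicted arc;
* two cohorts ("weak" and "strong" bending) sharing identical
  surface-strain conditions but differing in thickness and VB asymmetry;
* monotone adaxial→abaxial wall-density transects.

Default study conditions, chosen once as realistic for this system and
then left alone: 6 specimens per cohort; dry→wet surface strains
adaxial (−0.03 longitudinal, +0.06 transverse) and abaxial (+0.05,
+0.08) — longitudinal adaxial shrinkage with stronger abaxial expansion,
giving a shared wet→dry strain ratio \(\rho \approx 1.082\); thickness
means 1.2 mm (weak) vs 0.6 mm (strong) with 10% CV; asymmetry means
0.45 vs 0.25 (sd 0.04); square length \(L = 5\) mm; digitization noise
0.01 mm on landmarks and profiles. Distributions are truncated normals
(resampled into valid ranges). Under these conditions the strong cohort's
dry arcs span ≈ 37° and the weak cohort's ≈ 19°.

What passing tests on such data demonstrate is *internal consistency*:
strains, curvature, the model and the statistics agree with each other
and with analytic ground truth at documented tolerances. What they do
not demonstrate is robustness to everything real data adds — spatially
inhomogeneous deformation within a strip (visible here only as residual
RMS), non-Gaussian digitization error, profiles that are not exactly
circular arcs, and calibration error of the pixel-to-mm scale factor,
which is left entirely to the user because instrument calibrations vary.

## The simulated study

The `analysis/` scripts run the full chain at the default conditions
(seed 42): simulate cohorts, recover surface strains (statistically
indistinguishable between cohorts), measure dry-profile curvature
(ratio ≈ 2 strong:weak), compare measured curvature with the
laminate-model prediction per specimen, and test thickness, asymmetry
and curvature differences (all `strong`, while both surface strains are
`ns`). The geometric milling experiment — removing adaxial-plate
thickness at fixed \(\rho\) — raises predicted curvature by exactly the
inverse thickness ratio, reproducing the observation that thinning the
adaxial plate of a weakly bending scale makes it bend strongly.

Problem sizes throughout (6 specimens per cohort, 20 points per profile,
500 replicates for noise-recovery checks, 1000 replicates for the
type-I-error check) are the package's own choices, small enough to run
anywhere yet large enough that the binomial and law-of-large-numbers
tolerances in the tests are meaningful.

## Known limitations

* Only planar (1D profile) curvature; no 3D saddle-shape reconstruction
  or Gaussian/mean surface curvature.
* The strain estimator assumes homogeneous deformation per landmark
  patch; it reports inhomogeneity but does not model it.
* The laminate model is geometric, not mechanical: no stiffness,
  prestress or stress-relief modelling, and no time dynamics.
* Whether a real analysis would group strain crosses per strip or per
  landmark sub-quadrilateral is a digitization-protocol choice; both are
  supported via region tags, with per-strip fitting as the default.
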