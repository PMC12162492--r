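# Analytic arc-bending laminate model: a lamina square that is flat in
# the wet state bends into a circular arc on drying because its adaxial
# and abaxial surfaces contract by different amounts. With L the wet
# length, t_dry the dry thickness, eps_ad/eps_ab the wet->dry
# longitudinal surface strains and r the dry curvature radius of the
# abaxial surface, the arc geometry imposes
#   (1 + eps_ad) L = 2 pi p (r + t_dry)
#   (1 + eps_ab) L = 2 pi p r
# where p is the portion of a full circle subtended by the arc.

#' Forward arc-bending prediction
#'
#' Solves the two arc equations for the circle fraction `p`, the abaxial
#' curvature radius `r` and the dry curvature `kappa = 1/r`:
#' \deqn{p = (\epsilon_{ad} - \epsilon_{ab}) L / (2\pi t_{dry}), \quad
#'       r = (1+\epsilon_{ab}) t_{dry} / (\epsilon_{ad} - \epsilon_{ab}).}
#' Strains are wet-to-dry reference, so both are typically negative with
#' the adaxial surface (outer side of the bent arc) contracting less than
#' the abaxial one.
#'
#' @param eps_ad,eps_ab Longitudinal surface strains (wet->dry reference,
#'   each > -1) of the adaxial and abaxial surface. `eps_ad < eps_ab`
#'   would put the abaxial surface on the outside of the bend and is
#'   rejected as a sign-convention error.
#' @param t_dry Dry lamina thickness (mm, > 0).
#' @param L Wet length of the square in the bending direction (mm, > 0).
#' @param t_wet Optional wet thickness, carried as metadata only.
#' @return A `laminate_arc`: list with `L`, `t_dry`, `t_wet`, `eps_ad`,
#'   `eps_ab`, `r` (Inf when flat), `p`, `kappa` (1/mm). An arc beyond a
#'   semicircle (`p > 0.5`) triggers an over-bend warning.
#' @export
forward_bend <- function(eps_ad, eps_ab, t_dry, L, t_wet = NA_real_) {
  if (!(L > 0 && t_dry > 0)) stop_conebend("L and t_dry must be positive", "conebend_domain_error")
  if (eps_ad <= -1 || eps_ab <= -1) stop_conebend("strains must exceed -1", "conebend_domain_error")
  if (eps_ad < eps_ab) {
    stop_conebend("eps_ad < eps_ab: abaxial surface would lie outside the bend; check the wet->dry sign convention",
                  "conebend_convention_error")
  }
  d <- eps_ad - eps_ab
  if (d == 0) {
    arc <- list(L = L, t_dry = t_dry, t_wet = t_wet, eps_ad = eps_ad,
                eps_ab = eps_ab, r = Inf, p = 0, kappa = 0)
    return(structure(arc, class = "laminate_arc"))
  }
  p <- d * L / (2 * pi * t_dry)
  r <- (1 + eps_ab) * t_dry / d
  if (p > 0.5) {
    warning(sprintf("arc exceeds a semicircle (p = %.3f); outside the model's geometric regime", p))
  }
  structure(list(L = L, t_dry = t_dry, t_wet = t_wet, eps_ad = eps_ad,
                 eps_ab = eps_ab, r = r, p = p, kappa = 1 / r),
            class = "laminate_arc")
}

#' Adaxial/abaxial strain ratio of an arc
#'
#' \eqn{\rho = (1+\epsilon_{ad})/(1+\epsilon_{ab})}; geometrically
#' \eqn{\rho = (r + t_{dry})/r = 1 + \kappa t_{dry}}.
#'
#' @param arc A `laminate_arc`.
#' @return The dimensionless ratio \eqn{\rho \ge 1}.
#' @export
strain_ratio <- function(arc) {
  stopifnot(inherits(arc, "laminate_arc"))
  (1 + arc$eps_ad) / (1 + arc$eps_ab)
}

#' Strain ratio implied by measured curvature and thickness
#'
#' Inverts the arc model: \eqn{\rho = 1 + \kappa t_{dry}}. The extent of
#' bending thus depends on both the strain contrast between the surfaces
#' and on the lamina thickness.
#'
#' @param kappa Dry curvature (1/mm, >= 0; a negative value from a signed
#'   curvature convention is used in absolute value with a warning).
#' @param t_dry Dry thickness (mm, > 0).
#' @return The implied ratio \eqn{\rho}.
#' @export
invert_to_ratio <- function(kappa, t_dry) {
  if (t_dry <= 0) stop_conebend("t_dry must be positive", "conebend_domain_error")
  if (any(kappa < 0)) {
    warning("negative curvature: using absolute value (signed profile convention)")
    kappa <- abs(kappa)
  }
  1 + kappa * t_dry
}

#' Theoretical curvature-thickness curve
#'
#' For a fixed surface-strain ratio \eqn{\rho}, dry curvature falls off
#' with thickness as \eqn{\kappa(t) = (\rho - 1)/t}: thin laminae bend
#' strongly, thick ones weakly, at identical surface strains.
#'
#' @param rho Strain ratio (>= 1).
#' @param thickness Vector of dry thicknesses (mm, > 0).
#' @return Data frame `(t_dry, kappa)`, monotone decreasing in `t_dry`.
#' @export
curvature_thickness_curve <- function(rho, thickness) {
  if (rho < 1) stop_conebend("rho must be >= 1 (adaxial side outermost)", "conebend_convention_error")
  if (any(thickness <= 0)) stop_conebend("thicknesses must be positive", "conebend_domain_error")
  thickness <- sort(thickness)
  data.frame(t_dry = thickness, kappa = (rho - 1) / thickness)
}

#' Predicted bending contrast between two cohorts
#'
#' Evaluates \eqn{\kappa = (\rho - 1)/t} for two cohorts of specimens
#' (e.g. weakly and strongly bending scales) and reports the curvature
#' ratio. With equal strain ratios the curvature ratio is the inverse
#' thickness ratio.
#'
#' @param cohortA,cohortB Lists with elements `rho` and `t` (mean dry
#'   thickness, mm), optionally `label`.
#' @return List with per-cohort predicted `kappa` and `kappa_ratio_B_A`.
#' @export
predict_bending_contrast <- function(cohortA, cohortB) {
  kA <- (cohortA$rho - 1) / cohortA$t
  kB <- (cohortB$rho - 1) / cohortB$t
  list(label_A = cohortA$label %||% "A", label_B = cohortB$label %||% "B",
       kappa_A = kA, kappa_B = kB,
       kappa_ratio_B_A = if (kA > 0) kB / kA else Inf)
}
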