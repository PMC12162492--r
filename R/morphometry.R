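# Structural indices from cross-section measurements: circle fit for the
# vascular-bundle center, plate-position asymmetry, thickness strain, and
# the cell-wall density gradient across the VB plate.

#' Algebraic least-squares circle fit
#'
#' Kasa fit: writing the circle as \eqn{x^2 + y^2 = b_1 x + b_2 y + b_3},
#' the parameters are linear and solved by ordinary least squares, with
#' center \eqn{(b_1/2, b_2/2)} and radius
#' \eqn{\sqrt{b_3 + b_1^2/4 + b_2^2/4}}. Deterministic, no initialization;
#' used to estimate the vascular-bundle center from digitized outline
#' points. Three points give the circumscribed circle exactly.
#'
#' @param x,y Coordinates (mm) of at least 3 non-collinear points; `x` may
#'   also be a 2-column matrix or data frame.
#' @return A `circle_fit`: list with `center` (x, y), `radius` (mm) and
#'   `rms_residual` (RMS of radial residuals, mm).
#' @export
fit_circle <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3) stop_conebend("need >= 3 points for a circle fit", "conebend_degenerate_error")
  check_finite_xy(x, y, "circle points")
  M <- cbind(x - mean(x), y - mean(y))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (min(sv) <= 1e-9 * max(sv, 1e-300)) {
    stop_conebend("points are (near-)collinear; circle fit degenerate", "conebend_degenerate_error")
  }
  A <- cbind(x, y, 1)
  b <- unname(qr.solve(A, x^2 + y^2))
  center <- c(x = b[1] / 2, y = b[2] / 2)
  radius <- sqrt(b[3] + sum(center^2))
  resid <- sqrt((x - center[1])^2 + (y - center[2])^2) - radius
  structure(list(center = center, radius = unname(radius),
                 rms_residual = sqrt(mean(resid^2))),
            class = "circle_fit")
}

#' Plate geometry of a lamina cross-section
#'
#' @param d_ad Adaxial plate thickness: distance from the adaxial surface
#'   to the vascular-bundle center (mm, > 0).
#' @param d_ab Abaxial plate thickness: distance from the VB center to the
#'   abaxial surface (mm, > 0).
#' @param t_total Total lamina thickness (mm); defaults to `d_ad + d_ab`
#'   when the two distances span the full thickness.
#' @return A `plate_geometry` list.
#' @export
plate_geometry <- function(d_ad, d_ab, t_total = d_ad + d_ab) {
  if (d_ad <= 0 || d_ab <= 0) stop_conebend("plate thicknesses must be positive", "conebend_domain_error")
  if (d_ad + d_ab > t_total * (1 + 1e-6)) {
    stop_conebend("d_ad + d_ab exceeds total thickness", "conebend_domain_error")
  }
  structure(list(d_ad = d_ad, d_ab = d_ab, t_total = t_total),
            class = "plate_geometry")
}

#' Vascular-bundle position asymmetry index
#'
#' \eqn{A = d_{ad} / (d_{ad} + d_{ab})}: 0.5 for a mid-plane VB plate,
#' below 0.5 when the bundles sit closer to the adaxial surface (the
#' pattern of strongly bending scales).
#'
#' @param g A [plate_geometry].
#' @return Asymmetry index in (0, 1).
#' @export
asymmetry_index <- function(g) {
  stopifnot(inherits(g, "plate_geometry"))
  g$d_ad / (g$d_ad + g$d_ab)
}

#' Thickness strain of a lamina segment
#'
#' Engineering strain of a thickness-direction segment with dry reference,
#' the convention used for the apparent swelling of the whole lamina
#' (AB-AD) and of the abaxial plate (AB-VB).
#'
#' @param pair A [segment_pair] with direction `"THICKNESS"`.
#' @return A `segment_strain` (see [segment_strain]).
#' @export
thickness_strain <- function(pair) {
  stopifnot(inherits(pair, "segment_pair"))
  if (pair$direction != "THICKNESS") {
    stop_conebend("thickness_strain requires a THICKNESS-direction segment", "conebend_convention_error")
  }
  segment_strain(pair, reference = "dry")
}

#' Cell-wall density profile across the vascular-bundle plate
#'
#' Per-cell wall density is wall thickness divided by the outer cell
#' radius; positions are normalized so the adaxial VB margin maps to 0 and
#' the abaxial margin to 1. A Spearman rank correlation of density against
#' normalized distance summarises the gradient (negative when density
#' decreases abaxially).
#'
#' @param wall_thickness,outer_radius,raw_distance Per-cell measurements
#'   (same units); thickness must be positive and no larger than the
#'   radius.
#' @param adaxial_margin,abaxial_margin Raw positions of the two VB-plate
#'   margins (distinct).
#' @return List with `samples` (data frame `normalized_distance, density,
#'   out_of_range`) and `trend_rho` (Spearman correlation, `NA` for
#'   constant input).
#' @export
wall_density_profile <- function(wall_thickness, outer_radius, raw_distance,
                                 adaxial_margin, abaxial_margin) {
  width <- abaxial_margin - adaxial_margin
  if (width == 0) stop_conebend("margin interval has zero width", "conebend_domain_error")
  if (any(wall_thickness <= 0) || any(outer_radius <= 0)) {
    stop_conebend("wall thickness and radius must be positive", "conebend_domain_error")
  }
  if (any(wall_thickness > outer_radius)) {
    stop_conebend("wall thickness exceeds outer radius", "conebend_domain_error")
  }
  u <- (raw_distance - adaxial_margin) / width
  out_of_range <- u < 0 | u > 1
  if (any(out_of_range)) warning("samples outside the margin interval were clipped to [0, 1]")
  u <- pmin(pmax(u, 0), 1)
  density <- wall_thickness / outer_radius
  rho <- if (length(u) > 2 && sd(u) > 0 && sd(density) > 0) {
    cor(u, density, method = "spearman")
  } else NA_real_
  list(samples = data.frame(normalized_distance = u, density = density,
                            out_of_range = out_of_range),
       trend_rho = rho)
}
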