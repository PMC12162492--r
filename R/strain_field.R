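# Segment strains and planar principal strains from landmark
# correspondences between dry and wet states.

#' Engineering strain of a measured segment
#'
#' Relative length change \eqn{\epsilon = (L_{obs} - L_{ref}) / L_{ref}}
#' with respect to a declared reference hydration state. With a dry
#' reference this is the strain accompanying wetting,
#' \eqn{(L_{wet} - L_{dry})/L_{dry}}; with a wet reference the strain
#' accompanying drying. The two conventions are not negatives of each
#' other; they satisfy \eqn{(1+\epsilon_{dry})(1+\epsilon_{wet}) = 1}.
#'
#' @param pair A [segment_pair].
#' @param reference `"dry"` or `"wet"`: the state whose length is the
#'   denominator.
#' @return A `segment_strain` list with fields `epsilon`, `direction`,
#'   `reference`, `label`.
#' @export
segment_strain <- function(pair, reference = c("dry", "wet")) {
  stopifnot(inherits(pair, "segment_pair"))
  reference <- match.arg(reference)
  L_ref <- if (reference == "dry") pair$L_dry else pair$L_wet
  L_obs <- if (reference == "dry") pair$L_wet else pair$L_dry
  if (L_ref <= 0) stop_conebend("reference length must be positive", "conebend_domain_error")
  structure(list(epsilon = (L_obs - L_ref) / L_ref,
                 direction = pair$direction,
                 reference = reference,
                 label = pair$label),
            class = "segment_strain")
}

#' Convert a strain between dry- and wet-reference conventions
#'
#' Uses the identity \eqn{(1+\epsilon_{dry\,ref})(1+\epsilon_{wet\,ref})=1}.
#'
#' @param epsilon Strain (> -1) in the source convention.
#' @return The same length change expressed in the opposite reference
#'   convention.
#' @export
flip_strain_reference <- function(epsilon) {
  if (any(epsilon <= -1)) stop_conebend("strain must exceed -1", "conebend_domain_error")
  1 / (1 + epsilon) - 1
}

#' Least-squares affine deformation of a landmark correspondence
#'
#' Fits the homogeneous planar deformation \eqn{x_i \approx F X_i + c}
#' mapping reference landmarks \eqn{X_i} to observed landmarks \eqn{x_i}
#' by ordinary least squares over all pairs. The fit assumes deformation
#' is homogeneous across the landmark patch; the reported residual RMS
#' (root mean squared Euclidean landmark misfit, mm) flags inhomogeneity.
#'
#' @param corr A [landmark_correspondence] with at least 3 non-collinear
#'   reference landmarks. Collinearity is rejected when the smallest
#'   singular value of the centred reference coordinates is below
#'   `1e-6` times the landmark-cloud RMS size.
#' @return A `deformation_gradient`: list with `F` (2x2), `c`
#'   (translation, mm), `residual_rms` (mm), `n` and the correspondence
#'   metadata.
#' @export
fit_deformation <- function(corr) {
  stopifnot(inherits(corr, "landmark_correspondence"))
  X <- corr$X; x <- corr$x
  n <- nrow(X)
  if (n < 3) stop_conebend("need >= 3 paired landmarks", "conebend_degenerate_error")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  rms_size <- sqrt(mean(rowSums(Xc^2)))
  if (rms_size == 0 || min(sv) <= 1e-6 * rms_size) {
    stop_conebend("reference landmarks are (near-)collinear", "conebend_degenerate_error")
  }
  A <- cbind(1, X)
  B <- qr.solve(A, x)              # 3 x 2: rows = (intercept, x, y)
  Fm <- t(B[2:3, , drop = FALSE])  # x_obs = Fm %*% X + c
  cc <- as.numeric(B[1, ])
  if (det(Fm) <= 0) {
    stop_conebend("fitted deformation is not orientation-preserving; check landmark pairing",
                  "conebend_orientation_error")
  }
  res <- x - A %*% B
  structure(list(F = unname(Fm), c = cc,
                 residual_rms = sqrt(mean(rowSums(res^2))),
                 n = n,
                 specimen_id = corr$specimen_id, surface = corr$surface,
                 region = corr$region, reference_state = corr$reference_state,
                 center = colMeans(X)),
            class = "deformation_gradient")
}

fold_half_pi <- function(theta) {
  # fold an angle into (-pi/2, pi/2]
  theta <- theta %% pi
  if (theta > pi / 2) theta <- theta - pi
  theta
}

#' Principal strains and direction from a deformation gradient
#'
#' Polar decomposition \eqn{F = R U} with \eqn{U = \sqrt{F^T F}} symmetric
#' positive-definite removes the rigid rotation; the eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2} of \eqn{U} are the principal stretches and
#' the reported engineering strains are \eqn{\lambda - 1}. The direction of
#' maximal strain is the \eqn{\lambda_1} eigenvector, expressed in the
#' reference configuration relative to a declared longitudinal axis and
#' folded into \eqn{(-\pi/2, \pi/2]}.
#'
#' @param F A `deformation_gradient` from [fit_deformation], or a plain
#'   2x2 matrix with positive determinant.
#' @param axis_direction Angle (radians) of the longitudinal scale axis in
#'   the reference frame; `theta` is measured from this axis.
#' @return A `strain_cross`: list with `eps_max`, `eps_min`, `theta`
#'   (radians), `isotropic` flag, `center`, `residual_rms`, and metadata.
#' @export
principal_strains <- function(F, axis_direction = 0) {
  meta <- list(specimen_id = NA_character_, surface = NA_character_,
               region = NA_character_, center = c(NA_real_, NA_real_),
               residual_rms = NA_real_)
  if (inherits(F, "deformation_gradient")) {
    meta <- F[c("specimen_id", "surface", "region", "center", "residual_rms")]
    F <- F$F
  }
  stopifnot(is.matrix(F), all(dim(F) == c(2, 2)))
  if (!all(is.finite(F)) || det(F) <= 0) {
    stop_conebend("deformation gradient must be finite with det > 0",
                  "conebend_domain_error")
  }
  C <- crossprod(F)                 # F^T F, right Cauchy-Green
  e <- eigen(C, symmetric = TRUE)
  lambda <- sqrt(pmax(e$values, 0)) # principal stretches, decreasing
  eps_max <- lambda[1] - 1
  eps_min <- lambda[2] - 1
  iso_tol <- 1e-12 * max(1, lambda[1])
  isotropic <- (lambda[1] - lambda[2]) < iso_tol
  theta <- if (isotropic) 0 else {
    v <- e$vectors[, 1]
    fold_half_pi(atan2(v[2], v[1]) - axis_direction)
  }
  structure(c(list(eps_max = eps_max, eps_min = eps_min, theta = theta,
                   isotropic = isotropic), meta),
            class = "strain_cross")
}

#' Strain anisotropy of a surface
#'
#' Signed difference between transverse and longitudinal strain of one
#' surface, positive when transverse expansion dominates.
#'
#' @param longit,transv `segment_strain` results sharing a reference state.
#' @return Numeric anisotropy \eqn{\epsilon_{transv} - \epsilon_{longit}}.
#' @export
strain_anisotropy <- function(longit, transv) {
  stopifnot(inherits(longit, "segment_strain"), inherits(transv, "segment_strain"))
  if (longit$reference != transv$reference) {
    stop_conebend("strains use different reference states", "conebend_convention_error")
  }
  transv$epsilon - longit$epsilon
}

#' Regional strain profile along the lamina axis
#'
#' Summarises segment strains per lamina region, ordered
#' proximal -> middle -> distal, to expose a strain gradient along the
#' scale axis.
#'
#' @param results List of `list(region =, strain =)` pairs where `strain`
#'   is a `segment_strain`.
#' @return Data frame with columns `region, n, mean_epsilon, sd_epsilon`,
#'   rows ordered proximal, middle, distal (regions present only).
#' @export
regional_strain_profile <- function(results) {
  if (!length(results)) stop_conebend("no regional results", "conebend_domain_error")
  regions <- vapply(results, function(r) r$region, character(1))
  order_ref <- c("proximal", "middle", "distal")
  if (!all(regions %in% order_ref)) {
    stop_conebend(sprintf("unknown region label(s): %s",
                          paste(setdiff(regions, order_ref), collapse = ", ")),
                  "conebend_schema_error")
  }
  eps <- vapply(results, function(r) r$strain$epsilon, numeric(1))
  out <- do.call(rbind, lapply(intersect(order_ref, regions), function(reg) {
    v <- eps[regions == reg]
    data.frame(region = reg, n = length(v), mean_epsilon = mean(v),
               sd_epsilon = if (length(v) > 1) sd(v) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
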