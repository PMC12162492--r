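# Curvature of digitized profile traces: chord-frame alignment,
# least-squares polynomial fitting with rank selection, analytic
# curvature, and before/after comparison.

#' Align a profile trace to its chord
#'
#' Rigidly transforms a digitized trace so that the chord from its first to
#' its last point lies on the abscissa with the first point at the origin.
#' Profiles imaged at arbitrary orientation then yield identical fits. The
#' transform (rotation angle and translation) is recorded in the
#' `chord_frame` attribute.
#'
#' @param trace A [profile_trace] with at least 5 points.
#' @return The trace in the fit frame, with strictly increasing abscissae.
#'   A profile that folds back on its chord (e.g. an arc beyond a
#'   half-turn) raises a geometry error.
#' @export
align_to_chord <- function(trace) {
  stopifnot(inherits(trace, "profile_trace"))
  n <- nrow(trace)
  if (n < 5) stop_conebend("profile needs >= 5 points", "conebend_domain_error")
  p0 <- c(trace$x[1], trace$y[1])
  p1 <- c(trace$x[n], trace$y[n])
  if (identical(p0, p1)) stop_conebend("first and last points coincide", "conebend_geometry_error")
  ang <- atan2(p1[2] - p0[2], p1[1] - p0[1])
  co <- cos(-ang); si <- sin(-ang)
  dx <- trace$x - p0[1]; dy <- trace$y - p0[2]
  xs <- co * dx - si * dy
  ys <- si * dx + co * dy
  if (any(diff(xs) <= 0)) {
    stop_conebend("profile folds back along its chord; curvature by single-valued fit undefined",
                  "conebend_geometry_error")
  }
  out <- profile_trace(attr(trace, "specimen_id"), attr(trace, "orientation"),
                       attr(trace, "side"), attr(trace, "state"), xs, ys,
                       treatment = attr(trace, "treatment"))
  attr(out, "chord_frame") <- list(rotation = -ang, origin = p0)
  out
}

r2_stats <- function(y, fitted, p) {
  n <- length(y)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-300) {
    # degenerate ordinates (trace collinear with chord): any fit through
    # them is exact
    return(list(R2 = 1, adj = 1))
  }
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(R2 = r2, adj = adj)
}

#' Least-squares polynomial fit of a chord-aligned profile
#'
#' Fits each candidate rank by ordinary least squares and keeps the rank
#' with the larger adjusted coefficient of determination. Raw R-squared
#' cannot decrease as the rank grows (nested OLS models), so the adjusted
#' form is what makes rank selection meaningful; ties within 1e-9 fall
#' back to the lower rank.
#'
#' @param trace A chord-aligned [profile_trace] (see [align_to_chord]).
#' @param ranks Candidate polynomial degrees (default 2 and 3).
#' @return A `poly_fit`: list with `degree`, `coefficients` (ascending
#'   powers, mm units), `R2`, `adjusted_R2`, `x_range`, and the candidate
#'   table.
#' @export
fit_profile <- function(trace, ranks = c(2L, 3L)) {
  stopifnot(inherits(trace, "profile_trace"))
  ranks <- sort(unique(as.integer(ranks)))
  n <- nrow(trace)
  if (n < max(ranks) + 2) {
    stop_conebend(sprintf("need >= %d points for rank %d fit", max(ranks) + 2, max(ranks)),
                  "conebend_domain_error")
  }
  x <- trace$x; y <- trace$y
  cand <- lapply(ranks, function(d) {
    fit <- lm(y ~ poly(x, degree = d, raw = TRUE))
    cf <- unname(coef(fit))
    cf[is.na(cf)] <- 0
    st <- r2_stats(y, fitted(fit), d)
    list(degree = d, coefficients = cf, R2 = st$R2, adjusted_R2 = st$adj)
  })
  adj <- vapply(cand, `[[`, numeric(1), "adjusted_R2")
  best <- which(adj >= max(adj) - 1e-9)[1]  # tie -> lowest rank
  sel <- cand[[best]]
  structure(list(degree = sel$degree, coefficients = sel$coefficients,
                 R2 = sel$R2, adjusted_R2 = sel$adjusted_R2,
                 x_range = range(x),
                 candidates = data.frame(
                   degree = ranks, R2 = vapply(cand, `[[`, numeric(1), "R2"),
                   adjusted_R2 = adj)),
            class = "poly_fit")
}

poly_eval <- function(cf, x, deriv = 0) {
  k <- seq_along(cf) - 1
  if (deriv > 0) {
    for (i in seq_len(deriv)) {
      cf <- cf[-1] * seq_along(cf[-1])
      k <- seq_along(cf) - 1
    }
    if (!length(cf)) return(rep(0, length(x)))
  }
  drop(outer(x, k, `^`) %*% cf)
}

#' Signed curvature of a fitted profile polynomial
#'
#' \eqn{\kappa(x) = f''(x) / (1 + f'(x)^2)^{3/2}} for the fitted
#' polynomial \eqn{f}. The sign follows the fit frame (positive when the
#' profile is convex toward positive ordinates, i.e. convex toward the
#' abaxial side under the package's digitization convention); summaries
#' use absolute values.
#'
#' @param fit A `poly_fit`.
#' @param x Abscissae (mm) in the fit frame; values outside the fitted
#'   range are flagged with a warning.
#' @return Signed curvature values (1/mm).
#' @export
curvature_at <- function(fit, x) {
  stopifnot(inherits(fit, "poly_fit"))
  if (any(x < fit$x_range[1] - 1e-9 | x > fit$x_range[2] + 1e-9)) {
    warning("curvature evaluated outside the fitted abscissa range (extrapolation)")
  }
  d1 <- poly_eval(fit$coefficients, x, 1)
  d2 <- poly_eval(fit$coefficients, x, 2)
  d2 / (1 + d1^2)^(3 / 2)
}

#' Mean absolute curvature of a digitized profile
#'
#' The full per-trace pipeline: chord alignment, polynomial fitting with
#' rank selection, and curvature evaluated at the abscissa of every
#' digitized point. The summary statistic is the mean of absolute
#' curvature values over all points.
#'
#' @param trace A [profile_trace] (raw frame; aligned internally).
#' @param ranks Candidate polynomial degrees.
#' @return A `curvature_profile`: list with `kappa` (signed, per point),
#'   `mean_abs_kappa` (1/mm), `fit`, and trace metadata.
#' @export
mean_abs_curvature <- function(trace, ranks = c(2L, 3L)) {
  aligned <- align_to_chord(trace)
  fit <- fit_profile(aligned, ranks)
  kappa <- curvature_at(fit, aligned$x)
  structure(list(kappa = kappa, mean_abs_kappa = mean(abs(kappa)), fit = fit,
                 specimen_id = attr(trace, "specimen_id"),
                 orientation = attr(trace, "orientation"),
                 side = attr(trace, "side"), state = attr(trace, "state"),
                 treatment = attr(trace, "treatment")),
            class = "curvature_profile")
}

#' Compare curvature before and after a treatment
#'
#' Paired report of mean absolute curvature for the same specimen and
#' orientation (e.g. before/after surface milling), with a relative-change
#' classification.
#'
#' @param before,after `curvature_profile` objects for the same specimen
#'   and orientation.
#' @param rel_threshold Relative change below which the profile counts as
#'   `"unchanged"`.
#' @return List with `before`, `after`, `difference`, `ratio` and
#'   `classification` (`"increase"`, `"decrease"`, `"unchanged"`).
#' @export
compare_profiles <- function(before, after, rel_threshold = 0.05) {
  stopifnot(inherits(before, "curvature_profile"), inherits(after, "curvature_profile"))
  if (!identical(before$specimen_id, after$specimen_id) ||
      !identical(before$orientation, after$orientation)) {
    stop_conebend("profiles must share specimen and orientation", "conebend_pairing_error")
  }
  b <- before$mean_abs_kappa; a <- after$mean_abs_kappa
  diff <- a - b
  ratio <- if (b > 0) a / b else if (a == 0) 1 else Inf
  rel <- if (b > 0) abs(diff) / b else abs(diff)
  classification <- if (rel <= rel_threshold) "unchanged" else if (diff > 0) "increase" else "decrease"
  list(specimen_id = before$specimen_id, orientation = before$orientation,
       before = b, after = a, difference = diff, ratio = ratio,
       classification = classification)
}
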