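# Synthetic-specimen generators. Every downstream stage is exercised on
# inputs with known ground truth: affinely deformed landmark grids, noisy
# arc/polynomial profiles, laminate squares, two-cohort bundles, and
# wall-density transects. Noise is isotropic Gaussian on landmark
# coordinates and normal-direction Gaussian on profiles, the simplest
# model of digitization error.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Generate a deformed landmark correspondence
#'
#' Reference landmarks on an evenly spaced grid (default 2 x 4, the 8
#' landmarks applied per strip surface), observed landmarks
#' \eqn{x_i = F X_i + c + noise}. The imposed deformation is recorded in
#' the `truth` attribute; recovery tests read it from there only.
#'
#' @param F 2x2 deformation matrix (det > 0).
#' @param noise_sd Isotropic Gaussian coordinate noise sd (mm) on the
#'   observed configuration.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param grid_dims Grid rows x columns (product = landmark count, >= 3).
#' @param spacing Grid spacing (mm).
#' @param translation Translation part `c` (mm).
#' @param specimen_id,surface,region Metadata for the generated sets.
#' @return A [landmark_correspondence] (dry reference) with attribute
#'   `truth = list(F, c, noise_sd)`.
#' @export
gen_landmark_pair <- function(F = diag(2), noise_sd = 0, seed = NULL,
                              grid_dims = c(2L, 4L), spacing = 1,
                              translation = c(0, 0),
                              specimen_id = "synthetic", surface = "abaxial",
                              region = "unspecified") {
  stopifnot(is.matrix(F), all(dim(F) == c(2, 2)))
  if (det(F) <= 0) stop_conebend("deformation matrix must have det > 0", "conebend_domain_error")
  if (noise_sd < 0) stop_conebend("noise_sd must be >= 0", "conebend_domain_error")
  n <- prod(grid_dims)
  if (n < 3) stop_conebend("grid must contain >= 3 landmarks", "conebend_domain_error")
  g <- expand.grid(x = (seq_len(grid_dims[2]) - 1) * spacing,
                   y = (seq_len(grid_dims[1]) - 1) * spacing)
  X <- as.matrix(g)
  x_obs <- t(F %*% t(X)) + matrix(translation, n, 2, byrow = TRUE)
  if (noise_sd > 0) {
    x_obs <- x_obs + with_seed(seed, matrix(rnorm(2 * n, sd = noise_sd), n, 2))
  }
  ids <- sprintf("L%02d", seq_len(n))
  ref <- landmark_set(specimen_id, surface, "dry", ids, X[, 1], X[, 2], region = region)
  obs <- landmark_set(specimen_id, surface, "wet", ids, x_obs[, 1], x_obs[, 2], region = region)
  corr <- landmark_correspondence(ref, obs)
  attr(corr, "truth") <- list(F = F, c = translation, noise_sd = noise_sd)
  corr
}

#' Generate a synthetic profile trace
#'
#' Samples points uniformly along a line, circular arc or polynomial and
#' perturbs them along the local normal direction. Ground-truth curvature
#' is stored in the `truth` attribute.
#'
#' @param shape `"line"`, `"arc"` or `"polynomial"`.
#' @param params For `"line"`: `list(length =)`. For `"arc"`:
#'   `list(radius =, span_deg =)` with span at most 150 degrees. For
#'   `"polynomial"`: `list(coefficients =, x_range =)` (ascending powers).
#' @param n_points Number of digitized points (>= 5).
#' @param noise_sd Normal-direction Gaussian noise sd (mm).
#' @param seed Integer seed.
#' @param specimen_id,orientation,side,state,treatment Trace metadata.
#' @return A [profile_trace] with a `truth` attribute (`kappa` for
#'   line/arc, `coefficients` for polynomial).
#' @export
gen_profile <- function(shape = c("line", "arc", "polynomial"), params,
                        n_points = 20L, noise_sd = 0, seed = NULL,
                        specimen_id = "synthetic", orientation = "LONGIT",
                        side = "abaxial", state = "dry", treatment = "intact") {
  shape <- match.arg(shape)
  if (n_points < 5) stop_conebend("need >= 5 points", "conebend_domain_error")
  if (noise_sd < 0) stop_conebend("noise_sd must be >= 0", "conebend_domain_error")
  if (shape == "line") {
    x <- seq(0, params$length, length.out = n_points)
    y <- rep(0, n_points)
    nx <- rep(0, n_points); ny <- rep(1, n_points)
    truth <- list(kappa = 0)
  } else if (shape == "arc") {
    R <- params$radius
    span <- params$span_deg * pi / 180
    if (span > 150 * pi / 180) stop_conebend("arc span exceeds 150 degrees", "conebend_domain_error")
    th <- seq(-span / 2, span / 2, length.out = n_points)
    x <- R * sin(th)
    y <- R * (1 - cos(th))   # convex toward positive y
    nx <- -sin(th); ny <- cos(th)
    truth <- list(kappa = 1 / R)
  } else {
    cf <- params$coefficients
    xr <- params$x_range
    x <- seq(xr[1], xr[2], length.out = n_points)
    y <- poly_eval(cf, x)
    d1 <- poly_eval(cf, x, 1)
    nn <- sqrt(1 + d1^2)
    nx <- -d1 / nn; ny <- 1 / nn
    truth <- list(coefficients = cf)
  }
  if (noise_sd > 0) {
    e <- with_seed(seed, rnorm(n_points, sd = noise_sd))
    x <- x + e * nx
    y <- y + e * ny
  }
  tr <- profile_trace(specimen_id, orientation, side, state, x, y, treatment)
  attr(tr, "truth") <- truth
  tr
}

#' Generate wet and dry profile traces of a laminate square
#'
#' The wet trace is a straight segment of length `L` (the model's flat wet
#' state); the dry trace is a circular arc of radius `r` spanning the
#' fraction `p` of a full circle — the abaxial surface geometry the arc
#' model predicts.
#'
#' @param arc A `laminate_arc` from [forward_bend].
#' @param n_points Points per trace.
#' @param noise_sd Normal-direction noise sd (mm).
#' @param seed Integer seed.
#' @param specimen_id Metadata.
#' @return List `(wet, dry)` of [profile_trace] objects; each carries the
#'   arc as its `truth` attribute.
#' @export
gen_laminate_specimen <- function(arc, n_points = 20L, noise_sd = 0,
                                  seed = NULL, specimen_id = "synthetic") {
  stopifnot(inherits(arc, "laminate_arc"))
  wet <- gen_profile("line", list(length = arc$L), n_points, noise_sd,
                     seed = if (is.null(seed)) NULL else seed,
                     specimen_id = specimen_id, state = "wet")
  dry <- if (arc$p == 0) {
    gen_profile("line", list(length = arc$L), n_points, noise_sd,
                seed = if (is.null(seed)) NULL else seed + 1L,
                specimen_id = specimen_id, state = "dry")
  } else {
    gen_profile("arc", list(radius = arc$r, span_deg = 360 * arc$p),
                n_points, noise_sd,
                seed = if (is.null(seed)) NULL else seed + 1L,
                specimen_id = specimen_id, state = "dry")
  }
  attr(wet, "truth") <- arc
  attr(dry, "truth") <- arc
  list(wet = wet, dry = dry)
}

#' Cohort specification for the two-cohort simulation
#'
#' Defines the study conditions of one bending cohort: specimen count,
#' shared dry-to-wet surface strains (longitudinal and transverse, both
#' surfaces), and the distributions of dry thickness and VB-position
#' asymmetry. Defaults describe the two phenotypes contrasted in the
#' study system: weakly bending scales are about twice as thick
#' (1.2 vs 0.6 mm) with a more symmetric VB plate (asymmetry 0.45 vs
#' 0.25), while surface strains are shared by both cohorts.
#'
#' @param label Cohort label.
#' @param n_specimens Specimens per cohort.
#' @param eps_ad_longit,eps_ad_transv Adaxial surface strains, dry->wet
#'   reference (longitudinal shrinkage, transverse expansion).
#' @param eps_ab_longit,eps_ab_transv Abaxial surface strains, dry->wet.
#' @param t_dry_mean,t_dry_sd Dry thickness distribution (mm).
#' @param asym_mean,asym_sd VB asymmetry distribution (dimensionless).
#' @param L Wet square length in the longitudinal direction (mm).
#' @param landmark_noise_sd,profile_noise_sd Digitization noise (mm).
#' @param seed Integer seed for this cohort's draws.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(label, n_specimens = 6L,
                        eps_ad_longit = -0.03, eps_ad_transv = 0.06,
                        eps_ab_longit = 0.05, eps_ab_transv = 0.08,
                        t_dry_mean = 0.9, t_dry_sd = 0.09,
                        asym_mean = 0.35, asym_sd = 0.04,
                        L = 5,
                        landmark_noise_sd = 0.01, profile_noise_sd = 0.01,
                        seed = 1L) {
  if (n_specimens < 1) stop_conebend("n_specimens must be >= 1", "conebend_domain_error")
  if (t_dry_sd < 0 || asym_sd < 0 || landmark_noise_sd < 0 || profile_noise_sd < 0) {
    stop_conebend("standard deviations must be >= 0", "conebend_domain_error")
  }
  eps <- c(eps_ad_longit, eps_ad_transv, eps_ab_longit, eps_ab_transv)
  if (any(eps <= -1)) stop_conebend("strains must exceed -1", "conebend_domain_error")
  if (!(asym_mean > 0 && asym_mean < 1)) stop_conebend("asymmetry mean must lie in (0,1)", "conebend_domain_error")
  structure(list(label = label, n_specimens = as.integer(n_specimens),
                 eps_ad_longit = eps_ad_longit, eps_ad_transv = eps_ad_transv,
                 eps_ab_longit = eps_ab_longit, eps_ab_transv = eps_ab_transv,
                 t_dry_mean = t_dry_mean, t_dry_sd = t_dry_sd,
                 asym_mean = asym_mean, asym_sd = asym_sd, L = L,
                 landmark_noise_sd = landmark_noise_sd,
                 profile_noise_sd = profile_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default weak- and strong-bending cohort specifications
#'
#' @param seed Base seed; the two cohorts use `seed` and `seed + 1`.
#' @param ... Overrides passed to [cohort_spec] (applied to both).
#' @return List `(weak, strong)` of `cohort_spec` objects.
#' @export
default_cohorts <- function(seed = 1L, ...) {
  list(
    weak = cohort_spec("weak", t_dry_mean = 1.2, t_dry_sd = 0.12,
                       asym_mean = 0.45, asym_sd = 0.04, seed = seed, ...),
    strong = cohort_spec("strong", t_dry_mean = 0.6, t_dry_sd = 0.06,
                         asym_mean = 0.25, asym_sd = 0.04, seed = seed + 1L, ...)
  )
}

rnorm_bounded <- function(n, mean, sd, lower, upper) {
  # resample out-of-range draws; degenerate sd returns the mean
  if (sd == 0) return(rep(mean, n))
  v <- rnorm(n, mean, sd)
  bad <- which(v <= lower | v >= upper)
  tries <- 0
  while (length(bad) && tries < 100) {
    v[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(v <= lower | v >= upper)
    tries <- tries + 1
  }
  if (length(bad)) v[bad] <- mean
  v
}

gen_cohort_tables <- function(spec, what) {
  set.seed(spec$seed)
  n <- spec$n_specimens
  ids <- sprintf("%s_%02d", spec$label, seq_len(n))
  t_dry <- rnorm_bounded(n, spec$t_dry_mean, spec$t_dry_sd, 0.05, Inf)
  A <- rnorm_bounded(n, spec$asym_mean, spec$asym_sd, 0.02, 0.98)

  landmarks <- profiles <- plates <- NULL

  if ("plates" %in% what) {
    plates <- data.frame(specimen_id = ids, cohort = spec$label,
                         d_ad = A * t_dry, d_ab = (1 - A) * t_dry,
                         t_total = t_dry)
  }

  if ("landmarks" %in% what) {
    landmarks <- do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(c("adaxial", "abaxial"), function(surf) {
        Fm <- if (surf == "adaxial") {
          diag(c(1 + spec$eps_ad_longit, 1 + spec$eps_ad_transv))
        } else {
          diag(c(1 + spec$eps_ab_longit, 1 + spec$eps_ab_transv))
        }
        corr <- gen_landmark_pair(Fm, noise_sd = spec$landmark_noise_sd,
                                  seed = NULL, specimen_id = ids[i],
                                  surface = surf)
        rbind(
          data.frame(specimen_id = ids[i], surface = surf, state = "dry",
                     region = "unspecified", landmark_id = corr$landmark_id,
                     x = corr$X[, 1], y = corr$X[, 2]),
          data.frame(specimen_id = ids[i], surface = surf, state = "wet",
                     region = "unspecified", landmark_id = corr$landmark_id,
                     x = corr$x[, 1], y = corr$x[, 2])
        )
      }))
    }))
  }

  if ("profiles" %in% what) {
    eps_ad_wd <- flip_strain_reference(spec$eps_ad_longit)
    eps_ab_wd <- flip_strain_reference(spec$eps_ab_longit)
    profiles <- do.call(rbind, lapply(seq_len(n), function(i) {
      arc <- forward_bend(eps_ad_wd, eps_ab_wd, t_dry[i], spec$L)
      pr <- gen_laminate_specimen(arc, n_points = 20L,
                                  noise_sd = spec$profile_noise_sd,
                                  seed = NULL, specimen_id = ids[i])
      do.call(rbind, lapply(c("wet", "dry"), function(st) {
        tr <- pr[[st]]
        data.frame(specimen_id = ids[i], orientation = "LONGIT",
                   side = "abaxial", state = st, treatment = "intact",
                   point_index = seq_len(nrow(tr)), x = tr$x, y = tr$y)
      }))
    }))
  }

  eps_ad_wd <- flip_strain_reference(spec$eps_ad_longit)
  eps_ab_wd <- flip_strain_reference(spec$eps_ab_longit)
  truth <- data.frame(specimen_id = ids, cohort = spec$label,
                      t_dry = t_dry, asymmetry = A, L = spec$L,
                      eps_ad_longit_dw = spec$eps_ad_longit,
                      eps_ab_longit_dw = spec$eps_ab_longit,
                      eps_ad_transv_dw = spec$eps_ad_transv,
                      eps_ab_transv_dw = spec$eps_ab_transv,
                      rho = (1 + eps_ad_wd) / (1 + eps_ab_wd),
                      kappa_true = (eps_ad_wd - eps_ab_wd) / ((1 + eps_ab_wd) * t_dry))
  list(landmarks = landmarks, profiles = profiles, plates = plates,
       truth = truth)
}

#' Generate a two-cohort input bundle
#'
#' Draws per-specimen dry thickness and VB asymmetry from each cohort's
#' distribution, shares the surface-strain conditions across cohorts, and
#' emits landmark, profile and plate-geometry tables in the package's CSV
#' schemas together with a ground-truth manifest.
#'
#' @param weak,strong [cohort_spec] objects (see [default_cohorts]).
#' @param what Which tables to generate (subset of `"landmarks"`,
#'   `"profiles"`, `"plates"`); trimming the set speeds up replicated
#'   simulations that use only one table.
#' @param dir Optional directory: when given, the tables are written as
#'   `landmarks.csv`, `profiles.csv`, `plates.csv`, `truth.csv`.
#' @return List with combined data frames `landmarks`, `profiles`,
#'   `plates` and the ground-truth manifest `truth`.
#' @export
gen_cohorts <- function(weak, strong,
                        what = c("landmarks", "profiles", "plates"),
                        dir = NULL) {
  stopifnot(inherits(weak, "cohort_spec"), inherits(strong, "cohort_spec"))
  what <- match.arg(what, several.ok = TRUE)
  a <- gen_cohort_tables(weak, what)
  b <- gen_cohort_tables(strong, what)
  bundle <- list(landmarks = rbind(a$landmarks, b$landmarks),
                 profiles = rbind(a$profiles, b$profiles),
                 plates = rbind(a$plates, b$plates),
                 truth = rbind(a$truth, b$truth))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(bundle)) {
      if (!is.null(bundle[[nm]])) {
        write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                  row.names = FALSE, quote = FALSE)
      }
    }
  }
  bundle
}

#' Generate a cell-wall density transect
#'
#' Linear density trend from the adaxial to the abaxial VB margin plus
#' Gaussian noise, expressed as per-cell (wall thickness, outer radius,
#' distance) triples: outer radii are fixed and wall thickness carries the
#' density signal.
#'
#' @param n_cells Cells along the transect.
#' @param density_at_adaxial,density_at_abaxial Endpoint densities in
#'   (0, 1]; the adaxial endpoint is at least the abaxial one under the
#'   gradient observed in this tissue.
#' @param noise_sd Gaussian noise on density (clipped to (0, 1]).
#' @param seed Integer seed.
#' @param outer_radius Cell outer radius (mm).
#' @param transect_length Raw transect length (mm); margins at 0 and this
#'   value.
#' @return Data frame `wall_thickness, outer_radius, raw_distance` with
#'   attributes `adaxial_margin`, `abaxial_margin` and a `truth` attribute.
#' @export
gen_wall_density_transect <- function(n_cells = 20L,
                                      density_at_adaxial = 0.6,
                                      density_at_abaxial = 0.2,
                                      noise_sd = 0, seed = NULL,
                                      outer_radius = 0.01,
                                      transect_length = 0.5) {
  d <- c(density_at_adaxial, density_at_abaxial)
  if (any(d <= 0 | d > 1)) stop_conebend("endpoint densities must lie in (0,1]", "conebend_domain_error")
  if (density_at_adaxial < density_at_abaxial) {
    stop_conebend("adaxial density must be >= abaxial (observed gradient)", "conebend_domain_error")
  }
  u <- seq(0, 1, length.out = n_cells)
  dens <- density_at_adaxial + u * (density_at_abaxial - density_at_adaxial)
  if (noise_sd > 0) {
    dens <- dens + with_seed(seed, rnorm(n_cells, sd = noise_sd))
    dens <- pmin(pmax(dens, 1e-6), 1)
  }
  out <- data.frame(wall_thickness = dens * outer_radius,
                    outer_radius = outer_radius,
                    raw_distance = u * transect_length)
  attr(out, "adaxial_margin") <- 0
  attr(out, "abaxial_margin") <- transect_length
  attr(out, "truth") <- list(density_at_adaxial = density_at_adaxial,
                             density_at_abaxial = density_at_abaxial,
                             noise_sd = noise_sd)
  out
}
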