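# End-to-end orchestration: strain -> curvature -> morphometry ->
# laminate prediction -> group comparisons, on synthetic or user data,
# with a reproducible run manifest.

stretch_tensor <- function(F) {
  # right stretch U = sqrt(F^T F)
  e <- eigen(crossprod(F), symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

infer_cohort <- function(specimen_id) sub("_[^_]*$", "", specimen_id)

strain_stage <- function(landmark_sets) {
  key <- vapply(landmark_sets, function(s)
    paste(attr(s, "specimen_id"), attr(s, "surface"), sep = "|"), character(1))
  out <- lapply(split(landmark_sets, key), function(pair) {
    states <- vapply(pair, attr, character(1), "state")
    if (!setequal(states, c("dry", "wet"))) return(NULL)
    corr <- landmark_correspondence(pair[[which(states == "dry")]],
                                    pair[[which(states == "wet")]])
    dg <- fit_deformation(corr)
    cross <- principal_strains(dg)
    U <- stretch_tensor(dg$F)
    data.frame(specimen_id = dg$specimen_id, surface = dg$surface,
               eps_max = cross$eps_max, eps_min = cross$eps_min,
               theta = cross$theta,
               eps_longit = U[1, 1] - 1, eps_transv = U[2, 2] - 1,
               residual_rms = dg$residual_rms)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

curvature_stage <- function(traces, ranks = c(2L, 3L)) {
  out <- do.call(rbind, lapply(traces, function(tr) {
    cp <- mean_abs_curvature(tr, ranks)
    data.frame(specimen_id = cp$specimen_id, orientation = cp$orientation,
               side = cp$side, state = cp$state, treatment = cp$treatment,
               degree = cp$fit$degree, R2 = cp$fit$R2,
               mean_abs_kappa = cp$mean_abs_kappa)
  }))
  rownames(out) <- NULL
  out
}

chord_length <- function(trace) {
  n <- nrow(trace)
  sqrt((trace$x[n] - trace$x[1])^2 + (trace$y[n] - trace$y[1])^2)
}

#' Run the full analysis pipeline on an input directory
#'
#' Reads the landmark, profile and plate-geometry tables written by
#' [gen_cohorts] (or digitized from real specimens in the same schemas)
#' and executes every stage: per-surface principal strains, dry-profile
#' curvature, VB asymmetry, laminate-model curvature prediction (measured
#' surface strains + measured thickness -> predicted dry curvature,
#' compared with the curvature measured on the dry profile), and weak
#' versus strong cohort comparisons by Student t-test.
#'
#' @param config An [analysis_config].
#' @param input_dir Directory containing `landmarks.csv`, `profiles.csv`,
#'   `plates.csv` (any subset).
#' @param out_dir Optional directory for result CSVs (with manifest
#'   sidecars).
#' @return List of data frames `strains`, `curvature`, `morphometry`,
#'   `laminate`, `comparisons`, plus `manifest`. Empty inputs yield empty
#'   tables with a warning.
#' @export
run_full_analysis <- function(config = analysis_config(), input_dir,
                              out_dir = NULL) {
  stopifnot(is.character(input_dir), length(input_dir) == 1)
  paths <- list(landmarks = file.path(input_dir, "landmarks.csv"),
                profiles = file.path(input_dir, "profiles.csv"),
                plates = file.path(input_dir, "plates.csv"))
  have <- vapply(paths, file.exists, logical(1))
  if (!any(have)) {
    warning("no input tables found; returning empty report")
    return(list(strains = NULL, curvature = NULL, morphometry = NULL,
                laminate = NULL, comparisons = NULL,
                manifest = list(input_dir = input_dir, inputs = character(0))))
  }

  strains <- curvature <- morpho <- laminate <- comparisons <- NULL

  if (have[["landmarks"]]) {
    sets <- read_landmark_table(paths$landmarks, config)
    if (length(sets)) strains <- strain_stage(sets)
  }
  if (have[["profiles"]]) {
    traces <- read_profile_table(paths$profiles, config)
    if (length(traces)) curvature <- curvature_stage(traces, config$poly_ranks)
  }
  if (have[["plates"]]) {
    pl <- read.csv(paths$plates, stringsAsFactors = FALSE)
    if (nrow(pl)) {
      if (is.null(pl$cohort)) pl$cohort <- infer_cohort(pl$specimen_id)
      morpho <- data.frame(specimen_id = pl$specimen_id, cohort = pl$cohort,
                           t_dry = pl$t_total,
                           asymmetry = vapply(seq_len(nrow(pl)), function(i)
                             asymmetry_index(plate_geometry(pl$d_ad[i], pl$d_ab[i],
                                                            pl$t_total[i])),
                             numeric(1)))
    }
  }

  # laminate prediction: measured surface strains (wet->dry) + measured
  # thickness -> predicted dry curvature, against measured dry curvature
  if (!is.null(strains) && !is.null(morpho)) {
    wide <- merge(
      setNames(strains[strains$surface == "adaxial", c("specimen_id", "eps_longit")],
               c("specimen_id", "eps_ad_dw")),
      setNames(strains[strains$surface == "abaxial", c("specimen_id", "eps_longit")],
               c("specimen_id", "eps_ab_dw")))
    wide <- merge(wide, morpho[, c("specimen_id", "cohort", "t_dry", "asymmetry")])
    wide$eps_ad_wd <- flip_strain_reference(wide$eps_ad_dw)
    wide$eps_ab_wd <- flip_strain_reference(wide$eps_ab_dw)
    wide$rho <- (1 + wide$eps_ad_wd) / (1 + wide$eps_ab_wd)
    wide$kappa_pred <- (wide$eps_ad_wd - wide$eps_ab_wd) /
      ((1 + wide$eps_ab_wd) * wide$t_dry)
    if (!is.null(curvature)) {
      meas <- curvature[curvature$state == "dry" & curvature$orientation == "LONGIT",
                        c("specimen_id", "mean_abs_kappa")]
      names(meas)[2] <- "kappa_measured"
      wide <- merge(wide, meas, all.x = TRUE)
    }
    laminate <- wide
  }

  # cohort comparisons
  if (!is.null(laminate) && length(unique(laminate$cohort)) == 2) {
    cohorts <- sort(unique(laminate$cohort))
    grp <- function(v) split(v, laminate$cohort)
    vars <- c("t_dry", "asymmetry", "kappa_pred",
              if ("kappa_measured" %in% names(laminate)) "kappa_measured",
              "eps_ad_dw", "eps_ab_dw")
    comparisons <- do.call(rbind, lapply(vars, function(v) {
      g <- grp(laminate[[v]])
      if (any(vapply(g, function(x) sum(is.finite(x)), 0L) < 2)) return(NULL)
      r <- students_t(g[[1]], g[[2]],
                      p_moderate = config$p_moderate, p_strong = config$p_strong)
      data.frame(variable = v, group_a = cohorts[1], group_b = cohorts[2],
                 mean_a = r$mean_a, mean_b = r$mean_b,
                 t = r$t_statistic, df = r$degrees_of_freedom,
                 p_value = r$p_value, class = r$significance_class)
    }))
    if (!is.null(comparisons)) rownames(comparisons) <- NULL
  }

  report <- list(strains = strains, curvature = curvature,
                 morphometry = morpho, laminate = laminate,
                 comparisons = comparisons,
                 manifest = list(input_dir = input_dir,
                                 inputs = names(paths)[have],
                                 seed = config$seed,
                                 config = unclass(config)))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in c("strains", "curvature", "morphometry", "laminate", "comparisons")) {
      if (!is.null(report[[nm]])) {
        write_results(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                      config = config)
      }
    }
  }
  report
}

#' Geometric milling experiment
#'
#' Models adaxial-surface milling purely geometrically: the adaxial plate
#' thickness is reduced by `thinning_fraction`, which thins the whole
#' lamina and shifts the VB plate toward the adaxial surface. At a fixed
#' surface-strain ratio the arc model then predicts stronger bending,
#' \eqn{\kappa' / \kappa = t / t'}.
#'
#' @param geometry A [plate_geometry] for the intact lamina.
#' @param rho Surface-strain ratio (>= 1), unchanged by milling.
#' @param thinning_fraction Fraction of the adaxial plate removed, in
#'   `[0, 1)`.
#' @return List with before/after thickness, asymmetry, predicted kappa,
#'   `kappa_ratio` and a `classification` matching [compare_profiles]
#'   semantics.
#' @export
milling_experiment <- function(geometry, rho, thinning_fraction,
                               rel_threshold = 0.05) {
  stopifnot(inherits(geometry, "plate_geometry"))
  if (thinning_fraction < 0 || thinning_fraction >= 1) {
    stop_conebend("thinning_fraction must lie in [0, 1)", "conebend_domain_error")
  }
  d_ad2 <- geometry$d_ad * (1 - thinning_fraction)
  if (d_ad2 <= 0) stop_conebend("milling removes the whole adaxial plate", "conebend_domain_error")
  t1 <- geometry$t_total
  t2 <- t1 - geometry$d_ad * thinning_fraction
  g2 <- plate_geometry(d_ad2, geometry$d_ab, t2)
  k1 <- (rho - 1) / t1
  k2 <- (rho - 1) / t2
  rel <- if (k1 > 0) abs(k2 - k1) / k1 else abs(k2 - k1)
  list(t_before = t1, t_after = t2,
       asymmetry_before = asymmetry_index(geometry),
       asymmetry_after = asymmetry_index(g2),
       kappa_before = k1, kappa_after = k2,
       kappa_ratio = if (k1 > 0) k2 / k1 else 1,
       classification = if (rel <= rel_threshold) "unchanged"
                        else if (k2 > k1) "increase" else "decrease")
}
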