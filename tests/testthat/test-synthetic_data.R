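test_that("landmark generator is deterministic and records ground truth", {
  F <- diag(c(1.08, 1.02))
  a <- gen_landmark_pair(F, noise_sd = 0.01, seed = 5)
  b <- gen_landmark_pair(F, noise_sd = 0.01, seed = 5)
  expect_identical(a$x, b$x)
  expect_equal(attr(a, "truth")$F, F)

  # noise-free observed equals the deformed grid exactly
  clean <- gen_landmark_pair(F, noise_sd = 0)
  expect_equal(clean$x, t(F %*% t(clean$X)), tolerance = 1e-14,
               ignore_attr = TRUE)
  ps <- principal_strains(fit_deformation(clean))
  expect_equal(ps$eps_max, 0.08, tolerance = 1e-12)
  expect_equal(ps$eps_min, 0.02, tolerance = 1e-12)

  expect_error(gen_landmark_pair(diag(c(1, -1))), class = "conebend_domain_error")
})

test_that("profile generator encodes curvature ground truth", {
  line <- gen_profile("line", list(length = 10), 20)
  expect_lt(mean_abs_curvature(line)$mean_abs_kappa, 1e-10)
  expect_equal(attr(line, "truth")$kappa, 0)

  arc <- gen_profile("arc", list(radius = 10, span_deg = 30), 20)
  expect_equal(attr(arc, "truth")$kappa, 0.1)
  # all points lie exactly on the circle
  d <- sqrt(arc$x^2 + (arc$y - 10)^2)
  expect_equal(d, rep(10, 20), tolerance = 1e-12)

  pol <- gen_profile("polynomial", list(coefficients = c(0, -0.2, 0, 0.05),
                                        x_range = c(-2, 2)), 20)
  refit <- fit_profile(align_to_chord(pol))
  # refit in the chord frame reproduces the shape: curvature at the
  # original abscissae matches the generating polynomial
  d1 <- conebend:::poly_eval(c(0, -0.2, 0, 0.05), pol$x, 1)
  d2 <- conebend:::poly_eval(c(0, -0.2, 0, 0.05), pol$x, 2)
  kappa_true <- mean(abs(d2 / (1 + d1^2)^1.5))
  expect_equal(mean_abs_curvature(pol)$mean_abs_kappa, kappa_true,
               tolerance = 1e-9)

  expect_error(gen_profile("arc", list(radius = 5, span_deg = 170), 20),
               class = "conebend_domain_error")
})

test_that("laminate specimen generator matches the arc model geometry", {
  arc <- forward_bend(-0.02, -0.10, 0.6, 10)
  pair <- gen_laminate_specimen(arc, n_points = 25)
  # wet trace: straight, length L
  expect_lt(mean_abs_curvature(pair$wet)$mean_abs_kappa, 1e-10)
  expect_equal(conebend:::chord_length(pair$wet), arc$L)
  # dry trace: arc of radius r; its arc length is the contracted abaxial
  # surface length (1 + eps_ab) L
  seg <- sqrt(diff(pair$dry$x)^2 + diff(pair$dry$y)^2)
  arclen_polyline <- sum(seg)
  expect_equal(arclen_polyline, (1 + arc$eps_ab) * arc$L, tolerance = 1e-3)

  flat <- forward_bend(-0.05, -0.05, 0.6, 10)
  fpair <- gen_laminate_specimen(flat, n_points = 10)
  expect_lt(mean_abs_curvature(fpair$dry)$mean_abs_kappa, 1e-10)

  p1 <- gen_laminate_specimen(arc, 20, noise_sd = 0.01, seed = 3)
  p2 <- gen_laminate_specimen(arc, 20, noise_sd = 0.01, seed = 3)
  expect_identical(p1$dry$y, p2$dry$y)
})

test_that("cohort bundles share strains but differ in thickness and asymmetry", {
  ch <- default_cohorts(seed = 17)
  bundle <- gen_cohorts(ch$weak, ch$strong)
  expect_equal(nrow(bundle$truth), 12)
  expect_setequal(unique(bundle$truth$cohort), c("weak", "strong"))
  # identical strain conditions across cohorts
  expect_equal(unique(bundle$truth$eps_ab_longit_dw), 0.05)
  expect_length(unique(bundle$truth$rho), 1)
  # generated thickness and asymmetry separate the cohorts
  w <- bundle$truth[bundle$truth$cohort == "weak", ]
  s <- bundle$truth[bundle$truth$cohort == "strong", ]
  expect_gt(min(w$t_dry), max(s$t_dry))
  expect_gt(mean(w$asymmetry), mean(s$asymmetry))

  # determinism: same specs, same bundle
  again <- gen_cohorts(ch$weak, ch$strong)
  expect_identical(bundle$landmarks, again$landmarks)
  expect_identical(bundle$profiles, again$profiles)

  # written tables re-read into the same grouped objects
  d <- tempfile()
  gen_cohorts(ch$weak, ch$strong, dir = d)
  sets <- suppressMessages(read_landmark_table(file.path(d, "landmarks.csv")))
  expect_length(sets, 12 * 2 * 2)  # specimen x surface x state
  traces <- suppressMessages(read_profile_table(file.path(d, "profiles.csv")))
  expect_length(traces, 12 * 2)
})

test_that("cohort draws converge to the specified distributions", {
  # law-of-large-numbers check on the generator's thickness draws
  spec <- cohort_spec("w", n_specimens = 200, t_dry_mean = 1.2,
                      t_dry_sd = 0.12, asym_mean = 0.45, asym_sd = 0.04,
                      seed = 23)
  tab <- conebend:::gen_cohort_tables(spec, what = "plates")
  expect_equal(mean(tab$truth$t_dry), 1.2,
               tolerance = 3 * 0.12 / sqrt(200) / 1.2)
  expect_equal(mean(tab$truth$asymmetry), 0.45,
               tolerance = 3 * 0.04 / sqrt(200) / 0.45)
})

test_that("wall-density transect generator is reproducible with known trend", {
  flat <- gen_wall_density_transect(15, 0.4, 0.4)
  expect_equal(sd(flat$wall_thickness / flat$outer_radius), 0)

  dec <- gen_wall_density_transect(20, 0.6, 0.2)
  res <- wall_density_profile(dec$wall_thickness, dec$outer_radius,
                              dec$raw_distance, 0, 0.5)
  expect_equal(res$trend_rho, -1)

  n1 <- gen_wall_density_transect(20, 0.6, 0.2, noise_sd = 0.05, seed = 8)
  n2 <- gen_wall_density_transect(20, 0.6, 0.2, noise_sd = 0.05, seed = 8)
  expect_identical(n1$wall_thickness, n2$wall_thickness)

  expect_error(gen_wall_density_transect(10, 0.2, 0.6),
               class = "conebend_domain_error")
})
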