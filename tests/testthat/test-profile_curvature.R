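test_that("chord alignment restores arbitrary orientation and detects fold-back", {
  tr <- gen_profile("polynomial", list(coefficients = c(0, 0, 0.05),
                                       x_range = c(0, 5)), 12)
  aligned <- align_to_chord(tr)
  expect_equal(aligned$x[1], 0)
  expect_equal(aligned$y[1], 0)
  expect_equal(aligned$y[nrow(aligned)], 0, tolerance = 1e-12)
  expect_true(all(diff(aligned$x) > 0))

  rot <- transform_trace(tr, theta = pi / 2, shift = c(3, -1))
  realigned <- align_to_chord(rot)
  expect_equal(realigned$x, aligned$x, tolerance = 1e-10)
  expect_equal(realigned$y, aligned$y, tolerance = 1e-10)

  # an arc beyond a half-turn folds back on its chord
  th <- seq(0, 1.2 * pi, length.out = 20)
  fold <- profile_trace("s", "LONGIT", "abaxial", "dry",
                        cos(th), sin(th))
  expect_error(align_to_chord(fold), class = "conebend_geometry_error")
})

test_that("polynomial fitting selects rank by adjusted R2", {
  x <- seq(-2, 3, length.out = 12)
  exact <- profile_trace("s", "LONGIT", "abaxial", "dry", x, x^2)
  fit <- fit_profile(exact)
  expect_equal(fit$degree, 2L)
  expect_equal(fit$coefficients, c(0, 0, 1), tolerance = 1e-10)
  expect_equal(fit$R2, 1)

  flat <- profile_trace("s", "LONGIT", "abaxial", "dry", x, rep(0, 12))
  fit0 <- fit_profile(flat)
  expect_lt(abs(fit0$coefficients[3]), 1e-10)

  # noisy cubic: rank 3 wins on adjusted R2 and matches the
  # normal-equations oracle at both candidate ranks
  tr3 <- gen_profile("polynomial", list(coefficients = c(0, -0.2, 0, 0.05),
                                        x_range = c(-2, 2)),
                     20, noise_sd = 0.01, seed = 7)
  al <- align_to_chord(tr3)
  fit3 <- fit_profile(al)
  o2 <- oracle_poly_fit(al$x, al$y, 2)
  o3 <- oracle_poly_fit(al$x, al$y, 3)
  expect_gt(o3$adjusted_R2, o2$adjusted_R2)
  expect_equal(fit3$degree, 3L)
  expect_equal(fit3$coefficients, o3$coefficients, tolerance = 1e-8)
  # OLS nesting: raw R2 of the cubic can never fall below the quadratic
  expect_gte(fit3$candidates$R2[2], fit3$candidates$R2[1])

  expect_error(fit_profile(exact[1:4, ]), class = "conebend_domain_error")
})

test_that("curvature formula matches closed forms", {
  x <- seq(-2, 2, length.out = 12)
  fit <- fit_profile(profile_trace("s", "LONGIT", "abaxial", "dry", x, x^2))
  expect_equal(curvature_at(fit, 0), 2)
  expect_equal(curvature_at(fit, 1), 2 / 5^1.5)
  expect_warning(curvature_at(fit, 10), "extrapolation")

  line <- fit_profile(profile_trace("s", "LONGIT", "abaxial", "dry", x, 0.3 * x))
  expect_equal(curvature_at(line, c(-1, 0, 1)), rep(0, 3), tolerance = 1e-12)
})

test_that("mean absolute curvature recovers circular-arc curvature within 5%", {
  for (R in c(5, 10, 20)) {
    tr <- gen_profile("arc", list(radius = R, span_deg = 30), 20)
    cp <- mean_abs_curvature(tr)
    expect_equal(cp$mean_abs_kappa, 1 / R, tolerance = 0.05)
  }
  # curvature scales as 1/R
  k5 <- mean_abs_curvature(gen_profile("arc", list(radius = 5, span_deg = 30), 20))
  k20 <- mean_abs_curvature(gen_profile("arc", list(radius = 20, span_deg = 30), 20))
  expect_equal(k5$mean_abs_kappa / k20$mean_abs_kappa, 4, tolerance = 0.01)

  line <- gen_profile("line", list(length = 8), 16)
  expect_lt(mean_abs_curvature(line)$mean_abs_kappa, 1e-10)
})

test_that("curvature is rigid-motion invariant and scale covariant", {
  tr <- gen_profile("arc", list(radius = 10, span_deg = 25), 18,
                    noise_sd = 0.01, seed = 9)
  base <- mean_abs_curvature(tr)$mean_abs_kappa
  set.seed(10)
  for (i in 1:5) {
    moved <- transform_trace(tr, theta = runif(1, -pi, pi), shift = rnorm(2, sd = 5))
    expect_equal(mean_abs_curvature(moved)$mean_abs_kappa, base,
                 tolerance = 1e-9)
  }
  # scaling all coordinates by s scales curvature by 1/s
  s <- 2.5
  scaled <- profile_trace("synthetic", "LONGIT", "abaxial", "dry",
                          tr$x * s, tr$y * s)
  expect_equal(mean_abs_curvature(scaled)$mean_abs_kappa, base / s,
               tolerance = 1e-9)
})

test_that("profile comparison classifies curvature change", {
  tr <- gen_profile("arc", list(radius = 10, span_deg = 30), 20)
  cp <- mean_abs_curvature(tr)
  same <- compare_profiles(cp, cp)
  expect_equal(same$difference, 0)
  expect_equal(same$classification, "unchanged")

  # thinning the lamina increases model curvature; the milled profile
  # bends more than the intact one
  intact <- forward_bend(-0.02, -0.10, t_dry = 1.0, L = 5)
  milled <- forward_bend(-0.02, -0.10, t_dry = 0.6, L = 5)
  cp_before <- mean_abs_curvature(gen_laminate_specimen(intact, 20)$dry)
  cp_after <- mean_abs_curvature(gen_laminate_specimen(milled, 20)$dry)
  res <- compare_profiles(cp_before, cp_after)
  expect_equal(res$classification, "increase")
  expect_equal(res$ratio, intact$t_dry / milled$t_dry, tolerance = 0.05)

  flatten <- mean_abs_curvature(gen_profile("line", list(length = 5), 20))
  flat_res <- compare_profiles(cp, flatten)
  expect_equal(flat_res$classification, "decrease")
  expect_equal(flat_res$ratio, 0, tolerance = 1e-8)

  other <- mean_abs_curvature(gen_profile("arc", list(radius = 8, span_deg = 30),
                                          20, specimen_id = "other"))
  expect_error(compare_profiles(cp, other), class = "conebend_pairing_error")
})
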