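test_that("segment strain follows the declared reference convention", {
  p <- segment_pair(L_dry = 10, L_wet = 11)
  expect_equal(segment_strain(p, "dry")$epsilon, 0.10)
  expect_equal(segment_strain(segment_pair(5, 5), "dry")$epsilon, 0)

  # the two conventions are reciprocal, not negatives
  p2 <- segment_pair(L_dry = 11, L_wet = 10)
  e_wet <- segment_strain(p2, "wet")$epsilon
  e_dry <- segment_strain(p2, "dry")$epsilon
  expect_equal(e_wet, 0.10)
  expect_equal(e_dry, -1 / 11)
  expect_equal((1 + e_wet) * (1 + e_dry), 1)
  expect_equal(flip_strain_reference(e_dry), e_wet)

  expect_error(segment_pair(-1, 2), class = "conebend_domain_error")
})

test_that("affine fit recovers imposed deformations", {
  # identity
  corr <- gen_landmark_pair(diag(2))
  dg <- fit_deformation(corr)
  expect_equal(dg$F, diag(2), tolerance = 1e-12)
  expect_equal(dg$c, c(0, 0), tolerance = 1e-12)
  expect_lt(dg$residual_rms, 1e-12)

  # pure rotation about the centroid: F is the rotation matrix, residual 0
  R <- rot2(30 * pi / 180)
  corr_r <- gen_landmark_pair(R)
  dg_r <- fit_deformation(corr_r)
  expect_equal(dg_r$F, R, tolerance = 1e-12)
  expect_lt(dg_r$residual_rms, 1e-12)

  # noisy anisotropic stretch: agree with the normal-equations oracle
  Ftrue <- diag(c(1.2, 0.9))
  corr_n <- gen_landmark_pair(Ftrue, noise_sd = 0.01, seed = 11)
  dg_n <- fit_deformation(corr_n)
  orc <- oracle_affine_fit(corr_n$X, corr_n$x)
  expect_equal(dg_n$F, orc$F, tolerance = 1e-10)
  expect_equal(dg_n$c, orc$c, tolerance = 1e-10)
  expect_equal(dg_n$F, Ftrue, tolerance = 0.05)
})

test_that("degenerate and mis-paired landmark configurations are rejected", {
  collinear <- landmark_set("s", "abaxial", "dry", c("a", "b", "c", "d"),
                            x = 0:3, y = rep(0, 4))
  obs <- landmark_set("s", "abaxial", "wet", c("a", "b", "c", "d"),
                      x = 0:3, y = rep(0.1, 4))
  expect_error(fit_deformation(landmark_correspondence(collinear, obs)),
               class = "conebend_degenerate_error")

  # mirrored pairing flips orientation
  corr <- gen_landmark_pair(diag(2))
  corr$x[, 1] <- -corr$x[, 1]
  expect_error(fit_deformation(corr), class = "conebend_orientation_error")

  ref2 <- landmark_set("s", "abaxial", "dry", c("a", "b"), x = 0:1, y = 0:1)
  obs2 <- landmark_set("s", "abaxial", "wet", c("a", "b"), x = 0:1, y = 0:1)
  expect_error(fit_deformation(landmark_correspondence(ref2, obs2)),
               class = "conebend_degenerate_error")
})

test_that("principal strains come from the right stretch tensor", {
  iso <- principal_strains(diag(2))
  expect_equal(iso$eps_max, 0)
  expect_equal(iso$eps_min, 0)
  expect_equal(iso$theta, 0)
  expect_true(iso$isotropic)

  ax <- principal_strains(diag(c(1.15, 1.05)))
  expect_equal(ax$eps_max, 0.15)
  expect_equal(ax$eps_min, 0.05)
  expect_equal(ax$theta, 0)

  # rotation is removed by the polar decomposition
  F <- rot2(pi / 4) %*% diag(c(1.1, 0.9))
  ps <- principal_strains(F)
  expect_equal(ps$eps_max, 0.1, tolerance = 1e-12)
  expect_equal(ps$eps_min, -0.1, tolerance = 1e-12)
  expect_equal(ps$theta, 0, tolerance = 1e-12)

  # random sheared gradients against the characteristic-polynomial oracle
  set.seed(3)
  for (i in 1:20) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.15), 2, 2)
    if (det(F) <= 0) next
    lam <- oracle_principal_stretches(F)
    ps <- principal_strains(F)
    expect_equal(ps$eps_max, lam[1] - 1, tolerance = 1e-10)
    expect_equal(ps$eps_min, lam[2] - 1, tolerance = 1e-10)
    expect_gte(ps$eps_max, ps$eps_min)
  }
})

test_that("strain cross is invariant under rigid motion and covariant under frame rotation", {
  set.seed(4)
  for (i in 1:10) {
    ang <- runif(1, -pi, pi)
    corr <- gen_landmark_pair(rot2(ang), translation = rnorm(2))
    ps <- principal_strains(fit_deformation(corr))
    expect_lt(abs(ps$eps_max), 1e-12)
    expect_lt(abs(ps$eps_min), 1e-12)
  }

  # rotating both configurations rotates theta by the same angle (mod pi)
  F <- diag(c(1.12, 0.95))
  phi <- 0.4
  base <- principal_strains(F)
  Q <- rot2(phi)
  rotated <- principal_strains(Q %*% F %*% t(Q))
  expect_equal(rotated$eps_max, base$eps_max, tolerance = 1e-12)
  expect_equal(rotated$eps_min, base$eps_min, tolerance = 1e-12)
  d <- (rotated$theta - base$theta - phi) %% pi
  expect_true(min(d, pi - d) < 1e-9)
  # equivalently, declaring the rotated axis recovers theta
  expect_equal(principal_strains(Q %*% F %*% t(Q), axis_direction = phi)$theta,
               base$theta, tolerance = 1e-9)
})

test_that("noise-free affine recovery is exact to 1e-10", {
  set.seed(5)
  for (i in 1:10) {
    stretches <- 1 + runif(2, -0.2, 0.3)
    F <- rot2(runif(1, -pi, pi)) %*% diag(sort(stretches, decreasing = TRUE))
    ps <- principal_strains(fit_deformation(gen_landmark_pair(F)))
    expect_equal(ps$eps_max, max(stretches) - 1, tolerance = 1e-10)
    expect_equal(ps$eps_min, min(stretches) - 1, tolerance = 1e-10)
  }
})

test_that("anisotropy is the signed transverse-longitudinal difference", {
  s <- function(e) structure(list(epsilon = e, direction = "LONGIT",
                                  reference = "dry", label = ""),
                             class = "segment_strain")
  expect_equal(strain_anisotropy(s(0.02), s(0.08)), 0.06)
  expect_equal(strain_anisotropy(s(0.05), s(0.05)), 0)
  # adaxial-like signature: longitudinal shrinkage, transverse expansion
  expect_equal(strain_anisotropy(s(-0.03), s(0.05)), 0.08)

  wet <- s(0.02); wet$reference <- "wet"
  expect_error(strain_anisotropy(s(0.02), wet), class = "conebend_convention_error")
})

test_that("regional strain profile orders proximal -> middle -> distal", {
  s <- function(e) structure(list(epsilon = e, direction = "LONGIT",
                                  reference = "dry", label = ""),
                             class = "segment_strain")
  res <- list(list(region = "distal", strain = s(0.02)),
              list(region = "proximal", strain = s(0.08)),
              list(region = "middle", strain = s(0.07)),
              list(region = "proximal", strain = s(0.09)))
  tab <- regional_strain_profile(res)
  expect_equal(tab$region, c("proximal", "middle", "distal"))
  expect_equal(tab$n, c(2L, 1L, 1L))
  expect_true(all(diff(tab$mean_epsilon) < 0))  # gradient along the axis

  one <- regional_strain_profile(list(list(region = "middle", strain = s(0.05))))
  expect_equal(nrow(one), 1)

  expect_error(regional_strain_profile(list(list(region = "apex", strain = s(0)))),
               class = "conebend_schema_error")
})
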