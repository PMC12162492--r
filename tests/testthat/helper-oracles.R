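# Independent oracles, kept deliberately separate from the package's own
# code paths: explicit normal equations for the affine fit, characteristic-
# polynomial eigenvalues for principal stretches, numerical root-solving of
# the two arc equations, a grid-search circle fit, and the closed-form
# pooled t-test.

# Affine fit x ~ F X + c by explicitly assembled normal equations.
oracle_affine_fit <- function(X, x) {
  A <- cbind(1, X)
  B <- unname(solve(t(A) %*% A, t(A) %*% x))
  list(F = t(B[2:3, , drop = FALSE]), c = as.numeric(B[1, ]))
}

# Principal stretches of F from the characteristic polynomial of C = F'F:
# lambda^2 are roots of z^2 - tr(C) z + det(C).
oracle_principal_stretches <- function(F) {
  C <- t(F) %*% F
  tr <- C[1, 1] + C[2, 2]
  dt <- C[1, 1] * C[2, 2] - C[1, 2] * C[2, 1]
  disc <- sqrt(max(tr^2 / 4 - dt, 0))
  sqrt(c(tr / 2 + disc, tr / 2 - disc))
}

# Solve the two arc equations (1+eps_ad)L = 2*pi*p*(r + t) and
# (1+eps_ab)L = 2*pi*p*r numerically: eliminate r via the second equation
# and find p by bisection on the first.
oracle_arc_solve <- function(eps_ad, eps_ab, t_dry, L) {
  g <- function(p) {
    r <- (1 + eps_ab) * L / (2 * pi * p)
    (1 + eps_ad) * L - 2 * pi * p * (r + t_dry)
  }
  p <- uniroot(g, c(1e-12, 10), tol = 1e-15)$root
  r <- (1 + eps_ab) * L / (2 * pi * p)
  list(p = p, r = r, kappa = 1 / r)
}

# Coarse-to-fine grid search for the circle minimizing radial variance.
oracle_circle_grid <- function(x, y, span = 2, steps = 3) {
  cx <- mean(x); cy <- mean(y); half <- span
  for (s in seq_len(steps)) {
    gx <- seq(cx - half, cx + half, length.out = 41)
    gy <- seq(cy - half, cy + half, length.out = 41)
    best <- Inf
    for (i in gx) for (j in gy) {
      d <- sqrt((x - i)^2 + (y - j)^2)
      v <- var(d)
      if (v < best) { best <- v; cx <- i; cy <- j }
    }
    half <- half / 10
  }
  list(center = c(cx, cy), radius = mean(sqrt((x - cx)^2 + (y - cy)^2)))
}

# Closed-form pooled-variance two-sample t-test.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Polynomial OLS of one rank via normal equations.
oracle_poly_fit <- function(x, y, degree) {
  V <- outer(x, 0:degree, `^`)
  cf <- solve(t(V) %*% V, t(V) %*% y)
  fitted <- V %*% cf
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  n <- length(y)
  list(coefficients = as.numeric(cf), R2 = r2,
       adjusted_R2 = 1 - (1 - r2) * (n - 1) / (n - degree - 1))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Rigidly transform a profile_trace.
transform_trace <- function(trace, theta = 0, shift = c(0, 0)) {
  R <- rot2(theta)
  xy <- t(R %*% t(cbind(trace$x, trace$y))) +
    matrix(shift, nrow(trace), 2, byrow = TRUE)
  profile_trace(attr(trace, "specimen_id"), attr(trace, "orientation"),
                attr(trace, "side"), attr(trace, "state"),
                xy[, 1], xy[, 2], attr(trace, "treatment"))
}
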