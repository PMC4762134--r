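test_that("companion matrix realizes the trinomial", {
  # m = 1: eigenvalues against the quadratic formula
  poly <- char_poly(std_params, 1, 0.2, step_grid(1), "nsfd")
  A <- companion_matrix(poly)
  expect_identical(dim(A), c(2L, 2L))
  expect_identical(A[2, 1], 1)
  disc <- as.complex(poly$a0_tilde^2 + 4 * poly$a1_tilde)
  quad <- (poly$a0_tilde + c(1, -1) * sqrt(disc)) / 2
  ev <- eigen(A, only.values = TRUE)$values
  expect_equal(sort(Mod(ev)), sort(Mod(quad)), tolerance = 1e-12)

  # at tau = 0 (NSFD): a0 = 1, a1 = 0 -> m-fold root 0 and a simple root 1
  poly0 <- char_poly(std_params, 0.8, 0, step_grid(4), "nsfd")
  expect_identical(poly0$a0_tilde, 1)
  expect_identical(poly0$a1_tilde, 0)
  ev0 <- sort(Mod(eigen(companion_matrix(poly0), only.values = TRUE)$values))
  expect_equal(ev0, c(0, 0, 0, 0, 1), tolerance = 1e-12)
  expect_equal(spectral_radius(poly0), 1, tolerance = 1e-12)
})

test_that("companion eigenvalues agree with direct polynomial root-finding", {
  # cross-oracle on random trinomials: polyroot() is the independent solver
  set.seed(123)
  for (i in 1:100) {
    m <- sample(1:6, 1)
    poly <- char_poly(std_params, runif(1, 0.3, 1), runif(1, 0, 3),
                      step_grid(m), sample(c("nsfd", "euler"), 1))
    # polynomial coefficients in increasing degree: -a1, 0...0, -a0, 1
    coefs <- c(-poly$a1_tilde, rep(0, m - 1), -poly$a0_tilde, 1)
    direct <- max(Mod(polyroot(coefs)))
    expect_equal(spectral_radius(poly), direct, tolerance = 1e-10)
  }
})

test_that("critical delays reproduce the reference tables at print precision", {
  ref <- reference_tau0()
  for (i in seq_len(nrow(ref))) {
    cp <- critical_tau(std_params, ref$alpha[i],
                       step_grid(round(1 / ref$h[i])), kind = ref$scheme[i])
    expect_lt(abs(cp$tau0 - ref$tau0_ref[i]), 5e-4)
    expect_lt(abs(Mod(cp$crossing_eigenvalue) - 1), 1e-8)
    expect_gt(Im(cp$crossing_eigenvalue), 0)
  }
})

test_that("bisection agrees with the m = 1 analytic unit-circle condition", {
  for (kind in c("nsfd", "euler")) {
    for (alpha in c(1, 0.9, 0.6)) {
      cp <- critical_tau(std_params, alpha, step_grid(1), kind = kind)
      expect_equal(cp$tau0, analytic_tau0_m1(std_params, alpha, kind),
                   tolerance = 1e-8)
    }
  }
})

test_that("no crossing exists in the stable-for-all-delay regime", {
  # alpha = 0.4: upper threshold 2.75 > b u* = 2.708
  expect_error(critical_tau(std_params, 0.4, step_grid(2), "nsfd"),
               "no crossing")
  # spectral radius stays below 1 on a grid to tau = 10
  taus <- seq(0.05, 10, by = 0.05)
  rads <- vapply(taus, function(t)
    spectral_radius(char_poly(std_params, 0.4, t, step_grid(2), "nsfd")),
    numeric(1))
  expect_true(all(rads < 1))
  # and the crossing-angle equation is infeasible: cos(omega) > 1
  expect_error(crossing_angle(std_params, 0.4, 1, step_grid(2)),
               "no real angle")
})

test_that("crossing angle formula matches the dominant eigenvalue at tau0", {
  for (alpha in c(1, 0.9, 0.6)) {
    for (m in c(1, 2)) {
      cp <- critical_tau(std_params, alpha, step_grid(m), "nsfd")
      ang <- crossing_angle(std_params, alpha, cp$tau0, step_grid(m))
      expect_equal(ang, cp$omega0, tolerance = 1e-6)
    }
  }
  # degenerate factor: b u* exactly at the upper threshold gives omega = 0
  p_edge <- blowfly_params(a = exp(2), b = 1, c = 1)
  expect_equal(crossing_angle(p_edge, 1, 0.5, step_grid(2)), 0)
})

test_that("discrete transversality is positive and matches the closed form", {
  for (alpha in c(1, 0.9, 0.6)) {
    for (m in c(1, 2)) {
      cp <- critical_tau(std_params, alpha, step_grid(m), "nsfd")
      chk <- eigen_derivative_check(cp)
      expect_gt(chk$finite_difference, 0)
      expect_gt(chk$closed_form, 0)
      expect_lt(chk$rel_error, 1e-4)
    }
  }
  # Euler: finite difference only
  cp_e <- critical_tau(std_params, 1, step_grid(1), "euler")
  chk_e <- eigen_derivative_check(cp_e)
  expect_gt(chk_e$finite_difference, 0)
  expect_true(is.na(chk_e$closed_form))
})

test_that("unit-root slope at zero delay matches the tracked-root derivative", {
  # closed form 2h(1 - alpha - b u* alpha c); at alpha = 1, h = 1 this is
  # -4 ln(15) = -10.8322 (the finite-difference oracle below is the arbiter)
  expect_equal(unit_root_slope(std_params, 1, step_grid(1)),
               -4 * log(15), tolerance = 1e-12)
  for (alpha in c(1, 0.9, 0.6)) {
    for (m in c(1, 2)) {
      g <- step_grid(m)
      cf <- unit_root_slope(std_params, alpha, g)
      expect_lt(cf, 0)  # b u* > (1-alpha)/(alpha c) for these gains
      # finite-difference oracle: track the root leaving lambda = 1
      lam_at <- function(tau) {
        ev <- eigen(companion_matrix(
          char_poly(std_params, alpha, tau, g, "nsfd")),
          only.values = TRUE)$values
        ev[which.min(Mod(ev - 1))]
      }
      d <- 1e-6
      fd <- (Mod(lam_at(d))^2 - 1) / d
      fd2 <- (Mod(lam_at(2 * d))^2 - 1) / (2 * d)
      fd_rich <- 2 * fd - fd2  # Richardson-extrapolated one-sided difference
      expect_equal(fd_rich, cf, tolerance = 1e-4)
    }
  }
  # boundary of the stability condition: 1 - alpha = b u* alpha c
  al0 <- 1 / (1 + std_params$b_u_star * std_params$c)
  expect_equal(unit_root_slope(std_params, al0, step_grid(2)), 0,
               tolerance = 1e-14)
})

test_that("tau0 rises as the gain drops, Euler < NSFD, and tau0(h) approaches the continuous limit", {
  for (m in c(1, 2)) {
    t_by_alpha <- function(kind) vapply(c(1, 0.9, 0.6), function(al)
      critical_tau(std_params, al, step_grid(m), kind)$tau0, numeric(1))
    t_n <- t_by_alpha("nsfd"); t_e <- t_by_alpha("euler")
    expect_true(all(diff(t_n) > 0))  # alpha 1 -> 0.9 -> 0.6 delays the onset
    expect_true(all(diff(t_e) > 0))
    expect_true(all(t_e < t_n))      # NSFD holds stability longer
  }
  tau_cont <- hopf_points(std_params, 1)$tau_k[1]
  for (kind in c("nsfd", "euler")) {
    errs <- vapply(c(2, 4, 8, 16), function(m)
      abs(critical_tau(std_params, 1, step_grid(m), kind)$tau0 - tau_cont),
      numeric(1))
    expect_true(all(diff(errs) < 0))
  }
})
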