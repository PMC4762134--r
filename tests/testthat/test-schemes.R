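test_that("the equilibrium is an exact fixed point of both step maps", {
  grids <- list(step_grid(1), step_grid(2), step_grid(7))
  for (p in c(list(std_params), random_params(10, seed = 7))) {
    for (g in grids) {
      for (alpha in c(1, 0.7, 0.3)) {
        expect_identical(nsfd_step(0, 0, p, alpha, tau = 1.3, g), 0)
        expect_equal(euler_step(0, 0, p, alpha, tau = 1.3, g), 0,
                     tolerance = 1e-13)
      }
    }
  }
})

test_that("step maps agree with an independent literal transcription", {
  # the update rules re-typed term by term, as an independent transcription
  nsfd_lit <- function(vn, vnm, a, b, c, alpha, tau, h) {
    us <- log(a / c) / b
    exp(-alpha * c * tau * h) * vn +
      (exp(-alpha * c * tau * h) - 1) * us +
      (1 - exp(-alpha * c * tau * h)) * (vnm + us) * exp(-b * vnm) +
      ((1 - exp(-alpha * c * tau * h)) * (1 - alpha) / (alpha * c)) * vnm
  }
  euler_lit <- function(vn, vnm, a, b, c, alpha, tau, h) {
    us <- log(a / c) / b
    vn + alpha * tau * h * (a * (vnm + us) * exp(-b * (vnm + us)) -
                              c * (vn + us)) +
      (1 - alpha) * tau * h * vnm
  }
  g2 <- step_grid(2)
  expect_equal(nsfd_step(0.1, 0.1, std_params, 1, 0.5, g2),
               nsfd_lit(0.1, 0.1, 30, 2, 2, 1, 0.5, 0.5), tolerance = 1e-14)
  expect_equal(euler_step(0.1, 0.1, std_params, 0.6, 1, g2),
               euler_lit(0.1, 0.1, 30, 2, 2, 0.6, 1, 0.5), tolerance = 1e-14)
  # off-equilibrium, asymmetric arguments, several configurations
  set.seed(11)
  for (i in 1:20) {
    vn <- rnorm(1, 0, 0.3); vnm <- rnorm(1, 0, 0.3)
    al <- runif(1, 0.2, 1); tau <- runif(1, 0.1, 2)
    expect_equal(nsfd_step(vn, vnm, std_params, al, tau, g2),
                 nsfd_lit(vn, vnm, 30, 2, 2, al, tau, 0.5),
                 tolerance = 1e-14)
    expect_equal(euler_step(vn, vnm, std_params, al, tau, g2),
                 euler_lit(vn, vnm, 30, 2, 2, al, tau, 0.5),
                 tolerance = 1e-14)
  }
})

test_that("NSFD denominator solves linear decay exactly; both denominators are h + O(h^2)", {
  # v' = -ac*tau*v  discretized with the NSFD denominator reproduces
  # v0 * exp(-ac*tau*t) to machine precision at every step
  alpha <- 0.8; tau <- 1.7
  p <- std_params
  act <- alpha * p$c * tau
  for (m in c(1, 4, 16)) {
    g <- step_grid(m)
    spec <- scheme_spec("nsfd", g, p, alpha, tau)
    v <- 0.37
    for (n in 1:(3 * m)) {
      v <- v - act * spec$denominator * v
      expect_equal(v, 0.37 * exp(-act * n * g$h), tolerance = 1e-14)
    }
  }
  # psi(h) = h + O(h^2): (psi(h) - h)/h^2 stays bounded as h -> 0
  hs <- 10^-(1:4)
  ratio <- vapply(hs, function(h) {
    g <- step_grid(round(1 / h))
    (scheme_spec("nsfd", g, p, alpha, tau)$denominator - h) / h^2
  }, numeric(1))
  expect_lt(max(abs(ratio)), act)  # limit is -act/2
  expect_equal(ratio[3] / ratio[4], 1, tolerance = 0.01)
  expect_identical(scheme_spec("euler", step_grid(4), p, alpha, tau)$denominator,
                   0.25)
})

test_that("NSFD and Euler steps differ by O((ac tau h)^2) on identical inputs", {
  p <- std_params; alpha <- 1
  diffs <- vapply(c(1e-2, 1e-3, 1e-4), function(scale) {
    tau <- scale / (alpha * p$c)  # so ac*tau*h = scale at h = 1
    g <- step_grid(1)
    abs(nsfd_step(0.1, 0.2, p, alpha, tau, g) -
          euler_step(0.1, 0.2, p, alpha, tau, g))
  }, numeric(1))
  expect_equal(diffs[1] / diffs[2], 100, tolerance = 0.05)
  expect_equal(diffs[2] / diffs[3], 100, tolerance = 0.05)
})

test_that("numerical Jacobian of one NSFD step matches the companion-matrix entries", {
  alpha <- 0.9; tau <- 0.7; g <- step_grid(3)
  poly <- char_poly(std_params, alpha, tau, g, "nsfd")
  d <- 1e-6
  j_now <- (nsfd_step(d, 0, std_params, alpha, tau, g) -
              nsfd_step(-d, 0, std_params, alpha, tau, g)) / (2 * d)
  j_del <- (nsfd_step(0, d, std_params, alpha, tau, g) -
              nsfd_step(0, -d, std_params, alpha, tau, g)) / (2 * d)
  expect_equal(j_now, poly$a0_tilde, tolerance = 1e-6)
  expect_equal(j_del, poly$a1_tilde, tolerance = 1e-6)
  # same for the Euler linearization (coefficients derived, not printed)
  poly_e <- char_poly(std_params, alpha, tau, g, "euler")
  j_now_e <- (euler_step(d, 0, std_params, alpha, tau, g) -
                euler_step(-d, 0, std_params, alpha, tau, g)) / (2 * d)
  j_del_e <- (euler_step(0, d, std_params, alpha, tau, g) -
                euler_step(0, -d, std_params, alpha, tau, g)) / (2 * d)
  expect_equal(j_now_e, poly_e$a0_tilde, tolerance = 1e-6)
  expect_equal(j_del_e, poly_e$a1_tilde, tolerance = 1e-6)
})

test_that("simulation converges below the critical delay and oscillates above", {
  g <- step_grid(2)
  tr_sub <- simulate_scheme("nsfd", std_params, 1, tau = 0.5, g)
  expect_identical(classify_trajectory(tr_sub), "converges")
  tr_sup <- simulate_scheme("nsfd", std_params, 1, tau = 0.6, g)
  expect_identical(classify_trajectory(tr_sup), "oscillates")
  expect_false(tr_sup$diverged)

  # zero history stays exactly at the fixed point
  tr0 <- simulate_scheme("euler", std_params, 0.6, tau = 1, g,
                         history = rep(0, 3), n_steps = 100)
  expect_identical(tr0$v, rep(0, 100))
})

test_that("divergence is flagged loudly, not returned as infinity", {
  g <- step_grid(1)
  expect_error(nsfd_step(0, -40, std_params, 1, 1, g, bound = 1e6),
               class = "blowflyNS_divergence")
  # Euler far above the critical delay blows up; trajectory is flagged
  tr <- simulate_scheme("euler", std_params, 1, tau = 3, g, n_steps = 500)
  expect_true(tr$diverged)
  expect_identical(classify_trajectory(tr), "diverges")
  expect_true(all(is.finite(tr$v)))
})

test_that("trajectory CSV has the documented layout", {
  g <- step_grid(2)
  tr <- simulate_scheme("nsfd", std_params, 1, tau = 0.5, g, n_steps = 10)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f, original_time = TRUE)
  txt <- readLines(f)
  expect_identical(txt[1], "n,t_scaled,u,t")
  df <- read.csv(f)
  expect_identical(nrow(df), 13L)             # m + 1 history rows + 10 steps
  expect_identical(df$n, seq.int(-2, 10))
  expect_equal(df$u[1:3], rep(std_params$u_star + 0.1, 3), tolerance = 1e-12)
  expect_equal(df$t, df$t_scaled * 0.5, tolerance = 1e-12)
  # byte-identical on re-run (end-to-end determinism)
  f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(simulate_scheme("nsfd", std_params, 1, 0.5, g,
                                       n_steps = 10), f2,
                       original_time = TRUE)
  expect_identical(readLines(f2), txt)
})
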