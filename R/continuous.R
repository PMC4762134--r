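#' Characteristic structure of the controlled delay equation
#'
#' In scaled time (delay normalized to 1, so the delay \eqn{\tau} enters as a
#' coefficient), the linearization of the hybrid-controlled equation at the
#' equilibrium has the transcendental characteristic equation
#' \deqn{\lambda = \alpha c \tau [(1 - b u^*) e^{-\lambda} - 1]
#'       + (1-\alpha)\tau e^{-\lambda}.}
#' The delayed-feedback coefficient per unit \eqn{\tau} is
#' \eqn{\beta = \alpha c (1 - b u^*) + (1 - \alpha)}; in the conditionally
#' stable regime \eqn{\beta < -\alpha c < 0}, which is exactly what makes a
#' purely imaginary crossing possible.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @return An object of class `cont_char`: list with `alpha_c` (decay
#'   coefficient \eqn{\alpha c}), `feedback_coeff` (\eqn{\beta}), `alpha`,
#'   and `params`.
#' @export
continuous_characteristic <- function(params, alpha) {
  stopifnot(inherits(params, "blowfly_params"))
  check_alpha(alpha)
  ac <- alpha * params$c
  beta <- ac * (1 - params$b_u_star) + (1 - alpha)
  structure(
    list(alpha_c = ac, feedback_coeff = beta, decay_coeff = ac,
         alpha = alpha, params = params),
    class = "cont_char"
  )
}

#' Evaluate the continuous characteristic function
#'
#' Returns \eqn{\lambda - \alpha c \tau[(1-bu^*)e^{-\lambda} - 1]
#' - (1-\alpha)\tau e^{-\lambda}}; a characteristic root gives 0. The function
#' is entire, so any complex `lam` is accepted.
#'
#' @param chi a [continuous_characteristic()] object.
#' @param tau delay (nonnegative).
#' @param lam complex (or real) trial eigenvalue.
#' @return complex residual value.
#' @export
characteristic_value <- function(chi, tau, lam) {
  stopifnot(inherits(chi, "cont_char"), tau >= 0)
  lam <- as.complex(lam)
  lam - tau * (chi$feedback_coeff * exp(-lam) - chi$alpha_c)
}

# derivative of the characteristic function wrt lambda
characteristic_deriv <- function(chi, tau, lam) {
  1 + tau * chi$feedback_coeff * exp(-as.complex(lam))
}

# Newton refinement of a characteristic root from a starting guess.
# The equation is scalar and analytic; plain Newton with a small damping
# safeguard converges in a handful of steps from the crossing seed.
track_characteristic_root <- function(chi, tau, lam0,
                                      tol = 1e-13, max_iter = 100L) {
  lam <- as.complex(lam0)
  for (i in seq_len(max_iter)) {
    f <- characteristic_value(chi, tau, lam)
    if (Mod(f) < tol) return(lam)
    step <- f / characteristic_deriv(chi, tau, lam)
    # damp very large steps (only relevant far from a root)
    if (Mod(step) > 1) step <- step / Mod(step)
    lam <- lam - step
  }
  if (Mod(characteristic_value(chi, tau, lam)) > 1e-9)
    stop("characteristic root tracking failed to converge", call. = FALSE)
  lam
}

#' Hopf crossing structure of the controlled delay equation
#'
#' Computes the critical-delay sequence at which a complex-conjugate pair of
#' characteristic roots crosses the imaginary axis. Writing
#' \eqn{\beta = \alpha c(1-bu^*) + (1-\alpha)}, a purely imaginary root
#' \eqn{i\omega} requires
#' \deqn{\beta\tau\cos\omega = \alpha c \tau, \qquad
#'       \beta\tau\sin\omega = -\omega,}
#' which has a solution iff \eqn{b u^* > 2 + (1-\alpha)/(\alpha c)}
#' (conditionally stable regime). The crossing angle
#' \eqn{\theta_0 \in (\pi/2, \pi)} satisfies \eqn{\cos\theta_0 = \alpha c/\beta}
#' and \eqn{\sin\theta_0 = -\sqrt{\beta^2-(\alpha c)^2}/\beta}, and the
#' critical delays are
#' \deqn{\tau_k = \frac{\theta_0 + 2k\pi}{\sqrt{\beta^2 - (\alpha c)^2}},
#'       \quad k = 0, 1, 2, \ldots}
#' The transversality derivative (speed of the real part across zero) is the
#' closed form
#' \deqn{\alpha_k'(\tau_k) = \frac{\tau_k (\beta^2 - (\alpha c)^2)}{\Delta},
#'   \quad
#'   \Delta = (1+\tau_k\beta\cos\theta_0)^2 + (\tau_k\beta\sin\theta_0)^2,}
#' obtained from the quotient-rule derivative of the characteristic root and
#' the crossing relations \eqn{\beta\cos\theta_0 = \alpha c},
#' \eqn{\beta\sin\theta_0 = -\sqrt{\beta^2 - (\alpha c)^2}}; it is positive
#' at every crossing, so the root pair always moves into the right
#' half-plane as the delay grows.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param k_max largest index of the critical-delay sequence to return
#'   (default 3; only the first crossing matters in practice).
#' @return An object of class `cont_hopf`: list with `beta`, `angular_rate`
#'   (\eqn{\sqrt{\beta^2-(\alpha c)^2}}), `theta0`, `tau_k` (length
#'   `k_max + 1`), `transversality` (same length), `alpha`, `params`.
#' @examples
#' hp <- hopf_points(blowfly_params(30, 2, 2), alpha = 1)
#' hp$tau_k[1]   # first critical delay, ~0.793
#' @export
hopf_points <- function(params, alpha, k_max = 3L) {
  stopifnot(inherits(params, "blowfly_params"), k_max >= 0)
  chi <- continuous_characteristic(params, alpha)
  verdict <- classify_regime(params, alpha)
  if (verdict$regime != "conditional_stability")
    stop("no Hopf point: requires b u* > 2 + (1-alpha)/(alpha c) ",
         "(regime is '", verdict$regime, "')", call. = FALSE)
  beta <- chi$feedback_coeff
  ac <- chi$alpha_c
  radicand <- beta^2 - ac^2
  if (radicand <= 0) # unreachable in the conditional regime; defensive
    stop("no Hopf point: imaginary-axis crossing equation has no real solution",
         call. = FALSE)
  rate <- sqrt(radicand)
  theta0 <- atan2(-rate / beta, ac / beta)  # beta < 0 puts this in (pi/2, pi)
  k <- 0:k_max
  tau_k <- (theta0 + 2 * pi * k) / rate
  delta <- (1 + tau_k * beta * cos(theta0))^2 + (tau_k * beta * sin(theta0))^2
  trans <- tau_k * radicand / delta
  structure(
    list(beta = beta, angular_rate = rate, theta0 = theta0,
         tau_k = tau_k, transversality = trans,
         alpha = alpha, params = params),
    class = "cont_hopf"
  )
}

#' @export
print.cont_hopf <- function(x, ...) {
  cat("Hopf crossing structure (controlled delay equation)\n")
  cat(sprintf("  beta = %.6f, angular rate = %.6f, theta0 = %.6f\n",
              x$beta, x$angular_rate, x$theta0))
  cat("  tau_k:", paste(sprintf("%.6f", x$tau_k), collapse = ", "), "\n")
  cat("  transversality:",
      paste(sprintf("%.6f", x$transversality), collapse = ", "), "\n")
  invisible(x)
}

#' Transversality at a continuous Hopf crossing: closed form vs continuation
#'
#' Evaluates the closed-form crossing speed \eqn{\alpha_k'(\tau_k)} and an
#' independent finite-difference estimate obtained by Newton-tracking the
#' characteristic root \eqn{\lambda(\tau)} across the crossing (two-sided
#' difference of \eqn{\mathrm{Re}\,\lambda}).
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param k crossing index (0 = first crossing).
#' @param step finite-difference step in \eqn{\tau} (default 1e-5).
#' @return list with `closed_form`, `finite_difference`, and `rel_error`.
#' @export
verify_transversality <- function(params, alpha, k = 0L, step = 1e-5) {
  hp <- hopf_points(params, alpha, k_max = k)
  chi <- continuous_characteristic(params, alpha)
  tau_k <- hp$tau_k[k + 1L]
  omega <- hp$theta0 + 2 * pi * k
  seed <- complex(real = 0, imaginary = omega)
  lam_plus <- track_characteristic_root(chi, tau_k + step, seed)
  lam_minus <- track_characteristic_root(chi, tau_k - step, seed)
  fd <- (Re(lam_plus) - Re(lam_minus)) / (2 * step)
  cf <- hp$transversality[k + 1L]
  list(closed_form = cf, finite_difference = fd,
       rel_error = abs(cf - fd) / abs(cf))
}
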