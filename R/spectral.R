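#' Characteristic polynomial of a discretization's linearization
#'
#' Linearizing either hybrid-control scheme at the equilibrium and stacking
#' the last `m + 1` states gives a companion system whose characteristic
#' polynomial is the trinomial
#' \deqn{\lambda^{m+1} - \tilde a_0 \lambda^m - \tilde a_1 = 0.}
#' For the NSFD scheme, with \eqn{E = e^{-\alpha c \tau h}},
#' \eqn{\tilde a_0 = E} and
#' \eqn{\tilde a_1 = (1 - E)(1 - b u^* + (1-\alpha)/(\alpha c))}. For the
#' Euler scheme, \eqn{\tilde a_0 = 1 - \alpha c \tau h} and
#' \eqn{\tilde a_1 = \tau h [\alpha c (1 - b u^*) + (1 - \alpha)]}.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param tau delay (nonnegative).
#' @param grid a [step_grid()].
#' @param kind `"nsfd"` or `"euler"`.
#' @return object of class `char_poly`: list with `kind`, `degree = m + 1`,
#'   `a0_tilde`, `a1_tilde`, `m`, `h`, and the model context.
#' @export
char_poly <- function(params, alpha, tau, grid, kind = c("nsfd", "euler")) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"),
            is.numeric(tau), length(tau) == 1L, tau >= 0)
  check_alpha(alpha)
  ac <- alpha * params$c
  bu <- params$b_u_star
  if (kind == "nsfd") {
    E <- exp(-ac * tau * grid$h)
    a0 <- E
    a1 <- (1 - E) * (1 - bu + (1 - alpha) / ac)
  } else {
    a0 <- 1 - ac * tau * grid$h
    a1 <- tau * grid$h * (ac * (1 - bu) + (1 - alpha))
  }
  structure(
    list(kind = kind, degree = grid$m + 1L, a0_tilde = a0, a1_tilde = a1,
         m = grid$m, h = grid$h, params = params, alpha = alpha, tau = tau),
    class = "char_poly"
  )
}

# evaluate the trinomial a(lambda) = lambda^{m+1} - a0 lambda^m - a1
poly_value <- function(poly, lam) {
  lam <- as.complex(lam)
  lam^(poly$m + 1) - poly$a0_tilde * lam^poly$m - poly$a1_tilde
}

#' Companion matrix of the linearized scheme
#'
#' The `(m+1) x (m+1)` matrix with first row
#' \eqn{(\tilde a_0, 0, \ldots, 0, \tilde a_1)}, ones on the subdiagonal and
#' zeros elsewhere; its characteristic polynomial is the scheme's trinomial
#' and its eigenvalues govern local stability of the fixed point.
#'
#' @param poly a [char_poly()] object.
#' @return numeric matrix of size `degree x degree`.
#' @export
companion_matrix <- function(poly) {
  stopifnot(inherits(poly, "char_poly"))
  n <- poly$degree
  A <- matrix(0, n, n)
  A[1, 1] <- poly$a0_tilde
  A[1, n] <- poly$a1_tilde
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  A
}

poly_eigenvalues <- function(poly) {
  eigen(companion_matrix(poly), only.values = TRUE)$values
}

# dominant eigenvalue, represented with nonnegative imaginary part
dominant_eigenvalue <- function(poly) {
  ev <- poly_eigenvalues(poly)
  lam <- ev[which.max(Mod(ev))]
  if (Im(lam) < 0) lam <- Conj(lam)
  lam
}

#' Spectral radius of the linearized scheme
#'
#' Maximum modulus over the roots of the characteristic trinomial, computed
#' from the companion-matrix eigenvalues. The fixed point of the scheme is
#' locally asymptotically stable iff the radius is below 1.
#'
#' @param poly a [char_poly()] object.
#' @return nonnegative scalar.
#' @export
spectral_radius <- function(poly) {
  max(Mod(poly_eigenvalues(poly)))
}

#' Critical delay of a discretization (Neimark-Sacker point)
#'
#' Finds the smallest delay at which the scheme's spectral radius reaches 1:
#' a grid scan in \eqn{\tau} (step `scan_step`, starting just above 0 because
#' at \eqn{\tau = 0} the polynomial degenerately has the simple root
#' \eqn{\lambda = 1}) locates the first sign change of
#' \eqn{\rho(\tau) - 1}, then bisection refines it to `tol`. The crossing
#' eigenpair must be a complex-conjugate pair (a real crossing is a flip
#' bifurcation, outside this theory, and raises an error). For the NSFD
#' scheme the transversality derivative \eqn{dr^2/d\tau} at the crossing is
#' the closed form
#' \deqn{\frac{2\alpha c h E (m + 1 + m E)(1 - \cos\omega_0)}
#'   {(1-E)[((m+1)\cos\omega_0 - m E)^2 + ((m+1)\sin\omega_0)^2]},}
#' with \eqn{E = e^{-\alpha c \tau_0 h}}; for the Euler scheme it is
#' estimated by a two-sided finite difference on the tracked dominant
#' eigenvalue.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param grid a [step_grid()].
#' @param kind `"nsfd"` or `"euler"`.
#' @param tau_max upper end of the scan (default 10).
#' @param tol upper bound on the bisection error in \eqn{\tau_0} (default
#'   1e-8); the bracket is in practice polished to near machine precision so
#'   that the crossing eigenpair is well conditioned.
#' @param scan_step scan resolution (default 0.01).
#' @return object of class `critical_point`: list with `tau0`, `omega0`
#'   (argument of the crossing eigenvalue, in \eqn{(0, \pi)}),
#'   `crossing_eigenvalue` (modulus 1 within 1e-8, positive imaginary part),
#'   `transversality`, `k_index` (0: first crossing), plus the scheme context.
#' @examples
#' cp <- critical_tau(blowfly_params(30, 2, 2), alpha = 1, grid = step_grid(1),
#'                    kind = "nsfd")
#' round(cp$tau0, 4)   # 0.4403
#' @export
critical_tau <- function(params, alpha, grid, kind = c("nsfd", "euler"),
                         tau_max = 10, tol = 1e-8, scan_step = 0.01) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"),
            tau_max > 0, tol > 0, scan_step > 0)
  check_alpha(alpha)
  rad <- function(tau) spectral_radius(char_poly(params, alpha, tau, grid, kind))
  tau_lo <- 1e-6
  f_lo <- rad(tau_lo) - 1
  if (f_lo >= 0)
    stop("spectral radius already >= 1 at tau = 1e-6; no stable range",
         call. = FALSE)
  tau_hi <- tau_lo
  found <- FALSE
  while (tau_hi < tau_max) {
    tau_next <- tau_hi + scan_step
    f_next <- rad(tau_next) - 1
    if (f_next >= 0) { found <- TRUE; break }
    tau_hi <- tau_next
    f_lo <- f_next
  }
  if (!found)
    stop(sprintf("no crossing in [0, %g]: spectral radius stays below 1 %s",
                 tau_max, "(stable-for-all-tau regime)"), call. = FALSE)
  root <- uniroot(function(t) rad(t) - 1, c(tau_hi, tau_next),
                  f.lower = f_lo, f.upper = f_next, tol = min(tol, 1e-13))
  tau0 <- root$root
  lam <- dominant_eigenvalue(char_poly(params, alpha, tau0, grid, kind))
  if (abs(Im(lam)) < 1e-8)
    stop("flip crossing: dominant eigenvalue crosses the unit circle on the ",
         "real axis; not a Neimark-Sacker point", call. = FALSE)
  omega0 <- Arg(lam)
  trans <- if (kind == "nsfd") {
    ns_transversality_closed(params, alpha, tau0, grid, omega0)
  } else {
    eigen_modulus_derivative(params, alpha, grid, kind, tau0, lam)
  }
  structure(
    list(tau0 = tau0, omega0 = omega0, crossing_eigenvalue = lam,
         transversality = trans, k_index = 0L,
         kind = kind, m = grid$m, h = grid$h, alpha = alpha, params = params),
    class = "critical_point"
  )
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("Neimark-Sacker point (%s, alpha = %g, h = 1/%d)\n",
              x$kind, x$alpha, x$m))
  cat(sprintf("  tau0 = %.6f, omega0 = %.6f, |lambda| = %.10f\n",
              x$tau0, x$omega0, Mod(x$crossing_eigenvalue)))
  cat(sprintf("  d(r^2)/dtau = %.6f\n", x$transversality))
  invisible(x)
}

# closed-form d(r^2)/dtau at an NSFD unit-circle crossing
ns_transversality_closed <- function(params, alpha, tau, grid, omega) {
  ac <- alpha * params$c
  E <- exp(-ac * tau * grid$h)
  m <- grid$m
  num <- 2 * ac * grid$h * E * (m + 1 + m * E) * (1 - cos(omega))
  den <- (1 - E) *
    (((m + 1) * cos(omega) - m * E)^2 + ((m + 1) * sin(omega))^2)
  num / den
}

# two-sided finite difference of the dominant-pair modulus squared in tau,
# tracking the eigenvalue closest to `lam`
eigen_modulus_derivative <- function(params, alpha, grid, kind, tau0, lam,
                                     step = 1e-5) {
  track <- function(tau) {
    ev <- poly_eigenvalues(char_poly(params, alpha, tau, grid, kind))
    ev[which.min(Mod(ev - lam))]
  }
  (Mod(track(tau0 + step))^2 - Mod(track(tau0 - step))^2) / (2 * step)
}

#' Crossing speed of the discrete eigenpair: closed form vs finite difference
#'
#' Independently re-estimates the transversality derivative
#' \eqn{dr^2/d\tau} at a computed Neimark-Sacker point by a two-sided finite
#' difference on the tracked dominant eigenvalue, and (NSFD only) compares it
#' with the closed form.
#'
#' @param cp a `critical_point` from [critical_tau()].
#' @param step finite-difference step (default 1e-5).
#' @return list with `finite_difference`, `closed_form` (`NA` for Euler), and
#'   `rel_error` (`NA` for Euler).
#' @export
eigen_derivative_check <- function(cp, step = 1e-5) {
  stopifnot(inherits(cp, "critical_point"))
  grid <- step_grid(cp$m)
  fd <- eigen_modulus_derivative(cp$params, cp$alpha, grid, cp$kind,
                                 cp$tau0, cp$crossing_eigenvalue, step = step)
  if (cp$kind == "nsfd") {
    cf <- ns_transversality_closed(cp$params, cp$alpha, cp$tau0, grid,
                                   cp$omega0)
    list(finite_difference = fd, closed_form = cf,
         rel_error = abs(cf - fd) / abs(cf))
  } else {
    list(finite_difference = fd, closed_form = NA_real_, rel_error = NA_real_)
  }
}

#' Candidate crossing angle of the NSFD scheme at a given delay
#'
#' For the NSFD trinomial, a root on the unit circle at angle \eqn{\omega}
#' requires
#' \deqn{\cos\omega = 1 + \frac{(1-E)^2 (b u^* - L)(2 + L - b u^*)}{2E},
#'   \quad E = e^{-\alpha c \tau h},\ L = \frac{1-\alpha}{\alpha c}.}
#' In the stable-for-all-delay regime the right-hand side exceeds 1 for every
#' \eqn{\tau > 0} (no unit-modulus root can exist); in the conditionally
#' stable regime it lies in \eqn{(-1, 1)} and the principal arccos gives the
#' crossing angle. The branch shift `2*pi*k` enumerates the at most
#' `floor((m-1)/2)` further candidate angles.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param tau delay (positive).
#' @param grid a [step_grid()].
#' @param k branch index, `0 <= k <= floor((m-1)/2)` (default 0).
#' @return the angle \eqn{\omega_k} (radians).
#' @export
crossing_angle <- function(params, alpha, tau, grid, k = 0L) {
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"),
            tau > 0, k >= 0)
  check_alpha(alpha)
  if (k > floor((grid$m - 1) / 2))
    stop("branch index k exceeds floor((m-1)/2)", call. = FALSE)
  ac <- alpha * params$c
  L <- (1 - alpha) / ac
  bu <- params$b_u_star
  E <- exp(-ac * tau * grid$h)
  rhs <- 1 + (1 - E)^2 * (bu - L) * (2 + L - bu) / (2 * E)
  if (abs(rhs) > 1)
    stop(sprintf("no real angle: cos(omega) = %.6f is outside [-1, 1]", rhs),
         call. = FALSE)
  acos(rhs) + 2 * pi * k
}

#' Departure slope of the unit root at zero delay
#'
#' At \eqn{\tau = 0} the characteristic trinomial of the NSFD scheme has an
#' m-fold root 0 and a simple root 1. The slope of \eqn{|\lambda|^2} in
#' \eqn{\tau} on the root branch leaving \eqn{\lambda = 1} is the closed form
#' \eqn{2h(1 - \alpha - b u^* \alpha c)}: negative whenever
#' \eqn{b u^* > (1-\alpha)/(\alpha c)}, so the root moves into the unit disk
#' and the fixed point is stable for all sufficiently small delays.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param grid a [step_grid()].
#' @return the slope \eqn{d|\lambda|^2/d\tau} at \eqn{\tau = 0^+}.
#' @export
unit_root_slope <- function(params, alpha, grid) {
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"))
  check_alpha(alpha)
  2 * grid$h * (1 - alpha - params$b_u_star * alpha * params$c)
}
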