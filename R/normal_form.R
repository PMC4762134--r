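#' Right and adjoint eigenvectors at a unit-circle crossing
#'
#' For the companion matrix \eqn{\tilde A} of the trinomial
#' \eqn{\lambda^{m+1} - \tilde a_0 \lambda^m - \tilde a_1}, the right
#' eigenvector belonging to a root \eqn{\lambda_0 = e^{i\omega_0}} is the
#' Vandermonde-type vector
#' \eqn{q = (e^{i m \omega_0}, e^{i(m-1)\omega_0}, \ldots, e^{i\omega_0}, 1)^T},
#' and the adjoint eigenvector (of \eqn{\tilde A^T}, eigenvalue
#' \eqn{\bar\lambda_0}) normalized so that
#' \eqn{\langle q^*, q\rangle = \sum_i \bar q^*_i q_i = 1} is
#' \eqn{q^* = \bar K (1, \tilde a_1 e^{i m\omega_0}, \ldots,
#' \tilde a_1 e^{i\omega_0})^T} with
#' \eqn{K = [e^{i m \omega_0} + m \tilde a_1 e^{-i\omega_0}]^{-1}}.
#'
#' @param poly a [char_poly()] object whose trinomial has \eqn{e^{i\omega_0}}
#'   as a root (residual below `root_tol`).
#' @param omega0 crossing angle in \eqn{(0, \pi)}.
#' @param root_tol residual tolerance for accepting `omega0` as a root angle
#'   (default 1e-8).
#' @return object of class `eigen_pair`: list with complex vectors `q`,
#'   `q_star` (length `m + 1`), the normalization constant `K`, and
#'   `lambda0 = exp(1i * omega0)`.
#' @export
eigen_pair <- function(poly, omega0, root_tol = 1e-8) {
  stopifnot(inherits(poly, "char_poly"), is.numeric(omega0),
            length(omega0) == 1L)
  lam0 <- exp(1i * omega0)
  resid <- Mod(poly_value(poly, lam0))
  if (resid > root_tol)
    stop(sprintf("exp(1i*omega0) is not a root of the trinomial (residual %.2e)",
                 resid), call. = FALSE)
  m <- poly$m
  a1 <- poly$a1_tilde
  q <- exp(1i * omega0 * (m:0))
  K <- 1 / (exp(1i * m * omega0) + m * a1 * exp(-1i * omega0))
  q_star <- Conj(K) * c(1, a1 * exp(1i * omega0 * (m:1)))
  structure(list(q = q, q_star = q_star, K = K, lambda0 = lam0, m = m),
            class = "eigen_pair")
}

# <x, y> = sum conj(x_i) y_i
cplx_inner <- function(x, y) sum(Conj(x) * y)

# Taylor coefficients of the scalar NSFD update's nonlinearity at v = 0:
# quadratic b~ = (1-E)(b^2 u* - 2b), cubic c~ = (1-E)(3 b^2 - b^3 u*)
nsfd_taylor_coeffs <- function(params, alpha, tau, grid) {
  E <- exp(-alpha * params$c * tau * grid$h)
  b <- params$b
  u <- params$u_star
  list(b_tilde = (1 - E) * (b^2 * u - 2 * b),
       c_tilde = (1 - E) * (3 * b^2 - b^3 * u))
}

#' Multilinear forms of the NSFD map at the equilibrium
#'
#' The second- and third-order terms of the NSFD map act only through the
#' delayed (last) coordinate of the state stack: with
#' \eqn{\tilde b = (1-E)(b^2 u^* - 2b)} and
#' \eqn{\tilde c = (1-E)(3b^2 - b^3 u^*)}, the symmetric forms are
#' \eqn{b_0(\phi, \psi) = \tilde b\, \phi_m \psi_m} and
#' \eqn{c_0(\phi, \psi, \chi) = \tilde c\, \phi_m \psi_m \chi_m}
#' (the off-diagonal extension of the diagonal forms is forced by symmetry of
#' the derivatives). The vector-valued forms `B`, `C` place these scalars in
#' the first coordinate and zeros elsewhere.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param tau delay (positive).
#' @param grid a [step_grid()].
#' @param phi,psi,chi complex vectors of length `m + 1`; `chi` may be omitted.
#' @return list with scalars `b0` (and `c0` when `chi` is supplied), the
#'   coefficients `b_tilde`, `c_tilde`, and the vector-valued `B(phi, psi)`
#'   (and `C(phi, psi, chi)`).
#' @export
multilinear_forms <- function(params, alpha, tau, grid, phi, psi,
                              chi = NULL) {
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"),
            length(phi) == grid$m + 1L, length(psi) == grid$m + 1L)
  tc <- nsfd_taylor_coeffs(params, alpha, tau, grid)
  last <- grid$m + 1L
  b0 <- tc$b_tilde * phi[last] * psi[last]
  Bvec <- c(b0, rep(0 + 0i, grid$m))
  out <- list(b0 = b0, B = Bvec,
              b_tilde = tc$b_tilde, c_tilde = tc$c_tilde)
  if (!is.null(chi)) {
    stopifnot(length(chi) == grid$m + 1L)
    c0 <- tc$c_tilde * phi[last] * psi[last] * chi[last]
    out$c0 <- c0
    out$C <- c(c0, rep(0 + 0i, grid$m))
  }
  out
}

#' Normal-form coefficient and bifurcation classification (NSFD scheme)
#'
#' Computes, at the Neimark-Sacker point \eqn{\tau_0} of the NSFD scheme, the
#' center-manifold normal-form data of the map: the projected quadratic
#' coefficients \eqn{g_{20}, g_{11}, g_{02}}, the second-order
#' center-manifold correction vectors \eqn{w_{20}, w_{11}}, the mixed cubic
#' coefficient \eqn{g_{21}}, and the critical coefficient
#' \deqn{c_1(\tau_0) = \frac{g_{20} g_{11} (1 - 2\lambda_0)}
#'   {2(\lambda_0^2 - \lambda_0)} + \frac{|g_{11}|^2}{1 - \bar\lambda_0}
#'   + \frac{|g_{02}|^2}{2(\lambda_0^2 - \bar\lambda_0)} + \frac{g_{21}}{2},}
#' together with its closed form
#' \eqn{c_1(\tau_0) = \frac{K}{2}\bigl(\tilde b^2 / a(\lambda_0^2)
#' + 2 \tilde b^2 / a(1) + \tilde c\bigr)} (an exact simplification: the
#' projection terms cancel because the last coordinate of \eqn{q} is 1).
#' The bifurcating invariant closed curve for \eqn{\tau > \tau_0} is
#' attracting iff \eqn{\Re[e^{-i\omega_0} c_1(\tau_0)] < 0} (supercritical),
#' repelling if positive.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param grid a [step_grid()].
#' @param cp optionally, a precomputed `critical_point` from [critical_tau()]
#'   (must be NSFD); computed if omitted.
#' @param resonance_tol divisions by \eqn{\lambda_0^2 - \lambda_0},
#'   \eqn{1 - \lambda_0}, \eqn{a(\lambda_0^2)} or \eqn{a(1)} with modulus
#'   below this raise a resonance error (default 1e-10).
#' @return object of class `normal_form`: list with `tau0`, `omega0`,
#'   `lambda0`, `b_tilde`, `c_tilde`, `g20`, `g11`, `g02`, `g21`, `w20`,
#'   `w11`, `c1`, `c1_closed`, `stability_indicator`
#'   (\eqn{\Re[e^{-i\omega_0} c_1]}), and `classification` (`"attracting"` or
#'   `"repelling"`).
#' @examples
#' nf <- critical_coefficient(blowfly_params(30, 2, 2), alpha = 1,
#'                            grid = step_grid(2))
#' nf$classification   # "attracting"
#' @export
critical_coefficient <- function(params, alpha, grid, cp = NULL,
                                 resonance_tol = 1e-10) {
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"))
  check_alpha(alpha)
  if (is.null(cp)) cp <- critical_tau(params, alpha, grid, kind = "nsfd")
  stopifnot(inherits(cp, "critical_point"))
  if (cp$kind != "nsfd")
    stop("the normal form is derived for the NSFD scheme only", call. = FALSE)
  tau0 <- cp$tau0
  omega0 <- cp$omega0
  poly <- char_poly(params, alpha, tau0, grid, "nsfd")
  ep <- eigen_pair(poly, omega0)
  q <- ep$q; qs <- ep$q_star; lam0 <- ep$lambda0; K <- ep$K
  m <- grid$m
  a_of <- function(l) poly_value(poly, l)
  denoms <- c(`lambda0^2 - lambda0` = lam0^2 - lam0,
              `1 - lambda0` = 1 - lam0,
              `a(lambda0^2)` = a_of(lam0^2),
              `a(1)` = a_of(1))
  small <- Mod(denoms) < resonance_tol
  if (any(small))
    stop("resonance: ", paste(names(denoms)[small], collapse = ", "),
         " smaller than the tolerance; the normal form is ill-conditioned",
         call. = FALSE)
  Bf <- function(x, y) multilinear_forms(params, alpha, tau0, grid, x, y)$B
  Cf <- function(x, y, z)
    multilinear_forms(params, alpha, tau0, grid, x, y, z)$C
  tc <- nsfd_taylor_coeffs(params, alpha, tau0, grid)
  g20 <- cplx_inner(qs, Bf(q, q))
  g11 <- cplx_inner(qs, Bf(q, Conj(q)))
  g02 <- cplx_inner(qs, Bf(Conj(q), Conj(q)))
  p_of <- function(xi) as.complex(xi)^(m:0)
  b0_qq <- multilinear_forms(params, alpha, tau0, grid, q, q)$b0
  b0_qqb <- multilinear_forms(params, alpha, tau0, grid, q, Conj(q))$b0
  w20 <- b0_qq / a_of(lam0^2) * p_of(lam0^2) -
    g20 / (lam0^2 - lam0) * q -
    cplx_inner(Conj(qs), Bf(q, q)) / (lam0^2 - Conj(lam0)) * Conj(q)
  w11 <- b0_qqb / a_of(1) * p_of(1) -
    g11 / (1 - lam0) * q -
    cplx_inner(Conj(qs), Bf(q, Conj(q))) / (1 - Conj(lam0)) * Conj(q)
  g21 <- cplx_inner(qs, Bf(Conj(q), w20)) +
    2 * cplx_inner(qs, Bf(q, w11)) +
    cplx_inner(qs, Cf(q, q, Conj(q)))
  c1 <- g20 * g11 * (1 - 2 * lam0) / (2 * (lam0^2 - lam0)) +
    Mod(g11)^2 / (1 - Conj(lam0)) +
    Mod(g02)^2 / (2 * (lam0^2 - Conj(lam0))) +
    g21 / 2
  c1_closed <- K / 2 * (tc$b_tilde^2 / a_of(lam0^2) +
                          2 * tc$b_tilde^2 / a_of(1) + tc$c_tilde)
  indicator <- Re(exp(-1i * omega0) * c1)
  structure(
    list(tau0 = tau0, omega0 = omega0, lambda0 = lam0,
         b_tilde = tc$b_tilde, c_tilde = tc$c_tilde,
         g20 = g20, g11 = g11, g02 = g02, g21 = g21,
         w20 = w20, w11 = w11, c1 = c1, c1_closed = c1_closed,
         stability_indicator = indicator,
         classification = if (indicator < 0) "attracting" else "repelling",
         alpha = alpha, m = m, h = grid$h, params = params),
    class = "normal_form"
  )
}

#' @export
print.normal_form <- function(x, ...) {
  cat(sprintf("Normal form at the Neimark-Sacker point (NSFD, alpha = %g, h = 1/%d)\n",
              x$alpha, x$m))
  cat(sprintf("  tau0 = %.6f, omega0 = %.6f\n", x$tau0, x$omega0))
  cat(sprintf("  c1 = %.6f %+.6fi   (closed form: %.6f %+.6fi)\n",
              Re(x$c1), Im(x$c1), Re(x$c1_closed), Im(x$c1_closed)))
  cat(sprintf("  Re[e^{-i omega0} c1] = %.6f  ->  %s invariant curve\n",
              x$stability_indicator, x$classification))
  invisible(x)
}
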