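#' Model parameters for the delayed blowflies equation
#'
#' Bundles the three biological rates of the Nicholson's blowflies equation
#' \deqn{x'(t) = a\, x(t-\tau) e^{-b x(t-\tau)} - c\, x(t)}
#' and precomputes the positive equilibrium \eqn{u^* = (1/b)\ln(a/c)}.
#'
#' @param a maximum per-capita daily egg production rate (1/day), `a > 0`.
#' @param b inverse of the population size at which reproduction is maximal,
#'   `b > 0`.
#' @param c per-capita daily adult death rate (1/day), `c > 0`. A positive
#'   equilibrium requires `a > c`.
#'
#' @return An object of class `blowfly_params`: a list with elements `a`,
#'   `b`, `c`, the equilibrium `u_star`, and the product `b_u_star = b * u_star`
#'   that governs every stability threshold.
#'
#' @examples
#' p <- blowfly_params(a = 30, b = 2, c = 2)
#' p$u_star   # 1.354...
#' @export
blowfly_params <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L,
            is.finite(a), is.finite(b), is.finite(c))
  if (a <= 0 || b <= 0 || c <= 0)
    stop("all of a, b, c must be positive", call. = FALSE)
  if (a <= c)
    stop("a > c is required for a positive equilibrium (ln(a/c) > 0)",
         call. = FALSE)
  u_star <- log(a / c) / b
  structure(
    list(a = a, b = b, c = c, u_star = u_star, b_u_star = b * u_star),
    class = "blowfly_params"
  )
}

#' @export
print.blowfly_params <- function(x, ...) {
  cat("Blowflies model parameters\n")
  cat(sprintf("  a = %g, b = %g, c = %g\n", x$a, x$b, x$c))
  cat(sprintf("  equilibrium u* = %.6f  (b u* = %.6f)\n", x$u_star, x$b_u_star))
  invisible(x)
}

#' Positive equilibrium of the blowflies equation
#'
#' Returns \eqn{u^* = (1/b)\ln(a/c)}, the unique positive equilibrium, which
#' satisfies the fixed-point identity \eqn{c = a e^{-b u^*}}.
#'
#' @param params a [blowfly_params()] object.
#' @return the equilibrium population size (positive scalar).
#' @examples
#' equilibrium(blowfly_params(30, 2, 2))
#' @export
equilibrium <- function(params) {
  stopifnot(inherits(params, "blowfly_params"))
  params$u_star
}

check_alpha <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0 || alpha > 1)
    stop("control gain alpha must lie in (0, 1]", call. = FALSE)
  alpha
}

#' Stability regime of the hybrid-controlled equilibrium
#'
#' The hybrid control law scales the vector field by a gain
#' \eqn{\alpha \in (0,1]} and adds delayed state feedback
#' \eqn{(1-\alpha)\tau(u(t-1) - u^*)}; the equilibrium is unchanged but the
#' stability boundary moves. With \eqn{L = (1-\alpha)/(\alpha c)}, the theory
#' distinguishes:
#' \itemize{
#'   \item `stable_all_tau`: \eqn{L < b u^* < 2 + L} — the equilibrium is
#'     asymptotically stable for every delay (continuous system and any
#'     step-size discretization alike);
#'   \item `conditional_stability`: \eqn{b u^* > 2 + L} — stable only below a
#'     critical delay, with a Hopf (Neimark-Sacker) bifurcation at the
#'     crossing;
#'   \item `out_of_theory`: \eqn{b u^* \le L} or equality with either
#'     threshold — the theorems make no claim (strict inequalities).
#' }
#' At `alpha = 1` (uncontrolled system) the thresholds reduce to 0 and 2.
#'
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @return An object of class `regime_verdict`: list with `regime`,
#'   `lower_threshold`, `upper_threshold`, and `b_u_star`.
#' @examples
#' classify_regime(blowfly_params(30, 2, 2), alpha = 1)    # conditional
#' classify_regime(blowfly_params(30, 2, 2), alpha = 0.4)  # stable for all tau
#' @export
classify_regime <- function(params, alpha) {
  stopifnot(inherits(params, "blowfly_params"))
  check_alpha(alpha)
  lower <- (1 - alpha) / (alpha * params$c)
  upper <- 2 + lower
  bu <- params$b_u_star
  regime <- if (bu > lower && bu < upper) {
    "stable_all_tau"
  } else if (bu > upper) {
    "conditional_stability"
  } else {
    "out_of_theory"
  }
  structure(
    list(regime = regime, lower_threshold = lower, upper_threshold = upper,
         b_u_star = bu, alpha = alpha),
    class = "regime_verdict"
  )
}

#' @export
print.regime_verdict <- function(x, ...) {
  cat(sprintf("Regime: %s\n", x$regime))
  cat(sprintf("  b u* = %.6f, thresholds (%.6f, %.6f), alpha = %g\n",
              x$b_u_star, x$lower_threshold, x$upper_threshold, x$alpha))
  invisible(x)
}
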