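#' Uniform step grid resolving the unit delay
#'
#' Both discretizations work in scaled time, where the delay spans exactly one
#' time unit; the step-size is constrained to `h = 1/m` so that the delayed
#' state is `m` steps back on the grid.
#'
#' @param m delay resolution, positive integer.
#' @return object of class `step_grid`: list with `m` and `h = 1/m`.
#' @export
step_grid <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (m < 1 || m != round(m))
    stop("m must be a positive integer (step-size h = 1/m)", call. = FALSE)
  m <- as.integer(m)
  structure(list(m = m, h = 1 / m), class = "step_grid")
}

#' Discretization specification
#'
#' Identifies one of the two hybrid-control discretizations and its
#' denominator function:
#' \itemize{
#'   \item `"nsfd"` — nonstandard finite-difference scheme with denominator
#'     \eqn{\psi(h) = (1 - e^{-\alpha c \tau h})/(\alpha c \tau)}, chosen so
#'     the linear decay subproblem \eqn{v' = -\alpha c \tau v} is solved
#'     exactly; \eqn{\psi(h) = h + O(h^2)}.
#'   \item `"euler"` — forward Euler, denominator \eqn{h}.
#' }
#'
#' @param kind `"nsfd"` or `"euler"`.
#' @param grid a [step_grid()].
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param tau delay (positive).
#' @return object of class `scheme_spec` with `kind`, `grid`, `denominator`,
#'   and the model context.
#' @export
scheme_spec <- function(kind = c("nsfd", "euler"), grid, params, alpha, tau) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "step_grid"), inherits(params, "blowfly_params"),
            is.numeric(tau), length(tau) == 1L, tau > 0)
  check_alpha(alpha)
  denom <- if (kind == "nsfd") {
    act <- alpha * params$c * tau
    (1 - exp(-act * grid$h)) / act
  } else {
    grid$h
  }
  structure(
    list(kind = kind, grid = grid, denominator = denom,
         params = params, alpha = alpha, tau = tau),
    class = "scheme_spec"
  )
}

divergence_check <- function(v, bound = 1e6, what = "state") {
  if (!is.finite(v) || abs(v) > bound)
    stop(structure(
      class = c("blowflyNS_divergence", "error", "condition"),
      list(message = sprintf("trajectory diverged: |%s| exceeded %g", what, bound),
           call = NULL)))
  v
}

#' One step of the hybrid-control NSFD map
#'
#' Advances the deviation coordinate \eqn{v = u - u^*} by
#' \deqn{v_{n+1} = E v_n + (E - 1)u^* + (1-E)(v_{n-m} + u^*) e^{-b v_{n-m}}
#'       + \frac{(1-E)(1-\alpha)}{\alpha c} v_{n-m},}
#' with \eqn{E = e^{-\alpha c \tau h}}. The equilibrium \eqn{v \equiv 0} is an
#' exact fixed point for every parameter value.
#'
#' @param v_now current deviation \eqn{v_n}.
#' @param v_delayed delayed deviation \eqn{v_{n-m}}.
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param tau delay (positive).
#' @param grid a [step_grid()].
#' @param bound divergence guard on the inputs/output (default 1e6); exceeding
#'   it raises an error of class `blowflyNS_divergence` rather than silently
#'   returning an overflowing value.
#' @return next deviation \eqn{v_{n+1}}.
#' @export
nsfd_step <- function(v_now, v_delayed, params, alpha, tau, grid,
                      bound = 1e6) {
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"),
            tau > 0)
  check_alpha(alpha)
  divergence_check(v_now, bound, "v_n")
  divergence_check(v_delayed, bound, "v_{n-m}")
  E <- exp(-alpha * params$c * tau * grid$h)
  u <- params$u_star
  out <- E * v_now + (E - 1) * u +
    (1 - E) * (v_delayed + u) * exp(-params$b * v_delayed) +
    (1 - E) * (1 - alpha) / (alpha * params$c) * v_delayed
  divergence_check(out, bound, "v_{n+1}")
}

#' One step of the hybrid-control Euler map
#'
#' Advances the deviation coordinate by the forward Euler discretization
#' \deqn{v_{n+1} = v_n + \alpha\tau h\,[a(v_{n-m}+u^*)e^{-b(v_{n-m}+u^*)}
#'       - c(v_n + u^*)] + (1-\alpha)\tau h\, v_{n-m}.}
#'
#' @inheritParams nsfd_step
#' @return next deviation \eqn{v_{n+1}}.
#' @export
euler_step <- function(v_now, v_delayed, params, alpha, tau, grid,
                       bound = 1e6) {
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"),
            tau > 0)
  check_alpha(alpha)
  divergence_check(v_now, bound, "v_n")
  divergence_check(v_delayed, bound, "v_{n-m}")
  u <- params$u_star
  out <- v_now + alpha * tau * grid$h *
    (params$a * (v_delayed + u) * exp(-params$b * (v_delayed + u)) -
       params$c * (v_now + u)) +
    (1 - alpha) * tau * grid$h * v_delayed
  divergence_check(out, bound, "v_{n+1}")
}

#' Simulate a hybrid-control discretization
#'
#' Iterates the NSFD or Euler step map from an initial history segment. The
#' method is fully deterministic. Trajectories are produced in scaled time
#' (delay = 1, step `h = 1/m`).
#'
#' @param kind `"nsfd"` or `"euler"`.
#' @param params a [blowfly_params()] object.
#' @param alpha hybrid control gain in (0, 1].
#' @param tau delay (positive).
#' @param grid a [step_grid()].
#' @param n_steps number of steps to take beyond the history (default 4000).
#' @param history numeric vector of length `m + 1` giving
#'   \eqn{v_{-m}, \ldots, v_0} in deviation coordinates \eqn{v = u - u^*};
#'   default is the constant history `eta`.
#' @param eta constant history level used when `history` is `NULL`
#'   (default 0.1, i.e. \eqn{u \equiv u^* + 0.1} on \eqn{[-1, 0]}).
#' @param bound divergence guard (default 1e6). If the state exceeds it the
#'   trajectory is truncated and flagged `diverged = TRUE`.
#' @return object of class `trajectory`: list with `kind`, `m`, `h`, `alpha`,
#'   `tau`, `history`, `v` (the steps \eqn{v_1 \ldots v_N}, possibly truncated
#'   on divergence), `n_steps`, `diverged`, `params`.
#' @examples
#' p <- blowfly_params(30, 2, 2)
#' tr <- simulate_scheme("nsfd", p, alpha = 1, tau = 0.5, grid = step_grid(2),
#'                       n_steps = 2000)
#' classify_trajectory(tr)   # "converges"
#' @export
simulate_scheme <- function(kind = c("nsfd", "euler"), params, alpha, tau,
                            grid, n_steps = 4000L, history = NULL, eta = 0.1,
                            bound = 1e6) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "blowfly_params"), inherits(grid, "step_grid"),
            n_steps >= 1)
  m <- grid$m
  if (is.null(history)) history <- rep(eta, m + 1L)
  if (length(history) != m + 1L || !all(is.finite(history)))
    stop("history must be a finite numeric vector of length m + 1",
         call. = FALSE)
  step_fun <- if (kind == "nsfd") nsfd_step else euler_step
  # buffer holds v_{n-m} .. v_n; index 1 is the delayed value
  buf <- history
  v <- numeric(n_steps)
  diverged <- FALSE
  n_done <- 0L
  for (n in seq_len(n_steps)) {
    nxt <- tryCatch(
      step_fun(buf[m + 1L], buf[1L], params, alpha, tau, grid, bound = bound),
      blowflyNS_divergence = function(e) NA_real_
    )
    if (is.na(nxt)) { diverged <- TRUE; break }
    buf <- c(buf[-1L], nxt)
    v[n] <- nxt
    n_done <- n
  }
  structure(
    list(kind = kind, m = m, h = grid$h, alpha = alpha, tau = tau,
         history = history, v = v[seq_len(n_done)], n_steps = n_done,
         diverged = diverged, params = params),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: m = %d, alpha = %g, tau = %g, %d steps%s\n",
              x$kind, x$m, x$alpha, x$tau, x$n_steps,
              if (x$diverged) " (DIVERGED)" else ""))
  cat(sprintf("  verdict: %s\n", classify_trajectory(x)))
  invisible(x)
}

#' @describeIn simulate_scheme convert a trajectory to a data frame with
#'   columns `n` (step index, from `-m` through `n_steps`), `t_scaled`
#'   (`n * h`), and `u` (population, `v + u_star`).
#' @param x a `trajectory`.
#' @param ... unused.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  n <- seq.int(-x$m, x$n_steps)
  data.frame(n = n, t_scaled = n * x$h,
             u = c(x$history, x$v) + x$params$u_star)
}

#' Write a trajectory to CSV
#'
#' Comma-separated, `.` decimal, header row, LF line endings; one row per grid
#' point including the history segment (`n` from `-m`). Columns
#' `n,t_scaled,u`; with `original_time = TRUE` an extra column `t = t_scaled *
#' tau` (original time units) is appended.
#'
#' @param traj a `trajectory` from [simulate_scheme()].
#' @param file output path.
#' @param original_time also emit original-time stamps (default `FALSE`).
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, file, original_time = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  df <- as.data.frame(traj)
  if (original_time) df$t <- df$t_scaled * traj$tau
  con <- file(file, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(file)
}

#' Qualitative verdict on a simulated trajectory
#'
#' Classifies the long-run behavior from the tail of the trajectory (by
#' default the last 10% of steps): `"diverges"` if the divergence guard
#' tripped, `"converges"` if the maximal tail deviation from the equilibrium
#' is below `conv_tol`, `"oscillates"` if it exceeds `osc_tol` (sustained
#' motion on an invariant curve), `"indeterminate"` in the gap between the
#' two tolerances (transient not yet resolved).
#'
#' @param traj a `trajectory`.
#' @param tail_frac fraction of the steps used as the stationary tail
#'   (default 0.1).
#' @param conv_tol convergence tolerance on `|v|` (default 1e-3).
#' @param osc_tol sustained-oscillation threshold on `|v|` (default 1e-2).
#' @return one of `"converges"`, `"oscillates"`, `"diverges"`,
#'   `"indeterminate"`.
#' @export
classify_trajectory <- function(traj, tail_frac = 0.1, conv_tol = 1e-3,
                                osc_tol = 1e-2) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$diverged) return("diverges")
  n <- traj$n_steps
  tail_n <- max(1L, ceiling(tail_frac * n))
  amp <- max(abs(traj$v[(n - tail_n + 1L):n]))
  if (amp < conv_tol) "converges"
  else if (amp > osc_tol) "oscillates"
  else "indeterminate"
}
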