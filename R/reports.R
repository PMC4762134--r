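#' Published reference values of the critical delay
#'
#' Tabulated critical delays \eqn{\tau_0} (4 decimals) for the standard test
#' parameters `a = 30, b = 2, c = 2`, for both hybrid-control schemes at the
#' gains \eqn{\alpha \in \{1, 0.9, 0.6\}} and step-sizes
#' \eqn{h \in \{1, 1/2\}}. These are the values against which
#' [reproduce_tables()] checks the spectral-radius pipeline.
#'
#' @return data frame with columns `scheme`, `alpha`, `h`, `tau0_ref`.
#' @export
reference_tau0 <- function() {
  data.frame(
    scheme = rep(c("nsfd", "euler"), each = 6L),
    alpha = rep(c(1, 1, 0.9, 0.9, 0.6, 0.6), 2L),
    h = rep(c(1, 0.5), 6L),
    tau0_ref = c(0.4403, 0.5891, 0.5162, 0.6938, 1.0832, 1.5058,
                 0.2927, 0.4452, 0.3362, 0.5160, 0.6062, 0.9914)
  )
}

#' Reproduce the reference critical-delay tables
#'
#' Runs the spectral-radius bisection pipeline ([critical_tau()]) over a grid
#' of (scheme, gain, step-size) configurations and compares each computed
#' \eqn{\tau_0} with the published reference value where one exists.
#'
#' @param params a [blowfly_params()] object (default the standard test
#'   parameters `a = 30, b = 2, c = 2`).
#' @param alphas control gains to cover (default `c(1, 0.9, 0.6)`).
#' @param step_sizes step-sizes, each of the form `1/m` (default `c(1, 0.5)`).
#' @param schemes schemes to cover (default both).
#' @param tol tolerance on `abs_error` for the `pass` flag (default 5e-4,
#'   i.e. agreement at 4-decimal print precision).
#' @return data frame with columns `scheme`, `alpha`, `h`, `status`
#'   (`"ok"` or `"no crossing"`), `tau0_computed`, `tau0_ref`, `abs_error`,
#'   `pass`. Reference columns are `NA` for configurations outside the
#'   published grid; `pass` is `NA` there too.
#' @examples
#' \donttest{
#' tab <- reproduce_tables()
#' all(tab$pass)   # TRUE
#' }
#' @export
reproduce_tables <- function(params = blowfly_params(30, 2, 2),
                             alphas = c(1, 0.9, 0.6),
                             step_sizes = c(1, 0.5),
                             schemes = c("nsfd", "euler"),
                             tol = 5e-4) {
  stopifnot(inherits(params, "blowfly_params"))
  grid_ok <- abs(1 / step_sizes - round(1 / step_sizes)) < 1e-12
  if (!all(grid_ok))
    stop("every step-size must be 1/m for a positive integer m", call. = FALSE)
  ref <- reference_tau0()
  rows <- expand.grid(scheme = schemes, alpha = alphas, h = step_sizes,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    sc <- rows$scheme[i]; al <- rows$alpha[i]; h <- rows$h[i]
    g <- step_grid(round(1 / h))
    tau0 <- tryCatch(critical_tau(params, al, g, kind = sc)$tau0,
                     error = function(e) NA_real_)
    status <- if (is.na(tau0)) "no crossing" else "ok"
    hit <- ref$scheme == sc & abs(ref$alpha - al) < 1e-12 &
      abs(ref$h - h) < 1e-12
    t_ref <- if (any(hit)) ref$tau0_ref[hit] else NA_real_
    err <- abs(tau0 - t_ref)
    data.frame(scheme = sc, alpha = al, h = h, status = status,
               tau0_computed = tau0, tau0_ref = t_ref, abs_error = err,
               pass = if (is.na(t_ref)) NA else isTRUE(err <= tol))
  })
  do.call(rbind, out)
}

#' Standard qualitative simulation grid
#'
#' The twelve (scheme, gain, step-size, delay) configurations used to
#' exercise both schemes just below and just above their critical delays at
#' `h = 1/2`: for each scheme and each gain in `{1, 0.9, 0.6}` one
#' sub-critical and one super-critical delay.
#'
#' @return data frame with columns `scheme`, `alpha`, `h`, `tau`, `expected`
#'   (`"converges"` below the critical delay, `"oscillates"` above).
#' @export
figure_grid <- function() {
  data.frame(
    scheme = rep(c("nsfd", "euler"), each = 6L),
    alpha = rep(rep(c(1, 0.9, 0.6), each = 2L), 2L),
    h = 0.5,
    tau = c(0.5, 0.6, 0.6, 0.8, 1, 1.6,     # nsfd
            0.4, 0.5, 0.5, 0.6, 0.9, 1),    # euler
    expected = rep(c("converges", "oscillates"), 6L)
  )
}

#' Run the qualitative trajectory experiments
#'
#' Simulates every configuration of a grid (default [figure_grid()]) and
#' classifies the long-run behavior with [classify_trajectory()]. Optionally
#' writes each trajectory to a CSV in `out_dir` (file name
#' `<scheme>_alpha<alpha>_h<h>_tau<tau>.csv`).
#'
#' @param config data frame with columns `scheme`, `alpha`, `h`, `tau`
#'   (and optionally `expected`); default [figure_grid()].
#' @param params a [blowfly_params()] object (default `a=30, b=2, c=2`).
#' @param n_steps steps per simulation (default 4000).
#' @param eta constant-history perturbation (default 0.1).
#' @param out_dir directory for trajectory CSVs, or `NULL` (default) to skip
#'   writing.
#' @return the config data frame with extra columns `tau0` (computed critical
#'   delay), `verdict`, and `agrees` (`NA` if the config has no `expected`).
#' @export
run_figure_experiment <- function(config = figure_grid(),
                                  params = blowfly_params(30, 2, 2),
                                  n_steps = 4000L, eta = 0.1,
                                  out_dir = NULL) {
  stopifnot(all(c("scheme", "alpha", "h", "tau") %in% names(config)))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  config$tau0 <- NA_real_
  config$verdict <- NA_character_
  for (i in seq_len(nrow(config))) {
    g <- step_grid(round(1 / config$h[i]))
    config$tau0[i] <- tryCatch(
      critical_tau(params, config$alpha[i], g, kind = config$scheme[i])$tau0,
      error = function(e) NA_real_)
    tr <- simulate_scheme(config$scheme[i], params, config$alpha[i],
                          config$tau[i], g, n_steps = n_steps, eta = eta)
    config$verdict[i] <- classify_trajectory(tr)
    if (!is.null(out_dir)) {
      fn <- sprintf("%s_alpha%g_h%g_tau%g.csv", config$scheme[i],
                    config$alpha[i], config$h[i], config$tau[i])
      write_trajectory_csv(tr, file.path(out_dir, fn))
    }
  }
  config$agrees <- if ("expected" %in% names(config))
    config$verdict == config$expected else NA
  config
}

# ---- JSON report serialization ------------------------------------------

cplx_json <- function(z) c(Re(z), Im(z))

#' Serialize an analysis result to JSON
#'
#' Produces the compact JSON report for the continuous Hopf analysis, a
#' discrete critical point, or a normal-form result.
#'
#' @param x a `cont_hopf`, `critical_point`, or `normal_form` object.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  rep <- if (inherits(x, "cont_hopf")) {
    list(beta = x$beta, angular_rate = x$angular_rate, theta0 = x$theta0,
         tau_k = x$tau_k, transversality = x$transversality)
  } else if (inherits(x, "critical_point")) {
    list(scheme = x$kind, alpha = x$alpha, h = x$h, m = x$m,
         tau0 = x$tau0, omega0 = x$omega0,
         transversality = x$transversality,
         crossing_eigenvalue = cplx_json(x$crossing_eigenvalue))
  } else if (inherits(x, "normal_form")) {
    list(tau0 = x$tau0, omega0 = x$omega0,
         g20 = cplx_json(x$g20), g11 = cplx_json(x$g11),
         g02 = cplx_json(x$g02), g21 = cplx_json(x$g21),
         c1 = cplx_json(x$c1), c1_closed = cplx_json(x$c1_closed),
         stability_indicator = x$stability_indicator,
         classification = x$classification)
  } else {
    stop("no JSON report defined for class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
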