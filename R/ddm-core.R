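#' Scaled parameters of the pure drift diffusion model
#'
#' Container for one trial's scaled diffusion parameters. In the scaled
#' parameterization the threshold and initial condition are divided by the
#' drift rate (so both carry units of seconds) and the drift enters only
#' through the squared signal-to-noise rate `mu_tilde = (mu/sigma)^2`
#' (units 1/seconds).
#'
#' @param mu_tilde Scaled drift (squared signal-to-noise rate, 1/s); must be
#'   positive. The drift convention is positive toward the correct boundary.
#' @param z_tilde Scaled threshold (s); must be positive. Boundaries sit at
#'   `+z_tilde` (correct) and `-z_tilde` (error).
#' @param x0_tilde Scaled initial condition (s); must satisfy
#'   `|x0_tilde| < z_tilde` strictly.
#' @param t_nd Non-decision time (s); added to decision times to give
#'   reaction times. Must be non-negative.
#'
#' @return An object of class `ddm_params` (a list with the four fields).
#' @seealso [scale_parameters()] to build one from unscaled quantities,
#'   [first_passage_stats()] for the closed-form statistics.
#' @export
#' @examples
#' p <- ddm_params(mu_tilde = 19.33, z_tilde = 0.05, x0_tilde = 0, t_nd = 0.34)
#' error_rate(p)
ddm_params <- function(mu_tilde, z_tilde, x0_tilde = 0, t_nd = 0) {
  stopifnot(is.numeric(mu_tilde), is.numeric(z_tilde),
            is.numeric(x0_tilde), is.numeric(t_nd))
  if (any(mu_tilde <= 0)) stop("mu_tilde must be positive", call. = FALSE)
  if (any(z_tilde <= 0)) stop("z_tilde must be positive", call. = FALSE)
  if (any(abs(x0_tilde) >= z_tilde))
    stop("|x0_tilde| must be strictly less than z_tilde", call. = FALSE)
  if (any(t_nd < 0)) stop("t_nd must be non-negative", call. = FALSE)
  structure(list(mu_tilde = mu_tilde, z_tilde = z_tilde,
                 x0_tilde = x0_tilde, t_nd = t_nd),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Scaled DDM parameters:\n")
  cat(sprintf("  mu_tilde = %g 1/s, z_tilde = %g s, x0_tilde = %g s, t_nd = %g s\n",
              x$mu_tilde, x$z_tilde, x$x0_tilde, x$t_nd))
  invisible(x)
}

#' Scale raw diffusion parameters
#'
#' Converts the unscaled drift `mu`, noise amplitude `sigma`, threshold `z`
#' and initial evidence `x0` of the diffusion `dx = mu dt + sigma dW` into
#' the scaled parameterization: `z_tilde = z/mu`, `x0_tilde = x0/mu`,
#' `mu_tilde = (mu/sigma)^2`.
#'
#' @param mu Drift rate (evidence per second); positive.
#' @param sigma Noise amplitude; positive.
#' @param z Threshold magnitude (boundaries at `+/-z`); positive.
#' @param x0 Initial evidence; `|x0| < z`.
#' @param t_nd Non-decision time (s), carried through unchanged.
#' @return A [ddm_params()] object.
#' @export
#' @examples
#' scale_parameters(mu = 2, sigma = 1, z = 0.2, x0 = 0.1)
scale_parameters <- function(mu, sigma, z, x0 = 0, t_nd = 0) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (z <= 0) stop("z must be positive", call. = FALSE)
  if (abs(x0) >= z) stop("|x0| must be strictly less than z", call. = FALSE)
  ddm_params(mu_tilde = (mu / sigma)^2, z_tilde = z / mu,
             x0_tilde = x0 / mu, t_nd = t_nd)
}

.as_zxm <- function(p) {
  stopifnot(inherits(p, "ddm_params"))
  list(z = p$z_tilde, x = p$x0_tilde, m = p$mu_tilde)
}

#' Closed-form error rate of the pure DDM
#'
#' Probability that the diffusion is absorbed at the error boundary `-z`
#' before the correct boundary `+z`. Evaluated in a numerically stable form
#' with only non-positive exponents, so large `z_tilde * mu_tilde` does not
#' overflow. A start on a boundary gives exactly 0 (correct boundary) or 1
#' (error boundary); the `ddm_params` constructor forbids that, but the
#' internal evaluator is exact in the limit.
#'
#' @param p A [ddm_params()] object (fields may be equal-length vectors).
#' @return Error probability in `[0, 1]`.
#' @export
error_rate <- function(p) {
  q <- .as_zxm(p)
  n <- max(lengths(q))
  .er_closed_cpp(rep_len(q$z, n), rep_len(q$x, n), rep_len(q$m, n))
}

#' Closed-form mean decision time of the pure DDM
#'
#' Mean first-passage time to either boundary (decision time only; the
#' non-decision time is added by callers that report reaction times).
#'
#' @inheritParams error_rate
#' @return Mean decision time in seconds.
#' @export
mean_decision_time <- function(p) {
  q <- .as_zxm(p)
  n <- max(lengths(q))
  .dt_mean_closed_cpp(rep_len(q$z, n), rep_len(q$x, n), rep_len(q$m, n))
}

#' Conditional mean decision times for correct and error trials
#'
#' With a non-zero starting point the mean decision time differs between
#' trials absorbed at the correct and the error boundary. The closed forms
#' used are the standard absorbing-boundary results
#' `DT_correct = 2 z coth(2 z m) - (z + x0) coth((z + x0) m)` and
#' `DT_error  = 2 z coth(2 z m) - (z - x0) coth((z - x0) m)` (scaled units),
#' which reduce to `z tanh(z m)` at `x0 = 0` and satisfy the law of total
#' expectation with [error_rate()] and [mean_decision_time()].
#'
#' When the error rate is exactly 0 (or 1) the error (correct) mean is
#' undefined and reported as `NA`.
#'
#' @inheritParams error_rate
#' @return A list with numeric components `dt_correct` and `dt_error` (s).
#' @export
conditional_mean_dts <- function(p) {
  q <- .as_zxm(p)
  n <- max(lengths(q))
  out <- .dt_cond_closed_cpp(rep_len(q$z, n), rep_len(q$x, n), rep_len(q$m, n))
  er <- error_rate(p)
  out$dt_error[er <= 0] <- NA_real_
  out$dt_correct[er >= 1] <- NA_real_
  out
}

#' All closed-form first-passage statistics at once
#'
#' @inheritParams error_rate
#' @return A list of class `first_passage_stats` with components `er`,
#'   `dt_mean`, `dt_correct`, `dt_error`.
#' @export
first_passage_stats <- function(p) {
  cond <- conditional_mean_dts(p)
  structure(list(er = error_rate(p),
                 dt_mean = mean_decision_time(p),
                 dt_correct = cond$dt_correct,
                 dt_error = cond$dt_error),
            class = "first_passage_stats")
}

#' Monte-Carlo first-passage oracle (Euler-Maruyama)
#'
#' Brute-force stochastic simulation of `dx = mu dt + sigma dW` from `x0`
#' with absorbing boundaries at `+/-z`, used as an independent numerical
#' check of the closed-form statistics. Each Euler step additionally applies
#' the Brownian-bridge within-step crossing probability for both boundaries,
#' which removes the leading discretization bias of naive thresholding.
#'
#' The step should be small relative to the diffusive scale `(z/sigma)^2`;
#' the default `1e-4` s is adequate for the parameter ranges used here.
#' Paths not absorbed by `horizon` are counted and excluded from the means;
#' more than 0.1% unabsorbed triggers a warning.
#'
#' @param mu,sigma,z,x0 Unscaled diffusion parameters as in
#'   [scale_parameters()].
#' @param step Euler time step in seconds.
#' @param n_paths Number of simulated paths (at least 1e4 recommended).
#' @param horizon Maximum simulated time per path (s); default `200 * z/mu`.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with empirical `er`, `dt_mean`, `dt_correct`, `dt_error`,
#'   their standard errors (`se_*`), counts, and `n_unabsorbed`.
#' @export
#' @examples
#' mc <- mc_first_passage(mu = 2, sigma = 1, z = 0.2, x0 = 0,
#'                        n_paths = 5000, seed = 1)
#' mc$er
mc_first_passage <- function(mu, sigma, z, x0 = 0, step = 1e-4,
                             n_paths = 2e5, horizon = NULL, seed = NULL) {
  if (mu < 0 || sigma <= 0 || z <= 0) stop("invalid diffusion parameters",
                                           call. = FALSE)
  if (abs(x0) > z) stop("|x0| must not exceed z", call. = FALSE)
  if (n_paths < 1) stop("n_paths must be positive", call. = FALSE)
  if (is.null(horizon)) horizon <- if (mu > 0) 200 * z / mu else 200 * (z / sigma)^2
  if (!is.null(seed)) set.seed(seed)
  out <- .em_first_passage_cpp(mu, sigma, z, x0, step, as.integer(n_paths),
                               horizon)
  if (out$n_unabsorbed > 1e-3 * n_paths)
    warning(sprintf("%.0f of %d paths not absorbed within horizon",
                    out$n_unabsorbed, n_paths))
  out
}
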