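# Internal parameterization for bounded least squares: the threshold
# ceiling is fitted as a non-negative margin above its floor, so the joint
# constraint z_max >= k/2 + x_offset reduces to box bounds.
.theta_names <- c("mu_tilde", "t_nd", "k", "x_offset", "delta",
                  "z_down", "z_up", "z_margin")

.theta_to_params <- function(theta) {
  theta <- as.list(theta)
  adaptive_params(mu_tilde = theta$mu_tilde, t_nd = theta$t_nd, k = theta$k,
                  x_offset = theta$x_offset, delta = theta$delta,
                  z_down = theta$z_down, z_up = theta$z_up,
                  z_max = theta$k / 2 + theta$x_offset + theta$z_margin)
}

.params_to_theta <- function(params) {
  c(mu_tilde = params$mu_tilde, t_nd = params$t_nd, k = params$k,
    x_offset = params$x_offset, delta = params$delta,
    z_down = params$z_down, z_up = params$z_up,
    z_margin = params$z_max - (params$k / 2 + params$x_offset))
}

.default_bounds <- function() {
  list(lower = c(mu_tilde = 1, t_nd = 0.05, k = 1e-4, x_offset = 1e-5,
                 delta = 0.01, z_down = 1e-5, z_up = 1e-5, z_margin = 1e-4),
       upper = c(mu_tilde = 60, t_nd = 0.60, k = 0.5, x_offset = 0.1,
                 delta = 0.99, z_down = 0.2, z_up = 0.5, z_margin = 0.9))
}

# typical magnitudes; the optimizer works on theta / .theta_scale so the
# eight parameters are comparably scaled
.theta_scale <- c(mu_tilde = 20, t_nd = 0.3, k = 0.1, x_offset = 0.01,
                  delta = 0.5, z_down = 0.01, z_up = 0.1, z_margin = 0.1)

.model_vector <- function(params, stimuli, by_condition, n_passes, seed) {
  sim <- simulate_session(stimuli, params, n_passes = n_passes, seed = seed)
  summary_vector(sim, by_condition = by_condition)
}

#' Sum-of-squares objective over condition summary vectors
#'
#' Simulates the adapted DDM on the same stimulus sequences that produced
#' the data, summarizes the simulated trials identically, and returns the
#' unweighted sum of squared differences between model and data summary
#' vectors. Elements undefined in either vector (empty cells) are dropped
#' pairwise. The same seed is used for every call at fixed `seed` (common
#' random numbers), making the stochastic objective deterministic.
#'
#' @param params An [adaptive_params()] object.
#' @param data_vector Data summary vector from [summary_vector()].
#' @param stimuli Stimulus table the data were collected on (columns
#'   `block`, `trial`, `p_alt`, `stimulus`).
#' @param n_passes Model passes through the stimulus sequences (>= 5
#'   recommended for fitting).
#' @param seed Integer seed for the simulated responses.
#' @return The scalar objective value with attribute `n` (number of compared
#'   elements).
#' @export
summary_objective <- function(params, data_vector, stimuli, n_passes = 5L,
                              seed = 1L) {
  by_condition <- grepl(":", names(data_vector)[1], fixed = TRUE)
  mv <- .model_vector(params, stimuli, by_condition, n_passes, seed)
  if (length(mv) != length(data_vector))
    stop("model and data summary vectors have different lengths", call. = FALSE)
  ok <- !is.na(mv) & !is.na(data_vector)
  if (!any(ok)) stop("no commonly defined summary elements", call. = FALSE)
  err <- sum((mv[ok] - data_vector[ok])^2)
  attr(err, "n") <- sum(ok)
  err
}

#' Information criteria for a least-squares fit
#'
#' Gaussian-residual least-squares forms: `AIC = n log(err/n) + 2p`,
#' `AICc = AIC + 2p(p+1)/(n-p-1)` (undefined when `n - p - 1 <= 0`, i.e.
#' when the number of compared means is too close to the number of
#' parameters), `BIC = n log(err/n) + p log(n)`.
#'
#' @param err Sum-of-squares objective value (>= 0).
#' @param n Number of compared summary elements.
#' @param p Number of free parameters.
#' @return A list with `aic`, `aicc` (may be `NA`), `bic`, and `exact_fit`
#'   (`TRUE` when `err = 0`, in which case the scores are `-Inf`).
#' @export
information_criteria <- function(err, n, p) {
  stopifnot(n > 0, p >= 1, err >= 0)
  exact <- err <= 0
  base <- if (exact) -Inf else n * log(err / n)
  aic <- base + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else NA_real_
  bic <- base + p * log(n)
  list(aic = aic, aicc = aicc, bic = bic, exact_fit = exact)
}

#' Fit the adapted DDM to a trial table
#'
#' Bounded nonlinear least squares on the condition summary vector
#' (Levenberg-Marquardt with box bounds). The model is simulated on the
#' stimulus sequences embedded in the data table with common random numbers
#' across objective evaluations, so finite-difference gradients see a smooth
#' surface. Undefined summary elements are dropped pairwise. Multiple
#' starting points can be requested; the best final objective wins.
#'
#' @param data_trials A trial table (e.g. from [read_trial_table()] or
#'   [generate_synthetic_subject()]) with columns `block`, `trial`, `p_alt`,
#'   `stimulus`, `response` or `correct`, `rt`.
#' @param n_passes Model passes per objective evaluation (>= 5 recommended).
#' @param seed Integer root seed (common random numbers and random starts).
#' @param start Optional [adaptive_params()] start; the default starts at
#'   the typical parameter magnitudes of the reference sets (the same
#'   magnitudes used to scale the search space).
#' @param n_starts Total number of starts (additional ones drawn uniformly
#'   within bounds).
#' @param lower,upper Optional named bound vectors over `mu_tilde`, `t_nd`,
#'   `k`, `x_offset`, `delta`, `z_down`, `z_up`, `z_margin` (the fitted
#'   margin of `z_max` above its floor `k/2 + x_offset`).
#' @param by_condition Group summaries by `p_alt`; default groups whenever
#'   the table contains more than one `p_alt` level.
#' @param max_iter Optimizer iteration cap per start.
#' @param epsfcn Relative squared step for the forward-difference Jacobian.
#'   The default (`1e-2`, i.e. 10% steps on the scaled parameters) is
#'   deliberately large: the simulated objective is piecewise smooth (a coin
#'   flip changes discretely as parameters move), and small steps measure
#'   those micro-jumps instead of the real slope.
#' @param refine Run a second optimization from the best optimum with a
#'   10-fold finer Jacobian step to polish the local solution.
#' @return A list of class `seqddm_fit`: `params` (fitted
#'   [adaptive_params()]), `err`, `n`, `p`, `aic`, `aicc`, `bic`,
#'   `converged`, `info`, `seed`, `n_passes`, `starts` (per-start
#'   objectives), `data_vector`, `model_vector`.
#' @export
fit_adaptive_ddm <- function(data_trials, n_passes = 5L, seed = 1L,
                             start = NULL, n_starts = 1L,
                             lower = NULL, upper = NULL,
                             by_condition = NULL, max_iter = 150L,
                             epsfcn = 1e-2, refine = TRUE) {
  stopifnot(all(c("block", "trial", "stimulus", "rt") %in% names(data_trials)))
  if (!"correct" %in% names(data_trials)) {
    if (!"response" %in% names(data_trials))
      stop("data must contain correct or response", call. = FALSE)
    data_trials$correct <- data_trials$response == data_trials$stimulus
  }
  if (is.null(by_condition)) {
    pa <- unique(data_trials$p_alt)
    by_condition <- "p_alt" %in% names(data_trials) &&
      length(pa[!is.na(pa)]) > 1
  }

  # the stimulus sequences the subject actually saw (first pass if several)
  d <- data_trials
  if ("pass" %in% names(d)) d <- d[d$pass == min(d$pass), , drop = FALSE]
  stim_cols <- intersect(c("block", "trial", "p_alt", "stimulus"), names(d))
  stimuli <- unique(d[, stim_cols])
  stimuli <- stimuli[order(stimuli$block, stimuli$trial), , drop = FALSE]

  data_vector <- summary_vector(data_trials, by_condition = by_condition)

  b <- .default_bounds()
  if (!is.null(lower)) b$lower[names(lower)] <- lower
  if (!is.null(upper)) b$upper[names(upper)] <- upper

  # default start = the typical reference magnitudes also used for scaling
  theta0 <- if (is.null(start)) .theta_scale else .params_to_theta(start)
  theta0 <- pmin(pmax(theta0, b$lower), b$upper)

  # restarts randomize the adaptation parameters, where the objective is
  # multimodal, and anchor mu_tilde and t_nd, which the overall RT level
  # and spread pin down from any reasonable start
  # restarts randomize the adaptation parameters, where the objective is
  # multimodal, and anchor mu_tilde and t_nd, which the overall RT level
  # and spread pin down from any reasonable start. The positive scale
  # parameters span decades, so they are drawn log-uniformly within bounds;
  # delta lives on a bounded interval and is drawn uniformly.
  starts <- list(theta0)
  if (n_starts > 1) {
    set.seed(.child_seed(seed, 0L, 1L))
    logu <- c("k", "x_offset", "z_down", "z_up", "z_margin")
    for (i in seq_len(n_starts - 1)) {
      th <- theta0
      th[logu] <- exp(log(b$lower[logu]) +
        stats::runif(length(logu)) * (log(b$upper[logu]) - log(b$lower[logu])))
      th["delta"] <- stats::runif(1, b$lower["delta"], b$upper["delta"])
      starts[[i + 1]] <- th
    }
  }

  resid_fn <- function(theta_scaled) {
    theta <- theta_scaled * .theta_scale
    params <- .theta_to_params(stats::setNames(theta, .theta_names))
    mv <- .model_vector(params, stimuli, by_condition, n_passes, seed)
    r <- mv - data_vector
    # a cell the data define but the model leaves empty is a bad fit, not a
    # free pass: penalize it so degenerate parameter regions (e.g. all RTs
    # beyond the outlier bounds) cannot win by emptying the summary
    r[is.na(mv) & !is.na(data_vector)] <- 0.5
    r[is.na(data_vector)] <- 0  # pairwise deletion, fixed residual length
    r
  }

  run_lm <- function(par, eps) {
    tryCatch(
      minpack.lm::nls.lm(par = par,
                         lower = b$lower / .theta_scale,
                         upper = b$upper / .theta_scale,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, epsfcn = eps)),
      error = function(e) NULL)
  }
  # each start gets the coarse stage and, if requested, the fine polish;
  # selection is on the final objective, since polishing can reorder starts
  fits <- lapply(starts, function(th) {
    f <- run_lm(th / .theta_scale, epsfcn)
    if (refine && !is.null(f)) {
      p <- run_lm(f$par, epsfcn / 10)
      if (!is.null(p) && p$deviance < f$deviance) f <- p
    }
    f
  })
  dev <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance,
                numeric(1))
  if (all(!is.finite(dev)))
    stop("all optimization starts failed", call. = FALSE)
  best <- fits[[which.min(dev)]]

  params <- .theta_to_params(stats::setNames(best$par * .theta_scale,
                                             .theta_names))
  err <- summary_objective(params, data_vector, stimuli, n_passes, seed)
  n_used <- attr(err, "n")
  ic <- information_criteria(as.numeric(err), n_used, p = 8L)

  structure(list(
    params = params, err = as.numeric(err), n = n_used, p = 8L,
    aic = ic$aic, aicc = ic$aicc, bic = ic$bic,
    converged = best$info %in% 1:4, info = best$info,
    message = best$message, seed = seed, n_passes = n_passes,
    starts = dev,
    data_vector = data_vector,
    model_vector = .model_vector(params, stimuli, by_condition, n_passes,
                                 seed)),
    class = "seqddm_fit")
}

#' @export
print.seqddm_fit <- function(x, ...) {
  cat(sprintf("Adapted DDM fit: Err = %.5g over %d summary elements (p = %d)\n",
              x$err, x$n, x$p))
  cat(sprintf("  AIC = %.1f, AICc = %s, BIC = %.1f, converged = %s\n",
              x$aic, ifelse(is.na(x$aicc), "undefined", sprintf("%.1f", x$aicc)),
              x$bic, x$converged))
  print(x$params)
  invisible(x)
}

#' Rerun a fitted model and average its summary vectors
#'
#' Reruns the model `n_runs` times with distinct child seeds and reports the
#' per-element mean and standard error of the summary vector, the form in
#' which model predictions are compared with behavioral summaries.
#'
#' @param params An [adaptive_params()] object.
#' @param stimuli Stimulus table (columns `block`, `trial`, `p_alt`,
#'   `stimulus`).
#' @param n_runs Number of replicate runs (>= 2).
#' @param seed Integer root seed.
#' @param n_passes Passes per run.
#' @param by_condition Group summaries by `p_alt`.
#' @return A data.frame with `element`, `mean`, `se`, `n_defined`.
#' @export
replicate_and_average <- function(params, stimuli, n_runs = 10L, seed = 1L,
                                  n_passes = 1L, by_condition = FALSE) {
  stopifnot(n_runs >= 2)
  runs <- vapply(seq_len(n_runs), function(r) {
    .model_vector(params, stimuli, by_condition, n_passes,
                  seed = .child_seed(seed, r, 0L))
  }, numeric(length(.model_vector(params, stimuli, by_condition, 1L, seed))))
  m <- rowMeans(runs, na.rm = TRUE)
  nn <- rowSums(!is.na(runs))
  sdv <- apply(runs, 1, stats::sd, na.rm = TRUE)
  data.frame(element = rownames(runs), mean = m,
             se = ifelse(nn > 1, sdv / sqrt(nn), NA_real_),
             n_defined = nn, row.names = NULL)
}
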