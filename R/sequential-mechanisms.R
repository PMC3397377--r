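#' Parameters of the adapted (sequentially updating) DDM
#'
#' The adapted model augments the pure DDM with two trial-to-trial
#' mechanisms: priming of the starting point from an exponentially decaying
#' memory of repetitions, and post-error threshold modulation. Eight
#' parameters define it.
#'
#' @param mu_tilde Scaled drift (squared signal-to-noise rate, 1/s).
#' @param t_nd Non-decision time (s).
#' @param k Priming scale (s per unit memory deviation): the starting point
#'   moves by `k * (M - 1/2)` with memory `M`.
#' @param x_offset Fixed starting-point bias magnitude (s), applied with the
#'   sign of the upcoming transition.
#' @param delta Memory decay in (0, 1); larger values weight trials further
#'   back in the sequence.
#' @param z_down Threshold decrement after a correct trial (s).
#' @param z_up Threshold increment after an error trial (s).
#' @param z_max Threshold ceiling (s); also the initial threshold. Must be at
#'   least `k/2 + x_offset` so that the admissible threshold range, whose
#'   lower bound keeps the threshold above any attainable starting point, is
#'   non-empty.
#' @return An object of class `adaptive_params`.
#' @seealso [adaptive_params_defaults()] for reference parameter sets,
#'   [simulate_session()] for the generative loop.
#' @export
adaptive_params <- function(mu_tilde, t_nd, k, x_offset, delta,
                            z_down, z_up, z_max) {
  vals <- c(mu_tilde = mu_tilde, t_nd = t_nd, k = k, x_offset = x_offset,
            delta = delta, z_down = z_down, z_up = z_up, z_max = z_max)
  if (any(!is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (any(vals <= 0)) stop("all parameters must be positive", call. = FALSE)
  if (delta >= 1) stop("delta must lie in (0, 1)", call. = FALSE)
  if (z_max < k / 2 + x_offset)
    stop("z_max must be at least k/2 + x_offset", call. = FALSE)
  structure(as.list(vals), class = "adaptive_params")
}

#' @export
print.adaptive_params <- function(x, ...) {
  cat("Adapted DDM parameters (8):\n")
  cat(sprintf("  mu_tilde = %.4f 1/s, t_nd = %.4f s\n", x$mu_tilde, x$t_nd))
  cat(sprintf("  priming: k = %.4f s, x_offset = %.4f s, delta = %.4f\n",
              x$k, x$x_offset, x$delta))
  cat(sprintf("  thresholds: z_down = %.4f s, z_up = %.4f s, z_max = %.4f s (floor %.4f s)\n",
              x$z_down, x$z_up, x$z_max, x$k / 2 + x$x_offset))
  invisible(x)
}

#' Reference parameter sets for the two task designs
#'
#' Fitted parameter values for the unbiased letter-discrimination design
#' (`"exp1"`: 13 blocks of 120 trials, alternation probability 0.5) and the
#' transition-biased dot-motion design (`"exp2"`: 9 blocks of 200 trials,
#' alternation probability 0.1/0.5/0.9). These serve as defaults for
#' synthetic-subject generation and as ground truth in recovery studies.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @return An [adaptive_params()] object.
#' @export
adaptive_params_defaults <- function(design = c("exp1", "exp2")) {
  design <- match.arg(design)
  switch(design,
    exp1 = adaptive_params(mu_tilde = 38.1747, t_nd = 0.2626, k = 0.0943,
                           x_offset = 0.0051, delta = 0.6860,
                           z_down = 0.0058, z_up = 0.0348, z_max = 0.2857),
    exp2 = adaptive_params(mu_tilde = 19.3312, t_nd = 0.3359, k = 0.1181,
                           x_offset = 0.0034, delta = 0.6882,
                           z_down = 0.0034, z_up = 0.1635, z_max = 0.2062))
}

#' Update the repetition memory
#'
#' Exponential filter on the indicator of repetitions:
#' `M_n = delta * M_{n-1} + (1 - delta)` after a repetition and
#' `M_n = delta * M_{n-1}` after an alternation, keeping `M` in `[0, 1]`.
#' With `delta = 0.5` the influence of a trial four steps back has decayed
#' to `0.5^4 = 0.0625`.
#'
#' @param memory Current memory value(s) in `[0, 1]`.
#' @param transition `"R"` (repetition) or `"A"` (alternation); vectorized.
#' @param delta Memory decay in (0, 1).
#' @return Updated memory in `[0, 1]`.
#' @export
update_memory <- function(memory, transition, delta) {
  stopifnot(all(memory >= 0 & memory <= 1), delta > 0, delta < 1)
  transition <- match.arg(as.character(transition), c("R", "A"),
                          several.ok = TRUE)
  delta * memory + (1 - delta) * (transition == "R")
}

#' Primed starting point for the upcoming trial
#'
#' `x0 = s * (k * (M - 1/2) + x_offset)` with `s = +1` when the upcoming
#' trial is a repetition and `s = -1` when it is an alternation: memory
#' biased toward repetitions speeds repetitions and slows alternations
#' symmetrically. The magnitude never exceeds `k/2 + x_offset`.
#'
#' @param memory Memory value(s) in `[0, 1]` from [update_memory()].
#' @param transition Transition type of the upcoming trial, `"R"` or `"A"`.
#' @param k,x_offset Priming parameters, see [adaptive_params()].
#' @return Scaled starting point in seconds.
#' @export
initial_condition <- function(memory, transition, k, x_offset) {
  stopifnot(all(memory >= 0 & memory <= 1), k > 0, x_offset >= 0)
  transition <- match.arg(as.character(transition), c("R", "A"),
                          several.ok = TRUE)
  s <- ifelse(transition == "R", 1, -1)
  s * (k * (memory - 0.5) + x_offset)
}

#' Post-trial threshold update
#'
#' Lowers the threshold by `z_down` after a correct trial and raises it by
#' `z_up` after an error, then clamps to the admissible range
#' `[k/2 + x_offset, z_max]`.
#'
#' @param z_current Current threshold (s).
#' @param was_correct Logical; was the completed trial correct?
#' @param params An [adaptive_params()] object.
#' @return Updated threshold (s), inside the admissible range.
#' @export
update_threshold <- function(z_current, was_correct, params) {
  stopifnot(inherits(params, "adaptive_params"), is.logical(was_correct))
  z <- z_current + ifelse(was_correct, -params$z_down, params$z_up)
  pmin(pmax(z, params$k / 2 + params$x_offset), params$z_max)
}

#' Model state for the sequential simulation
#'
#' @param memory Repetition memory in `[0, 1]`; initialized unbiased at 1/2.
#' @param z_current Current threshold (s); initialized conservatively at the
#'   ceiling `z_max`.
#' @param trial_index 1-based index of the next trial within the block.
#' @param params An [adaptive_params()] object (used to validate bounds).
#' @return A list of class `model_state`.
#' @export
model_state <- function(params, memory = 0.5, z_current = params$z_max,
                        trial_index = 1L) {
  stopifnot(inherits(params, "adaptive_params"))
  if (memory < 0 || memory > 1) stop("memory must lie in [0, 1]", call. = FALSE)
  lo <- params$k / 2 + params$x_offset
  if (z_current < lo - 1e-12 || z_current > params$z_max + 1e-12)
    stop("z_current outside admissible threshold range", call. = FALSE)
  structure(list(memory = memory, z_current = z_current,
                 trial_index = as.integer(trial_index)),
            class = "model_state")
}

#' Simulate a single trial of the adapted DDM
#'
#' Computes the primed starting point from the current state and the trial's
#' transition type, evaluates the closed-form error rate, draws the
#' trial's correctness as a biased coin flip, sets the reaction time to the
#' non-decision time plus the conditional mean decision time for the drawn
#' outcome, and returns the updated state (memory and threshold). Consumes
#' exactly one uniform deviate from R's RNG.
#'
#' @param state A [model_state()] object.
#' @param transition `"R"`, `"A"`, or `NA` (first trial of a block: no
#'   transition, unbiased start).
#' @param stimulus Stimulus identity, 1 or 2.
#' @param params An [adaptive_params()] object.
#' @return A list with `trial` (one-row data.frame) and `state` (updated
#'   [model_state()]).
#' @export
simulate_trial <- function(state, transition, stimulus, params) {
  stopifnot(inherits(state, "model_state"), inherits(params, "adaptive_params"),
            stimulus %in% c(1L, 2L))
  has_trans <- !is.na(transition)
  x0 <- if (has_trans)
    initial_condition(state$memory, transition, params$k, params$x_offset)
  else 0
  lim <- state$z_current * (1 - 1e-9)
  x0 <- min(max(x0, -lim), lim)

  er <- .er_closed_cpp(state$z_current, x0, params$mu_tilde)
  u <- stats::runif(1)
  ok <- if (er <= 0) TRUE else if (er >= 1) FALSE else u >= er
  cond <- .dt_cond_closed_cpp(state$z_current, x0, params$mu_tilde)
  dt <- if (ok) cond$dt_correct else cond$dt_error

  trial <- data.frame(
    trial = state$trial_index, stimulus = as.integer(stimulus),
    transition = if (has_trans) as.character(transition) else NA_character_,
    response = as.integer(if (ok) stimulus else 3L - as.integer(stimulus)),
    correct = ok, rt = params$t_nd + dt,
    x0_tilde = x0, z_tilde = state$z_current, er_trial = er,
    stringsAsFactors = FALSE)

  # memory held at 1/2 through trial 2, exponential filter afterwards
  new_mem <- if (state$trial_index >= 3L && has_trans)
    update_memory(state$memory, transition, params$delta)
  else 0.5
  new_state <- model_state(params, memory = new_mem,
                           z_current = update_threshold(state$z_current, ok, params),
                           trial_index = state$trial_index + 1L)
  list(trial = trial, state = new_state)
}

# Reference R implementation of one block pass; mirrors the compiled kernel
# and is used to cross-check it in the tests.
.simulate_block_r <- function(stimuli, params) {
  state <- model_state(params)
  rows <- vector("list", length(stimuli))
  for (i in seq_along(stimuli)) {
    trans <- if (i == 1L) NA_character_
             else if (stimuli[i] == stimuli[i - 1L]) "R" else "A"
    step <- simulate_trial(state, trans, stimuli[i], params)
    rows[[i]] <- step$trial
    state <- step$state
  }
  do.call(rbind, rows)
}

.child_seed <- function(root, pass, block) {
  (root + 1000003 * pass + 7919 * block) %% 2147483629L
}

#' Simulate full sessions of the adapted DDM over a stimulus table
#'
#' Runs the generative model through every block of a stimulus table
#' `n_passes` times. State (memory, threshold) is re-initialized at every
#' block boundary (`M = 1/2`, `z = z_max`): blocks are separated by breaks
#' and may change transition probability. Each (pass, block) pair gets a
#' deterministic child seed derived from `seed`, so increasing `n_passes`
#' reproduces earlier passes exactly.
#'
#' @param stimuli A data.frame with columns `block`, `trial`, `stimulus`
#'   (values 1/2) and optionally `p_alt` (carried through), ordered by trial
#'   within block; see [generate_stimulus_table()].
#' @param params An [adaptive_params()] object.
#' @param n_passes Number of passes through the stimulus sequence (>= 1).
#' @param seed Optional integer root seed.
#' @return A trial table (data.frame) with one row per simulated trial:
#'   `pass`, `block`, `trial`, `p_alt`, `stimulus`, `transition`, `response`,
#'   `correct`, `rt` (s), plus model diagnostics `x0_tilde`, `z_tilde`,
#'   `er_trial`, `memory`.
#' @export
simulate_session <- function(stimuli, params, n_passes = 1L, seed = NULL) {
  stopifnot(inherits(params, "adaptive_params"))
  if (!is.data.frame(stimuli) || nrow(stimuli) == 0)
    stop("stimuli must be a non-empty data.frame", call. = FALSE)
  req <- c("block", "trial", "stimulus")
  if (!all(req %in% names(stimuli)))
    stop("stimuli must have columns block, trial, stimulus", call. = FALSE)
  if (n_passes < 1) stop("n_passes must be >= 1", call. = FALSE)
  if (!all(stimuli$stimulus %in% c(1L, 2L)))
    stop("stimulus values must be 1 or 2", call. = FALSE)
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^30))

  blocks <- split(stimuli, stimuli$block)
  block_ids <- names(blocks)
  out <- vector("list", n_passes * length(blocks))
  idx <- 1L
  for (pass in seq_len(n_passes)) {
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      blk <- blk[order(blk$trial), , drop = FALSE]
      set.seed(.child_seed(seed, pass, b))
      sim <- .simulate_block_cpp(as.integer(blk$stimulus),
                                 params$mu_tilde, params$t_nd, params$k,
                                 params$x_offset, params$delta,
                                 params$z_down, params$z_up, params$z_max)
      sim$pass <- pass
      sim$block <- blk$block[1]
      sim$trial <- blk$trial
      sim$p_alt <- if ("p_alt" %in% names(blk)) blk$p_alt else NA_real_
      out[[idx]] <- sim
      idx <- idx + 1L
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("pass", "block", "trial", "p_alt", "stimulus", "transition",
                 "response", "correct", "rt", "x0_tilde", "z_tilde",
                 "er_trial", "memory")]
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}
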