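#' Generate a block of stimuli from a transition-oriented Markov process
#'
#' The first stimulus is 1 or 2 with equal probability; each subsequent
#' stimulus alternates (differs from its predecessor) with probability
#' `p_alt` and repeats with probability `1 - p_alt`.
#'
#' @param n_trials Number of trials in the block (>= 3, so that three-trial
#'   sequence labels exist).
#' @param p_alt Alternation probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer vector of stimulus identities in `{1, 2}`.
#' @export
#' @examples
#' generate_markov_stimuli(10, p_alt = 0.9, seed = 1)
generate_markov_stimuli <- function(n_trials, p_alt, seed = NULL) {
  if (n_trials < 3) stop("n_trials must be at least 3", call. = FALSE)
  if (p_alt < 0 || p_alt > 1) stop("p_alt must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  first <- sample(c(1L, 2L), 1L)
  alt <- stats::runif(n_trials - 1L) < p_alt
  # cumulative alternation count determines identity relative to the first
  flips <- cumsum(alt) %% 2L
  c(first, ifelse(flips == 1L, 3L - first, first))
}

#' Build an experiment schedule
#'
#' `"exp1"` is the unbiased design: 13 blocks of 120 trials, all with
#' alternation probability 0.5. `"exp2"` is the transition-biased design: 9
#' blocks of 200 trials with alternation probability 0.1, 0.5, or 0.9, three
#' blocks each, in a seeded balanced permutation (a per-subject stand-in for
#' counterbalancing block order across subjects).
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param seed Optional integer seed (orders the exp2 blocks).
#' @return A data.frame of class `experiment_schedule` with columns `block`,
#'   `n_trials`, `p_alt`, and a `design` attribute.
#' @export
generate_experiment_schedule <- function(design = c("exp1", "exp2"),
                                         seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  sched <- switch(design,
    exp1 = data.frame(block = 1:13, n_trials = 120L, p_alt = 0.5),
    exp2 = data.frame(block = 1:9, n_trials = 200L,
                      p_alt = sample(rep(c(0.1, 0.5, 0.9), each = 3L))))
  attr(sched, "design") <- design
  class(sched) <- c("experiment_schedule", "data.frame")
  sched
}

#' Draw the stimulus table for a schedule
#'
#' Generates one Markov stimulus sequence per block of a schedule, with
#' per-block child seeds derived from `seed`.
#'
#' @param schedule A data.frame with columns `block`, `n_trials`, `p_alt`
#'   (see [generate_experiment_schedule()]).
#' @param seed Optional integer root seed.
#' @return A data.frame with columns `block`, `trial` (1-based within
#'   block), `p_alt`, `stimulus`.
#' @export
generate_stimulus_table <- function(schedule, seed = NULL) {
  stopifnot(all(c("block", "n_trials", "p_alt") %in% names(schedule)))
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^30))
  out <- lapply(seq_len(nrow(schedule)), function(b) {
    stim <- generate_markov_stimuli(schedule$n_trials[b], schedule$p_alt[b],
                                    seed = .child_seed(seed, 0L, b))
    data.frame(block = schedule$block[b],
               trial = seq_len(schedule$n_trials[b]),
               p_alt = schedule$p_alt[b], stimulus = stim)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Generate a synthetic subject with known ground truth
#'
#' Draws a stimulus table for the schedule and generates responses with the
#' adapted DDM (one pass), returning both the behavioral trial table and a
#' ground-truth record (the generating parameters and seeds) for parameter
#' recovery studies.
#'
#' @param true_params An [adaptive_params()] object (the generating truth).
#' @param schedule An experiment schedule; see
#'   [generate_experiment_schedule()].
#' @param seed Optional integer root seed (stimuli and responses derive
#'   deterministic child seeds from it).
#' @param subject Subject identifier stored in the trial table.
#' @return A list with `trials` (labeled trial table including a `subject`
#'   column) and `truth` (list of generating parameters, seed, design).
#' @export
generate_synthetic_subject <- function(true_params, schedule, seed = NULL,
                                       subject = "synth01") {
  stopifnot(inherits(true_params, "adaptive_params"))
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^30))
  stim <- generate_stimulus_table(schedule, seed = seed)
  trials <- simulate_session(stim, true_params, n_passes = 1L,
                             seed = .child_seed(seed, 1L, 0L))
  trials$subject <- subject
  trials <- trials[, c("subject", setdiff(names(trials), "subject"))]
  truth <- list(params = unclass(true_params), seed = seed,
                design = attr(schedule, "design"))
  list(trials = trials, truth = truth)
}
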