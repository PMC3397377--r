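# Group key for operations that must not cross session/block boundaries:
# subject and pass are optional columns, block is required.
.block_key <- function(trials) {
  key <- as.character(trials$block)
  if ("pass" %in% names(trials)) key <- paste(trials$pass, key, sep = "\r")
  if ("subject" %in% names(trials)) key <- paste(trials$subject, key, sep = "\r")
  key
}

.seq_labels <- c("RR", "AR", "RA", "AA")

#' Label transitions and three-trial sequences
#'
#' Adds a `transition` column (`"R"` if the stimulus repeats the previous
#' trial's stimulus, `"A"` if it alternates, `NA` on the first trial of a
#' block) and a `seq_label` column giving the transitions of the three most
#' recent stimuli: the previous trial's transition followed by the current
#' one (`"RR"`, `"AR"`, `"RA"`, `"AA"`; `NA` for the first two trials of a
#' block). Labels are stimulus-based — correctness plays no role — and never
#' cross block (or pass, or subject) boundaries. A label's RT/ER belongs to
#' the final trial of its three-trial window: stimuli (left, left, left)
#' label the third trial `RR`; (left, right, right) label it `AR`.
#'
#' @param trials A trial table with columns `block`, `trial`, `stimulus`
#'   (and optionally `subject`, `pass`), ordered by trial within block.
#' @return The table with `transition` and `seq_label` columns replaced.
#' @export
label_sequences <- function(trials) {
  stopifnot(all(c("block", "trial", "stimulus") %in% names(trials)))
  key <- .block_key(trials)
  ord <- order(key, trials$trial, method = "radix")
  if (is.unsorted(ord, strictly = TRUE)) {
    trials <- trials[ord, , drop = FALSE]
    key <- key[ord]
  }
  n <- nrow(trials)
  same_grp <- c(FALSE, key[-1] == key[-n])
  dup <- same_grp & c(FALSE, diff(trials$trial) <= 0)
  if (any(dup))
    stop("trial indices must be strictly increasing within a block",
         call. = FALSE)
  prev_stim <- c(NA_integer_, trials$stimulus[-n])
  transition <- ifelse(!same_grp, NA_character_,
                       ifelse(trials$stimulus == prev_stim, "R", "A"))
  prev_trans <- c(NA_character_, transition[-n])
  prev_trans[!same_grp] <- NA_character_
  seq_label <- ifelse(is.na(prev_trans) | is.na(transition), NA_character_,
                      paste0(prev_trans, transition))
  trials$transition <- transition
  trials$seq_label <- seq_label
  rownames(trials) <- NULL
  trials
}

#' Flag outlier reaction times
#'
#' Marks trials with RT below `lo` or above `hi` (defaults 100 ms and
#' 900 ms). Flagged trials are excluded from RT and ER summaries but still
#' contribute to the transition and sequence labels of later trials, since
#' an outlier precedes trials that remain in the analysis.
#'
#' @param trials A trial table with an `rt` column (seconds).
#' @param lo,hi Outlier bounds in seconds.
#' @return The table with a logical `outlier` column replaced.
#' @export
flag_outliers <- function(trials, lo = 0.100, hi = 0.900) {
  stopifnot("rt" %in% names(trials), lo < hi)
  trials$outlier <- trials$rt < lo | trials$rt > hi
  trials
}

.condition_key <- function(trials, by_condition) {
  if (by_condition) {
    if (!"p_alt" %in% names(trials))
      stop("by_condition requires a p_alt column", call. = FALSE)
    trials$p_alt
  } else rep(NA_real_, nrow(trials))
}

#' Per-sequence RT and ER summaries
#'
#' Means and counts for each sequence label (`RR`, `AR`, `RA`, `AA`),
#' overall and split by the correctness of the labeled trial, over
#' non-outlier labeled trials. Empty cells yield `NA` means with zero
#' counts, never zeros.
#'
#' @param trials A labeled, outlier-flagged trial table (see
#'   [label_sequences()], [flag_outliers()]; a missing `outlier` column is
#'   treated as all-unflagged).
#' @param by_condition Group by the block's alternation probability `p_alt`
#'   (blocked-design analysis)?
#' @return A data.frame with one row per (condition, label): `condition`
#'   (p_alt, `NA` when pooled), `label`, `n_total`, `n_correct`, `n_error`,
#'   `rt_mean`, `rt_correct`, `rt_error` (seconds), `er` (fraction).
#' @export
summarize_by_sequence <- function(trials, by_condition = FALSE) {
  stopifnot(all(c("seq_label", "correct", "rt") %in% names(trials)))
  if (!"outlier" %in% names(trials)) trials$outlier <- FALSE
  cond <- .condition_key(trials, by_condition)
  keep <- !trials$outlier & !is.na(trials$seq_label)
  d <- trials[keep, , drop = FALSE]
  dcond <- cond[keep]

  conds <- sort(unique(cond), na.last = TRUE)
  lev <- as.vector(outer(.seq_labels, conds, function(l, co) paste(co, l)))
  f <- factor(paste(dcond, d$seq_label), levels = lev)

  cnt <- function(x) { t <- tapply(x, f, sum); ifelse(is.na(t), 0, t) }
  n_total <- cnt(rep(1L, nrow(d)))
  n_correct <- cnt(as.integer(d$correct))
  n_error <- n_total - n_correct
  sum_all <- cnt(d$rt)
  sum_c <- cnt(d$rt * d$correct)
  sum_e <- sum_all - sum_c

  res <- data.frame(
    condition = rep(conds, each = length(.seq_labels)),
    label = rep(.seq_labels, times = length(conds)),
    n_total = as.integer(n_total),
    n_correct = as.integer(n_correct),
    n_error = as.integer(n_error),
    rt_mean = ifelse(n_total > 0, sum_all / n_total, NA_real_),
    rt_correct = ifelse(n_correct > 0, sum_c / n_correct, NA_real_),
    rt_error = ifelse(n_error > 0, sum_e / n_error, NA_real_),
    er = ifelse(n_total > 0, n_error / n_total, NA_real_),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Mean RTs before, on, and after errors
#'
#' For every error trial whose two neighbors lie inside the same block (and
#' pass, and subject), accumulates the RTs of the preceding trial, the error
#' trial itself, and the following trial. Each of the three positions
#' contributes only non-outlier entries to its mean; neighbors may
#' themselves be errors. Errors on the first or last trial of a block are
#' excluded.
#'
#' @inheritParams summarize_by_sequence
#' @return A data.frame with one row per condition: `condition`, `rt_pre`,
#'   `rt_on`, `rt_post` (seconds), `n_triplets`.
#' @export
summarize_error_triplets <- function(trials, by_condition = FALSE) {
  stopifnot(all(c("block", "trial", "correct", "rt") %in% names(trials)))
  if (!"outlier" %in% names(trials)) trials$outlier <- FALSE
  key <- .block_key(trials)
  ord <- order(key, trials$trial, method = "radix")
  trials <- trials[ord, , drop = FALSE]
  key <- key[ord]
  cond <- .condition_key(trials, by_condition)

  n <- nrow(trials)
  same_prev <- c(FALSE, key[-1] == key[-n])        # row i-1 in same block
  same_next <- c(same_prev[-1], FALSE)             # row i+1 in same block
  anchor <- which(!trials$correct & same_prev & same_next)

  conds <- sort(unique(cond), na.last = TRUE)
  res <- lapply(conds, function(co) {
    a <- anchor[if (is.na(co)) rep(TRUE, length(anchor)) else cond[anchor] == co]
    grab <- function(idx) {
      v <- trials$rt[idx][!trials$outlier[idx]]
      if (length(v)) mean(v) else NA_real_
    }
    data.frame(condition = co, rt_pre = grab(a - 1L), rt_on = grab(a),
               rt_post = grab(a + 1L), n_triplets = length(a))
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Assemble the canonical condition summary vector
#'
#' Stacks, for each condition, the 19 summary statistics that enter the
#' least-squares fitting objective, in this fixed order: overall mean RT for
#' (RR, AR, RA, AA); correct mean RT for the four labels; error mean RT for
#' the four labels; ER for the four labels; then mean RT before, on, and
#' after errors. Units are seconds and decimal fractions, so all elements
#' are of comparable magnitude. Conditions are ordered by increasing
#' `p_alt`; a single (pooled) condition gives 19 elements, three conditions
#' give 57. Undefined cells are carried as `NA`.
#'
#' @param seq_summary Output of [summarize_by_sequence()].
#' @param triplet_summary Output of [summarize_error_triplets()] on the same
#'   table with the same grouping.
#' @return A named numeric vector of length `19 * n_conditions` with
#'   attribute `n_conditions`.
#' @export
assemble_summary_vector <- function(seq_summary, triplet_summary) {
  conds <- sort(unique(seq_summary$condition), na.last = TRUE)
  tconds <- sort(unique(triplet_summary$condition), na.last = TRUE)
  if (!identical(conds, tconds))
    stop("summaries come from different condition sets", call. = FALSE)
  pieces <- lapply(conds, function(co) {
    s <- if (is.na(co)) seq_summary[is.na(seq_summary$condition), ]
         else seq_summary[!is.na(seq_summary$condition) & seq_summary$condition == co, ]
    t <- if (is.na(co)) triplet_summary[is.na(triplet_summary$condition), ]
         else triplet_summary[!is.na(triplet_summary$condition) & triplet_summary$condition == co, ]
    s <- s[match(.seq_labels, s$label), ]
    v <- c(s$rt_mean, s$rt_correct, s$rt_error, s$er,
           t$rt_pre, t$rt_on, t$rt_post)
    names(v) <- c(paste0("rt_mean_", .seq_labels),
                  paste0("rt_correct_", .seq_labels),
                  paste0("rt_error_", .seq_labels),
                  paste0("er_", .seq_labels),
                  "rt_pre_error", "rt_on_error", "rt_post_error")
    if (!is.na(co)) names(v) <- paste0("p", co, ":", names(v))
    v
  })
  out <- do.call(c, pieces)
  attr(out, "n_conditions") <- length(conds)
  out
}

#' Summarize a trial table into its condition summary vector
#'
#' Convenience wrapper: labels, flags outliers, summarizes, and assembles
#' the canonical summary vector in one call.
#'
#' @inheritParams summarize_by_sequence
#' @param relabel Recompute labels and outlier flags (set `FALSE` if the
#'   table already carries them).
#' @param lo,hi Outlier bounds in seconds, see [flag_outliers()].
#' @return See [assemble_summary_vector()].
#' @export
summary_vector <- function(trials, by_condition = FALSE, relabel = TRUE,
                           lo = 0.100, hi = 0.900) {
  if (relabel) trials <- flag_outliers(label_sequences(trials), lo, hi)
  assemble_summary_vector(summarize_by_sequence(trials, by_condition),
                          summarize_error_triplets(trials, by_condition))
}

#' The sequential RT tradeoff line
#'
#' Ordinary least-squares regression of per-label mean error RT on mean
#' correct RT over the (RR, AR, RA, AA) points, pooled across conditions
#' when several are present. A negative slope is the sequential RT tradeoff:
#' sequences answered quickly when wrong are answered slowly when right.
#'
#' @param seq_summary Output of [summarize_by_sequence()] (possibly by
#'   condition).
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_points`.
#' @export
tradeoff_statistics <- function(seq_summary) {
  d <- seq_summary[!is.na(seq_summary$rt_correct) &
                   !is.na(seq_summary$rt_error), , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 labels with defined correct and error means",
         call. = FALSE)
  fit <- stats::lm(rt_error ~ rt_correct, data = d)
  # collinear inputs are legitimate here; silence the perfect-fit warning
  s <- suppressWarnings(summary(fit))
  pv <- if (nrow(d) > 2 && s$coefficients["rt_correct", "Std. Error"] > 0)
    s$coefficients["rt_correct", "Pr(>|t|)"] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, p_value = unname(pv), n_points = nrow(d))
}

#' R-line and A-line slopes
#'
#' The R line connects the RR and AR mean RTs (trials ending in a
#' repetition); the A line connects RA and AA (trials ending in an
#' alternation). Their signed slopes, `RT(AR) - RT(RR)` and
#' `RT(RA) - RT(AA)` in seconds, diagnose the relative preference for
#' repetitions or alternations (the automatic-facilitation versus
#' strategic-expectancy signature).
#'
#' @param seq_summary Output of [summarize_by_sequence()].
#' @param which_rt Which mean to use: `"rt_mean"` (default), `"rt_correct"`,
#'   or `"rt_error"`.
#' @return A data.frame per condition with `r_line_slope` and
#'   `a_line_slope`; `NA` where a needed cell is undefined.
#' @export
line_geometry <- function(seq_summary, which_rt = "rt_mean") {
  which_rt <- match.arg(which_rt, c("rt_mean", "rt_correct", "rt_error"))
  conds <- sort(unique(seq_summary$condition), na.last = TRUE)
  res <- lapply(conds, function(co) {
    s <- if (is.na(co)) seq_summary[is.na(seq_summary$condition), ]
         else seq_summary[!is.na(seq_summary$condition) & seq_summary$condition == co, ]
    v <- s[[which_rt]][match(.seq_labels, s$label)]
    names(v) <- .seq_labels
    data.frame(condition = co,
               r_line_slope = v[["AR"]] - v[["RR"]],
               a_line_slope = v[["RA"]] - v[["AA"]])
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}
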