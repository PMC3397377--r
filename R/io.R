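.required_cols <- c("subject", "block", "trial", "p_alt", "stimulus",
                    "response", "rt")

#' Read a trial table from CSV
#'
#' Validates the schema: required columns `subject`, `block`, `trial`,
#' `p_alt`, `stimulus`, `response`, `rt`; optional `pass`, `correct`,
#' `transition`, `seq_label`, `outlier`. RTs are in seconds; a table whose
#' median RT exceeds 10 looks like milliseconds and is rejected unless
#' `assume_ms = TRUE` converts it.
#'
#' @param path CSV file path.
#' @param assume_ms Divide `rt` by 1000 on read.
#' @return A validated trial table (data.frame) with a `correct` column.
#' @export
read_trial_table <- function(path, assume_ms = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.required_cols, names(tab))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(tab$rt))
    stop("rt column must be numeric (seconds)", call. = FALSE)
  bad <- which(!is.finite(tab$rt) | tab$rt < 0)
  if (length(bad))
    stop("non-finite or negative rt at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (assume_ms) tab$rt <- tab$rt / 1000
  if (stats::median(tab$rt) > 10)
    stop("rt values look like milliseconds (median > 10 s); ",
         "re-read with assume_ms = TRUE if so", call. = FALSE)
  if (!all(tab$stimulus %in% c(1L, 2L)) || !all(tab$response %in% c(1L, 2L)))
    stop("stimulus and response must take values 1 or 2", call. = FALSE)
  if (!"correct" %in% names(tab)) tab$correct <- tab$response == tab$stimulus
  tab
}

#' Write a trial table to CSV
#'
#' @param trials A trial table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Run the simulate / analyze / fit / recover pipeline
#'
#' End-to-end orchestration over the package functions. `config` is a list
#' with components:
#' \describe{
#'   \item{stages}{Character subset of `c("simulate", "analyze", "fit",
#'     "recover")`.}
#'   \item{design}{`"exp1"` or `"exp2"` (simulate/recover stages).}
#'   \item{params}{An [adaptive_params()] object; defaults to the design's
#'     reference set.}
#'   \item{seed}{Integer seed (required; no silent global RNG).}
#'   \item{trials}{A trial table (analyze/fit without simulate), or a CSV
#'     path.}
#'   \item{n_passes, n_starts, max_iter}{Fitting controls.}
#'   \item{outlier_lo, outlier_hi}{Outlier bounds in seconds.}
#' }
#'
#' @param config Configuration list, see above.
#' @param out_dir Output directory (created if needed); trial tables and
#'   summaries are written as CSV, fit results and ground truth as JSON, and
#'   a short human-readable report as text.
#' @return A list with the computed objects (`trials`, `seq_summary`,
#'   `triplets`, `tradeoff`, `lines`, `fit`, `truth`) invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$stages) || !length(config$stages))
    stop("config$stages must name at least one stage", call. = FALSE)
  stages <- match.arg(config$stages,
                      c("simulate", "analyze", "fit", "recover"),
                      several.ok = TRUE)
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lo <- config$outlier_lo %||% 0.100
  hi <- config$outlier_hi %||% 0.900
  res <- list()

  if (any(c("simulate", "recover") %in% stages)) {
    design <- config$design %||% "exp2"
    params <- config$params %||% adaptive_params_defaults(design)
    sched <- generate_experiment_schedule(design,
                                          seed = .child_seed(config$seed, 2L, 0L))
    subj <- generate_synthetic_subject(params, sched, seed = config$seed)
    res$trials <- subj$trials
    res$truth <- subj$truth
    write_trial_table(subj$trials, file.path(out_dir, "trials.csv"))
    jsonlite::write_json(subj$truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (!is.null(config$trials)) {
    res$trials <- if (is.character(config$trials))
      read_trial_table(config$trials) else config$trials
  } else stop("no trial data: supply config$trials or a simulate stage",
              call. = FALSE)

  trials <- flag_outliers(label_sequences(res$trials), lo, hi)
  by_cond <- length(unique(trials$p_alt[!is.na(trials$p_alt)])) > 1

  if ("analyze" %in% stages) {
    res$seq_summary <- summarize_by_sequence(trials, by_condition = by_cond)
    res$triplets <- summarize_error_triplets(trials, by_condition = by_cond)
    res$tradeoff <- tradeoff_statistics(res$seq_summary)
    res$lines <- line_geometry(res$seq_summary)
    utils::write.csv(res$seq_summary,
                     file.path(out_dir, "sequence_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(res$triplets,
                     file.path(out_dir, "error_triplets.csv"),
                     row.names = FALSE)
  }

  if (any(c("fit", "recover") %in% stages)) {
    res$fit <- fit_adaptive_ddm(trials,
                                n_passes = config$n_passes %||% 5L,
                                seed = .child_seed(config$seed, 3L, 0L),
                                n_starts = config$n_starts %||% 1L,
                                max_iter = config$max_iter %||% 30L)
    out <- res$fit[c("err", "n", "p", "aic", "aicc", "bic", "converged",
                     "seed", "n_passes")]
    out$params <- unclass(res$fit$params)
    jsonlite::write_json(out, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  report <- c(
    sprintf("seqddm pipeline report (seed %s)", config$seed),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    sprintf("trials: %d rows, %d block(s), outlier bounds [%.3f, %.3f] s",
            nrow(trials), length(unique(trials$block)), lo, hi))
  if (!is.null(res$tradeoff))
    report <- c(report, sprintf(
      "sequential RT tradeoff: slope %.3f, R^2 %.3f", res$tradeoff$slope,
      res$tradeoff$r_squared))
  if (!is.null(res$fit)) {
    report <- c(report, sprintf(
      "fit: Err %.5g over %d elements; AIC %.1f, BIC %.1f",
      res$fit$err, res$fit$n, res$fit$aic, res$fit$bic))
    if ("recover" %in% stages) {
      tr <- unlist(res$truth$params)
      es <- unlist(unclass(res$fit$params))[names(tr)]
      report <- c(report, "recovery (truth -> estimate):",
                  sprintf("  %-9s %.4f -> %.4f", names(tr), tr, es))
    }
  }
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
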