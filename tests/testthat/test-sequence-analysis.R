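test_that("transition and sequence labels follow the stimulus history", {
  tt <- label_sequences(toy_trials())
  # stimuli 1,1,1,2,2,1,1,1
  expect_equal(tt$transition, c(NA, "R", "R", "A", "R", "A", "R", "R"))
  expect_equal(tt$seq_label, c(NA, NA, "RR", "RA", "AR", "RA", "AR", "RR"))

  # (left, left, left) -> RR on trial 3; (left, right, right) -> AR
  t3 <- label_sequences(data.frame(block = 1, trial = 1:3,
                                   stimulus = c(1L, 2L, 2L)))
  expect_equal(t3$seq_label[3], "AR")

  # labels never cross block boundaries
  two <- data.frame(block = rep(1:2, each = 3), trial = rep(1:3, 2),
                    stimulus = rep(c(1L, 1L, 1L), 2))
  lab <- label_sequences(two)
  expect_true(all(is.na(lab$seq_label[lab$trial <= 2])))
  expect_equal(lab$seq_label[lab$trial == 3], c("RR", "RR"))

  dup <- data.frame(block = 1, trial = c(1, 2, 2), stimulus = c(1L, 1L, 2L))
  expect_error(label_sequences(dup), "strictly increasing")
})

test_that("outlier flags exclude RTs but preserve labelling of successors", {
  tt <- toy_trials()
  tt$rt[2] <- 0.050   # below 100 ms
  tt$rt[5] <- 1.2     # above 900 ms
  lab <- flag_outliers(label_sequences(tt))
  expect_equal(which(lab$outlier), c(2L, 5L))
  expect_false(lab$outlier[4])  # 0.45 s is kept
  # the flagged trial still defines its successors' labels
  expect_equal(lab$seq_label[3], "RR")
  expect_equal(lab$transition[6], "A")
  # flagged trials do not enter the summaries
  ss <- summarize_by_sequence(lab)
  expect_equal(sum(ss$n_total), sum(!lab$outlier & !is.na(lab$seq_label)))
})

test_that("sequence summaries do brute-force arithmetic per cell", {
  # two RR trials: rt 0.4 correct, rt 0.3 error
  tt <- data.frame(block = 1, trial = 1:4, stimulus = c(1L, 1L, 1L, 1L),
                   correct = c(TRUE, TRUE, TRUE, FALSE),
                   rt = c(0.5, 0.5, 0.4, 0.3))
  ss <- summarize_by_sequence(flag_outliers(label_sequences(tt)))
  rr <- ss[ss$label == "RR", ]
  expect_equal(rr$n_total, 2)
  expect_equal(rr$rt_mean, 0.35)
  expect_equal(rr$rt_correct, 0.4)
  expect_equal(rr$rt_error, 0.3)
  expect_equal(rr$er, 0.5)
  # empty cells are NA with zero counts, never zero means
  ar <- ss[ss$label == "AR", ]
  expect_equal(ar$n_total, 0)
  expect_true(is.na(ar$rt_mean))

  # an all-correct table has ER 0 and undefined error means
  tt$correct <- TRUE
  ss2 <- summarize_by_sequence(flag_outliers(label_sequences(tt)))
  expect_true(all(is.na(ss2$rt_error)))
  expect_equal(ss2$er[ss2$label == "RR"], 0)

  # row order does not matter
  set.seed(4)
  lab <- flag_outliers(label_sequences(tt))
  expect_equal(summarize_by_sequence(lab[sample(nrow(lab)), ]),
               summarize_by_sequence(lab))
})

test_that("pooled means equal the ER-weighted mix of correct and error means", {
  sched <- generate_experiment_schedule("exp1")
  sub <- generate_synthetic_subject(exp1_pars, sched, seed = 22)
  ss <- summarize_by_sequence(flag_outliers(label_sequences(sub$trials)))
  for (i in seq_len(nrow(ss))) {
    if (ss$n_error[i] > 0 && ss$n_correct[i] > 0)
      expect_equal((1 - ss$er[i]) * ss$rt_correct[i] + ss$er[i] * ss$rt_error[i],
                   ss$rt_mean[i], tolerance = 1e-12)
  }
  # long unbiased block: all four labels near one quarter of labeled trials
  n_lab <- sum(ss$n_total)
  for (l in c("RR", "AR", "RA", "AA"))
    expect_lt(abs(ss$n_total[ss$label == l] / n_lab - 0.25),
              3 * sqrt(0.25 * 0.75 / n_lab) + 0.01)
})

test_that("error triplets require in-block neighbors and skip outlier entries", {
  tt <- data.frame(block = 1, trial = 1:5, stimulus = 1L,
                   correct = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                   rt = c(0.40, 0.35, 0.50, 0.45, 0.30))
  # error at trial 5 has no successor -> only the trial-2 error counts
  trip <- summarize_error_triplets(flag_outliers(label_sequences(tt)))
  expect_equal(trip$n_triplets, 1)
  expect_equal(trip$rt_pre, 0.40)
  expect_equal(trip$rt_on, 0.35)
  expect_equal(trip$rt_post, 0.50)

  # an error on the first trial of a block is excluded too
  tt2 <- tt; tt2$correct <- c(FALSE, TRUE, TRUE, TRUE, TRUE)
  expect_equal(summarize_error_triplets(label_sequences(tt2))$n_triplets, 0)

  # consecutive errors each contribute their own triplet
  tt3 <- data.frame(block = 1, trial = 1:4, stimulus = 1L,
                    correct = c(TRUE, FALSE, FALSE, TRUE),
                    rt = c(0.4, 0.3, 0.32, 0.5))
  trip3 <- summarize_error_triplets(label_sequences(tt3))
  expect_equal(trip3$n_triplets, 2)
  expect_equal(trip3$rt_pre, mean(c(0.4, 0.3)))

  # outlier neighbor is dropped from its position's mean only
  tt4 <- tt; tt4$rt[3] <- 1.5
  trip4 <- summarize_error_triplets(flag_outliers(label_sequences(tt4)))
  expect_equal(trip4$n_triplets, 1)
  expect_true(is.na(trip4$rt_post))
  expect_equal(trip4$rt_pre, 0.40)
})

test_that("summary vectors have the canonical length and ordering", {
  sched <- generate_experiment_schedule("exp1")
  sub <- generate_synthetic_subject(exp1_pars, sched, seed = 23)
  v <- summary_vector(sub$trials)
  expect_length(v, 19)
  expect_equal(names(v)[1:4], paste0("rt_mean_", c("RR", "AR", "RA", "AA")))
  expect_equal(names(v)[17:19],
               c("rt_pre_error", "rt_on_error", "rt_post_error"))

  sched2 <- generate_experiment_schedule("exp2", seed = 24)
  sub2 <- generate_synthetic_subject(exp2_pars, sched2, seed = 25)
  v2 <- summary_vector(sub2$trials, by_condition = TRUE)
  expect_length(v2, 57)
  expect_equal(attr(v2, "n_conditions"), 3)
  # conditions ordered by increasing p_alt
  expect_true(startsWith(names(v2)[1], "p0.1:"))
  expect_true(startsWith(names(v2)[39], "p0.9:"))

  # round-trip through text serialization
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(element = names(v2), value = as.numeric(v2)),
                   tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(back$value, as.numeric(v2))
  unlink(tmp)
})

test_that("tradeoff regression recovers exact collinear geometry", {
  ss <- data.frame(condition = NA_real_, label = c("RR", "AR", "RA"),
                   rt_correct = c(0.3, 0.4, 0.5),
                   rt_error = c(0.5, 0.4, 0.3))
  tr <- tradeoff_statistics(ss)
  expect_equal(tr$slope, -1)
  expect_equal(tr$r_squared, 1)

  ss$rt_error <- c(0.5, 0.4, 0.45)  # not collinear
  expect_lt(tradeoff_statistics(ss)$r_squared, 1)

  expect_error(tradeoff_statistics(ss[1:2, ]), "at least 3")
})

test_that("line geometry reports signed R-line and A-line slopes", {
  ss <- data.frame(condition = NA_real_, label = c("RR", "AR", "RA", "AA"),
                   rt_mean = c(0.30, 0.38, 0.40, 0.35))
  lg <- line_geometry(ss)
  expect_equal(lg$r_line_slope, 0.08)
  expect_equal(lg$a_line_slope, 0.05)

  # equal means everywhere: both slopes zero
  ss$rt_mean <- 0.4
  lg0 <- line_geometry(ss)
  expect_equal(lg0$r_line_slope, 0)
  expect_equal(lg0$a_line_slope, 0)

  # swapping the R/A roles swaps the slopes
  ss2 <- data.frame(condition = NA_real_, label = c("RR", "AR", "RA", "AA"),
                    rt_mean = c(0.40, 0.35, 0.38, 0.30))
  lg2 <- line_geometry(ss2)
  expect_equal(lg2$r_line_slope, -0.05)
  expect_equal(lg2$a_line_slope, 0.08)
})
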