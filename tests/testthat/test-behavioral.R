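test_that("filtering removes guesses and out-of-range response times", {
  trials <- rbind(
    make_trial(trial_index = 1, rt_ms = 100), # anticipatory
    make_trial(trial_index = 2, rt_ms = 149.9), # anticipatory (strict)
    make_trial(trial_index = 3, rt_ms = 150), # kept: bound is strict
    make_trial(trial_index = 4, rt_ms = 5000), # kept: bound is strict
    make_trial(trial_index = 5, rt_ms = 5000.1), # slow outlier
    make_trial(trial_index = 6, confidence = 50), # guess
    make_trial(trial_index = 7, format = "split")
  )
  out <- filter_trials(trials)
  expect_equal(out$kept$trial_index, c(3, 4, 7))
  expect_equal(out$removed$trial_index, c(1, 2, 5, 6))
  expect_equal(out$report$n_removed, 4L)
  expect_equal(out$report$by_reason$fast_guess, 2L)
  expect_equal(out$report$by_reason$slow_outlier, 1L)
  expect_equal(out$report$by_reason$confidence_50, 1L)
  expect_equal(out$report$fraction_by_format$split, 0)
  # partition: kept and removed reassemble the input
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(trials))
  expect_setequal(c(out$kept$trial_index, out$removed$trial_index),
                  trials$trial_index)
})

test_that("accuracy coding matches the correct family", {
  trials <- rbind(
    make_trial(response = "A"), # w_A/s_A
    make_trial(top_strength = "m", bottom_family = "B",
               bottom_strength = "w", response = "B"), # m_A/w_B, B wrong
    make_trial(top_family = NA, top_strength = NA, bottom_family = "B",
               bottom_strength = "m", response = "B") # half m_B
  )
  expect_equal(code_accuracy(trials)$correct, c(1L, 0L, 1L))
})

# a small deterministic trial set: participant 1 sees half faces with known
# accuracies plus whole faces
half_block <- function(participant, acc_top_w, acc_bot_s, n = 10) {
  rbind(
    make_trial(participant, trial_index = seq_len(n), format = "half",
               top_family = "A", top_strength = "w",
               bottom_family = NA, bottom_strength = NA,
               response = rep(c("A", "B"),
                              c(round(acc_top_w * n), n - round(acc_top_w * n)))),
    make_trial(participant, trial_index = n + seq_len(n), format = "half",
               top_family = NA, top_strength = NA,
               bottom_family = "A", bottom_strength = "s",
               response = rep(c("A", "B"),
                              c(round(acc_bot_s * n), n - round(acc_bot_s * n))))
  )
}

test_that("half-face means and the stronger-half rule follow the data", {
  trials <- code_accuracy(half_block(1, acc_top_w = 0.6, acc_bot_s = 0.8))
  means <- half_face_means(trials)
  expect_equal(nrow(means), 2L)
  expect_equal(means$accuracy[means$location == "top"], 0.6)
  expect_equal(means$accuracy[means$location == "bottom"], 0.8)
  face <- cbind(participant = 1, make_trial(top_strength = "w",
                                            bottom_strength = "s"))
  ref <- stronger_half(means, face)
  expect_equal(ref$location, "bottom")
  expect_equal(ref$accuracy, 0.8)
  # the empirical rule overrides the strength labels
  means2 <- half_face_means(
    code_accuracy(half_block(1, acc_top_w = 0.9, acc_bot_s = 0.7))
  )
  ref2 <- stronger_half(means2, face)
  expect_equal(ref2$location, "top")
  expect_equal(ref2$accuracy, 0.9)
  # exact tie on w/s: the strength label breaks it toward the strong half
  means3 <- half_face_means(
    code_accuracy(half_block(1, acc_top_w = 0.8, acc_bot_s = 0.8))
  )
  expect_equal(stronger_half(means3, face)$location, "bottom")
  # missing half-face data is an error
  expect_error(
    stronger_half(means[means$location == "top", , drop = FALSE], face),
    "no half-face mean"
  )
})

test_that("deviation scores subtract the stronger half's mean accuracy", {
  trials <- rbind(
    half_block(1, acc_top_w = 0.6, acc_bot_s = 0.8),
    make_trial(1, trial_index = 100, response = "A"), # correct whole
    make_trial(1, trial_index = 101, response = "B") # error whole
  )
  dev <- deviation_scores(code_accuracy(trials))
  expect_equal(nrow(dev), 2L)
  expect_equal(dev$deviation, c(1 - 0.8, 0 - 0.8))
  expect_true(all(dev$deviation >= -1 & dev$deviation <= 1))
  # at-ceiling reference: a correct response deviates by zero
  trials2 <- rbind(
    half_block(2, acc_top_w = 0.5, acc_bot_s = 1),
    make_trial(2, trial_index = 100, response = "A")
  )
  dev2 <- deviation_scores(code_accuracy(trials2))
  expect_equal(dev2$deviation, 0)
})

test_that("condition summaries average participants then compute SEMs", {
  trials <- rbind(
    half_block(1, 0.6, 0.8),
    make_trial(1, trial_index = 100:109,
               response = rep(c("A", "B"), c(8, 2))), # p1 ws: .8
    half_block(2, 0.6, 0.8),
    make_trial(2, trial_index = 100:109,
               response = rep(c("A", "B"), c(9, 1))) # p2 ws: .9
  )
  s <- summarize_conditions(filter_trials(trials)$kept)
  ws <- s[s$condition == "ws" & s$format == "together", ]
  expect_equal(ws$acc_mean, 0.85)
  expect_equal(ws$acc_sem, stats::sd(c(0.8, 0.9)) / sqrt(2))
  expect_equal(ws$acc_sem, 0.05)
  expect_equal(ws$n_participants, 2L)
  # w/s and s/w trials share the ws cell (half-face means for the s top
  # and w bottom halves are needed for the swapped face's deviation)
  swapped <- rbind(
    make_trial(1, trial_index = 200,
               top_strength = "s", bottom_strength = "w"),
    make_trial(1, trial_index = 201:202, format = "half",
               top_family = "A", top_strength = "s",
               bottom_family = NA, bottom_strength = NA),
    make_trial(1, trial_index = 203:204, format = "half",
               top_family = NA, top_strength = NA,
               bottom_family = "A", bottom_strength = "w")
  )
  s2 <- summarize_conditions(
    filter_trials(rbind(trials, swapped))$kept
  )
  expect_equal(
    s2$n_participants[s2$condition == "ws" & s2$format == "together"], 2L
  )
  # single-participant cells get a flagged, NA SEM
  solo <- rbind(half_block(3, 0.6, 0.8),
                make_trial(3, trial_index = 300, format = "split"))
  s3 <- summarize_conditions(filter_trials(solo)$kept)
  split_ws <- s3$condition == "ws" & s3$format == "split"
  expect_equal(s3$acc_mean[split_ws], 1)
  expect_true(is.na(s3$acc_sem[split_ws]))
  expect_true("ws split" %in% attr(s3, "flagged"))
})

test_that("the pipeline is invariant to trial order", {
  sim <- simulate_experiment(sim_config(n_participants = 3, seed = 21))
  kept <- code_accuracy(filter_trials(sim$trials)$kept)
  s1 <- summarize_conditions(kept)
  perm <- withr::with_seed(1, sample(nrow(kept)))
  s2 <- summarize_conditions(kept[perm, , drop = FALSE])
  expect_equal(s2, s1, ignore_attr = TRUE)
})

test_that("condition-mean deviation equals accuracy minus reference", {
  sim <- simulate_experiment(sim_config(n_participants = 4, seed = 31))
  kept <- code_accuracy(filter_trials(sim$trials)$kept)
  dev <- deviation_scores(kept)
  # per participant and condition, mean deviation = mean accuracy - the
  # stronger-half reference (constant within participant x face)
  key <- paste(dev$participant, dev$condition, dev$format)
  lhs <- tapply(dev$deviation, key, mean)
  rhs <- tapply(dev$correct - dev$stronger_accuracy, key, mean)
  expect_equal(as.numeric(lhs), as.numeric(rhs))
})

test_that("strength differences code as -1, 0, +1", {
  trials <- rbind(
    half_block(1, 0.6, 0.8),
    make_trial(1, trial_index = 100, top_strength = "w",
               bottom_strength = "s"),
    make_trial(1, trial_index = 101, top_strength = "m",
               bottom_strength = "m"),
    make_trial(1, trial_index = 102, top_strength = "m",
               bottom_strength = "s")
  )
  trials <- code_accuracy(trials)
  # mm and ms faces need half-face means for the m halves too
  trials <- rbind(trials, code_accuracy(rbind(
    make_trial(1, trial_index = 110:113, format = "half",
               top_family = NA, top_strength = NA,
               bottom_family = "A", bottom_strength = "m",
               response = c("A", "A", "A", "B")),
    make_trial(1, trial_index = 114:117, format = "half",
               top_family = "A", top_strength = "m",
               bottom_family = NA, bottom_strength = NA,
               response = c("A", "A", "A", "B"))
  )))
  tab <- strength_difference_table(deviation_scores(trials))
  expect_setequal(tab$strength_difference, c(-1, 0, 1))
  expect_equal(tab$n_trials[tab$strength_difference == 1], 1L)
  empty <- strength_difference_table(
    deviation_scores(code_accuracy(half_block(1, 0.6, 0.8)))
  )
  expect_equal(nrow(empty), 0L)
})

test_that("median splits are computed within participant", {
  trials <- rbind(
    half_block(1, 0.6, 0.8),
    make_trial(1, trial_index = 100:103, rt_ms = c(400, 600, 800, 1000)),
    half_block(2, 0.6, 0.8),
    make_trial(2, trial_index = 100:103, rt_ms = c(2000, 2200, 2400, 2600))
  )
  ms <- median_split(deviation_scores(code_accuracy(trials)))
  # participant 2's fastest trials are slower than participant 1's slowest,
  # yet still count as fast within participant 2
  p2_fast <- ms[ms$participant == "2" & ms$format == "all" &
                  ms$speed == "fast", ]
  expect_equal(p2_fast$n_trials, 2L)
  # trials at the median count as slow
  p1_slow <- ms[ms$participant == "1" & ms$format == "all" &
                  ms$speed == "slow", ]
  expect_equal(p1_slow$n_trials, 2L)
  # degenerate all-identical RTs: everything slow, participant flagged
  one <- rbind(half_block(3, 0.6, 0.8),
               make_trial(3, trial_index = 100:101, rt_ms = 700))
  ms3 <- median_split(deviation_scores(code_accuracy(one)))
  expect_true("3" %in% attr(ms3, "flagged"))
  expect_true(all(ms3$speed[ms3$participant == "3"] == "slow"))
})

test_that("trial tables survive a CSV round trip", {
  sim <- simulate_experiment(sim_config(n_participants = 1, n_blocks = 1,
                                        seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  back <- read_trials(path)
  expect_equal(back$rt_ms, sim$trials$rt_ms)
  expect_equal(back$response, sim$trials$response)
  expect_equal(nrow(back), 68L)
})
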