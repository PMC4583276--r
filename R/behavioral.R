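# Trial-level behavioral pipeline: contaminant filtering, accuracy coding,
# per-participant deviation scores against the stronger half face, and the
# collapsed condition summary (the input to model fitting), plus the
# strength-difference and fast/slow median-split analyses.

CONFIDENCE_LEVELS <- c(50, 60, 70, 80, 90, 100)
RT_MIN_MS <- 150
RT_MAX_MS <- 5000

check_trials <- function(trials) {
  needed <- c(
    "participant", "block", "trial_index", "format", "top_family",
    "top_strength", "bottom_family", "bottom_strength", "response",
    "rt_ms", "confidence"
  )
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(trials)
}

#' Remove contaminated trials
#'
#' Drops trials with a confidence rating of 50% (a guess by the
#' participant's own report), or a response time below 150 ms (anticipatory)
#' or above 5 s (lapse).  Bounds are strict, so rt = 150 and rt = 5000 ms
#' are kept.
#'
#' @param trials A trial data frame (see [simulate_experiment()] for the
#'   schema).
#' @return A list with `kept`, `removed` (the complementary rows), and
#'   `report`: counts and fractions removed by reason and by format.
#' @export
filter_trials <- function(trials) {
  check_trials(trials)
  fast <- trials$rt_ms < RT_MIN_MS
  slow <- trials$rt_ms > RT_MAX_MS
  guess <- trials$confidence == 50
  drop <- fast | slow | guess
  by_format <- tapply(drop, trials$format, mean)
  report <- list(
    n_total = nrow(trials),
    n_removed = sum(drop),
    fraction_removed = mean(drop),
    by_reason = list(
      fast_guess = sum(fast), slow_outlier = sum(slow),
      confidence_50 = sum(guess)
    ),
    fraction_by_format = as.list(by_format)
  )
  list(
    kept = trials[!drop, , drop = FALSE],
    removed = trials[drop, , drop = FALSE],
    report = report
  )
}

#' Code each response as correct or incorrect
#'
#' A response is correct when it names the family of [correct_family()]:
#' the shared family for half and whole faces, the stronger (medium) half's
#' family for opposite faces.
#'
#' @param trials A trial data frame.
#' @return `trials` with an integer `correct` column (0/1) appended.
#' @export
code_accuracy <- function(trials) {
  check_trials(trials)
  trials$correct <- as.integer(trials$response == correct_family(trials))
  trials
}

half_condition_key <- function(trials) {
  loc <- ifelse(is.na(trials$top_family), "bottom", "top")
  fam <- ifelse(loc == "top", trials$top_family, trials$bottom_family)
  st <- ifelse(loc == "top", trials$top_strength, trials$bottom_strength)
  paste(loc, fam, st)
}

#' Per-participant half-face accuracy means
#'
#' Mean accuracy for every half-face condition (location x family x
#' strength), per participant, computed after filtering.  These means
#' define each participant's "stronger half" for the deviation scores.
#'
#' @param trials Filtered, accuracy-coded trials.
#' @return A data frame `participant`, `location`, `family`, `strength`,
#'   `accuracy`, `n_trials`.
#' @export
half_face_means <- function(trials) {
  half <- trials[face_type(trials) == "half", , drop = FALSE]
  if (!"correct" %in% names(half)) stop("run code_accuracy() first")
  key <- paste(half$participant, half_condition_key(half))
  agg <- tapply(half$correct, key, mean)
  cnt <- tapply(half$correct, key, length)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  data.frame(
    participant = vapply(parts, `[`, character(1), 1L),
    location = vapply(parts, `[`, character(1), 2L),
    family = vapply(parts, `[`, character(1), 3L),
    strength = vapply(parts, `[`, character(1), 4L),
    accuracy = as.numeric(agg),
    n_trials = as.integer(cnt),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Identify the stronger half of each whole face for a participant
#'
#' The stronger half is the one whose matching half-face condition has the
#' higher empirical accuracy for that participant; ties are broken by the
#' calibrated strength label (s > m > w), then in favour of the top half.
#' For opposite faces the stronger half is the medium half by definition
#' of the correct response.
#'
#' @param means Output of [half_face_means()].
#' @param faces Whole/opposite face rows with a `participant` column.
#' @param strict Error if a required half-face mean is absent (default);
#'   with `strict = FALSE` such rows get NA.
#' @return A list with `location` (`"top"`/`"bottom"`) and
#'   `accuracy` (the stronger half's mean accuracy) per row of `faces`.
#' @export
stronger_half <- function(means, faces, strict = TRUE) {
  mean_key <- paste(means$participant, means$location, means$family,
                    means$strength)
  top_acc <- means$accuracy[match(
    paste(faces$participant, "top", faces$top_family, faces$top_strength),
    mean_key
  )]
  bot_acc <- means$accuracy[match(
    paste(faces$participant, "bottom", faces$bottom_family,
          faces$bottom_strength),
    mean_key
  )]
  if (strict && (anyNA(top_acc) || anyNA(bot_acc))) {
    bad <- which(is.na(top_acc) | is.na(bot_acc))
    stop("no half-face mean for participant/face row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  rank <- function(s) match(s, STRENGTHS)
  top_wins <- top_acc > bot_acc |
    (top_acc == bot_acc &
       rank(faces$top_strength) >= rank(faces$bottom_strength))
  # opposite faces: the stronger half is the medium half by definition of
  # the correct response, not by the empirical rule
  opp <- face_type(faces) == "opposite"
  top_wins[opp] <- faces$top_strength[opp] == "m"
  list(
    location = ifelse(top_wins, "top", "bottom"),
    accuracy = ifelse(top_wins, top_acc, bot_acc)
  )
}

#' Per-trial deviation scores
#'
#' For every whole and opposite trial: trial accuracy (0/1) minus the
#' participant's mean accuracy for the stronger half face presented alone.
#' Negative values indicate dilution (the added half hurt); positive
#' values indicate additive integration.
#'
#' @param trials Filtered, accuracy-coded trials.
#' @param means Output of [half_face_means()]; computed from `trials` if
#'   omitted.
#' @return The whole/opposite rows of `trials` with `condition`,
#'   `stronger_location`, `stronger_accuracy`, `deviation` appended.
#' @export
deviation_scores <- function(trials, means = half_face_means(trials)) {
  if (!"correct" %in% names(trials)) stop("run code_accuracy() first")
  whole <- trials[face_type(trials) != "half", , drop = FALSE]
  ref <- stronger_half(means, whole, strict = FALSE)
  whole$condition <- condition_label(whole)
  whole$stronger_location <- ref$location
  whole$stronger_accuracy <- ref$accuracy
  whole$deviation <- whole$correct - ref$accuracy
  # a participant with no surviving trials of a constituent half-face
  # condition contributes no deviation for that face
  dropped <- sum(is.na(ref$accuracy))
  whole <- whole[!is.na(whole$deviation), , drop = FALSE]
  structure(whole, n_dropped_missing_reference = dropped)
}

participant_cell_means <- function(values, participant, cell) {
  key <- paste(participant, cell)
  agg <- tapply(values, key, mean)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  data.frame(
    participant = vapply(parts, `[`, character(1), 1L),
    cell = vapply(parts, function(x) paste(x[-1L], collapse = " "),
                  character(1)),
    mean = as.numeric(agg),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

grand_summary <- function(pm) {
  agg_mean <- tapply(pm$mean, pm$cell, mean)
  agg_sd <- tapply(pm$mean, pm$cell, stats::sd)
  agg_n <- tapply(pm$mean, pm$cell, length)
  data.frame(
    cell = names(agg_mean),
    mean = as.numeric(agg_mean),
    sem = as.numeric(agg_sd) / sqrt(as.numeric(agg_n)),
    n_participants = as.integer(agg_n),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Collapsed condition summary
#'
#' Produces the observed summary used for model fitting: for each of the
#' 17 collapsed conditions, participant-level means are computed first and
#' then averaged, with between-subject SEMs (sd of participant means /
#' sqrt(n)).  Deviation cells cover the 14 whole/opposite conditions.
#' Conditions observed in fewer than two participants get an NA SEM and
#' are listed in attribute `"flagged"`.
#'
#' @param trials Filtered trials (accuracy coding is applied here if
#'   absent).
#' @param deviations Optional output of [deviation_scores()]; computed
#'   from `trials` if omitted.
#' @return A data frame `condition`, `format`, `acc_mean`, `acc_sem`,
#'   `rt_mean`, `rt_sem`, `dev_mean`, `dev_sem`, `n_participants`.
#' @export
summarize_conditions <- function(trials, deviations = NULL) {
  check_trials(trials)
  if (!"correct" %in% names(trials)) trials <- code_accuracy(trials)
  if (is.null(deviations)) deviations <- deviation_scores(trials)
  cell <- paste(condition_label(trials), trials$format)
  acc <- grand_summary(
    participant_cell_means(trials$correct, trials$participant, cell)
  )
  rt <- grand_summary(
    participant_cell_means(trials$rt_ms, trials$participant, cell)
  )
  dcell <- paste(deviations$condition, deviations$format)
  dev <- grand_summary(
    participant_cell_means(deviations$deviation, deviations$participant, dcell)
  )
  cond <- condition_table()
  key <- paste(cond$condition, cond$format)
  out <- data.frame(
    condition = cond$condition,
    format = cond$format,
    acc_mean = acc$mean[match(key, acc$cell)],
    acc_sem = acc$sem[match(key, acc$cell)],
    rt_mean = rt$mean[match(key, rt$cell)],
    rt_sem = rt$sem[match(key, rt$cell)],
    dev_mean = dev$mean[match(key, dev$cell)],
    dev_sem = dev$sem[match(key, dev$cell)],
    n_participants = acc$n_participants[match(key, acc$cell)],
    stringsAsFactors = FALSE
  )
  flagged <- key[!is.na(out$acc_mean) & is.na(out$acc_sem) |
                   out$format != "half" &
                   !is.na(out$dev_mean) & is.na(out$dev_sem)]
  structure(out, flagged = flagged)
}

#' Deviation means by absolute strength difference
#'
#' Codes each whole-face deviation by the difference between its two
#' strength labels — equal pairs (ww, mm, ss) as -1, one-step pairs (wm,
#' ms) as 0, the two-step pair (ws) as +1 — and returns per-participant
#' mean deviations by code and format.  Dilution growing with strength
#' disparity shows up as a decreasing trend in this table.
#'
#' @param deviations Output of [deviation_scores()]; opposite (wom) trials
#'   are excluded.
#' @return A data frame `participant`, `format`, `strength_difference`,
#'   `deviation_mean`, `n_trials`.
#' @export
strength_difference_table <- function(deviations) {
  whole <- deviations[face_type(deviations) == "whole", , drop = FALSE]
  if (nrow(whole) == 0L) {
    return(data.frame(
      participant = character(0), format = character(0),
      strength_difference = numeric(0), deviation_mean = numeric(0),
      n_trials = integer(0), stringsAsFactors = FALSE
    ))
  }
  diff_code <- abs(match(whole$top_strength, STRENGTHS) -
                     match(whole$bottom_strength, STRENGTHS)) - 1
  key <- paste(whole$participant, whole$format, diff_code)
  agg <- tapply(whole$deviation, key, mean)
  cnt <- tapply(whole$deviation, key, length)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  data.frame(
    participant = vapply(parts, `[`, character(1), 1L),
    format = vapply(parts, `[`, character(1), 2L),
    strength_difference = as.numeric(vapply(parts, `[`, character(1), 3L)),
    deviation_mean = as.numeric(agg),
    n_trials = as.integer(cnt),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fast/slow median-split deviation analysis
#'
#' Splits each participant's whole-face trials at their own median RT
#' (trials at the median count as slow) and returns mean deviation scores
#' for fast and slow trials, overall and by format.  Lower deviations on
#' slow trials are the signature of controlled, averaging-like
#' integration.
#'
#' @param deviations Output of [deviation_scores()] (whole faces are
#'   used; opposite trials are excluded).
#' @return A data frame `participant`, `format` (including `"all"`),
#'   `speed`, `deviation_mean`, `n_trials`.  Participants with an empty
#'   fast cell (e.g. all-identical RTs) are listed in attribute
#'   `"flagged"`.
#' @export
median_split <- function(deviations) {
  whole <- deviations[face_type(deviations) == "whole", , drop = FALSE]
  med <- tapply(whole$rt_ms, whole$participant, stats::median)
  speed <- ifelse(whole$rt_ms < med[as.character(whole$participant)],
                  "fast", "slow")
  fmt <- c(as.character(whole$format), rep("all", nrow(whole)))
  key <- paste(
    rep(whole$participant, 2L), fmt, rep(speed, 2L)
  )
  dev2 <- rep(whole$deviation, 2L)
  agg <- tapply(dev2, key, mean)
  cnt <- tapply(dev2, key, length)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  out <- data.frame(
    participant = vapply(parts, `[`, character(1), 1L),
    format = vapply(parts, `[`, character(1), 2L),
    speed = vapply(parts, `[`, character(1), 3L),
    deviation_mean = as.numeric(agg),
    n_trials = as.integer(cnt),
    row.names = NULL, stringsAsFactors = FALSE
  )
  has_fast <- unique(out$participant[out$speed == "fast"])
  flagged <- setdiff(unique(out$participant), has_fast)
  structure(out, flagged = flagged)
}

#' Read or write tidy trial tables as CSV
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return `read_trials()` returns the trial data frame.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  check_trials(utils::read.csv(path, stringsAsFactors = FALSE))
}
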