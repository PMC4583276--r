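# Monte-Carlo generator.  Trials are produced by the McIA generative
# process itself (simulated random walks at each face's step probability),
# so the generator doubles as the independent oracle for the closed-form
# predictions and as the input factory for the behavioral pipeline and for
# parameter-recovery studies.  Contaminant trials (anticipatory responses,
# slow outliers, 50%-confidence guesses) are planted at configurable rates
# to exercise the filters.

#' Simulation configuration
#'
#' Defaults reproduce the experiment's scale: 19 participants, 1 + 3
#' integration blocks of 68 trials, generating parameters at the published
#' best-fitting values, and a combined contamination rate of about 13%
#' (the reported fraction of removed trials), split between anticipatory
#' responses, slow outliers, and 50%-confidence guesses.
#'
#' @param n_participants Number of simulated participants.
#' @param n_blocks Integration blocks per participant.
#' @param seed Integer master seed; every downstream RNG stream derives
#'   from it.
#' @param params Generating [mcia_params()].
#' @param variant Generating variant id.
#' @param jitter_sd Scale of between-participant parameter variability:
#'   lognormal on theta and k, logit-normal on alpha and the deltas (0
#'   disables jitter).
#' @param rate_fast,rate_slow,rate_conf50 Contamination rates (fractions
#'   of trials overwritten with rt < 150 ms, rt > 5000 ms, or
#'   confidence = 50); must sum below 1.
#' @param observer_midpoint,observer_slope,observer_lapse Synthetic
#'   observer used for the calibration staircases.
#' @return A list of class `mcia_sim_config`.
#' @export
sim_config <- function(n_participants = 19L, n_blocks = 4L, seed = 1L,
                       params = mcia_params(), variant = "full",
                       jitter_sd = 0.1,
                       rate_fast = 0.052, rate_slow = 0.052,
                       rate_conf50 = 0.026,
                       observer_midpoint = 75, observer_slope = 0.08,
                       observer_lapse = 0.02) {
  stopifnot(
    n_participants >= 1L, n_blocks >= 1L,
    rate_fast >= 0, rate_slow >= 0, rate_conf50 >= 0,
    rate_fast + rate_slow + rate_conf50 < 1,
    jitter_sd >= 0
  )
  validate_params(params)
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_blocks = as.integer(n_blocks), seed = as.integer(seed),
      params = params, variant = check_variant(variant),
      jitter_sd = jitter_sd,
      rate_fast = rate_fast, rate_slow = rate_slow,
      rate_conf50 = rate_conf50,
      observer_midpoint = observer_midpoint,
      observer_slope = observer_slope, observer_lapse = observer_lapse
    ),
    class = "mcia_sim_config"
  )
}

#' Simulate random walks to absorption
#'
#' Unit-step walks from 0 with probability `p` of stepping toward the
#' correct boundary, absorbed at `+theta` (correct) or `-theta` (error).
#' All `n` replicates advance in lockstep vectorized sweeps.
#'
#' @param p Step probability in (0, 1).
#' @param theta Threshold (> 0); absorption requires `|position| >= theta`.
#' @param n Number of replicate walks.
#' @param step_cap Safety cap on steps per walk (default 1e6).
#' @return A data frame with logical `correct` and integer `n_steps`.
#' @export
simulate_walks <- function(p, theta, n = 1L, step_cap = 1e6) {
  stopifnot(p > 0, p < 1, theta > 0, n >= 1L)
  position <- numeric(n)
  steps <- integer(n)
  correct <- logical(n)
  active <- seq_len(n)
  pos_active <- position[active]
  steps_taken <- 0L
  while (length(active)) {
    steps_taken <- steps_taken + 1L
    if (steps_taken > step_cap) {
      stop("walk exceeded step cap (", format(step_cap), " steps); ",
           "check p and theta")
    }
    pos_active <- pos_active +
      ifelse(stats::runif(length(active)) < p, 1, -1)
    done <- abs(pos_active) >= theta
    if (any(done)) {
      idx <- active[done]
      steps[idx] <- steps_taken
      correct[idx] <- pos_active[done] > 0
      active <- active[!done]
      pos_active <- pos_active[!done]
    }
  }
  data.frame(correct = correct, n_steps = steps)
}

#' @rdname simulate_walks
#' @export
simulate_walk <- function(p, theta, step_cap = 1e6) {
  out <- simulate_walks(p, theta, n = 1L, step_cap = step_cap)
  list(correct = out$correct, n_steps = out$n_steps)
}

# map step counts to the 60..100 confidence scale: faster decisions
# (relative to threshold) read as more confident, with one categorical
# noise step in either direction
confidence_from_steps <- function(n_steps, theta) {
  breaks <- theta * c(2, 4, 8, 16)
  idx <- findInterval(n_steps, breaks) + 1L # 1 (fast) .. 5 (slow)
  shift <- sample(c(-1L, 0L, 1L), length(idx),
    replace = TRUE, prob = c(0.2, 0.6, 0.2)
  )
  idx <- pmin(pmax(idx + shift, 1L), 5L)
  c(100, 90, 80, 70, 60)[idx]
}

jitter_participant_params <- function(params, sd) {
  if (sd == 0) return(params)
  jl <- function(v) v * exp(stats::rnorm(1L, sd = sd)) # lognormal
  jp <- function(v) { # logit-normal, degenerate 0/1 left untouched
    if (v <= 0 || v >= 1) return(v)
    inv_logit(logit(v) + stats::rnorm(1L, sd = 2 * sd))
  }
  jd <- function(v) { # deltas stay in (0.5, 1)
    DELTA_LO + (1 - DELTA_LO) *
      jp((v - DELTA_LO) / (1 - DELTA_LO))
  }
  params$theta <- jl(params$theta)
  params$k <- jl(params$k)
  params$alpha <- jp(params$alpha)
  params$delta_weak <- jd(params$delta_weak)
  params$delta_medium <- jd(params$delta_medium)
  params$delta_strong <- jd(params$delta_strong)
  validate_params(params)
  params
}

#' Simulate trials for a set of faces
#'
#' Runs one McIA random walk per face row: the response follows the
#' absorbing boundary, rt = tau + k * N (h-scaled for half faces), and
#' confidence is a monotone-decreasing function of the step count over
#' \{60..100\} (the generative model does not define confidence; this
#' placeholder exists so the confidence filter and I/O schema are
#' exercised).
#'
#' @param faces A face data frame (e.g. a block from [build_block()]).
#' @param params [mcia_params()].
#' @param variant Variant id.
#' @return `faces` with `response`, `rt_ms`, `n_steps`, `confidence`
#'   appended.
#' @export
simulate_trials <- function(faces, params, variant = "full") {
  p <- step_probability(faces, params, variant)
  type <- face_type(faces)
  correct <- logical(nrow(faces))
  n_steps <- integer(nrow(faces))
  # walks grouped by step probability so replicates run vectorized
  for (pv in unique(p)) {
    rows <- which(p == pv)
    w <- simulate_walks(pv, params$theta, n = length(rows))
    correct[rows] <- w$correct
    n_steps[rows] <- w$n_steps
  }
  target <- correct_family(faces)
  other <- ifelse(target == "A", "B", "A")
  step_ms <- ifelse(type == "half", params$h * params$k, params$k)
  faces$response <- ifelse(correct, target, other)
  faces$rt_ms <- params$tau + step_ms * n_steps
  faces$n_steps <- n_steps
  faces$confidence <- confidence_from_steps(n_steps, params$theta)
  faces
}

participant_seed <- function(master, participant, block = 0L) {
  ((master %% 100000L) * 10007L + participant * 211L + block * 17L) %%
    2147483647L
}

#' Simulate a full experiment
#'
#' Per participant: four simulated 2-up-1-down staircases calibrate the
#' medium morph levels (one per location x family), weak/strong levels are
#' interpolated, the 56 test faces are enumerated and arranged into
#' shuffled 68-trial blocks, and each trial is generated from the McIA
#' random walk at that participant's (optionally jittered) parameters.
#' Contaminant trials are then planted by overwriting rt with a uniform
#' draw from (0, 150) or (5000, 8000) ms, or confidence with 50, at the
#' configured rates; `contaminant` records the ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with `trials` (tidy trial data frame) and `truth`
#'   (generating parameters, per-participant parameters and calibrated
#'   levels, contamination bookkeeping).
#' @examples
#' sim <- simulate_experiment(sim_config(n_participants = 2, seed = 42))
#' nrow(sim$trials) # 2 participants x 4 blocks x 68 trials
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "mcia_sim_config"))
  observer <- psychometric_observer(
    config$observer_midpoint, config$observer_slope, config$observer_lapse
  )
  staircases <- as.vector(outer(LOCATIONS, FAMILIES, paste, sep = "."))
  per_participant <- vector("list", config$n_participants)
  truth_params <- vector("list", config$n_participants)
  truth_levels <- vector("list", config$n_participants)
  for (pid in seq_len(config$n_participants)) {
    mediums <- vapply(seq_along(staircases), function(i) {
      as.numeric(run_calibration(observer,
        seed = participant_seed(config$seed, pid, 1000L + i)
      ))
    }, numeric(1))
    levels <- calibration_levels(stats::setNames(mediums, staircases))
    faces <- enumerate_test_faces(levels)
    pparams <- withr::with_seed(
      participant_seed(config$seed, pid, 2000L),
      jitter_participant_params(config$params, config$jitter_sd)
    )
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      block <- build_block(faces, participant_seed(config$seed, pid, b))
      block <- withr::with_seed(
        participant_seed(config$seed, pid, 100L + b),
        simulate_trials(block, pparams, config$variant)
      )
      cbind(participant = pid, block = b, block)
    })
    per_participant[[pid]] <- do.call(rbind, blocks)
    truth_params[[pid]] <- pparams
    truth_levels[[pid]] <- levels
  }
  trials <- do.call(rbind, per_participant)
  trials <- withr::with_seed(
    participant_seed(config$seed, 0L, 3000L),
    plant_contaminants(trials, config)
  )
  rownames(trials) <- NULL
  list(
    trials = trials,
    truth = list(
      config = config,
      participant_params = truth_params,
      participant_levels = truth_levels,
      contamination = table(trials$contaminant)
    )
  )
}

plant_contaminants <- function(trials, config) {
  n <- nrow(trials)
  u <- stats::runif(n)
  kind <- rep("none", n)
  kind[u < config$rate_fast] <- "fast"
  kind[u >= config$rate_fast &
         u < config$rate_fast + config$rate_slow] <- "slow"
  kind[u >= config$rate_fast + config$rate_slow &
         u < config$rate_fast + config$rate_slow + config$rate_conf50] <-
    "conf50"
  trials$rt_ms[kind == "fast"] <- stats::runif(sum(kind == "fast"), 1, 149)
  trials$rt_ms[kind == "slow"] <- stats::runif(sum(kind == "slow"), 5001, 8000)
  trials$confidence[kind == "conf50"] <- 50
  trials$contaminant <- kind
  trials
}

#' Simulate an experiment and summarize it for fitting
#'
#' Single entry point for parameter-recovery studies: simulates an
#' experiment, runs the behavioral pipeline (filtering, accuracy coding,
#' deviation scores), and returns the collapsed condition summary.
#'
#' A condition at ceiling for every participant has a zero between-subject
#' SEM, which cannot weight a least-squares cell; such SEMs are floored to
#' the smallest nonzero SEM of the same measure (accuracy, RT, or
#' deviation) so the summary is always fittable.
#'
#' @param config A [sim_config()].
#' @return The observed summary (see [summarize_conditions()]), with the
#'   simulation attached as attribute `"sim"` and the removal report as
#'   `"removal_report"`.
#' @export
make_observed_summary <- function(config = sim_config()) {
  sim <- simulate_experiment(config)
  filt <- filter_trials(sim$trials)
  kept <- code_accuracy(filt$kept)
  summary <- summarize_conditions(kept)
  for (col in c("acc_sem", "rt_sem", "dev_sem")) {
    zero <- !is.na(summary[[col]]) & summary[[col]] == 0
    if (any(zero)) {
      summary[[col]][zero] <-
        min(summary[[col]][!zero & !is.na(summary[[col]])])
    }
  }
  structure(summary, sim = sim, removal_report = filt$report)
}
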