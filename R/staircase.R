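# 2-up-1-down staircase calibration simulated against a synthetic
# psychometric observer.  The staircase lowers the morph level (harder) by
# 5.6 percentage points after every two consecutive correct responses and
# raises it (easier) by 5.6 after each error, clamped to [50, 100]; the
# rule converges where P(correct) = sqrt(0.5) ~ 0.707.

STAIRCASE_STEP <- 5.6
LEVEL_MIN <- 50
LEVEL_MAX <- 100

#' Create a fresh staircase state
#'
#' @param start_level Starting morph level, percent own-family (default 94,
#'   a nearly unambiguous morph).
#' @return A list with `level`, `consecutive_correct`, `trial_index`, and a
#'   `history` data frame of (level presented, response correct).
#' @export
new_staircase <- function(start_level = 94) {
  stopifnot(start_level >= LEVEL_MIN, start_level <= LEVEL_MAX)
  structure(
    list(
      level = start_level, consecutive_correct = 0L, trial_index = 0L,
      history = data.frame(level = numeric(0), correct = logical(0))
    ),
    class = "mcia_staircase"
  )
}

#' Advance a 2-up-1-down staircase by one response
#'
#' An incorrect response raises the level by 5.6 (clamped at 100) and
#' resets the consecutive-correct counter; a second consecutive correct
#' response lowers it by 5.6 (clamped at 50) and resets the counter.
#' Clamping is applied after the step.
#'
#' @param state Staircase state from [new_staircase()].
#' @param correct Logical: was the response correct?
#' @return The updated state.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "mcia_staircase"), is.logical(correct))
  state$history <- rbind(
    state$history,
    data.frame(level = state$level, correct = correct)
  )
  state$trial_index <- state$trial_index + 1L
  step <- staircase_transition(state$level, state$consecutive_correct,
                               correct)
  state$level <- step$level
  state$consecutive_correct <- step$counter
  state
}

# the bare 2-up-1-down transition, shared by the stateful update and the
# long-run simulation loop
staircase_transition <- function(level, counter, correct) {
  if (!correct) {
    list(level = min(level + STAIRCASE_STEP, LEVEL_MAX), counter = 0L)
  } else if (counter >= 1L) {
    list(level = max(level - STAIRCASE_STEP, LEVEL_MIN), counter = 0L)
  } else {
    list(level = level, counter = counter + 1L)
  }
}

#' Synthetic psychometric observer
#'
#' A logistic observer anchored at chance for the fully ambiguous morph:
#' P(correct at 50%) = 0.5 exactly, rising monotonically with morph level;
#' the `midpoint` is the level at which P(correct) = 0.75.  Internally the
#' logistic center is solved so that both anchors hold simultaneously.
#'
#' @param midpoint Level (percent) at which the observer is 75% correct.
#' @param slope Positive logistic slope per percent morph.
#' @param lapse Lapse probability in \[0, 0.1\]; caps asymptotic accuracy
#'   at `1 - lapse/2`.
#' @return An object of class `mcia_observer` with a `prob(level)` field.
#' @export
psychometric_observer <- function(midpoint = 75, slope = 0.08, lapse = 0.02) {
  stopifnot(midpoint > LEVEL_MIN, midpoint < LEVEL_MAX, slope > 0,
            lapse >= 0, lapse <= 0.1)
  p_of <- function(center) {
    force(center)
    function(level) {
      # (l(x) - l(50)) / (1 - l(50)) computed via logistic complements for
      # numerical stability at steep slopes
      ratio <- 1 - stats::plogis(slope * (center - level)) /
        stats::plogis(slope * (center - LEVEL_MIN))
      0.5 + 0.5 * (1 - lapse) * ratio
    }
  }
  # solve the logistic center so that P(midpoint) = 0.75
  root <- stats::uniroot(
    function(center) p_of(center)(midpoint) - 0.75,
    lower = midpoint - 30 / slope, upper = midpoint + 30 / slope, tol = 1e-10
  )
  structure(
    list(midpoint = midpoint, slope = slope, lapse = lapse,
         prob = p_of(root$root)),
    class = "mcia_observer"
  )
}

#' Observer probability of a correct response at a morph level
#'
#' @param observer An [psychometric_observer()] (or any object with a
#'   `prob` function for custom observers, e.g. step functions in tests).
#' @param level Morph level(s), percent.
#' @return Probability of a correct response.
#' @export
observer_prob <- function(observer, level) {
  observer$prob(level)
}

#' Run a simulated staircase calibration
#'
#' Presents `n_trials` staircase trials to the observer and returns the
#' level after the final update (the calibrated medium level).  The full
#' trajectory is attached as attribute `"history"`; the mean level over the
#' final `mean_of` presented trials is attached as `"mean_level"` for
#' convergence analyses.
#'
#' @param observer A psychometric observer.
#' @param n_trials Number of staircase trials (the calibration protocol
#'   uses 18).
#' @param start_level Starting level, percent (default 94).
#' @param seed Integer RNG seed.
#' @param mean_of Number of final trials averaged for `"mean_level"`
#'   (default: the last half).
#' @return The final level (numeric scalar) with attributes `history` and
#'   `mean_level`.
#' @export
run_calibration <- function(observer, n_trials = 18L, start_level = 94,
                            seed = 1L, mean_of = floor(n_trials / 2)) {
  stopifnot(n_trials >= 1L)
  stopifnot(start_level >= LEVEL_MIN, start_level <= LEVEL_MAX)
  levels <- numeric(n_trials)
  corrects <- logical(n_trials)
  level <- start_level
  counter <- 0L
  withr::with_seed(seed, {
    u <- stats::runif(n_trials)
    for (i in seq_len(n_trials)) {
      levels[i] <- level
      corrects[i] <- u[i] < observer_prob(observer, level)
      step <- staircase_transition(level, counter, corrects[i])
      level <- step$level
      counter <- step$counter
    }
  })
  tail_levels <- utils::tail(levels, max(mean_of, 1L))
  structure(level,
    history = data.frame(level = levels, correct = corrects),
    mean_level = mean(tail_levels)
  )
}

#' Long-run accuracy at the staircase's converged level
#'
#' Runs a long staircase, averages the presented level over the
#' post-burn-in half of trials, and evaluates the observer's percent
#' correct at that mean level.  For a smooth observer the 2-up-1-down rule
#' converges near the level where P(correct) = sqrt(0.5), i.e. roughly 71%
#' accuracy.
#'
#' @param observer A psychometric observer.
#' @param seed Integer RNG seed.
#' @param n_trials Staircase length (default 20000; at least 2000
#'   recommended for a stable mean level).
#' @return Percent correct (0-100 scale) at the converged mean level, with
#'   attribute `"mean_level"`.
#' @export
converged_accuracy <- function(observer, seed = 1L, n_trials = 20000L) {
  burn_in <- floor(n_trials / 2)
  res <- run_calibration(observer,
    n_trials = n_trials, seed = seed,
    mean_of = n_trials - burn_in
  )
  mean_level <- attr(res, "mean_level")
  structure(100 * observer_prob(observer, mean_level),
    mean_level = mean_level
  )
}
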