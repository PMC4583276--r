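# Independent oracles used across the suite.

# Absorbing-Markov-chain solution of the biased random walk with integer
# threshold: interior states -(theta-1)..(theta-1), absorption at +/-theta.
# Returns the probability of absorbing at +theta from 0 and the expected
# number of steps to absorption, via the fundamental matrix.
walk_oracle <- function(p, theta) {
  stopifnot(theta == round(theta), theta >= 1)
  n <- 2 * theta - 1 # interior states
  states <- seq(-(theta - 1), theta - 1)
  Q <- matrix(0, n, n)
  r_correct <- numeric(n) # one-step probability of absorbing at +theta
  for (i in seq_len(n)) {
    up <- states[i] + 1
    down <- states[i] - 1
    if (up == theta) r_correct[i] <- p else Q[i, match(up, states)] <- p
    if (down > -theta) Q[i, match(down, states)] <- 1 - p
  }
  fundamental <- solve(diag(n) - Q)
  start <- match(0, states)
  list(
    p_correct = (fundamental %*% r_correct)[start],
    expected_steps = sum(fundamental[start, ])
  )
}

# a convenience observer whose accuracy is a constant or a step function,
# for deterministic staircase trajectories
constant_observer <- function(p) list(prob = function(level) rep(p, length(level)))
step_observer <- function(at, lo = 0.5, hi = 1) {
  list(prob = function(level) ifelse(level >= at, hi, lo))
}

# minimal valid trial table builder for pipeline unit tests
make_trial <- function(participant = 1, block = 1, trial_index = 1,
                       format = "together",
                       top_family = "A", top_strength = "w",
                       bottom_family = "A", bottom_strength = "s",
                       response = "A", rt_ms = 800, confidence = 80) {
  data.frame(
    participant = participant, block = block, trial_index = trial_index,
    format = format,
    top_family = top_family, top_strength = top_strength,
    top_morph = NA_real_,
    bottom_family = bottom_family, bottom_strength = bottom_strength,
    bottom_morph = NA_real_,
    response = response, rt_ms = rt_ms, confidence = confidence,
    stringsAsFactors = FALSE
  )
}
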