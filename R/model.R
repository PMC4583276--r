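# The McIA model proper.  A trial is a biased random walk between two
# absorbing response thresholds at +/- theta, starting midway.  At each
# step one of three evidence sources is sampled: the whole face with
# probability alpha (step probability = odds-product optimal combination of
# the two halves) or either half with probability (1 - alpha)/2.  Because
# the source is redrawn independently every step, the walk is a simple
# random walk at the marginal step probability, so choice probabilities and
# mean step counts have gambler's-ruin closed forms.  RT = tau + k * N for
# whole faces and tau + h * k * N for half faces.

#' McIA model parameters
#'
#' The eight free parameters of the Multi-component Information
#' Accumulation model, plus optional extras used by particular variants.
#'
#' @param theta Response threshold in steps (> 0; need not be integer).
#' @param alpha Probability of sampling the automatically integrated
#'   whole-face source, in \[0, 1\] (applies to together faces under the
#'   default variant).
#' @param delta_weak,delta_medium,delta_strong Probability that a sampled
#'   half-face source steps toward the correct threshold, in (0, 1).
#' @param tau Non-decision time, ms (>= 0).
#' @param k Time per step, ms (> 0).
#' @param h Half-face step-time multiplier (> 0).
#' @param alpha_split Optional whole-face sampling probability for split
#'   faces (used by the `alpha_split_free` variant).
#' @param gamma Optional split-face rate attenuation in \[0, 1\] (used by
#'   the `rate_attenuation` variant).
#' @return A list of class `mcia_params`.
#' @examples
#' mcia_params() # the published best-fitting values
#' @export
mcia_params <- function(theta = 6.76, alpha = 0.30, delta_weak = 0.54,
                        delta_medium = 0.56, delta_strong = 0.64,
                        tau = 359, k = 20, h = 1.24,
                        alpha_split = NULL, gamma = NULL) {
  p <- list(
    theta = theta, alpha = alpha, delta_weak = delta_weak,
    delta_medium = delta_medium, delta_strong = delta_strong,
    tau = tau, k = k, h = h, alpha_split = alpha_split, gamma = gamma
  )
  validate_params(p)
  structure(p, class = "mcia_params")
}

validate_params <- function(p) {
  stopifnot(
    p$theta > 0, p$alpha >= 0, p$alpha <= 1,
    p$delta_weak > 0, p$delta_weak < 1,
    p$delta_medium > 0, p$delta_medium < 1,
    p$delta_strong > 0, p$delta_strong < 1,
    p$tau >= 0, p$k > 0, p$h > 0
  )
  if (!is.null(p$alpha_split)) {
    stopifnot(p$alpha_split >= 0, p$alpha_split <= 1)
  }
  if (!is.null(p$gamma)) stopifnot(p$gamma >= 0, p$gamma <= 1)
  invisible(p)
}

#' @export
print.mcia_params <- function(x, ...) {
  cat("McIA parameters:\n")
  flat <- unlist(x[!vapply(x, is.null, logical(1))])
  print(round(flat, 4))
  invisible(x)
}

#' Model variants
#'
#' * `full` — alpha free for together faces, alpha = 0 for split faces
#'   (whole-face integration disrupted by splitting).
#' * `alpha_one` — alpha = 1 everywhere: always-optimal integration.
#' * `alpha_zero` — alpha = 0 everywhere: pure half-face averaging.
#' * `alpha_split_free` — separate free alpha for together and split.
#' * `rate_attenuation` — alpha = 1 everywhere, but each delta is
#'   multiplied by gamma in \[0, 1\] for split faces (a general slowing of
#'   accumulation rather than a loss of integration).
#'
#' @return Character vector of variant ids.
#' @export
model_variants <- function() {
  c("full", "alpha_one", "alpha_zero", "alpha_split_free", "rate_attenuation")
}

check_variant <- function(variant) {
  match.arg(variant, model_variants())
}

#' Optimal (odds-product) combination of two evidence probabilities
#'
#' The whole-face step probability is the Bayes-optimal combination of the
#' two half-face step probabilities: the odds of the combination is the
#' product of the individual odds,
#' `p = (o_t * o_b) / (1 + o_t * o_b)` with `o = d / (1 - d)`.
#'
#' @param d_top,d_bottom Probabilities strictly in (0, 1); vectorized.
#' @return The combined probability.
#' @examples
#' combine_optimal(0.55, 0.75) # 0.81 to two decimals
#' @export
combine_optimal <- function(d_top, d_bottom) {
  if (any(d_top <= 0) || any(d_top >= 1) ||
      any(d_bottom <= 0) || any(d_bottom >= 1)) {
    stop("evidence probabilities must lie strictly in (0, 1): odds undefined")
  }
  o <- (d_top / (1 - d_top)) * (d_bottom / (1 - d_bottom))
  o / (1 + o)
}

delta_for <- function(params, strength) {
  unlist(params[c(
    w = "delta_weak", m = "delta_medium", s = "delta_strong"
  )[strength]], use.names = FALSE)
}

#' Effective step probabilities of the two halves, toward the correct response
#'
#' Same-family halves map their strength to the corresponding delta.  For
#' opposite faces the correct response is the stronger (medium) family, so
#' the weak half's evidence points the wrong way and enters as
#' `1 - delta_weak`.
#'
#' @param faces A face data frame (whole or opposite faces only).
#' @param params [mcia_params()].
#' @return A two-column matrix (`d_top`, `d_bottom`) of per-half step
#'   probabilities toward the correct threshold.
#' @export
effective_deltas <- function(faces, params) {
  type <- face_type(faces)
  if (any(type == "half")) {
    stop("half faces have a single evidence source; use the half-face path")
  }
  correct <- correct_family(faces)
  d_top <- delta_for(params, faces$top_strength)
  d_bottom <- delta_for(params, faces$bottom_strength)
  d_top <- ifelse(faces$top_family == correct, d_top, 1 - d_top)
  d_bottom <- ifelse(faces$bottom_family == correct, d_bottom, 1 - d_bottom)
  cbind(d_top = d_top, d_bottom = d_bottom)
}

variant_alpha <- function(format, params, variant) {
  variant <- check_variant(variant)
  switch(variant,
    full = ifelse(format == "split", 0, params$alpha),
    alpha_one = rep(1, length(format)),
    alpha_zero = rep(0, length(format)),
    alpha_split_free = ifelse(format == "split",
      if (is.null(params$alpha_split)) {
        stop("variant `alpha_split_free` requires params$alpha_split")
      } else params$alpha_split,
      params$alpha
    ),
    rate_attenuation = rep(1, length(format))
  )
}

#' Marginal step probability for each face
#'
#' For whole and opposite faces the sources mix as
#' `alpha * combine_optimal(d_t, d_b) + (1 - alpha)/2 * (d_t + d_b)`, with
#' alpha chosen per format by the variant; half faces use their single
#' delta.  Under the `rate_attenuation` variant, split-face deltas are
#' multiplied by gamma before mixing.
#'
#' @param faces A face data frame.
#' @param params [mcia_params()].
#' @param variant Variant id (see [model_variants()]).
#' @return Numeric vector of step probabilities toward the correct
#'   threshold.
#' @export
step_probability <- function(faces, params, variant = "full") {
  variant <- check_variant(variant)
  type <- face_type(faces)
  p <- numeric(nrow(faces))
  half <- type == "half"
  if (any(half)) {
    st <- ifelse(is.na(faces$top_strength[half]),
      faces$bottom_strength[half], faces$top_strength[half]
    )
    p[half] <- delta_for(params, st)
  }
  whole <- !half
  if (any(whole)) {
    d <- effective_deltas(faces[whole, , drop = FALSE], params)
    if (variant == "rate_attenuation") {
      if (is.null(params$gamma)) {
        stop("variant `rate_attenuation` requires params$gamma")
      }
      split <- faces$format[whole] == "split"
      d[split, ] <- d[split, , drop = FALSE] * params$gamma
    }
    a <- variant_alpha(faces$format[whole], params, variant)
    p[whole] <- a * combine_optimal(d[, "d_top"], d[, "d_bottom"]) +
      (1 - a) / 2 * (d[, "d_top"] + d[, "d_bottom"])
  }
  p
}

#' Gambler's-ruin choice probability
#'
#' Probability that a random walk starting midway between absorbing
#' boundaries at distance `theta` each, with step probability `p` toward
#' the correct boundary, is absorbed at the correct boundary:
#' `1 / (1 + r^theta)` with `r = (1 - p)/p`; 0.5 at `p = 0.5`.
#' Evaluated with real-valued exponents so non-integer thresholds are
#' admissible.
#'
#' @param p Step probability in (0, 1); vectorized.
#' @param theta Threshold distance in steps (> 0); vectorized.
#' @return Probability of a correct response.
#' @export
walk_choice_probability <- function(p, theta) {
  stopifnot(all(p > 0), all(p < 1), all(theta > 0))
  r <- (1 - p) / p
  1 / (1 + r^theta)
}

#' Gambler's-ruin expected number of steps to absorption
#'
#' Unconditional (over correct and error responses) expected duration of
#' the walk of [walk_choice_probability()]:
#' `(theta - 2*theta*(1 - r^theta)/(1 - r^(2*theta))) / (q - p)` for
#' `p != 0.5` (with `q = 1 - p`, `r = q/p`), and `theta^2` in the
#' symmetric limit.  Continuous in `p`; evaluated in the symmetric branch
#' within a small neighbourhood of 0.5 to avoid cancellation.
#'
#' @inheritParams walk_choice_probability
#' @return Expected step count.
#' @export
walk_expected_steps <- function(p, theta) {
  stopifnot(all(p > 0), all(p < 1), all(theta > 0))
  n <- max(length(p), length(theta))
  p <- rep_len(p, n)
  theta <- rep_len(theta, n)
  out <- numeric(n)
  sym <- abs(p - 0.5) < 1e-7
  out[sym] <- theta[sym]^2
  if (any(!sym)) {
    pp <- p[!sym]
    th <- theta[!sym]
    q <- 1 - pp
    r <- q / pp
    out[!sym] <- (th - 2 * th * (1 - r^th) / (1 - r^(2 * th))) / (q - pp)
  }
  out
}

#' The 17 collapsed analysis conditions
#'
#' Three half-face cells (`w`, `m`, `s`), the six unordered whole-face
#' strength pairs in each of the together and split formats, and the
#' opposite (`wom`) cell in each format.
#'
#' @return A data frame with columns `condition` and `format`.
#' @export
condition_table <- function() {
  whole <- c("ww", "wm", "ws", "mm", "ms", "ss")
  data.frame(
    condition = c(STRENGTHS, rep(c(whole, "wom"), 2L)),
    format = c(
      rep("half", 3L),
      rep(c("together", "split"), each = 7L)
    ),
    stringsAsFactors = FALSE
  )
}

# one representative face per collapsed condition (predictions are
# invariant to location/family by symmetry of the mixing rule)
representative_faces <- function(conditions = condition_table()) {
  strength1 <- substr(conditions$condition, 1L, 1L)
  strength2 <- substr(conditions$condition, 2L, 2L)
  is_half <- conditions$format == "half"
  is_wom <- conditions$condition == "wom"
  data.frame(
    format = conditions$format,
    top_family = ifelse(is_half, NA_character_, "A"),
    top_strength = ifelse(is_half, NA_character_,
      ifelse(is_wom, "m", strength1)
    ),
    top_morph = NA_real_,
    bottom_family = ifelse(is_wom, "B", "A"),
    bottom_strength = ifelse(is_half, strength1,
      ifelse(is_wom, "w", strength2)
    ),
    bottom_morph = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Closed-form predictions for faces
#'
#' Computes the choice probability, expected step count, and mean RT for
#' each face: `rt = tau + k * E[N]` for whole and opposite faces and
#' `rt = tau + h * k * E[N]` for half faces.
#'
#' @param faces A face data frame.
#' @param params [mcia_params()].
#' @param variant Variant id.
#' @return `faces` with columns `p_correct`, `expected_steps`, `mean_rt_ms`
#'   appended.
#' @export
predict_faces <- function(faces, params, variant = "full") {
  p <- step_probability(faces, params, variant)
  en <- walk_expected_steps(p, params$theta)
  step_ms <- ifelse(face_type(faces) == "half", params$h * params$k, params$k)
  cbind(faces,
    p_correct = walk_choice_probability(p, params$theta),
    expected_steps = en,
    mean_rt_ms = params$tau + step_ms * en
  )
}

# vectorized prediction core over the fixed 17-condition layout of
# condition_table(): rows 1-3 half w/m/s, rows 4-10 together (ww, wm, ws,
# mm, ms, ss, wom), rows 11-17 the same for split.  Shared by predict_all
# and the fitting objective, where it runs thousands of times.
CORE_IT <- c(1L, 1L, 1L, 2L, 2L, 3L) # whole-face strength index pairs
CORE_IB <- c(1L, 2L, 3L, 2L, 3L, 3L)
CORE_SPLIT <- rep(c(FALSE, TRUE), each = 7L)

predict_core <- function(params, variant) {
  d <- c(params$delta_weak, params$delta_medium, params$delta_strong)
  # effective per-half deltas (wom: the weak half opposes the correct,
  # medium, family), repeated for the together and split blocks
  dt <- rep(c(d[CORE_IT], d[2L]), 2L)
  db <- rep(c(d[CORE_IB], 1 - d[1L]), 2L)
  stronger <- pmax(dt, db)
  if (variant == "rate_attenuation") {
    if (is.null(params$gamma)) {
      stop("variant `rate_attenuation` requires params$gamma")
    }
    dt[CORE_SPLIT] <- dt[CORE_SPLIT] * params$gamma
    db[CORE_SPLIT] <- db[CORE_SPLIT] * params$gamma
  }
  a <- switch(variant,
    full = ifelse(CORE_SPLIT, 0, params$alpha),
    alpha_one = 1,
    alpha_zero = 0,
    alpha_split_free = {
      if (is.null(params$alpha_split)) {
        stop("variant `alpha_split_free` requires params$alpha_split")
      }
      ifelse(CORE_SPLIT, params$alpha_split, params$alpha)
    },
    rate_attenuation = 1
  )
  o <- (dt / (1 - dt)) * (db / (1 - db))
  p <- c(d, a * o / (1 + o) + (1 - a) / 2 * (dt + db))
  theta <- params$theta
  pc <- 1 / (1 + ((1 - p) / p)^theta)
  en <- walk_expected_steps(p, theta)
  rt <- params$tau +
    params$k * c(rep(params$h, 3L), rep(1, 14L)) * en
  # reference: the stronger half presented alone (half faces are never
  # split, so its delta is never attenuated)
  dev <- c(
    rep(NA_real_, 3L),
    pc[-(1:3)] - 1 / (1 + ((1 - stronger) / stronger)^theta)
  )
  list(p = p, p_correct = pc, expected_steps = en, mean_rt_ms = rt,
       deviation_pred = dev)
}

#' Predictions for all 17 collapsed conditions
#'
#' One prediction per condition of [condition_table()], plus the predicted
#' deviation score for the 14 whole/opposite cells: the whole-face choice
#' probability minus the choice probability of the model's stronger half
#' alone (the half with the larger effective delta), mirroring the
#' data-side deviation definition.
#'
#' @param params [mcia_params()].
#' @param variant Variant id.
#' @return A data frame with columns `condition`, `format`, `p_correct`,
#'   `expected_steps`, `mean_rt_ms`, `deviation_pred` (NA for half faces).
#' @examples
#' predict_all(mcia_params(), "full")
#' @export
predict_all <- function(params, variant = "full") {
  validate_params(params)
  variant <- check_variant(variant)
  conditions <- condition_table()
  core <- predict_core(params, variant)
  data.frame(
    condition = conditions$condition,
    format = conditions$format,
    p_correct = core$p_correct,
    expected_steps = core$expected_steps,
    mean_rt_ms = core$mean_rt_ms,
    deviation_pred = core$deviation_pred,
    stringsAsFactors = FALSE
  )
}

#' Read or write model parameters as JSON
#'
#' @param params [mcia_params()].
#' @param path File path.
#' @return `read_params()` returns an [mcia_params()] object.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(params[!vapply(params, is.null, logical(1))],
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(mcia_params, jsonlite::read_json(path, simplifyVector = TRUE))
}
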