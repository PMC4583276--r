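# Weighted least-squares fitting.  The objective standardizes each
# observed summary cell (accuracy, mean RT, and deviation score) by its
# between-subject SEM, squares, and sums; minimization is Nelder-Mead on
# transformed coordinates with seeded multi-start.

# free parameters and search transforms per variant ------------------------

# deltas are searched in (0.5, 0.999): the calibration design guarantees
# every half face carries evidence for its own family
DELTA_LO <- 0.5
DELTA_HI <- 0.999

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))
delta_to_raw <- function(d) logit((d - DELTA_LO) / (DELTA_HI - DELTA_LO))
raw_to_delta <- function(x) DELTA_LO + (DELTA_HI - DELTA_LO) * inv_logit(x)
# unit-probability transform, kept away from the exact 0/1 endpoints
prob_to_raw <- function(p) logit(pmin(pmax(p, 1e-6), 1 - 1e-6))

free_parameters <- function(variant) {
  variant <- check_variant(variant)
  base <- c("theta", "delta_weak", "delta_medium", "delta_strong",
            "tau", "k", "h")
  switch(variant,
    full = c(base, "alpha"),
    alpha_one = base,
    alpha_zero = base,
    alpha_split_free = c(base, "alpha", "alpha_split"),
    rate_attenuation = c(base, "gamma")
  )
}

pack_params <- function(params, variant) {
  nm <- free_parameters(variant)
  raw <- vapply(nm, function(f) {
    v <- params[[f]]
    switch(f,
      theta = log(v), k = log(v), h = log(v),
      tau = v,
      alpha = prob_to_raw(v), alpha_split = prob_to_raw(v),
      gamma = prob_to_raw(v),
      delta_to_raw(v) # the three deltas
    )
  }, numeric(1))
  stats::setNames(raw, nm)
}

unpack_params <- function(raw, variant) {
  nm <- free_parameters(variant)
  vals <- lapply(seq_along(nm), function(i) {
    f <- nm[i]
    x <- raw[i]
    switch(f,
      theta = exp(x), k = exp(x), h = exp(x),
      tau = max(x, 0),
      alpha = inv_logit(x), alpha_split = inv_logit(x),
      gamma = inv_logit(x),
      raw_to_delta(x)
    )
  })
  names(vals) <- nm
  fixed <- switch(variant,
    alpha_one = list(alpha = 1),
    alpha_zero = list(alpha = 0),
    rate_attenuation = list(alpha = 1),
    list()
  )
  do.call(mcia_params, c(vals, fixed))
}

# objective ----------------------------------------------------------------

#' Weighted sum-of-squares error between predictions and an observed summary
#'
#' Each observed cell (accuracy and mean RT for all 17 conditions, plus
#' deviation score for the 14 whole/opposite cells) contributes
#' `((observed - predicted) / SEM)^2`.
#'
#' @param predictions Output of [predict_all()].
#' @param observed An observed summary (see [summarize_conditions()]):
#'   a data frame with `condition`, `format`, `acc_mean`, `acc_sem`,
#'   `rt_mean`, `rt_sem`, and `dev_mean`, `dev_sem` for non-half cells.
#' @return Non-negative scalar wSSE.  Attribute `"residuals"` holds the
#'   per-cell standardized residuals.
#' @export
wsse_objective <- function(predictions, observed) {
  key <- function(d) paste(d$condition, d$format)
  idx <- match(key(observed), key(predictions))
  if (anyNA(idx)) {
    stop("no prediction for cell(s): ",
         paste(key(observed)[is.na(idx)], collapse = ", "))
  }
  pred <- predictions[idx, , drop = FALSE]
  whole <- observed$format != "half"
  obs_vals <- c(observed$acc_mean, observed$rt_mean, observed$dev_mean[whole])
  pred_vals <- c(pred$p_correct, pred$mean_rt_ms, pred$deviation_pred[whole])
  sems <- c(observed$acc_sem, observed$rt_sem, observed$dev_sem[whole])
  cells <- c(
    paste("acc", key(observed)), paste("rt", key(observed)),
    paste("dev", key(observed)[whole])
  )
  if (anyNA(obs_vals) || anyNA(sems)) {
    stop("observed summary has missing cell(s): ",
         paste(cells[is.na(obs_vals) | is.na(sems)], collapse = ", "))
  }
  if (any(sems <= 0)) {
    stop("zero or negative SEM in cell(s): ",
         paste(cells[sems <= 0], collapse = ", "))
  }
  resid <- (obs_vals - pred_vals) / sems
  structure(sum(resid^2), residuals = stats::setNames(resid, cells))
}

# fitting ------------------------------------------------------------------

default_start <- function(variant) {
  mcia_params(
    theta = 5, alpha = 0.5, delta_weak = 0.55, delta_medium = 0.6,
    delta_strong = 0.68, tau = 300, k = 25, h = 1.2,
    alpha_split = if (variant == "alpha_split_free") 0.5 else NULL,
    gamma = if (variant == "rate_attenuation") 0.8 else NULL
  )
}

#' Fit a McIA model variant by Nelder-Mead with multi-start
#'
#' Minimizes [wsse_objective()] over the variant's free parameters on
#' transformed coordinates (log for theta, k, h; logit for alpha and
#' gamma; bounded logit for the deltas; identity with a floor at zero for
#' tau).  Runs `n_restarts` seeded, jittered starts and keeps the best;
#' restarts whose search encounters a non-finite objective are discarded
#' and counted.
#'
#' @param observed Observed summary (see [wsse_objective()]).
#' @param variant Variant id (see [model_variants()]).
#' @param seed Integer seed for the restart jitter.
#' @param n_restarts Number of jittered starts (default 25).
#' @param start Optional [mcia_params()] giving the central start.
#' @param maxit Maximum Nelder-Mead iterations per restart.
#' @return A list of class `mcia_fit`: `variant`, `params`, `wsse`,
#'   `residuals`, `n_function_evals`, `converged`, `n_restarts`,
#'   `n_failed_restarts`, `seed`.
#' @export
fit_variant <- function(observed, variant = "full", seed = 1L,
                        n_restarts = 25L, start = NULL, maxit = 2000L) {
  variant <- check_variant(variant)
  if (is.null(start)) start <- default_start(variant)
  centre <- pack_params(start, variant)
  # validate the alignment once (with named-cell errors), then evaluate
  # the search objective on the vectorized core
  wsse_objective(predict_all(start, variant), observed)
  cond <- condition_table()
  idx <- match(paste(observed$condition, observed$format),
               paste(cond$condition, cond$format))
  whole <- observed$format != "half"
  obs_acc <- observed$acc_mean
  obs_rt <- observed$rt_mean
  obs_dev <- observed$dev_mean[whole]
  w_acc <- 1 / observed$acc_sem^2
  w_rt <- 1 / observed$rt_sem^2
  w_dev <- 1 / observed$dev_sem[whole]^2
  idx_whole <- idx[whole]
  objective <- function(raw) {
    p <- try(unpack_params(raw, variant), silent = TRUE)
    if (inherits(p, "try-error")) return(NA_real_)
    core <- predict_core(p, variant)
    sum((obs_acc - core$p_correct[idx])^2 * w_acc) +
      sum((obs_rt - core$mean_rt_ms[idx])^2 * w_rt) +
      sum((obs_dev - core$deviation_pred[idx_whole])^2 * w_dev)
  }
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1L) centre else
        centre + stats::rnorm(length(centre), sd = 0.5)
    })
  })
  best <- NULL
  n_failed <- 0L
  total_evals <- 0L
  for (s in starts) {
    res <- try(
      stats::optim(s, objective,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-8)
      ),
      silent = TRUE
    )
    if (inherits(res, "try-error") || !is.finite(res$value)) {
      n_failed <- n_failed + 1L
      next
    }
    total_evals <- total_evals + res$counts[["function"]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all restarts failed with non-finite objectives")
  # polish: re-seed the simplex around the incumbent at shrinking scales;
  # repeated restarts grind through the shallow valleys where a single
  # Nelder-Mead run stalls
  polish_jitter <- withr::with_seed(seed + 1L, {
    lapply(c(0, 0, 0, 0.05, 0, 0.02, 0, 0.01, 0, 0.005, 0, 0),
           function(s) stats::rnorm(length(centre), sd = s))
  })
  for (jit in polish_jitter) {
    res <- try(
      stats::optim(best$par + jit, objective,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-12)
      ),
      silent = TRUE
    )
    if (inherits(res, "try-error") || !is.finite(res$value)) next
    total_evals <- total_evals + res$counts[["function"]]
    if (res$value < best$value) best <- res
  }
  # convergence check: one last simplex from the incumbent at the working
  # tolerance must terminate on its own
  final <- stats::optim(best$par, objective,
    method = "Nelder-Mead", control = list(maxit = maxit, reltol = 1e-8)
  )
  total_evals <- total_evals + final$counts[["function"]]
  if (final$value < best$value) best$par <- final$par
  best$value <- min(best$value, final$value)
  best$convergence <- final$convergence
  params <- unpack_params(best$par, variant)
  wsse <- wsse_objective(predict_all(params, variant), observed)
  structure(
    list(
      variant = variant, params = params, wsse = as.numeric(wsse),
      residuals = attr(wsse, "residuals"),
      n_function_evals = total_evals,
      converged = best$convergence == 0L,
      n_restarts = n_restarts, n_failed_restarts = n_failed, seed = seed
    ),
    class = "mcia_fit"
  )
}

#' @export
print.mcia_fit <- function(x, ...) {
  cat(sprintf(
    "McIA fit, variant `%s`: wSSE = %.3f (%d restarts, %d failed)\n",
    x$variant, x$wsse, x$n_restarts, x$n_failed_restarts
  ))
  print(x$params)
  invisible(x)
}

#' Fit and rank several model variants
#'
#' @param observed Observed summary.
#' @param variants Character vector of variant ids (at least two).
#' @param seed Integer seed (shared across variants).
#' @param ... Passed to [fit_variant()].
#' @return A data frame sorted by wSSE with one row per variant; the full
#'   fit objects are attached as attribute `"fits"` (named by variant).
#' @export
compare_variants <- function(observed, variants = model_variants(),
                             seed = 1L, ...) {
  if (length(variants) < 2L) {
    stop("need at least two variants to compare")
  }
  fits <- lapply(variants, function(v) {
    fit_variant(observed, variant = v, seed = seed, ...)
  })
  names(fits) <- variants
  tab <- data.frame(
    variant = variants,
    wsse = vapply(fits, `[[`, numeric(1), "wsse"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    n_function_evals = vapply(fits, `[[`, integer(1), "n_function_evals"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$wsse), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits)
}
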