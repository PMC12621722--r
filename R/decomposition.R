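#' Deterministic learning rollout
#'
#' Replays the fitted learning rule through the animal's actual choices and
#' rewards with the noise omitted: the "learning component" of a trajectory,
#' \eqn{w_{t+1} = w_t + \mathrm{rate}_t \cdot \alpha \odot
#' \mathcal{L}(w_t; x_t, y_t) - Q \odot w_t}. For the dynamic-rate model the
#' posterior-mean learning-rate trajectory is supplied as `rate_traj`.
#'
#' @param params A [pg_params()] object (typically fitted).
#' @param trials Trial tibble supplying `x_t, y_t, r_t`.
#' @param w_start Length-M starting weights (e.g. the smoothed posterior
#'   mean at the first trial).
#' @param rate_traj Optional length-T learning-rate gate trajectory
#'   (default: constant 1).
#' @param regressors Optional precomputed regressor matrix.
#' @return A T-by-M matrix of rollout weights.
#' @export
learning_rollout <- function(params, trials, w_start, rate_traj = NULL,
                             regressors = NULL) {
  dat <- as_pf_data(trials, regressors)
  T_ <- nrow(dat$x)
  M <- ncol(dat$x)
  stopifnot(length(w_start) == M)
  if (is.null(rate_traj)) rate_traj <- rep(1, T_)
  if (length(rate_traj) != T_) abort("rate_traj must have one entry per trial")
  W <- matrix(NA_real_, T_, M)
  W[1, ] <- w_start
  for (t in seq_len(T_ - 1)) {
    W[t + 1, ] <- W[t, ] + vector_pg_drift(
      W[t, ], dat$x[t, ], dat$choice[t], dat$reward[t], params,
      rate_scale = rate_traj[t]
    )
  }
  colnames(W) <- if (M == length(regressor_names)) regressor_names else paste0("w", seq_len(M))
  W
}

#' Per-trial learning updates and residual noise
#'
#' Evaluates the fitted learning rule's deterministic update at the inferred
#' (posterior-mean) weights on every trial,
#' \eqn{\Delta^{\mathrm{learn}}_t = \mathrm{rate}_t \alpha \odot
#' \mathcal{L}(\hat w_t; x_t, y_t) - Q \odot \hat w_t},
#' and defines the residual noise as what the rule does not explain of the
#' inferred weight update:
#' \eqn{\hat\epsilon_t = (\hat w_{t+1} - \hat w_t) - \Delta^{\mathrm{learn}}_t}.
#'
#' @param inferred T-by-M matrix of inferred weights (e.g. `smooth_mean`
#'   from [smooth_posterior()], weight columns only).
#' @inheritParams learning_rollout
#' @return A `pg_decomposition` list: `delta_learn` and `residual`
#'   ((T-1)-by-M), `learn_norm` and `resid_norm` (length T-1), `inferred`,
#'   `params`.
#' @export
update_residuals <- function(inferred, params, trials, rate_traj = NULL,
                             regressors = NULL) {
  inferred <- as.matrix(inferred)
  dat <- as_pf_data(trials, regressors)
  T_ <- nrow(dat$x)
  if (T_ < 2) abort("need at least 2 trials to decompose updates")
  if (nrow(inferred) != T_) abort("inferred trajectory and trials disagree in length")
  M <- ncol(dat$x)
  if (is.null(rate_traj)) rate_traj <- rep(1, T_)
  dl <- matrix(NA_real_, T_ - 1, M)
  for (t in seq_len(T_ - 1)) {
    dl[t, ] <- vector_pg_drift(
      inferred[t, ], dat$x[t, ], dat$choice[t], dat$reward[t], params,
      rate_scale = rate_traj[t]
    )
  }
  res <- inferred[-1, , drop = FALSE] - inferred[-T_, , drop = FALSE] - dl
  structure(
    list(
      delta_learn = dl, residual = res,
      learn_norm = sqrt(rowSums(dl^2)),
      resid_norm = sqrt(rowSums(res^2)),
      inferred = inferred, params = params
    ),
    class = "pg_decomposition"
  )
}

#' @export
print.pg_decomposition <- function(x, ...) {
  lf <- learning_fraction(x)
  cat("<pg_decomposition>", nrow(x$delta_learn), "updates; learning fraction",
      round(lf$fraction, 3), "\n")
  invisible(x)
}

#' Learning fraction of a decomposed trajectory
#'
#' The per-trial share of the inferred weight update attributable to the
#' learning rule, \eqn{f_t = \|\Delta^{\mathrm{learn}}_t\| /
#' (\|\Delta^{\mathrm{learn}}_t\| + \|\hat\epsilon_t\|)}, averaged over
#' trials. Trials on which both norms vanish (to within `zero_tol`) carry no
#' information about the update and are excluded; a trajectory with no
#' informative trials has fraction 0. A noise-only model (zero learning
#' rate) scores exactly 0 and a noiseless deterministic rollout exactly 1.
#' Per-regressor fractions use per-coordinate absolute values. Alternate
#' summaries are reported alongside: the projection fraction
#' \eqn{\sum_t \langle \Delta\hat w_t, \Delta^{\mathrm{learn}}_t \rangle /
#' \sum_t \|\Delta\hat w_t\|^2} and the mean cosine similarity between
#' learning and inferred updates.
#'
#' @param decomp A `pg_decomposition` from [update_residuals()].
#' @param method `"per_trial"` (default, mean of bounded per-trial ratios)
#'   or `"ratio_of_sums"` (\eqn{\sum\|\Delta^{\mathrm{learn}}\| /
#'   (\sum\|\Delta^{\mathrm{learn}}\| + \sum\|\hat\epsilon\|)}).
#' @param zero_tol Norms below this count as exactly zero (default 1e-12).
#' @return A list: `fraction` (scalar in `[0, 1]`), `per_regressor`,
#'   `projection_fraction`, `mean_cosine`, `method`.
#' @export
learning_fraction <- function(decomp, method = c("per_trial", "ratio_of_sums"),
                              zero_tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(decomp, "pg_decomposition"))
  ln <- decomp$learn_norm
  rn <- decomp$resid_norm
  ln[ln < zero_tol] <- 0
  rn[rn < zero_tol] <- 0
  informative <- (ln + rn) > 0
  fraction <- if (method == "per_trial") {
    if (!any(informative)) 0 else mean(ln[informative] / (ln + rn)[informative])
  } else {
    if (sum(ln) + sum(rn) == 0) 0 else sum(ln) / (sum(ln) + sum(rn))
  }
  per_reg <- vapply(seq_len(ncol(decomp$delta_learn)), function(j) {
    a <- abs(decomp$delta_learn[, j])
    b <- abs(decomp$residual[, j])
    a[a < zero_tol] <- 0
    b[b < zero_tol] <- 0
    inf_j <- (a + b) > 0
    if (!any(inf_j)) 0 else mean(a[inf_j] / (a + b)[inf_j])
  }, numeric(1))
  names(per_reg) <- colnames(decomp$delta_learn) %||%
    colnames(decomp$inferred) %||% paste0("w", seq_along(per_reg))
  dw <- decomp$delta_learn + decomp$residual
  denom <- sum(dw^2)
  proj <- if (denom > 0) sum(dw * decomp$delta_learn) / denom else 0
  dwn <- sqrt(rowSums(dw^2))
  ok <- dwn > zero_tol & ln > 0
  cosine <- if (any(ok)) {
    mean(rowSums(dw[ok, , drop = FALSE] * decomp$delta_learn[ok, , drop = FALSE]) /
           (dwn[ok] * ln[ok]))
  } else {
    NA_real_
  }
  list(
    fraction = fraction, per_regressor = per_reg,
    projection_fraction = proj, mean_cosine = cosine, method = method
  )
}

#' Preferred/non-preferred weight relabeling across a cohort
#'
#' Re-labels each animal's left and right stimulus weights as preferred and
#' non-preferred, where the preferred side has the higher fitted stimulus
#' learning rate; weight magnitudes are trial-warped and averaged across
#' animals, alongside a control in which the animal-to-parameter assignment
#' is permuted before relabeling.
#'
#' @param cohort A list with one element per animal, each a list with
#'   `alpha` (length-M learning rates; entries 2 and 3 are the left/right
#'   stimulus rates) and `weights` (T-by-M inferred weight matrix).
#' @param grid_size Common warped grid size.
#' @param seed Seed for the control permutation.
#' @param permutation Optional explicit permutation of animals for the
#'   control (identity reproduces the unshuffled average).
#' @return A tibble with columns `frac`, `curve`
#'   (`preferred` / `nonpreferred` / `control_preferred` /
#'   `control_nonpreferred`), `mean`, `se`.
#' @export
preferred_relabel <- function(cohort, grid_size = 100, seed = 1L,
                              permutation = NULL) {
  n <- length(cohort)
  if (n < 2) abort("preferred-side relabeling needs a cohort of >= 2 animals")
  if (is.null(permutation)) {
    permutation <- withr::with_seed(seed, sample.int(n))
  }
  stopifnot(length(permutation) == n)
  relabel <- function(weights, alpha) {
    pref <- if (alpha[2] >= alpha[3]) 2L else 3L
    nonpref <- if (pref == 2L) 3L else 2L
    list(pref = abs(weights[, pref]), nonpref = abs(weights[, nonpref]))
  }
  avg_curves <- function(assign_alpha) {
    curves <- purrr::map(seq_len(n), function(i) {
      relabel(cohort[[i]]$weights, assign_alpha[[i]])
    })
    pref <- warp_average(purrr::map(curves, "pref"), grid_size)
    nonpref <- warp_average(purrr::map(curves, "nonpref"), grid_size)
    list(pref = pref, nonpref = nonpref)
  }
  own <- avg_curves(purrr::map(cohort, "alpha"))
  ctrl <- avg_curves(purrr::map(cohort[permutation], "alpha"))
  dplyr::bind_rows(
    dplyr::mutate(own$pref, curve = "preferred"),
    dplyr::mutate(own$nonpref, curve = "nonpreferred"),
    dplyr::mutate(ctrl$pref, curve = "control_preferred"),
    dplyr::mutate(ctrl$nonpref, curve = "control_nonpreferred")
  ) |>
    dplyr::select("frac", "curve", "mean", "se")
}

#' Expected reward after an incorrect trial
#'
#' Compares the conditional mean reward on trials following an error,
#' \eqn{E[r_{t+1} \mid r_t = 0]}, against the shuffled control (the overall
#' mean reward \eqn{E[r_t]}). Pairs spanning a session boundary are
#' excluded. A conditional mean below the control is the behavioural
#' signature of error-reinforcing updates (a negative reward baseline).
#'
#' @param trials A validated trial tibble.
#' @return A tibble with `conditional_mean`, `shuffled_mean`,
#'   `n_error_pairs`, `n_trials`.
#' @export
reward_after_error <- function(trials) {
  validate_trials(trials)
  r <- trials$reward
  T_ <- length(r)
  same_session <- trials$session[-1] == trials$session[-T_]
  err <- (r[-T_] == 0) & same_session
  if (!any(err)) abort("no incorrect non-final trial: conditional mean undefined")
  tibble::tibble(
    conditional_mean = mean(r[-1][err]),
    shuffled_mean = mean(r),
    n_error_pairs = sum(err),
    n_trials = T_
  )
}

#' Cross-animal consistency of residual noise and fitted noise scale
#'
#' Correlates, across animals, the average per-trial residual-noise norm
#' from the decomposition with the fitted noise-scale norm
#' \eqn{\|\sigma\|}; a high correlation supports the decomposition as
#' consistent with the fitted model.
#'
#' @param cohort Either a data frame with columns `resid_norm` and
#'   `sigma_norm` (one row per animal), or a list with per-animal elements
#'   `decomp` (a `pg_decomposition`) and `params` (a `pg_params`).
#' @return A tibble with `pearson_r`, `r_squared`, `n_animals`.
#' @export
noise_consistency <- function(cohort) {
  if (is.data.frame(cohort)) {
    tbl <- tibble::as_tibble(cohort)
  } else {
    tbl <- purrr::map_dfr(cohort, function(a) {
      tibble::tibble(
        resid_norm = mean(a$decomp$resid_norm),
        sigma_norm = sqrt(sum(a$params$sigma^2))
      )
    })
  }
  n <- nrow(tbl)
  if (n < 3) abort("noise consistency needs at least 3 animals")
  if (sd(tbl$resid_norm) == 0 || sd(tbl$sigma_norm) == 0) {
    warn("constant input: correlation undefined")
    return(tibble::tibble(pearson_r = NA_real_, r_squared = NA_real_, n_animals = n))
  }
  r <- cor(tbl$resid_norm, tbl$sigma_norm)
  tibble::tibble(pearson_r = r, r_squared = r^2, n_animals = n)
}

#' Cohort learning-rate trend and cumulative accuracy
#'
#' Summarizes dynamic-learning-rate fits across a cohort: per animal the
#' log-deviation \eqn{\Delta\log\hat\alpha_t = \log\hat\alpha_t -
#' \log\hat\alpha_1} (invariant to the static rate scaling; rates floored at
#' `alpha_floor` before logs), trial-warped to a common grid and averaged,
#' with pointwise one-sample t statistics against 0; alongside the warped
#' cohort mean of cumulative accuracy (running fraction of rewarded trials)
#' and the correlation between the two cohort curves.
#'
#' @param rate_trajs List of per-animal posterior-mean learning-rate
#'   trajectories \eqn{\hat\alpha_{1:T}}.
#' @param trials_list List of the corresponding trial tibbles.
#' @param grid_size Warped grid size.
#' @param alpha_floor Floor applied before taking logs (default 1e-6).
#' @return A list: `rates` (tibble `frac, mean, se, t_stat, p_value`),
#'   `accuracy` (tibble `frac, mean, se`), `correlation` (scalar),
#'   `excluded` (indices of animals with rates at the floor throughout).
#' @export
rate_trend_summary <- function(rate_trajs, trials_list, grid_size = 100,
                               alpha_floor = 1e-6) {
  stopifnot(length(rate_trajs) == length(trials_list))
  keep <- vapply(rate_trajs, function(a) any(a > alpha_floor), logical(1))
  if (!all(keep)) {
    warn(paste0(sum(!keep), " animal(s) with learning rate at the floor throughout; excluded"))
  }
  if (!any(keep)) abort("no animal with a usable learning-rate trajectory")
  dlog <- purrr::map(rate_trajs[keep], function(a) {
    la <- log(pmax(a, alpha_floor))
    la - la[1]
  })
  warped <- trial_warp(dlog, grid_size)
  rates <- warped |>
    dplyr::group_by(.data$frac) |>
    dplyr::summarise(
      mean = mean(.data$value), se = sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      t_stat = ifelse(.data$se > 0, .data$mean / .data$se, NA_real_),
      p_value = 2 * stats::pt(-abs(.data$t_stat), df = .data$n - 1)
    )
  acc <- purrr::map(trials_list[keep], function(tt) {
    cumsum(tt$reward > 0) / seq_len(nrow(tt))
  })
  accuracy <- warp_average(acc, grid_size)
  correlation <- if (sd(rates$mean) == 0 || sd(accuracy$mean) == 0) {
    NA_real_ # constant trend: correlation undefined
  } else {
    cor(rates$mean, accuracy$mean)
  }
  list(
    rates = dplyr::select(rates, "frac", "mean", "se", "t_stat", "p_value"),
    accuracy = accuracy,
    correlation = correlation,
    excluded = which(!keep)
  )
}
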