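#' Tidy a parameter set
#'
#' @param x A `pg_params` object.
#' @param ... Unused.
#' @return A tibble with one row per regressor and columns `term`, `alpha`,
#'   `beta`, `Qdiag`, `sigma`, `sigma_day`.
#' @export
tidy.pg_params <- function(x, ...) {
  tibble::tibble(
    term = regressor_names[seq_len(x$n_regressors)],
    alpha = x$alpha, beta = x$beta, Qdiag = x$Qdiag,
    sigma = x$sigma, sigma_day = x$sigma_day
  )
}

#' Tidy a maximum-likelihood fit
#'
#' @param x A `pg_fit` object.
#' @param ... Unused.
#' @return A long tibble of fitted parameter values with columns
#'   `parameter`, `term`, `estimate`.
#' @export
tidy.pg_fit <- function(x, ...) {
  p <- x$params_hat
  if (inherits(p, "tdrl_params")) {
    return(tibble::tibble(
      parameter = c("sigma_m", "td_rate", "V_L_init", "V_R_init", "stochasticity"),
      term = NA_character_,
      estimate = c(p$sigma_m, p$td_rate, p$V_init, p$stochasticity)
    ))
  }
  long <- tidy.pg_params(p) |>
    tidyr::pivot_longer(-"term", names_to = "parameter", values_to = "estimate") |>
    dplyr::select("parameter", "term", "estimate")
  extra <- tibble::tibble(
    parameter = c("alpha0", "sigma_alpha", "beta_sigma"),
    term = NA_character_,
    estimate = c(p$alpha0, p$sigma_alpha, p$beta_sigma)
  )
  if (p$variant == "dynamic_rate") long <- dplyr::bind_rows(long, extra[1:2, ])
  if (p$variant == "dynamic_baseline") long <- dplyr::bind_rows(long, extra[3, ])
  long
}

#' @rdname tidy.pg_fit
#' @export
glance.pg_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    loglik_full = x$loglik_full,
    loglik_train = x$loglik_train,
    loglik_heldout = x$loglik_heldout,
    n_trials = x$n_trials,
    n_heldout = sum(x$mask),
    n_particles = x$n_particles,
    convergence = x$convergence
  )
}

#' Tidy posterior trajectories
#'
#' @param x A `particle_posterior` object.
#' @param type `"filtered"` or `"smoothed"` (requires
#'   [smooth_posterior()]).
#' @param ... Unused.
#' @return A long tibble with columns `trial` (0-based), `state`, `mean`,
#'   `sd`.
#' @export
tidy.particle_posterior <- function(x, type = c("filtered", "smoothed"), ...) {
  type <- match.arg(type)
  m <- if (type == "filtered") x$filt_mean else x$smooth_mean
  s <- if (type == "filtered") x$filt_sd else x$smooth_sd
  if (is.null(m)) abort("run smooth_posterior() first for smoothed trajectories")
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(trial = seq_len(nrow(m)) - 1L) |>
    tidyr::pivot_longer(-"trial", names_to = "state", values_to = "mean") |>
    dplyr::left_join(
      tibble::as_tibble(as.data.frame(s)) |>
        dplyr::mutate(trial = seq_len(nrow(s)) - 1L) |>
        tidyr::pivot_longer(-"trial", names_to = "state", values_to = "sd"),
      by = c("trial", "state")
    )
}

#' @rdname tidy.particle_posterior
#' @export
glance.particle_posterior <- function(x, ...) {
  tibble::tibble(
    loglik_full = x$loglik_total,
    loglik_train = x$loglik_train,
    loglik_heldout = x$loglik_heldout,
    n_trials = length(x$loglik_per_trial),
    n_particles = x$n_particles,
    min_ess = min(x$ess_trace)
  )
}

#' Tidy a Metropolis-Hastings chain
#'
#' @param x An `mh_chain` object.
#' @param ... Unused.
#' @return A tibble with per-parameter posterior mean, SD and central 90%
#'   interval.
#' @export
tidy.mh_chain <- function(x, ...) {
  q <- apply(x$draws, 2, stats::quantile, probs = c(0.05, 0.95))
  tibble::tibble(
    parameter = colnames(x$draws),
    mean = colMeans(x$draws),
    sd = x$posterior_sd,
    q05 = q[1, ], q95 = q[2, ]
  )
}

#' @rdname tidy.mh_chain
#' @export
glance.mh_chain <- function(x, ...) {
  tibble::tibble(
    n_kept = nrow(x$draws),
    n_steps = x$n_steps,
    burn_in = x$burn_in,
    acceptance_rate = x$acceptance_rate
  )
}

#' Tidy a learning/noise decomposition
#'
#' @param x A `pg_decomposition` object.
#' @param ... Unused.
#' @return A tibble with per-update `trial`, `learn_norm`, `resid_norm` and
#'   the bounded per-trial learning ratio `f` (NA on uninformative trials).
#' @export
tidy.pg_decomposition <- function(x, ...) {
  ln <- x$learn_norm
  rn <- x$resid_norm
  tot <- ln + rn
  tibble::tibble(
    trial = seq_along(ln) - 1L,
    learn_norm = ln,
    resid_norm = rn,
    f = ifelse(tot > 0, ln / tot, NA_real_)
  )
}
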