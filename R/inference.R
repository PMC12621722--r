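# Normalize inputs for the particle filter: either a trial tibble (standard
# 5-regressor policy) or a list(x = T-by-M matrix, choice = +/-1, reward,
# session) for toy problems of other dimension.
as_pf_data <- function(trials, regressors = NULL) {
  if (is.data.frame(trials)) {
    validate_trials(trials)
    X <- if (is.null(regressors)) {
      as_regressor_matrix(build_regressors(trials))
    } else {
      as_regressor_matrix(regressors)
    }
    list(
      x = X,
      choice = side_to_num(trials$choice),
      reward = trials$reward,
      session = trials$session
    )
  } else {
    stopifnot(is.list(trials), !is.null(trials$x), !is.null(trials$choice))
    x <- as_regressor_matrix(trials$x)
    list(
      x = x,
      choice = as.numeric(trials$choice),
      reward = as.numeric(trials$reward %||% rep(0, nrow(x))),
      session = as.integer(trials$session %||% rep(1L, nrow(x)))
    )
  }
}

variant_code <- function(variant) {
  switch(variant, dynamic_rate = 1L, dynamic_baseline = 2L, 0L)
}

state_names <- function(params) {
  M <- params$n_regressors
  nm <- if (M == length(regressor_names)) regressor_names else paste0("w", seq_len(M))
  switch(variant_code(params$variant) + 1L,
    nm,
    c(nm, "alpha_t"),
    c(nm, paste0("beta_", nm))
  )
}

#' Particle filter for learning-rule state-space models
#'
#' Runs a bootstrap particle filter over the latent weight trajectory (plus
#' the latent learning-rate gate or baseline for the dynamic variants).
#' Particles are propagated through the learning rule conditioned on the
#' animal's realized choices and rewards — the realized choice drives the
#' dynamics even on held-out trials — and weighted by the Bernoulli
#' likelihood of the realized choice on observed trials. Held-out trials are
#' not reweighted; their predictive log probability under the particle
#' mixture is still recorded. Systematic resampling triggers when the
#' effective sample size drops below half the particle count. The summed
#' per-trial log increments estimate the marginal log-likelihood of the
#' choice sequence with the weight trajectory integrated out.
#'
#' @param trials A validated trial tibble, or a list with elements `x`
#'   (T-by-M regressor matrix), `choice` (+/-1), `reward`, `session` for toy
#'   problems.
#' @param params A [pg_params()] object.
#' @param mask Logical held-out mask from [heldout_mask()] (`NULL` = all
#'   trials observed).
#' @param n_particles Number of particles (>= 2; default 1000).
#' @param seed Integer seed; the filter is deterministic given the seed.
#' @param store_paths Keep particle states and genealogy for
#'   [smooth_posterior()] (memory ~ `8 * T * n_particles * D` bytes).
#' @param regressors Optional precomputed regressor matrix.
#' @return A `particle_posterior` object with elements `filt_mean`,
#'   `filt_sd` (T-by-D), `loglik_per_trial`, `loglik_total` (all trials),
#'   `loglik_train` (observed trials), `loglik_heldout`, `ess_trace`,
#'   `n_particles`, `mask`, `params`.
#' @export
particle_filter <- function(trials, params, mask = NULL, n_particles = 1000,
                            seed = 1L, store_paths = TRUE, regressors = NULL) {
  stopifnot(inherits(params, "pg_params"))
  if (n_particles < 2) abort("n_particles must be >= 2")
  dat <- as_pf_data(trials, regressors)
  T_ <- nrow(dat$x)
  if (ncol(dat$x) != params$n_regressors) {
    abort("regressor dimension does not match params$n_regressors")
  }
  if (is.null(mask)) mask <- rep(FALSE, T_)
  if (length(mask) != T_) abort("mask length must equal the number of trials")
  boundary_next <- c(diff(dat$session) != 0, FALSE)
  res <- withr::with_seed(seed, pf_pg_cpp(
    dat$x, dat$choice, dat$reward, boundary_next, !mask,
    params$alpha, params$beta, params$Qdiag, params$sigma, params$sigma_day,
    params$w1_mean, params$w1_sd,
    variant_code(params$variant), params$alpha0, params$sigma_alpha,
    params$beta_sigma, as.integer(n_particles), store_paths
  ))
  if (any(!is.finite(res$loglik_per_trial))) {
    abort(paste0(
      "particle weights underflowed at trial ",
      which(!is.finite(res$loglik_per_trial))[1],
      "; try more particles or a better initialization"
    ))
  }
  nm <- state_names(params)
  colnames(res$filt_mean) <- nm
  colnames(res$filt_sd) <- nm
  structure(
    list(
      filt_mean = res$filt_mean, filt_sd = res$filt_sd,
      smooth_mean = NULL, smooth_sd = NULL,
      loglik_per_trial = res$loglik_per_trial,
      loglik_total = sum(res$loglik_per_trial),
      loglik_train = sum(res$loglik_per_trial[!mask]),
      loglik_heldout = sum(res$loglik_per_trial[mask]),
      ess_trace = pmin(pmax(res$ess_trace, 1), n_particles),
      n_particles = as.integer(n_particles),
      mask = mask, params = params, seed = seed,
      paths = if (store_paths) {
        list(states = res$states, ancestors = res$ancestors,
             final_weights = res$final_weights)
      }
    ),
    class = "particle_posterior"
  )
}

#' @export
print.particle_posterior <- function(x, ...) {
  cat(
    "<particle_posterior>", length(x$loglik_per_trial), "trials,",
    x$n_particles, "particles; loglik (full)", round(x$loglik_total, 2), "\n"
  )
  cat(
    "  train", round(x$loglik_train, 2), "| held-out",
    round(x$loglik_heldout, 2), "| min ESS", round(min(x$ess_trace), 1), "\n"
  )
  if (!is.null(x$smooth_mean)) cat("  smoothed trajectories available\n")
  invisible(x)
}

#' Smoothed posterior trajectories by ancestral-lineage tracing
#'
#' Traces the genealogy of the final particle set back through every
#' resampling step, yielding draws from the joint smoothing distribution of
#' the latent trajectory; per-trial smoothed means and SDs are the
#' final-weight-weighted moments of the surviving lineages. Smoothing does
#' not change any likelihood quantity. A warning is raised when the
#' genealogy has collapsed (< 1% unique ancestors at the first trial).
#'
#' @param pf A `particle_posterior` from [particle_filter()] run with
#'   `store_paths = TRUE`.
#' @return The same object with `smooth_mean` and `smooth_sd` filled in.
#' @export
smooth_posterior <- function(pf) {
  stopifnot(inherits(pf, "particle_posterior"))
  if (is.null(pf$paths)) {
    abort("particle_filter() must be run with store_paths = TRUE for smoothing")
  }
  states <- pf$paths$states
  anc <- pf$paths$ancestors
  wfin <- pf$paths$final_weights
  dm <- dim(states)
  n <- dm[1]; D <- dm[2]; T_ <- dm[3]
  sm <- matrix(NA_real_, T_, D)
  ss <- matrix(NA_real_, T_, D)
  idx <- seq_len(n)
  for (t in T_:1) {
    st <- matrix(states[((t - 1) * n * D + 1):(t * n * D)], n, D)[idx, , drop = FALSE]
    m <- colSums(wfin * st)
    m2 <- colSums(wfin * st^2)
    sm[t, ] <- m
    ss[t, ] <- sqrt(pmax(m2 - m^2, 0))
    if (t > 1) idx <- anc[t, idx]
  }
  if (length(unique(idx)) < max(1, 0.01 * n)) {
    warn("particle genealogy is degenerate at early trials (< 1% unique ancestors); smoothed SDs there are unreliable")
  }
  colnames(sm) <- colnames(pf$filt_mean)
  colnames(ss) <- colnames(pf$filt_sd)
  pf$smooth_mean <- sm
  pf$smooth_sd <- ss
  pf
}

#' Per-trial predictive log probabilities on held-out trials
#'
#' For every held-out trial, the log of the particle-mixture predictive
#' probability of the animal's realized choice (the filter records these
#' while skipping reweighting). Their sum equals the filter's
#' `loglik_heldout`.
#'
#' @param pf A `particle_posterior`.
#' @param mask The same held-out mask the filter was run with.
#' @return A tibble with columns `trial` (0-based) and `loglik`.
#' @export
heldout_predictive <- function(pf, mask) {
  stopifnot(inherits(pf, "particle_posterior"))
  if (!identical(as.logical(mask), as.logical(pf$mask))) {
    abort("mask does not match the mask the filter was run with")
  }
  tibble::tibble(
    trial = which(as.logical(mask)) - 1L,
    loglik = pf$loglik_per_trial[as.logical(mask)]
  )
}

# ---- parameter vectorization for optimization / MH ----

positive_params <- c("sigma", "sigma_day", "Qdiag", "sigma_alpha", "beta_sigma")
vector_params <- c("alpha", "beta", "Qdiag", "sigma", "sigma_day")
scalar_params <- c("alpha0", "sigma_alpha", "beta_sigma")

default_free <- function(variant) {
  switch(variant,
    noise_only = c("sigma", "sigma_day"),
    scalar_pg = ,
    vector_pg = c("alpha", "beta", "Qdiag", "sigma", "sigma_day"),
    dynamic_rate = c("alpha", "beta", "Qdiag", "sigma", "sigma_day", "alpha0", "sigma_alpha"),
    dynamic_baseline = c("alpha", "beta", "Qdiag", "sigma", "sigma_day", "beta_sigma")
  )
}

# Builds the map between a constrained pg_params object and an unconstrained
# coordinate vector. `free` names parameters to optimize; `tie` collapses a
# vector parameter to one shared entry; `free_idx` restricts which components
# of an untied vector parameter move. Positivity enforced via softplus
# (alpha included unless alpha_positive = FALSE).
make_theta_map <- function(base, free, tie = character(), free_idx = list(),
                           alpha_positive = TRUE) {
  M <- base$n_regressors
  if (base$variant == "scalar_pg") tie <- union(tie, vector_params)
  pos <- positive_params
  if (alpha_positive) pos <- c(pos, "alpha")
  entries <- list()
  for (nm in free) {
    if (nm %in% vector_params) {
      idxs <- if (nm %in% tie) list(seq_len(M)) else {
        sel <- free_idx[[nm]] %||% seq_len(M)
        as.list(sel)
      }
      for (k in seq_along(idxs)) {
        lab <- if (nm %in% tie) nm else paste0(nm, "[", idxs[[k]][1], "]")
        entries[[length(entries) + 1]] <- list(name = nm, idx = idxs[[k]], label = lab,
                                               positive = nm %in% pos)
      }
    } else if (nm %in% scalar_params) {
      entries[[length(entries) + 1]] <- list(name = nm, idx = NA, label = nm,
                                             positive = nm %in% pos)
    } else {
      abort(paste0("unknown free parameter: ", nm))
    }
  }
  list(
    base = base, entries = entries,
    labels = vapply(entries, function(e) e$label, character(1))
  )
}

theta_from_params <- function(map, params = map$base) {
  vapply(map$entries, function(e) {
    v <- if (e$name %in% scalar_params) params[[e$name]] else params[[e$name]][e$idx[1]]
    if (e$positive) softplus_inv(max(v, 1e-8)) else v
  }, numeric(1))
}

params_from_theta <- function(map, theta) {
  p <- map$base
  for (k in seq_along(map$entries)) {
    e <- map$entries[[k]]
    v <- if (e$positive) softplus(theta[k]) else theta[k]
    if (e$name %in% scalar_params) {
      p[[e$name]] <- v
    } else {
      p[[e$name]][e$idx] <- v
    }
  }
  p
}

#' Maximum-likelihood estimation of learning-rule parameters
#'
#' Maximizes the particle-filter estimate of the marginal log-likelihood
#' over unconstrained parameter coordinates (positivity of learning rates,
#' noise scales and decay via softplus; baselines unconstrained). Common
#' random numbers freeze the filter's randomness within an optimization so
#' the objective is deterministic in the parameters; the training objective
#' sums only over non-held-out trials. Multi-start optimization takes the
#' best optimum. Full-trajectory and held-out log-likelihoods at the optimum
#' are re-evaluated with a fresh seed.
#'
#' @inheritParams particle_filter
#' @param variant Model variant (see [pg_params()]).
#' @param init Optional `pg_params` giving the starting point (and the
#'   values of parameters that are not free).
#' @param free Character vector of parameter names to optimize; defaults to
#'   the variant's full free set. Parameters not listed stay at `init`.
#' @param tie Names of vector parameters constrained to a single shared
#'   value during optimization.
#' @param free_idx Named list restricting which components of a free vector
#'   parameter move, e.g. `list(alpha = c(2, 3))` for the two stimulus
#'   learning rates.
#' @param alpha_positive Constrain learning rates nonnegative (default TRUE).
#' @param n_starts Number of optimizer starts (jittered; default 3).
#' @param n_chain Sequential Nelder-Mead restarts from the incumbent within
#'   each start (default 2): re-expanding the simplex guards against
#'   premature contraction on the jagged common-random-number surface.
#' @param n_rep Number of fixed filter randomizations averaged per objective
#'   evaluation (default 1); raising it lowers the Monte Carlo noise of the
#'   common-random-number surface at proportional cost.
#' @param maxit Maximum iterations per start.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param method [stats::optim()] method; `"Nelder-Mead"` (default) or
#'   `"BFGS"` (finite-difference gradients on the common-random-number
#'   objective).
#' @return A `pg_fit` object: `params_hat`, `loglik_full`, `loglik_train`,
#'   `loglik_heldout`, `mask`, `optim` diagnostics, `map` (free-parameter
#'   spec), `n_particles`, `seed`.
#' @export
fit_mle <- function(trials, variant = "vector_pg", init = NULL, mask = NULL,
                    n_particles = 300, seed = 1L, free = NULL,
                    tie = character(), free_idx = list(),
                    alpha_positive = TRUE, n_starts = 3, n_chain = 2,
                    n_rep = 1, maxit = 200, reltol = 1e-6,
                    method = c("Nelder-Mead", "BFGS"), regressors = NULL) {
  method <- match.arg(method)
  dat <- as_pf_data(trials, regressors)
  T_ <- nrow(dat$x)
  if (T_ < 500) warn("fewer than 500 trials: parameter estimates may be poorly constrained")
  M <- ncol(dat$x)
  if (is.null(init)) init <- pg_params(variant, n_regressors = M)
  stopifnot(identical(init$variant, variant))
  free <- free %||% default_free(variant)
  map <- make_theta_map(init, free, tie = tie, free_idx = free_idx,
                        alpha_positive = alpha_positive)
  if (is.null(mask)) mask <- rep(FALSE, T_)
  crn_seeds <- vapply(seq_len(n_rep), function(k) derive_seed(seed, 17L + 100L * k),
                      integer(1))

  objective <- function(theta) {
    p <- params_from_theta(map, theta)
    ll <- vapply(crn_seeds, function(cs) {
      particle_filter(dat, p, mask = mask, n_particles = n_particles,
                      seed = cs, store_paths = FALSE)$loglik_train
    }, numeric(1))
    -mean(ll)
  }

  theta0 <- theta_from_params(map)
  f0 <- objective(theta0)
  if (!is.finite(f0)) {
    abort("objective is not finite at the initial parameters")
  }
  starts <- withr::with_seed(derive_seed(seed, 19L), {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1) theta0 else theta0 + rnorm(length(theta0), 0, 0.5)
    })
  })
  if (length(theta0) == 1 && method == "Nelder-Mead") {
    # 1-D search: golden-section/parabolic (Brent) is far more reliable than
    # a one-dimensional simplex on the jagged CRN surface
    runs <- lapply(starts, function(th) {
      tryCatch({
        res <- optim(th, objective, method = "Brent",
                     lower = th - 5, upper = th + 5,
                     control = list(maxit = maxit))
        res
      }, error = function(e) NULL)
    })
  } else {
  runs <- lapply(starts, function(th) {
    tryCatch({
      res <- optim(th, objective, method = method,
                   control = list(maxit = maxit, reltol = reltol))
      for (chain in seq_len(max(0, n_chain - 1))) {
        nxt <- optim(res$par, objective, method = method,
                     control = list(maxit = maxit, reltol = reltol))
        if (nxt$value >= res$value - 1e-9) {
          res <- if (nxt$value < res$value) nxt else res
          break
        }
        res <- nxt
      }
      res
    }, error = function(e) NULL)
  })
  }
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) abort("all optimization starts failed")
  best <- runs[[which.min(vapply(runs, function(r) r$value, numeric(1)))]]
  if (best$value > f0 + 1e-9) {
    warn("optimization did not improve on the initial parameters; returning the initial point")
    best <- list(par = theta0, value = f0, convergence = 1L, counts = c(0, 0))
  }
  params_hat <- params_from_theta(map, best$par)
  pf_fresh <- particle_filter(dat, params_hat, mask = mask,
                              n_particles = n_particles,
                              seed = derive_seed(seed, 23L), store_paths = FALSE)
  structure(
    list(
      params_hat = params_hat, variant = variant,
      loglik_full = pf_fresh$loglik_total,
      loglik_train = pf_fresh$loglik_train,
      loglik_heldout = pf_fresh$loglik_heldout,
      loglik_trace = -vapply(runs, function(r) r$value, numeric(1)),
      mask = mask, map = map,
      convergence = best$convergence, counts = best$counts,
      n_particles = as.integer(n_particles), seed = seed, n_trials = T_
    ),
    class = "pg_fit"
  )
}

#' @export
print.pg_fit <- function(x, ...) {
  cat("<pg_fit>", x$variant, "fit on", x$n_trials, "trials (",
      x$n_particles, "particles )\n")
  cat("  loglik: full", round(x$loglik_full, 2),
      "| train", round(x$loglik_train, 2),
      "| held-out", round(x$loglik_heldout, 2), "\n")
  cat("  free:", paste(x$map$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Particle-marginal Metropolis-Hastings over model parameters
#'
#' Gaussian random-walk Metropolis in unconstrained parameter coordinates
#' with the particle-filter likelihood estimate in the acceptance ratio. A
#' fresh filter randomization is drawn for every proposal and the estimate
#' is carried with the chain state, which is what makes the pseudo-marginal
#' chain target the exact posterior (under a flat prior on the unconstrained
#' coordinates). The proposal scale is adapted toward ~25% acceptance during
#' burn-in, then frozen; reported acceptance is post burn-in.
#'
#' @inheritParams fit_mle
#' @param theta_init Starting parameters: a `pg_params` object, or a plain
#'   numeric vector when `loglik_fn` is supplied.
#' @param n_steps Total MH steps (including burn-in).
#' @param burn_in Steps of adaptation (default `n_steps %/% 5`); adapted
#'   draws are discarded from summaries but returned.
#' @param proposal_sd Initial per-coordinate proposal SD.
#' @param loglik_fn Optional function `function(theta) -> log-likelihood`
#'   replacing the particle filter (e.g. an analytic target for sampler
#'   validation); coordinates are then taken as unconstrained identity.
#' @return An `mh_chain` object: `draws` (kept steps, constrained scale),
#'   `draws_unconstrained`, `acceptance_rate`, `posterior_sd`, `labels`,
#'   `scale`.
#' @export
pmmh_sample <- function(trials = NULL, variant = "vector_pg", theta_init,
                        n_particles = 300, n_steps = 2000, seed = 1L,
                        mask = NULL, free = NULL, tie = character(),
                        free_idx = list(), proposal_sd = 0.1,
                        burn_in = max(1L, n_steps %/% 5L),
                        loglik_fn = NULL, regressors = NULL) {
  analytic <- !is.null(loglik_fn)
  if (analytic) {
    map <- NULL
    z <- as.numeric(theta_init)
    labels <- names(theta_init) %||% paste0("theta", seq_along(z))
    ll_of <- function(zz) loglik_fn(zz)
    to_constrained <- identity
  } else {
    stopifnot(inherits(theta_init, "pg_params"))
    dat <- as_pf_data(trials, regressors)
    if (is.null(mask)) mask <- rep(FALSE, nrow(dat$x))
    free <- free %||% default_free(variant)
    map <- make_theta_map(theta_init, free, tie = tie, free_idx = free_idx)
    z <- theta_from_params(map)
    labels <- map$labels
    ll_of <- function(zz) {
      p <- params_from_theta(map, zz)
      sub <- sample.int(2147483646L, 1)
      particle_filter(dat, p, mask = mask, n_particles = n_particles,
                      seed = sub, store_paths = FALSE)$loglik_train
    }
    to_constrained <- function(zz) {
      vapply(seq_along(zz), function(k) {
        if (map$entries[[k]]$positive) softplus(zz[k]) else zz[k]
      }, numeric(1))
    }
  }
  P <- length(z)
  scale <- rep(proposal_sd, length.out = P)
  withr::with_seed(seed, {
    ll <- ll_of(z)
    if (!is.finite(ll)) abort("theta_init has non-finite likelihood")
    draws <- matrix(NA_real_, n_steps, P)
    acc <- logical(n_steps)
    adapt_factor <- 1
    window_acc <- 0
    window_n <- 0
    for (s in seq_len(n_steps)) {
      zp <- z + adapt_factor * scale * rnorm(P)
      llp <- ll_of(zp)
      if (is.finite(llp) && log(runif(1)) < llp - ll) {
        z <- zp
        ll <- llp
        acc[s] <- TRUE
      }
      draws[s, ] <- z
      if (s <= burn_in) {
        window_acc <- window_acc + acc[s]
        window_n <- window_n + 1
        if (window_n == 50) {
          rate <- window_acc / window_n
          adapt_factor <- adapt_factor * exp(rate - 0.25)
          window_acc <- 0
          window_n <- 0
        }
      }
    }
    kept <- draws[(burn_in + 1):n_steps, , drop = FALSE]
    kept_c <- t(apply(kept, 1, to_constrained))
    if (P == 1) kept_c <- matrix(kept_c, ncol = 1)
    colnames(kept_c) <- labels
    colnames(kept) <- labels
    acc_rate <- mean(acc[(burn_in + 1):n_steps])
    if (acc_rate < 0.01 && any(adapt_factor * scale > 0)) {
      warn("PMMH acceptance below 1% after adaptation; posterior summaries unreliable")
    }
    structure(
      list(
        draws = kept_c, draws_unconstrained = kept,
        acceptance_rate = acc_rate,
        posterior_sd = apply(kept_c, 2, sd),
        labels = labels, scale = adapt_factor * scale,
        map = map, n_steps = n_steps, burn_in = burn_in, seed = seed
      ),
      class = "mh_chain"
    )
  })
}

#' @export
print.mh_chain <- function(x, ...) {
  cat("<mh_chain>", nrow(x$draws), "kept draws,",
      "acceptance", round(x$acceptance_rate, 3), "\n")
  print(round(rbind(mean = colMeans(x$draws), sd = x$posterior_sd), 4))
  invisible(x)
}

#' Compare fitted models by full-trajectory log-likelihood
#'
#' Tabulates each fitted model's full-trajectory marginal log-likelihood
#' (which includes held-out trials) minus a named baseline's; positive
#' differences favour the model over the baseline. All fits must share the
#' same trials and held-out mask.
#'
#' @param fits A named list of `pg_fit` objects (or any list with elements
#'   `loglik_full` and `mask`).
#' @param baseline Name of the baseline model in `fits`.
#' @return A tibble with columns `model`, `loglik_full`, `delta_loglik`.
#' @export
compare_models <- function(fits, baseline) {
  stopifnot(baseline %in% names(fits))
  masks <- lapply(fits, function(f) as.logical(f$mask))
  if (!all(vapply(masks, identical, logical(1), masks[[1]]))) {
    abort("all fits must use the same held-out mask")
  }
  ll <- vapply(fits, function(f) f$loglik_full, numeric(1))
  tibble::tibble(
    model = names(fits),
    loglik_full = unname(ll),
    delta_loglik = unname(ll - ll[[baseline]])
  )
}

#' Particle-filter likelihood for the TDRL model
#'
#' Bootstrap filter over the latent action-value pair `(V_L, V_R)`:
#' observation model is the percept-marginalized probit choice rule,
#' propagation the belief-weighted TD update with its percept-noise
#' fluctuation. Interface mirrors [particle_filter()].
#'
#' @inheritParams particle_filter
#' @param params A [tdrl_params()] object.
#' @return A `particle_posterior` object (state dimension 2).
#' @export
particle_filter_tdrl <- function(trials, params, mask = NULL,
                                 n_particles = 1000, seed = 1L) {
  stopifnot(inherits(params, "tdrl_params"))
  validate_trials(trials)
  T_ <- nrow(trials)
  if (is.null(mask)) mask <- rep(FALSE, T_)
  s <- trials$contrast_right - trials$contrast_left
  y <- side_to_num(trials$choice)
  res <- withr::with_seed(seed, pf_tdrl_cpp(
    s, y, trials$reward, !mask, params$sigma_m, params$td_rate,
    params$V_init[1], params$V_init[2], params$stochasticity,
    as.integer(n_particles)
  ))
  colnames(res$filt_mean) <- c("V_L", "V_R")
  colnames(res$filt_sd) <- c("V_L", "V_R")
  structure(
    list(
      filt_mean = res$filt_mean, filt_sd = res$filt_sd,
      smooth_mean = NULL, smooth_sd = NULL,
      loglik_per_trial = res$loglik_per_trial,
      loglik_total = sum(res$loglik_per_trial),
      loglik_train = sum(res$loglik_per_trial[!mask]),
      loglik_heldout = sum(res$loglik_per_trial[mask]),
      ess_trace = pmin(pmax(res$ess_trace, 1), n_particles),
      n_particles = as.integer(n_particles),
      mask = mask, params = params, seed = seed, paths = NULL
    ),
    class = "particle_posterior"
  )
}

#' Fit the TDRL model by maximum likelihood
#'
#' Common-random-number particle-filter objective over `(sigma_m, td_rate)`
#' (log / logit transformed), other parameters held at `init`.
#'
#' @inheritParams fit_mle
#' @param init A [tdrl_params()] starting point.
#' @return A `pg_fit`-style object with `params_hat` a `tdrl_params`.
#' @export
fit_tdrl <- function(trials, init = tdrl_params(), mask = NULL,
                     n_particles = 300, seed = 1L, maxit = 100) {
  validate_trials(trials)
  T_ <- nrow(trials)
  if (is.null(mask)) mask <- rep(FALSE, T_)
  crn_seed <- derive_seed(seed, 17L)
  objective <- function(theta) {
    p <- tdrl_params(
      sigma_m = exp(theta[1]), td_rate = plogis(theta[2]),
      V_init = init$V_init, stochasticity = init$stochasticity,
      rstar = init$rstar
    )
    -particle_filter_tdrl(trials, p, mask = mask, n_particles = n_particles,
                          seed = crn_seed)$loglik_train
  }
  theta0 <- c(log(init$sigma_m), qlogis(min(max(init$td_rate, 1e-4), 1 - 1e-4)))
  best <- optim(theta0, objective, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-7))
  params_hat <- tdrl_params(
    sigma_m = exp(best$par[1]), td_rate = plogis(best$par[2]),
    V_init = init$V_init, stochasticity = init$stochasticity, rstar = init$rstar
  )
  pf <- particle_filter_tdrl(trials, params_hat, mask = mask,
                             n_particles = n_particles,
                             seed = derive_seed(seed, 23L))
  structure(
    list(
      params_hat = params_hat, variant = "tdrl",
      loglik_full = pf$loglik_total, loglik_train = pf$loglik_train,
      loglik_heldout = pf$loglik_heldout,
      mask = mask, map = list(labels = c("sigma_m", "td_rate")),
      convergence = best$convergence, counts = best$counts,
      n_particles = as.integer(n_particles), seed = seed, n_trials = T_
    ),
    class = "pg_fit"
  )
}
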