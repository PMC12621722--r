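#' Stimulus curricula
#'
#' A curriculum defines, per training session, the sampling distribution over
#' stimulus side and contrast level. The `"staged"` schedule introduces lower
#' contrasts gradually (as in shaping protocols that unlock easier-to-harder
#' stimuli); the `"uniform"` schedule presents all levels with equal
#' probability from the first session.
#'
#' @param contrast_levels Ordered contrast set, fractions in `[0, 1]`
#'   (default `c(1, 0.5, 0.25, 0.125, 0.0625, 0)`).
#' @param schedule `"staged"` or `"uniform"`.
#' @param intro_sessions For the staged schedule, a numeric vector (same
#'   length as `contrast_levels`) giving the session at which each level
#'   unlocks. The default unlocks 1.0 and 0.5 at session 1, 0.25 at 6,
#'   0.125 at 9, 0.0625 at 12 and the zero-contrast level at 15.
#' @param side_prob Probability the stimulus appears on the right, in (0, 1).
#' @param sessions Number of sessions.
#' @param trials_per_session Trials per session: a scalar or a length-
#'   `sessions` vector.
#' @return A `curriculum` object.
#' @examples
#' make_curriculum(schedule = "uniform", sessions = 3, trials_per_session = 200)
#' @export
make_curriculum <- function(contrast_levels = c(1, 0.5, 0.25, 0.125, 0.0625, 0),
                            schedule = c("staged", "uniform"),
                            intro_sessions = NULL,
                            side_prob = 0.5,
                            sessions = 10,
                            trials_per_session = 300) {
  schedule <- match.arg(schedule)
  if (length(contrast_levels) == 0) abort("contrast_levels must be nonempty")
  if (any(contrast_levels < 0 | contrast_levels > 1)) {
    abort("contrast levels must lie in [0, 1]")
  }
  if (side_prob <= 0 || side_prob >= 1) abort("side_prob must lie in (0, 1)")
  if (schedule == "uniform") {
    intro_sessions <- rep(1, length(contrast_levels))
  } else if (is.null(intro_sessions)) {
    defaults <- c("1" = 1, "0.5" = 1, "0.25" = 6, "0.125" = 9, "0.0625" = 12, "0" = 15)
    intro_sessions <- defaults[as.character(contrast_levels)]
    intro_sessions[is.na(intro_sessions)] <- 1
  }
  if (length(intro_sessions) != length(contrast_levels)) {
    abort("intro_sessions must match contrast_levels in length")
  }
  tps <- if (length(trials_per_session) == 1) {
    rep(trials_per_session, sessions)
  } else {
    trials_per_session
  }
  if (length(tps) != sessions) abort("trials_per_session must be scalar or length `sessions`")
  structure(
    list(
      contrast_levels = as.numeric(contrast_levels),
      schedule = schedule,
      intro_sessions = as.numeric(unname(intro_sessions)),
      side_prob = side_prob,
      sessions = as.integer(sessions),
      trials_per_session = as.integer(tps)
    ),
    class = "curriculum"
  )
}

#' @rdname make_curriculum
#' @description `curriculum_levels()` returns the contrast levels available
#'   in a given session (uniform sampling among them).
#' @param curriculum A `curriculum` object.
#' @param session Session index (1-based).
#' @export
curriculum_levels <- function(curriculum, session) {
  curriculum$contrast_levels[curriculum$intro_sessions <= session]
}

#' @export
print.curriculum <- function(x, ...) {
  cat(
    "<curriculum>", x$schedule, "schedule,", x$sessions, "sessions,",
    sum(x$trials_per_session), "trials; side_prob =", x$side_prob, "\n"
  )
  cat("levels:", paste0(x$contrast_levels, " (s", x$intro_sessions, ")", collapse = ", "), "\n")
  invisible(x)
}

# Draw (side, contrast) sequences for every trial of a curriculum.
sample_stimuli <- function(curriculum) {
  purrr::map_dfr(seq_len(curriculum$sessions), function(s) {
    n <- curriculum$trials_per_session[s]
    levels <- curriculum_levels(curriculum, s)
    if (length(levels) == 0) abort(paste0("no contrast levels available in session ", s))
    tibble::tibble(
      session = s,
      side = ifelse(runif(n) < curriculum$side_prob, 1, -1),
      contrast = sample(levels, n, replace = TRUE)
    )
  })
}

# Counter-based master-seed splitting: stream i of a master seed never
# changes when more streams are added.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483629)
}

#' Simulate a policy-gradient learner
#'
#' Forward-simulates the full generative model: initial weights drawn from
#' their Gaussian prior, choices sampled from the logistic policy, rewards
#' from the task rule, and weights updated by the parametric policy-gradient
#' drift plus additive Gaussian noise whose SD is `sigma_day` on
#' session-boundary transitions and `sigma` within sessions. The
#' `dynamic_rate` variant additionally evolves a latent scalar learning-rate
#' gate by a Gaussian random walk; `dynamic_baseline` evolves a latent
#' per-regressor baseline likewise. On zero-contrast trials the correct side
#' is the drawn stimulus side, so reward labels are always defined.
#'
#' @param params A [pg_params()] object.
#' @param curriculum A [make_curriculum()] object.
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param rate_traj Optional length-T numeric vector forcing the latent
#'   learning-rate gate (e.g. a planted step change); overrides the
#'   random-walk draw.
#' @return A `sim_result` list: `trials` (trial tibble), `true_weights`
#'   (T-by-M matrix), `true_rates` (length-T gate trajectory), `true_baselines`
#'   (T-by-M, dynamic-baseline variant), `params`, `curriculum`, `seed`.
#' @examples
#' sim <- simulate_pg(pg_params("vector_pg", alpha = 0.1, sigma = 0.05),
#'   make_curriculum(sessions = 2, trials_per_session = 50), seed = 1)
#' sim$trials
#' @export
simulate_pg <- function(params, curriculum, seed = 1L, rate_traj = NULL) {
  stopifnot(inherits(params, "pg_params"), inherits(curriculum, "curriculum"))
  M <- params$n_regressors
  withr::with_seed(seed, {
    stim <- sample_stimuli(curriculum)
    T_ <- nrow(stim)
    if (!is.null(rate_traj) && length(rate_traj) != T_) {
      abort("rate_traj must have one entry per trial")
    }
    w <- params$w1_mean + params$w1_sd * rnorm(M)
    alpha_t <- if (params$variant == "dynamic_rate") {
      params$alpha0 + params$sigma_alpha * rnorm(1)
    } else {
      1
    }
    beta_t <- params$beta
    W <- matrix(NA_real_, T_, M)
    rates <- numeric(T_)
    B <- if (params$variant == "dynamic_baseline") matrix(NA_real_, T_, M) else NULL
    choice <- numeric(T_)
    reward <- numeric(T_)
    cl <- ifelse(stim$side < 0, stim$contrast, 0)
    cr <- ifelse(stim$side > 0, stim$contrast, 0)
    prev_y <- 0
    prev_s <- 0
    for (t in seq_len(T_)) {
      new_session <- t == 1 || stim$session[t] != stim$session[t - 1]
      if (new_session) {
        prev_y <- 0
        prev_s <- 0
      }
      x <- c(1, cl[t], cr[t], prev_y, prev_s)
      W[t, ] <- w
      rate <- if (!is.null(rate_traj)) rate_traj[t] else alpha_t
      rates[t] <- rate
      if (!is.null(B)) B[t, ] <- beta_t
      p <- policy_prob(w, x)
      y <- if (runif(1) < p) 1 else -1
      r <- if (y == stim$side[t]) params$rstar else 0
      choice[t] <- y
      reward[t] <- r
      if (t < T_) {
        boundary <- stim$session[t + 1] != stim$session[t]
        sdv <- if (boundary) params$sigma_day else params$sigma
        gate <- if (params$variant == "dynamic_rate") rate else 1
        w <- w + vector_pg_drift(w, x, y, r, params, rate_scale = gate, beta_t = beta_t) +
          sdv * rnorm(M)
        if (params$variant == "dynamic_rate") {
          alpha_t <- alpha_t + params$sigma_alpha * rnorm(1)
        }
        if (params$variant == "dynamic_baseline") {
          beta_t <- beta_t + params$beta_sigma * rnorm(M)
        }
      }
      prev_y <- y
      prev_s <- stim$side[t]
    }
    trials <- tibble::tibble(
      session = as.integer(stim$session),
      trial = 0:(T_ - 1),
      contrast_left = cl,
      contrast_right = cr,
      correct_side = num_to_side(stim$side),
      choice = num_to_side(choice),
      reward = reward
    )
    structure(
      list(
        trials = trials, true_weights = W,
        true_rates = rates, true_baselines = B,
        params = params, curriculum = curriculum, seed = seed
      ),
      class = "sim_result"
    )
  })
}

#' Simulate a TDRL learner
#'
#' Forward-simulates the action-value model: on each trial a Gaussian percept
#' of the signed contrast is drawn, the choice follows the value-determined
#' threshold rule (optionally mixed with an unbiased lapse), reward follows
#' the task rule, and the chosen action value is updated with the
#' belief-weighted prediction error plus its percept-noise fluctuation.
#'
#' @param params A [tdrl_params()] object.
#' @inheritParams simulate_pg
#' @return A `sim_result` list with `true_weights` holding the T-by-2 value
#'   trajectory `(V_L, V_R)`.
#' @export
simulate_tdrl <- function(params, curriculum, seed = 1L) {
  stopifnot(inherits(params, "tdrl_params"), inherits(curriculum, "curriculum"))
  withr::with_seed(seed, {
    stim <- sample_stimuli(curriculum)
    T_ <- nrow(stim)
    V <- params$V_init
    Vtraj <- matrix(NA_real_, T_, 2, dimnames = list(NULL, c("V_L", "V_R")))
    choice <- numeric(T_)
    reward <- numeric(T_)
    cl <- ifelse(stim$side < 0, stim$contrast, 0)
    cr <- ifelse(stim$side > 0, stim$contrast, 0)
    s <- cr - cl
    for (t in seq_len(T_)) {
      Vtraj[t, ] <- V
      m <- s[t] + params$sigma_m * rnorm(1)
      thr <- params$sigma_m * qnorm(clamp_prob(V[1] / (V[1] + V[2])))
      y <- if (m > thr) 1 else -1
      if (params$stochasticity > 0 && runif(1) < params$stochasticity) {
        y <- if (runif(1) < 0.5) 1 else -1
      }
      r <- if (y == stim$side[t]) params$rstar else 0
      choice[t] <- y
      reward[t] <- r
      V <- tdrl_value_update(V, y, s[t], r, params, noise_draw = rnorm(1))
      V <- pmax(V, 1e-8)
    }
    trials <- tibble::tibble(
      session = as.integer(stim$session),
      trial = 0:(T_ - 1),
      contrast_left = cl,
      contrast_right = cr,
      correct_side = num_to_side(stim$side),
      choice = num_to_side(choice),
      reward = reward
    )
    structure(
      list(
        trials = trials, true_weights = Vtraj,
        true_rates = rep(1, T_), true_baselines = NULL,
        params = params, curriculum = curriculum, seed = seed
      ),
      class = "sim_result"
    )
  })
}

#' Simulate a cohort of animals
#'
#' Generates independent per-animal datasets. Per-animal seeds are derived
#' from the master seed with a counter-based splitting scheme, so enlarging
#' the cohort never perturbs earlier animals. The parameter sampler is drawn
#' under its own derived stream and the draw is logged with each result.
#'
#' @param n_animals Number of animals (>= 1).
#' @param param_sampler Either a fixed parameter object or a function
#'   `function(i)` returning the i-th animal's parameters (any randomness
#'   inside it is governed by the derived seed).
#' @inheritParams simulate_pg
#' @return A list of `sim_result` objects, one per animal.
#' @export
simulate_cohort <- function(n_animals, param_sampler, curriculum, seed = 1L) {
  if (n_animals < 1) abort("n_animals must be >= 1")
  purrr::map(seq_len(n_animals), function(i) {
    params <- if (is.function(param_sampler)) {
      withr::with_seed(derive_seed(seed, 2L * i), param_sampler(i))
    } else {
      param_sampler
    }
    sim_fun <- if (inherits(params, "tdrl_params")) simulate_tdrl else simulate_pg
    sim_fun(params, curriculum, seed = derive_seed(seed, 2L * i + 1L))
  })
}

#' @export
print.sim_result <- function(x, ...) {
  T_ <- nrow(x$trials)
  cat(
    "<sim_result>", T_, "trials,", max(x$trials$session), "sessions;",
    "accuracy", round(mean(x$trials$reward > 0), 3), "\n"
  )
  invisible(x)
}

#' Write a simulation's trial table, latent truth and parameter snapshot
#'
#' @param sim A `sim_result` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Writes `trials.csv`, `latents.csv`
#'   (true weights and, when present, the latent rate) and `params.yaml`.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(sim$trials, file.path(dir, "trials.csv"))
  lat <- tibble::as_tibble(as.data.frame(sim$true_weights))
  names(lat) <- paste0("w_", seq_len(ncol(lat)))
  lat <- dplyr::mutate(lat, trial = sim$trials$trial, .before = 1)
  if (!is.null(sim$true_rates) && stats::var(sim$true_rates) > 0) {
    lat$alpha_t <- sim$true_rates
  }
  readr::write_csv(lat, file.path(dir, "latents.csv"), progress = FALSE)
  write_params(sim$params, file.path(dir, "params.yaml"))
  invisible(dir)
}
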