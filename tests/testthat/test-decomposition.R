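test_that("learning rollout replays the rule deterministically", {
  sim <- quick_sim(pg_params("vector_pg", alpha = 0.1, beta = -0.2, sigma = 0.05),
                   seed = 3)
  p <- sim$params

  # alpha = 0, Q = 0: trajectory frozen at the start point
  w0 <- c(0.3, -0.2, 0.5, 0, 0.1)
  roll0 <- learning_rollout(pg_params("noise_only"), sim$trials, w0)
  expect_equal(roll0, matrix(w0, nrow(sim$trials), 5, byrow = TRUE),
               ignore_attr = TRUE)

  # with zero simulator noise the rollout reproduces the true trajectory
  noiseless <- quick_sim(
    pg_params("vector_pg", alpha = 0.08, beta = -0.2, sigma = 0, sigma_day = 0),
    seed = 5
  )
  roll <- learning_rollout(noiseless$params, noiseless$trials,
                           noiseless$true_weights[1, ])
  expect_equal(roll, noiseless$true_weights, ignore_attr = TRUE,
               tolerance = 1e-12)

  # determinism
  expect_identical(learning_rollout(p, sim$trials, w0),
                   learning_rollout(p, sim$trials, w0))

  expect_error(learning_rollout(p, sim$trials, w0, rate_traj = 1:3), "entry per trial")
})

test_that("update residuals decompose the inferred trajectory exactly", {
  # hand-computed 3-trial example, M = 2 regressors
  x <- matrix(c(1, 0.5, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  y <- c(1, -1, 1)
  r <- c(1, 0, 1)
  dat <- list(x = x, choice = y, reward = r, session = rep(1L, 3))
  p <- pg_params("vector_pg", alpha = c(0.1, 0.2), beta = c(-0.5, -0.5),
                 Qdiag = c(0.01, 0), sigma = 0.1, n_regressors = 2L)
  inferred <- matrix(c(0.2, 0.1, 0.3, 0.0, 0.25, 0.4), ncol = 2, byrow = TRUE)
  d <- update_residuals(inferred, p, dat)

  # trial 1: p(y1) = plogis(0.2 + 0.05); (r - beta) = 1.5
  p1 <- plogis(0.2 * 1 + 0.1 * 0.5)
  dl1 <- c(0.1, 0.2) * 1.5 * (1 - p1) * 1 * c(1, 0.5) - c(0.01, 0) * c(0.2, 0.1)
  # trial 2: y = -1, r = 0 so (r - beta) = 0.5
  p2 <- plogis(-(0.3 * 1 + 0 * 0))
  dl2 <- c(0.1, 0.2) * 0.5 * (1 - p2) * -1 * c(1, 0) - c(0.01, 0) * c(0.3, 0)
  expect_equal(d$delta_learn[1, ], dl1, tolerance = 1e-12)
  expect_equal(d$delta_learn[2, ], dl2, tolerance = 1e-12)
  expect_equal(d$residual, diff(inferred) - d$delta_learn, tolerance = 1e-12)

  # reconstruction: w_start + cumulative (learn + resid) returns the inferred path
  recon <- rbind(inferred[1, ],
                 sweep(apply(d$delta_learn + d$residual, 2, cumsum), 2,
                       inferred[1, ], "+"))
  expect_equal(recon, inferred, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(update_residuals(inferred[1:2, ], p, dat), "length")
})

test_that("learning fraction hits its endpoints exactly", {
  # noise-only: zero learning updates, fraction exactly 0
  sim <- quick_sim(pg_params("noise_only", sigma = 0.1), T_ = 400, seed = 7)
  pf <- suppressWarnings(smooth_posterior(particle_filter(
    sim$trials, sim$params, n_particles = 300, seed = 2
  )))
  d0 <- update_residuals(pf$smooth_mean, sim$params, sim$trials)
  expect_identical(learning_fraction(d0)$fraction, 0)
  expect_identical(learning_fraction(d0, method = "ratio_of_sums")$fraction, 0)
  expect_true(all(learning_fraction(d0)$per_regressor == 0))

  # noiseless learning-only trajectory: fraction exactly 1
  nl <- quick_sim(pg_params("vector_pg", alpha = 0.08, beta = -0.2,
                            sigma = 0, sigma_day = 0), seed = 8)
  d1 <- update_residuals(nl$true_weights, nl$params, nl$trials)
  expect_identical(learning_fraction(d1)$fraction, 1)
  expect_equal(learning_fraction(d1)$projection_fraction, 1, tolerance = 1e-9)
  expect_equal(learning_fraction(d1)$mean_cosine, 1, tolerance = 1e-9)

  # fractions lie in [0, 1] and decrease on average as noise grows
  frac_at <- function(sigma, seed) {
    p <- pg_params("vector_pg", alpha = 0.1, beta = -0.2, sigma = sigma,
                   sigma_day = sigma)
    s <- quick_sim(p, T_ = 400, seed = seed)
    pf <- suppressWarnings(smooth_posterior(particle_filter(
      s$trials, p, n_particles = 300, seed = seed
    )))
    learning_fraction(update_residuals(pf$smooth_mean, p, s$trials))$fraction
  }
  lo <- vapply(1:5, function(s) frac_at(0.02, s), numeric(1))
  hi <- vapply(1:5, function(s) frac_at(0.3, 100 + s), numeric(1))
  expect_true(all(lo >= 0 & lo <= 1) && all(hi >= 0 & hi <= 1))
  expect_gt(mean(lo), mean(hi))
})

test_that("preferred-side relabeling separates asymmetric cohorts and not null ones", {
  mk_animal <- function(alpha_lr, seed, T_ = 300) {
    p <- pg_params("vector_pg", alpha = c(0.05, alpha_lr[1], alpha_lr[2], 0, 0),
                   beta = 0, sigma = 0.05)
    s <- simulate_pg(p, quick_curriculum(3, T_ / 3), seed = seed)
    list(alpha = p$alpha, weights = s$true_weights)
  }
  # identity permutation control equals the unshuffled average
  coh <- purrr::map(1:4, function(i) mk_animal(c(0.15, 0.03), 40 + i))
  tab <- preferred_relabel(coh, grid_size = 30, permutation = 1:4)
  pref <- dplyr::filter(tab, curve == "preferred")
  ctrl <- dplyr::filter(tab, curve == "control_preferred")
  expect_equal(pref$mean, ctrl$mean)

  # strong asymmetry: preferred curve ends above non-preferred
  late <- dplyr::filter(tab, frac > 0.7)
  expect_gt(
    mean(dplyr::filter(late, curve == "preferred")$mean),
    mean(dplyr::filter(late, curve == "nonpreferred")$mean)
  )

  # null cohort (alpha_L = alpha_R): preferred and shuffled overlap within 2 SE
  null_coh <- purrr::map(1:6, function(i) mk_animal(c(0.08, 0.08), 60 + i))
  ntab <- preferred_relabel(null_coh, grid_size = 20, seed = 3)
  np <- dplyr::filter(ntab, curve == "preferred")
  nc <- dplyr::filter(ntab, curve == "control_preferred")
  expect_true(mean(abs(np$mean - nc$mean) <= 2 * sqrt(np$se^2 + nc$se^2) + 1e-12) > 0.9)

  expect_error(preferred_relabel(coh[1], ), "cohort")
})

test_that("reward after an error matches hand enumeration and i.i.d. controls", {
  # constructed sequence 1,0,0,0,1: pairs after an error -> rewards 0,0,1
  tt <- tibble::tibble(
    session = 1L, trial = 0:4,
    contrast_left = 0, contrast_right = 1,
    correct_side = "R",
    choice = c("R", "L", "L", "L", "R"),
    reward = c(1, 0, 0, 0, 1)
  )
  out <- reward_after_error(tt)
  expect_equal(out$conditional_mean, 1 / 3)
  expect_equal(out$shuffled_mean, 2 / 5)
  expect_equal(out$n_error_pairs, 3)

  # i.i.d. rewards: conditional equals shuffled within 3 SE
  withr::with_seed(9, {
    r <- rbinom(1e5, 1, 0.6)
    tt2 <- tibble::tibble(
      session = 1L, trial = 0:(1e5 - 1),
      contrast_left = 0, contrast_right = 1,
      correct_side = "R",
      choice = ifelse(r == 1, "R", "L"),
      reward = r
    )
    out2 <- reward_after_error(tt2)
    se <- sqrt(0.6 * 0.4 / out2$n_error_pairs)
    expect_lt(abs(out2$conditional_mean - out2$shuffled_mean), 3 * se)
  })

  # invariant to relabeling of sides
  flip <- function(x) ifelse(x == "L", "R", "L")
  tt3 <- dplyr::mutate(tt,
    contrast_left = tt$contrast_right, contrast_right = tt$contrast_left,
    correct_side = flip(tt$correct_side), choice = flip(tt$choice)
  )
  expect_equal(reward_after_error(tt3), out)

  # session boundaries break (t, t+1) pairs
  tt4 <- tt
  tt4$session <- c(1L, 1L, 1L, 2L, 2L)
  expect_equal(reward_after_error(tt4)$n_error_pairs, 2)

  all_correct <- dplyr::mutate(tt, choice = "R", reward = 1)
  expect_error(reward_after_error(all_correct), "no incorrect")
})

test_that("error-reinforcing learners earn less after errors than the shuffled control", {
  worse <- replicate(5, {
    s <- simulate_pg(
      pg_params("vector_pg", alpha = 0.4, beta = -1, sigma = 0.02,
                sigma_day = 0.02, w1_sd = 0.3),
      quick_curriculum(4, 250), seed = sample.int(1e6, 1)
    )
    out <- reward_after_error(s$trials)
    out$conditional_mean < out$shuffled_mean
  })
  expect_gte(sum(worse), 3)
})

test_that("residual norms track the generative noise scale across a cohort", {
  withr::with_seed(17, {
    sig <- runif(20, 0.03, 0.35)
    tbl <- purrr::map_dfr(seq_along(sig), function(i) {
      p <- pg_params("noise_only", sigma = sig[i], sigma_day = sig[i])
      s <- quick_sim(p, T_ = 300, seed = 70 + i, sessions = 3)
      pf <- suppressWarnings(smooth_posterior(particle_filter(
        s$trials, p, n_particles = 300, seed = i
      )))
      d <- update_residuals(pf$smooth_mean, p, s$trials)
      tibble::tibble(resid_norm = mean(d$resid_norm),
                     sigma_norm = sqrt(sum(p$sigma^2)))
    })
    out <- noise_consistency(tbl)
    expect_gt(out$pearson_r, 0.5)
    expect_equal(out$r_squared, out$pearson_r^2)
  })
  expect_error(noise_consistency(tibble::tibble(resid_norm = 1:2, sigma_norm = 1:2)),
               "3 animals")
  expect_warning(
    out <- noise_consistency(tibble::tibble(resid_norm = rep(1, 4),
                                            sigma_norm = 1:4)),
    "constant"
  )
  expect_true(is.na(out$pearson_r))
})

test_that("cohort learning-rate trends are summarized on the warped grid", {
  # static truth: log-deviation flat at 0
  flat <- rate_trend_summary(
    purrr::map(1:4, ~ rep(0.8, 200)),
    purrr::map(1:4, ~ quick_sim(pg_params("noise_only", sigma = 0.05),
                                T_ = 200, seed = .x, sessions = 2)$trials),
    grid_size = 20
  )
  expect_true(all(abs(flat$rates$mean) < 1e-12))

  # upward-ramping rates give a positive late-trial mean trend
  ramp <- rate_trend_summary(
    purrr::map(1:4, function(i) seq(0.2, 1.5, length.out = 150 + 10 * i)),
    purrr::map(1:4, function(i) {
      simulate_pg(pg_params("noise_only", sigma = 0.05),
                  make_curriculum(sessions = 1, trials_per_session = 150 + 10 * i),
                  seed = i)$trials
    }),
    grid_size = 20
  )
  expect_gt(dplyr::last(ramp$rates$mean), 0)
  expect_true(all(diff(ramp$rates$mean) > -1e-9))

  # cumulative accuracy of an all-correct sequence is constant 1
  tt <- tibble::tibble(
    session = 1L, trial = 0:99, contrast_left = 0, contrast_right = 1,
    correct_side = "R", choice = "R", reward = 1
  )
  one <- rate_trend_summary(list(rep(1, 100), rep(1, 100)), list(tt, tt),
                            grid_size = 10)
  expect_equal(one$accuracy$mean, rep(1, 10))

  # animals stuck at the rate floor are excluded with a warning
  expect_warning(
    out <- rate_trend_summary(list(rep(1e-9, 100), rep(0.5, 100)), list(tt, tt),
                              grid_size = 10),
    "floor"
  )
  expect_equal(out$excluded, 1L)
})
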