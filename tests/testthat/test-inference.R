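test_that("particle filter log-likelihood agrees with grid quadrature on a small problem", {
  params <- pg_params("vector_pg", alpha = 0.3, beta = 0, Qdiag = 0,
                      sigma = 0.4, sigma_day = 0.4, w1_mean = 0, w1_sd = 1,
                      n_regressors = 1L)
  dat <- toy_1d(10)
  ll_grid <- grid_marginal_loglik(dat$x[, 1], dat$choice, dat$reward, params)
  lls <- vapply(1:200, function(s) {
    particle_filter(dat, params, n_particles = 1000, seed = s,
                    store_paths = FALSE)$loglik_total
  }, numeric(1))
  expect_lt(abs(mean(lls) - ll_grid), 0.1)

  # unbiasedness on the likelihood scale: mean of exp(loglik) within 3 SE
  w_lik <- exp(lls - ll_grid)
  expect_lt(abs(mean(w_lik) - 1), 3 * sd(w_lik) / sqrt(length(w_lik)))
})

test_that("filter is exact and particle-count-independent in the degenerate case", {
  sim <- quick_sim(pg_params("vector_pg", alpha = 0.1, sigma = 0.1), seed = 3)
  w0 <- c(0.2, -0.4, 0.6, 0.05, -0.1)
  params <- pg_params("noise_only", sigma = 0, sigma_day = 0,
                      w1_mean = w0, w1_sd = 0)
  X <- as.matrix(as.data.frame(build_regressors(sim$trials)))
  y <- ifelse(sim$trials$choice == "R", 1, -1)
  exact <- sum(log(plogis(y * drop(X %*% w0))))
  for (np in c(2, 17, 300)) {
    pf <- particle_filter(sim$trials, params, n_particles = np, seed = np)
    expect_equal(pf$loglik_total, exact, tolerance = 1e-8)
  }

  # with learning on but all noise off the filter is still deterministic:
  # smoothed SD collapses to 0
  pl <- pg_params("vector_pg", alpha = 0.1, beta = -0.2, sigma = 0, sigma_day = 0,
                  w1_mean = w0, w1_sd = 0)
  # all particles are identical, so posterior SDs vanish (up to one-pass
  # variance round-off)
  pf <- smooth_posterior(particle_filter(sim$trials, pl, n_particles = 50, seed = 1))
  expect_lt(max(pf$smooth_sd), 1e-6)
  expect_lt(max(pf$filt_sd), 1e-6)
})

test_that("more particles reduce the variance of the likelihood estimate", {
  params <- pg_params("vector_pg", alpha = 0.3, sigma = 0.4, n_regressors = 1L)
  dat <- toy_1d(30, seed = 6)
  sd_for <- function(np) {
    sd(vapply(1:50, function(s) {
      particle_filter(dat, params, n_particles = np, seed = 1000 + s,
                      store_paths = FALSE)$loglik_total
    }, numeric(1)))
  }
  expect_lt(sd_for(400), sd_for(50))
})

test_that("held-out trials are excluded from training but still scored", {
  sim <- quick_sim(pg_params("vector_pg", alpha = 0.1, beta = -0.2, sigma = 0.08),
                   seed = 9)
  mask <- heldout_mask(nrow(sim$trials), 0.1, seed = 2)
  pf <- particle_filter(sim$trials, sim$params, mask = mask, n_particles = 300,
                        seed = 4, store_paths = FALSE)
  expect_equal(pf$loglik_total, pf$loglik_train + pf$loglik_heldout)
  expect_equal(sum(mask), 40)
  hp <- heldout_predictive(pf, mask)
  expect_equal(nrow(hp), 40)
  expect_equal(sum(hp$loglik), pf$loglik_heldout)
  expect_error(heldout_predictive(pf, heldout_mask(nrow(sim$trials), 0.1, seed = 3)),
               "mask")
  # per-trial probabilities are valid
  expect_true(all(exp(pf$loglik_per_trial) <= 1 & exp(pf$loglik_per_trial) > 0))
  expect_true(all(pf$ess_trace >= 1 & pf$ess_trace <= 300))

  # on unpredictable (fair-coin) choices, even a huge-noise model scores
  # held-out trials at chance on average
  coin <- quick_sim(pg_params("noise_only", sigma = 0, sigma_day = 0, w1_sd = 0),
                    seed = 11)
  flat <- pg_params("noise_only", sigma = 25, sigma_day = 25, w1_sd = 25)
  mask2 <- heldout_mask(nrow(coin$trials), 0.1, seed = 6)
  pf_flat <- particle_filter(coin$trials, flat, mask = mask2, n_particles = 2000,
                             seed = 5, store_paths = FALSE)
  expect_lt(abs(mean(exp(pf_flat$loglik_per_trial[mask2])) - 0.5), 0.06)
})

test_that("smoothed posterior covers the true latent trajectory", {
  params <- pg_params("noise_only", sigma = 0.1, sigma_day = 0.1, w1_sd = 0.5)
  cur <- make_curriculum(sessions = 3, trials_per_session = 100)
  covs <- vapply(1:5, function(k) {
    sim <- simulate_pg(params, cur, seed = 20 + k)
    pf <- suppressWarnings(smooth_posterior(
      particle_filter(sim$trials, params, n_particles = 2000, seed = k)
    ))
    mean(abs(sim$true_weights - pf$smooth_mean) <= 2 * pf$smooth_sd)
  }, numeric(1))
  # +/- 2 SD nominal coverage, averaged over replicate trajectories
  expect_gt(mean(covs), 0.90)
  expect_lt(mean(covs), 0.99)

  # smoothing leaves every likelihood quantity untouched, and smoothed means
  # track the truth better than the prior mean
  sim <- quick_sim(params, T_ = 300, seed = 13, sessions = 3)
  pf <- suppressWarnings(smooth_posterior(
    particle_filter(sim$trials, params, n_particles = 2000, seed = 7)
  ))
  pf0 <- particle_filter(sim$trials, params, n_particles = 2000, seed = 7)
  expect_identical(pf$loglik_total, pf0$loglik_total)
  expect_identical(pf$loglik_per_trial, pf0$loglik_per_trial)
  expect_lt(mean((pf$smooth_mean - sim$true_weights)^2),
            mean(sim$true_weights^2))
})

test_that("likelihood nesting across variants holds under common seeds", {
  sim <- quick_sim(pg_params("vector_pg", alpha = 0.08, beta = -0.1, sigma = 0.1),
                   seed = 15)
  # vector PG with tied entries equals scalar PG bit-for-bit
  pv <- pg_params("vector_pg", alpha = 0.05, beta = -0.2, Qdiag = 0.01,
                  sigma = 0.1, sigma_day = 0.15)
  ps <- pg_params("scalar_pg", alpha = 0.05, beta = -0.2, Qdiag = 0.01,
                  sigma = 0.1, sigma_day = 0.15)
  llv <- particle_filter(sim$trials, pv, n_particles = 200, seed = 3,
                         store_paths = FALSE)$loglik_total
  lls <- particle_filter(sim$trials, ps, n_particles = 200, seed = 3,
                         store_paths = FALSE)$loglik_total
  expect_identical(llv, lls)

  # dynamic rate with sigma_alpha = 0 and alpha0 = 1 matches vector PG within
  # particle Monte Carlo error (extra RNG draws change the stream, so compare
  # averages over seeds)
  pd <- pg_params("dynamic_rate", alpha = 0.05, beta = -0.2, Qdiag = 0.01,
                  sigma = 0.1, sigma_day = 0.15, alpha0 = 1, sigma_alpha = 0)
  ll_d <- vapply(1:12, function(s) {
    particle_filter(sim$trials, pd, n_particles = 400, seed = s,
                    store_paths = FALSE)$loglik_total
  }, numeric(1))
  ll_v <- vapply(1:12, function(s) {
    particle_filter(sim$trials, pv, n_particles = 400, seed = 100 + s,
                    store_paths = FALSE)$loglik_total
  }, numeric(1))
  se <- sqrt(var(ll_d) / 12 + var(ll_v) / 12)
  expect_lt(abs(mean(ll_d) - mean(ll_v)), 4 * se)
})

test_that("MLE machinery: transforms round-trip and reduced fits recover structure", {
  p <- pg_params("vector_pg", alpha = c(0.1, 0.2, 0.05, 0, 0.01), beta = -0.3,
                 Qdiag = 0.02, sigma = 0.1, sigma_day = 0.2)
  map <- pgrule:::make_theta_map(p, free = c("alpha", "beta", "sigma"),
                                 tie = "sigma")
  th <- pgrule:::theta_from_params(map)
  expect_equal(length(th), 5 + 5 + 1)
  p2 <- pgrule:::params_from_theta(map, th)
  expect_equal(p2$alpha, p$alpha, tolerance = 1e-7)
  expect_equal(p2$beta, p$beta)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-7)

  # free_idx restricts which components move
  map2 <- pgrule:::make_theta_map(p, free = "alpha", free_idx = list(alpha = c(2, 3)))
  expect_equal(map2$labels, c("alpha[2]", "alpha[3]"))
  p3 <- pgrule:::params_from_theta(map2, c(softplus_inv <- pgrule:::softplus_inv(0.5),
                                           pgrule:::softplus_inv(0.7)))
  expect_equal(p3$alpha, c(0.1, 0.5, 0.7, 0, 0.01), tolerance = 1e-7)

  # a very short noise-only fit runs end to end and warns about short data
  sim <- quick_sim(pg_params("noise_only", sigma = 0.15), T_ = 300, seed = 5,
                   sessions = 3)
  expect_warning(
    fit <- fit_mle(sim$trials, "noise_only", n_particles = 100, seed = 2,
                   tie = c("sigma", "sigma_day"), n_starts = 1, maxit = 25),
    "500 trials"
  )
  expect_s3_class(fit, "pg_fit")
  expect_true(is.finite(fit$loglik_full))
  expect_equal(fit$loglik_full, fit$loglik_train + fit$loglik_heldout)
  g <- glance(fit)
  expect_equal(g$n_trials, 300)
  expect_true(all(c("parameter", "term", "estimate") %in% names(tidy(fit))))

  # identical seeds and settings reproduce the fit exactly
  fit2 <- suppressWarnings(
    fit_mle(sim$trials, "noise_only", n_particles = 100, seed = 2,
            tie = c("sigma", "sigma_day"), n_starts = 1, maxit = 25)
  )
  expect_identical(fit$params_hat, fit2$params_hat)
  expect_identical(fit$loglik_full, fit2$loglik_full)
})

test_that("PMMH with zero proposal never moves; with adaptation it mixes", {
  target <- function(z) dnorm(z, 2, 1, log = TRUE)
  ch0 <- pmmh_sample(theta_init = c(z = 0.5), loglik_fn = target,
                     n_steps = 200, proposal_sd = 0, seed = 1)
  expect_equal(ch0$acceptance_rate, 1)
  expect_true(all(ch0$draws == 0.5))

  ch <- pmmh_sample(theta_init = c(z = 0), loglik_fn = target,
                    n_steps = 4000, proposal_sd = 0.5, seed = 2)
  expect_gt(ch$acceptance_rate, 0.05)
  expect_lt(ch$acceptance_rate, 0.9)
  expect_lt(abs(mean(ch$draws) - 2), 0.2)
  expect_s3_class(tidy(ch), "tbl_df")
})

test_that("posterior uncertainty of the noise scale shrinks with more data", {
  p <- pg_params("noise_only", sigma = 0.15, sigma_day = 0.15)
  sd_for <- function(T_, seed) {
    sim <- simulate_pg(p, make_curriculum(sessions = 4, trials_per_session = T_ / 4),
                       seed = seed)
    ch <- pmmh_sample(sim$trials, "noise_only", p, n_particles = 150,
                      n_steps = 400, seed = seed, free = c("sigma"),
                      tie = "sigma", proposal_sd = 0.15)
    ch$posterior_sd[["sigma"]]
  }
  expect_lt(sd_for(2000, 31), sd_for(200, 32))
})

test_that("model comparison tables log-likelihood differences against a baseline", {
  f <- function(ll) list(loglik_full = ll, mask = rep(FALSE, 4))
  tab <- compare_models(list(a = f(-100), b = f(-90), c = f(-110)), baseline = "a")
  expect_equal(tab$delta_loglik, c(0, 10, -10))
  expect_error(
    compare_models(list(a = f(-1), b = list(loglik_full = -2, mask = rep(TRUE, 4))),
                   baseline = "a"),
    "mask"
  )
})
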