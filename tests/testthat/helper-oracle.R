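# Independent oracle: dense-grid numerical integration of the marginal
# likelihood for a 1-D weight state-space model. Propagates the latent
# density on a grid through the learning-rule transition kernel and
# multiplies in the Bernoulli likelihoods; shares no code with the particle
# filter.
grid_marginal_loglik <- function(x, y, r, params, lo = -8, hi = 8, n_grid = 1200) {
  g <- seq(lo, hi, length.out = n_grid)
  dg <- g[2] - g[1]
  dens <- dnorm(g, params$w1_mean[1], params$w1_sd[1])
  ll <- 0
  T_ <- length(y)
  for (t in seq_len(T_)) {
    lik <- plogis(y[t] * g * x[t])
    joint <- dens * lik
    incr <- sum(joint) * dg
    ll <- ll + log(incr)
    dens <- joint / incr
    if (t < T_) {
      p_y <- plogis(y[t] * g * x[t])
      drift <- params$alpha[1] * (r[t] - params$beta[1]) * (1 - p_y) * y[t] * x[t] -
        params$Qdiag[1] * g
      mu <- g + drift
      K <- outer(g, mu, function(gn, m) dnorm(gn, m, params$sigma[1]))
      dens <- as.vector(K %*% dens) * dg
      dens <- dens / (sum(dens) * dg)
    }
  }
  ll
}

# small 1-D choice sequence generated from a static weight
toy_1d <- function(T_ = 8, seed = 2) {
  withr::with_seed(seed, {
    x <- matrix(runif(T_, 0.3, 1), ncol = 1)
    w <- 0.4
    y <- numeric(T_)
    r <- numeric(T_)
    for (t in 1:T_) {
      y[t] <- if (runif(1) < plogis(w * x[t])) 1 else -1
      r[t] <- if (y[t] == 1) 1 else 0
    }
    list(x = x, choice = y, reward = r, session = rep(1L, T_))
  })
}

# study conditions shared by the recovery suite and the acceptance script:
# weight noise keeps |w| in a behaviourally plausible range over training
study_sigma <- 0.05
study_sigma_day <- 0.2
study_w1_sd <- 0.5
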