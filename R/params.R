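#' Policy-gradient model parameters
#'
#' Bundles the full parameter set of a policy-gradient learning-rule variant.
#' The weight update is, per regressor (all products elementwise),
#' \deqn{w_{t+1} = w_t + \alpha (r_t - \beta)(1 - p(y_t | w_t, x_t))
#'   \,\mathrm{sign}(y_t)\, x_t - Q w_t + \epsilon_t}
#' with \eqn{\epsilon_t \sim N(0, \mathrm{diag}(\sigma_t^2))} and
#' \eqn{\sigma_t} equal to `sigma_day` on session-boundary transitions and
#' `sigma` within sessions.
#'
#' Variants: `"noise_only"` (alpha and Qdiag forced to zero — a pure random
#' walk on the weights, no learning model), `"scalar_pg"` (alpha, beta,
#' Qdiag, sigma, sigma_day shared across the M regressors), `"vector_pg"`
#' (all of them per-regressor), `"dynamic_rate"` (vector PG whose learning
#' signal is additionally gated by a latent scalar rate following a random
#' walk with start `alpha0` and innovation SD `sigma_alpha`), and
#' `"dynamic_baseline"` (vector PG with a latent per-regressor baseline
#' random walk of innovation SD `beta_sigma` started at `beta`).
#'
#' @param variant One of `"noise_only"`, `"scalar_pg"`, `"vector_pg"`,
#'   `"dynamic_rate"`, `"dynamic_baseline"`.
#' @param alpha Learning rate(s), length 1 or M, nonnegative.
#' @param beta Reward baseline(s), length 1 or M (any sign; negative values
#'   make incorrect trials push weights away from the taken choice).
#' @param Qdiag Weight-decay rate(s) (diagonal of Q), nonnegative.
#' @param sigma,sigma_day Within-session and session-boundary innovation SDs.
#' @param rstar Reward magnitude on correct trials (> 0).
#' @param w1_mean,w1_sd Mean and SD of the Gaussian prior on the initial
#'   weights.
#' @param alpha0,sigma_alpha Initial mean and random-walk SD of the latent
#'   dynamic learning rate (`dynamic_rate` only).
#' @param beta_sigma Random-walk SD of the latent dynamic baseline
#'   (`dynamic_baseline` only).
#' @param n_regressors Number of policy regressors M (default 5).
#' @return An object of class `pg_params`: a list of validated, length-M
#'   parameter vectors plus scalars.
#' @examples
#' pg_params("vector_pg", alpha = c(0.1, 0.05, 0.05, 0, 0), beta = -0.2)
#' @export
pg_params <- function(variant = c(
                        "vector_pg", "scalar_pg", "noise_only",
                        "dynamic_rate", "dynamic_baseline"
                      ),
                      alpha = 0.05, beta = 0, Qdiag = 0,
                      sigma = 0.1, sigma_day = 0.1,
                      rstar = 1, w1_mean = 0, w1_sd = 1,
                      alpha0 = 1, sigma_alpha = 0.05, beta_sigma = 0.02,
                      n_regressors = 5L) {
  variant <- match.arg(variant)
  M <- as.integer(n_regressors)
  expand <- function(v, nm) {
    if (length(v) == 1) v <- rep(v, M)
    if (length(v) != M) abort(paste0(nm, " must have length 1 or ", M))
    as.numeric(v)
  }
  p <- list(
    variant = variant,
    alpha = expand(alpha, "alpha"),
    beta = expand(beta, "beta"),
    Qdiag = expand(Qdiag, "Qdiag"),
    sigma = expand(sigma, "sigma"),
    sigma_day = expand(sigma_day, "sigma_day"),
    rstar = as.numeric(rstar),
    w1_mean = expand(w1_mean, "w1_mean"),
    w1_sd = expand(w1_sd, "w1_sd"),
    alpha0 = as.numeric(alpha0),
    sigma_alpha = as.numeric(sigma_alpha),
    beta_sigma = as.numeric(beta_sigma),
    n_regressors = M
  )
  if (variant == "noise_only") {
    p$alpha <- rep(0, M)
    p$Qdiag <- rep(0, M)
  }
  if (variant == "scalar_pg") {
    for (nm in c("alpha", "beta", "Qdiag", "sigma", "sigma_day")) {
      if (length(unique(p[[nm]])) != 1) {
        abort(paste0("scalar_pg requires a single shared value for ", nm))
      }
    }
  }
  for (nm in c("sigma", "sigma_day", "Qdiag", "w1_sd")) {
    if (any(p[[nm]] < 0)) abort(paste0(nm, " must be nonnegative"))
  }
  if (p$rstar <= 0) abort("rstar must be positive")
  if (p$sigma_alpha < 0 || p$beta_sigma < 0) abort("noise scales must be nonnegative")
  structure(p, class = "pg_params")
}

#' @export
print.pg_params <- function(x, ...) {
  cat("<pg_params> variant:", x$variant, " (M =", x$n_regressors, ")\n")
  m <- rbind(
    alpha = x$alpha, beta = x$beta, Qdiag = x$Qdiag,
    sigma = x$sigma, sigma_day = x$sigma_day
  )
  colnames(m) <- regressor_names[seq_len(x$n_regressors)]
  print(round(m, 4))
  cat("rstar:", x$rstar, " w1 ~ N(", x$w1_mean[1], ",", x$w1_sd[1], "^2)\n")
  if (x$variant == "dynamic_rate") {
    cat("latent rate: alpha0 =", x$alpha0, " sigma_alpha =", x$sigma_alpha, "\n")
  }
  if (x$variant == "dynamic_baseline") cat("latent baseline: beta_sigma =", x$beta_sigma, "\n")
  invisible(x)
}

#' Temporal-difference (TDRL) model parameters
#'
#' Parameters of the action-value alternative: the agent receives a noisy
#' percept \eqn{m_t \sim N(s_t, \sigma_m^2)} of the signed stimulus contrast
#' \eqn{s_t} (right minus left), chooses right when the percept exceeds the
#' value-determined criterion \eqn{\sigma_m \Phi^{-1}(V_L / (V_L + V_R))},
#' and updates the chosen action value with a belief-weighted reward
#' prediction error.
#'
#' @param sigma_m Percept noise SD in contrast units (> 0).
#' @param td_rate TD step size in `[0, 1]` multiplying the prediction error.
#' @param V_init Positive initial action values `c(V_L, V_R)`.
#' @param stochasticity Lapse probability mixing the threshold rule with an
#'   unbiased coin (our stand-in for decision stochasticity; default 0).
#' @param rstar Reward magnitude on correct trials.
#' @return An object of class `tdrl_params`.
#' @export
tdrl_params <- function(sigma_m = 0.3, td_rate = 1, V_init = c(1, 1),
                        stochasticity = 0, rstar = 1) {
  if (sigma_m <= 0) abort("sigma_m must be positive")
  if (td_rate < 0 || td_rate > 1) abort("td_rate must lie in [0, 1]")
  if (length(V_init) != 2 || any(V_init <= 0)) abort("V_init must be two positive values")
  if (stochasticity < 0 || stochasticity > 1) abort("stochasticity must lie in [0, 1]")
  structure(
    list(
      sigma_m = as.numeric(sigma_m), td_rate = as.numeric(td_rate),
      V_init = as.numeric(V_init), stochasticity = as.numeric(stochasticity),
      rstar = as.numeric(rstar)
    ),
    class = "tdrl_params"
  )
}

#' @export
print.tdrl_params <- function(x, ...) {
  cat(
    "<tdrl_params> sigma_m:", x$sigma_m, " td_rate:", x$td_rate,
    " V_init: (", x$V_init[1], ",", x$V_init[2], ") lapse:", x$stochasticity, "\n"
  )
  invisible(x)
}

#' Serialize parameter sets to YAML-style config text
#'
#' @param params A `pg_params` or `tdrl_params` object.
#' @param path File path to write to.
#' @return `read_params()` reconstructs the parameter object.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  x$.class <- class(params)[1]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "tdrl_params")) {
    do.call(tdrl_params, x[c("sigma_m", "td_rate", "V_init", "stochasticity", "rstar")])
  } else {
    x$n_regressors <- x$n_regressors %||% length(x$alpha)
    do.call(pg_params, x)
  }
}
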