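#' Bernoulli GLM policy
#'
#' The behavioural policy maps a regressor row to a choice probability with
#' the logistic link: `policy_prob()` returns
#' \eqn{p(y = R \mid w, x) = 1 / (1 + e^{-w^\top x})}; the probability of a
#' left choice is its complement. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]` before any logs.
#'
#' @param w Numeric weight vector (length M).
#' @param x Numeric regressor row (length M) or a T-by-M matrix, in which
#'   case a vector of per-row probabilities is returned.
#' @return Probability (or vector of probabilities) of choosing right.
#' @examples
#' policy_prob(c(0, 0, 0, 0, 0), c(1, 0, 0.5, 0, 0)) # 0.5
#' @export
policy_prob <- function(w, x) {
  if (is.matrix(x)) {
    clamp_prob(plogis(drop(x %*% w)))
  } else {
    clamp_prob(plogis(sum(w * x)))
  }
}

#' @rdname policy_prob
#' @description `choice_loglik()` returns the Bernoulli log probability
#'   `log p(y | w, x)` of a realized choice `y` coded L = -1 / R = +1.
#' @param y Choice(s) in `{-1, +1}`.
#' @export
choice_loglik <- function(w, x, y) {
  stopifnot(all(y %in% c(-1, 1)))
  z <- if (is.matrix(x)) drop(x %*% w) else sum(w * x)
  log(clamp_prob(plogis(y * z)))
}

#' Trial reward
#'
#' Returns `rstar` when the choice matches the correct side and 0 otherwise.
#' The correct side is read off the nonzero stimulus column of the regressor
#' row; on zero-contrast trials it must be supplied explicitly.
#'
#' @param x Regressor row with named or positional `stim_left`/`stim_right`
#'   entries (positions 2 and 3).
#' @param y Choice in `{-1, +1}`.
#' @param rstar Reward magnitude (> 0).
#' @param correct_side Optional explicit label `"L"`/`"R"` (required when
#'   both contrasts are zero).
#' @return Scalar reward.
#' @export
trial_reward <- function(x, y, rstar = 1, correct_side = NULL) {
  if (is.null(correct_side)) {
    cl <- x[2]
    cr <- x[3]
    if (cl == 0 && cr == 0) {
      abort("zero-contrast trial: supply correct_side explicitly")
    }
    correct <- if (cr > 0) 1 else -1
  } else {
    correct <- side_to_num(correct_side)
  }
  if (y == correct) rstar else 0
}

#' Expected return of the policy on one trial
#'
#' The one-step expected return
#' \eqn{J(w; x) = \sum_y p(y \mid w, x) R(x, y) = r^* p(\mathrm{correct})}.
#' With no discounting over a single-step decision this coincides with the
#' state value.
#'
#' @inheritParams trial_reward
#' @param w Weight vector.
#' @return Scalar expected reward.
#' @export
expected_return <- function(w, x, rstar = 1, correct_side = NULL) {
  pR <- policy_prob(w, x)
  rR <- trial_reward(x, 1, rstar, correct_side)
  rL <- trial_reward(x, -1, rstar, correct_side)
  pR * rR + (1 - pR) * rL
}

#' REINFORCE weight update with reward baseline
#'
#' The Monte Carlo policy-gradient (REINFORCE) estimate of
#' \eqn{\partial J / \partial w} from a single realized trial,
#' \deqn{\Delta = (r - \beta) \odot (1 - p(y \mid w, x))\,
#'   \mathrm{sign}(y)\, x,}
#' with the scalar reward broadcast against a per-regressor baseline
#' \eqn{\beta} (all products elementwise). Subtracting any baseline leaves
#' the expected update unchanged — it is a variance-reduction device — but
#' changes trial-by-trial dynamics: with \eqn{\beta < 0} incorrect trials
#' (r = 0) produce a positive multiple of the score, reinforcing the
#' erroneous choice.
#'
#' @param w,x Weight vector and regressor row (length M).
#' @param y Realized choice in `{-1, +1}` (so `sign(y) = y`).
#' @param r Realized scalar reward.
#' @param beta Baseline, length 1 or M.
#' @return Length-M weight increment.
#' @examples
#' reinforce_update(rep(0, 5), c(1, 0, 0.5, 1, 1), y = 1, r = 1)
#' @export
reinforce_update <- function(w, x, y, r, beta = 0) {
  p <- exp(choice_loglik(w, x, y))
  (r - beta) * (1 - p) * y * x
}

#' Deterministic drift of the parametric policy-gradient rule
#'
#' The noiseless part of the weight update: the REINFORCE term scaled by the
#' per-regressor learning rates (and, for the dynamic-rate variant, a scalar
#' latent gate `rate_scale`), minus per-regressor weight decay:
#' \deqn{\Delta = \mathrm{rate} \cdot \alpha \odot (r - \beta)
#'   (1 - p(y \mid w, x))\, y\, x - Q \odot w.}
#'
#' @inheritParams reinforce_update
#' @param params A [pg_params()] object.
#' @param rate_scale Scalar gate on the learning term (1 for static
#'   variants; the latent \eqn{\alpha_t} for the dynamic-rate variant).
#' @param beta_t Optional length-M override of the baseline (latent dynamic
#'   baseline variant).
#' @return Length-M deterministic weight increment.
#' @export
vector_pg_drift <- function(w, x, y, r, params, rate_scale = 1, beta_t = NULL) {
  beta <- beta_t %||% params$beta
  rate_scale * params$alpha * reinforce_update(w, x, y, r, beta) - params$Qdiag * w
}

#' TDRL choice probability (percept-marginalized probit form)
#'
#' Marginalizing the threshold decision rule over the Gaussian percept
#' \eqn{m \sim N(s, \sigma_m^2)} gives the closed-form choice rule
#' \deqn{p(y = R \mid V, s) = \Phi\!\left(s / \sigma_m -
#'   \Phi^{-1}\!\big(V_L / (V_L + V_R)\big)\right),}
#' a probit-link GLM in \eqn{s / \sigma_m} — so the TDRL and
#' policy-gradient models are policy-equivalent and differ only in their
#' update rules.
#'
#' @param V Numeric pair `c(V_L, V_R)` of action values with positive sum.
#' @param s Signed stimulus, `contrast_right - contrast_left`.
#' @param sigma_m Percept noise SD.
#' @return Probability of choosing right.
#' @export
tdrl_choice_prob <- function(V, s, sigma_m) {
  if (sum(V) <= 0) abort("V_L + V_R must be positive")
  clamp_prob(pnorm(s / sigma_m - qnorm(clamp_prob(V[1] / (V[1] + V[2])))))
}

#' TDRL value update with belief-weighted prediction error
#'
#' Updates the chosen action's value with a belief-weighted reward
#' prediction error plus a percept-induced fluctuation:
#' \deqn{V_y \leftarrow V_y + \eta\,[\,r - V_y\, p_\mathrm{correct}(y \mid s)\,]
#'   + V_y\, \varphi_{\sigma_m}(s)\, \epsilon,}
#' where \eqn{p_\mathrm{correct}(y = R \mid s) = \Phi(s / (2\sigma_m))},
#' \eqn{\varphi_{\sigma_m}} is the \eqn{N(0, \sigma_m^2)} density and
#' \eqn{\epsilon} a standard normal draw. The unchosen value is unchanged.
#' The fluctuation grows with the current value and with lower-contrast
#' stimuli — unlike the trial-independent additive noise of the PG model.
#'
#' @param V Value pair `c(V_L, V_R)`.
#' @param y Choice in `{-1, +1}`.
#' @param s Signed stimulus.
#' @param r Realized reward.
#' @param params A [tdrl_params()] object (uses `sigma_m`, `td_rate`).
#' @param noise_draw Standard-normal draw \eqn{\epsilon} (0 gives the
#'   deterministic drift).
#' @return Updated value pair.
#' @export
tdrl_value_update <- function(V, y, s, r, params, noise_draw = 0) {
  i <- if (y > 0) 2 else 1
  pc <- pnorm(y * s / (2 * params$sigma_m))
  phi <- dnorm(s, 0, params$sigma_m)
  V[i] <- V[i] + params$td_rate * (r - V[i] * pc) + V[i] * phi * noise_draw
  V
}

#' @rdname tdrl_value_update
#' @description `tdrl_belief()` exposes the belief term
#'   \eqn{p_\mathrm{correct}(y \mid s)}.
#' @export
tdrl_belief <- function(y, s, sigma_m) pnorm(y * s / (2 * sigma_m))
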