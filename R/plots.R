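#' Plot posterior weight trajectories
#'
#' Ribbon (mean +/- 2 posterior SD) per latent state over trials.
#'
#' @param object A `particle_posterior`.
#' @param type `"filtered"` or `"smoothed"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.particle_posterior <- function(object, type = c("filtered", "smoothed"), ...) {
  type <- match.arg(type)
  df <- tidy.particle_posterior(object, type = type)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - 2 * .data$sd, ymax = .data$mean + 2 * .data$sd),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(
      x = "trial", y = "posterior weight",
      title = paste0(type, " posterior trajectories")
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated ground-truth weights
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_result <- function(object, ...) {
  W <- object$true_weights
  nm <- colnames(W) %||% paste0("w", seq_len(ncol(W)))
  colnames(W) <- nm
  df <- tibble::as_tibble(as.data.frame(W)) |>
    dplyr::mutate(trial = object$trials$trial) |>
    tidyr::pivot_longer(-"trial", names_to = "state", values_to = "weight")
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$weight, colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "true weight", colour = NULL,
                  title = "simulated latent trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a learning/noise decomposition
#'
#' Overlays the inferred trajectory with the deterministic learning rollout
#' started at the inferred initial weights, then shows the per-trial
#' residual norm.
#'
#' @param object A `pg_decomposition`.
#' @param rollout Optional T-by-M rollout matrix to overlay (e.g. from
#'   [learning_rollout()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pg_decomposition <- function(object, rollout = NULL, ...) {
  T_ <- nrow(object$inferred)
  nm <- colnames(object$inferred) %||% paste0("w", seq_len(ncol(object$inferred)))
  mk <- function(W, which) {
    colnames(W) <- nm
    tibble::as_tibble(as.data.frame(W)) |>
      dplyr::mutate(trial = seq_len(T_) - 1L, component = which) |>
      tidyr::pivot_longer(c(-"trial", -"component"),
                          names_to = "state", values_to = "weight")
  }
  df <- mk(object$inferred, "inferred")
  if (!is.null(rollout)) df <- dplyr::bind_rows(df, mk(as.matrix(rollout), "learning"))
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$weight,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(inferred = "grey30", learning = "firebrick")) +
    ggplot2::labs(x = "trial", y = "weight", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Empirical psychometric curve
#'
#' Fraction of rightward choices per signed-contrast level, with binomial
#' standard errors.
#'
#' @param trials A validated trial tibble.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(trials) {
  validate_trials(trials)
  df <- trials |>
    dplyr::mutate(s = .data$contrast_right - .data$contrast_left,
                  right = .data$choice == "R") |>
    dplyr::group_by(.data$s) |>
    dplyr::summarise(p = mean(.data$right), n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(se = sqrt(.data$p * (1 - .data$p) / .data$n))
  ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$p)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$p - .data$se,
                                          ymax = .data$p + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "signed contrast (R - L)", y = "P(choose R)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
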