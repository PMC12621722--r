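#' Trial tables
#'
#' A trial table is a tibble with one row per trial of a two-alternative
#' forced-choice task and columns `session` (integer, non-decreasing),
#' `trial` (0-based global index), `contrast_left` and `contrast_right`
#' (fractions in `[0, 1]`; at most one nonzero per trial), `correct_side` and
#' `choice` (labels `"L"`/`"R"`), and `reward` (`rstar` on correct trials,
#' 0 otherwise).
#'
#' @param trials A data frame with the seven trial-table columns.
#' @param rstar Reward magnitude delivered on correct trials. When `NULL`
#'   (default) it is taken as the largest reward present (1 if all rewards
#'   are 0).
#' @return `validate_trials()` returns its input (as a tibble) invisibly
#'   usable in a pipe; it throws an informative error naming the first
#'   offending row otherwise.
#' @examples
#' tt <- tibble::tibble(
#'   session = 1L, trial = 0:1, contrast_left = c(1, 0),
#'   contrast_right = c(0, 0.5), correct_side = c("L", "R"),
#'   choice = c("L", "L"), reward = c(1, 0)
#' )
#' validate_trials(tt)
#' @export
validate_trials <- function(trials, rstar = NULL) {
  cols <- c(
    "session", "trial", "contrast_left", "contrast_right",
    "correct_side", "choice", "reward"
  )
  missing <- setdiff(cols, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) abort("trial table is empty")

  bad_side <- which(!(trials$choice %in% side_levels))
  if (length(bad_side) > 0) {
    abort(paste0("row ", bad_side[1], ": choice must be 'L' or 'R', got '", trials$choice[bad_side[1]], "'"))
  }
  bad_side <- which(!(trials$correct_side %in% side_levels))
  if (length(bad_side) > 0) {
    abort(paste0("row ", bad_side[1], ": correct_side must be 'L' or 'R'"))
  }
  cl <- trials$contrast_left
  cr <- trials$contrast_right
  bad_c <- which(cl < 0 | cl > 1 | cr < 0 | cr > 1)
  if (length(bad_c) > 0) abort(paste0("row ", bad_c[1], ": contrasts must lie in [0, 1]"))
  both <- which(cl > 0 & cr > 0)
  if (length(both) > 0) {
    abort(paste0("row ", both[1], ": at most one of contrast_left/contrast_right may be nonzero"))
  }
  if (is.unsorted(trials$session)) {
    abort("session must be non-decreasing in trial order")
  }
  if (is.null(rstar)) rstar <- max(trials$reward, 1)
  correct <- trials$choice == trials$correct_side
  expected <- ifelse(correct, rstar, 0)
  bad_r <- which(abs(trials$reward - expected) > 1e-9)
  if (length(bad_r) > 0) {
    abort(paste0(
      "row ", bad_r[1], ": reward ", trials$reward[bad_r[1]],
      " inconsistent with choice/correct_side (expected ", expected[bad_r[1]], ")"
    ))
  }
  invisible(trials)
}

#' Read and write trial tables
#'
#' Trial tables are stored as comma-delimited UTF-8 text with the header
#' `session,trial,contrast_left,contrast_right,correct_side,choice,reward`.
#' `read_trials()` validates all trial-table invariants on read and errors
#' with the offending row; `write_trials()` writes a table that
#' `read_trials()` round-trips exactly.
#'
#' @param path Path to a delimited text file.
#' @return `read_trials()` returns a validated trial tibble.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      session = readr::col_integer(),
      trial = readr::col_integer(),
      contrast_left = readr::col_double(),
      contrast_right = readr::col_double(),
      correct_side = readr::col_character(),
      choice = readr::col_character(),
      reward = readr::col_double()
    ),
    progress = FALSE
  )
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @param trials A trial tibble (see [validate_trials()]).
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Build the policy regressor matrix
#'
#' Expands a trial table into the five task covariates entering the Bernoulli
#' GLM policy: a constant bias, left and right stimulus contrast (0 when the
#' stimulus is absent on that side), the previous choice and the previous
#' correct side, both coded L = -1 / R = +1 and reset to 0 on the first trial
#' of every session.
#'
#' @param trials A validated trial tibble.
#' @param contrast_transform Optional monotone function applied to the raw
#'   contrast columns (identity by default; contrasts enter untransformed).
#' @return A tibble with `nrow(trials)` rows and columns `bias`, `stim_left`,
#'   `stim_right`, `prev_choice`, `prev_correct_side`.
#' @examples
#' tt <- simulate_pg(pg_params("noise_only"), make_curriculum(sessions = 2,
#'   trials_per_session = 5), seed = 1)$trials
#' build_regressors(tt)
#' @export
build_regressors <- function(trials, contrast_transform = identity) {
  validate_trials(trials)
  y <- side_to_num(trials$choice)
  s <- side_to_num(trials$correct_side)
  first_of_session <- c(TRUE, diff(trials$session) != 0)
  prev_choice <- dplyr::lag(y, default = 0)
  prev_side <- dplyr::lag(s, default = 0)
  prev_choice[first_of_session] <- 0
  prev_side[first_of_session] <- 0
  tibble::tibble(
    bias = 1,
    stim_left = contrast_transform(trials$contrast_left),
    stim_right = contrast_transform(trials$contrast_right),
    prev_choice = prev_choice,
    prev_correct_side = prev_side
  )
}

regressor_names <- c("bias", "stim_left", "stim_right", "prev_choice", "prev_correct_side")

as_regressor_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(as.data.frame(x))
}

#' Held-out trial mask
#'
#' Draws a uniformly random subset of trials (without replacement) to be
#' treated as unobserved by the training objective, the cross-validation
#' device used when fitting single trajectories. Exactly
#' `round(fraction * n_trials)` trials are masked.
#'
#' @param n_trials Number of trials `T`.
#' @param fraction Fraction of trials to hold out, in `[0, 1)`; default 0.1.
#' @param seed Integer seed; the same `(n_trials, fraction, seed)` always
#'   yields the same mask.
#' @return A logical vector of length `n_trials`, `TRUE` for held-out trials,
#'   with attributes `fraction` and `seed`.
#' @export
heldout_mask <- function(n_trials, fraction = 0.1, seed = 1L) {
  if (fraction < 0 || fraction >= 1) abort("fraction must lie in [0, 1)")
  k <- round(fraction * n_trials)
  mask <- rep(FALSE, n_trials)
  if (k > 0) {
    idx <- withr::with_seed(seed, sample.int(n_trials, k))
    mask[idx] <- TRUE
  }
  structure(mask, fraction = fraction, seed = seed)
}

#' Warp per-animal trial series onto a common grid
#'
#' Each animal's trial axis is linearly rescaled to `[0, 1]` and the series
#' linearly interpolated onto a shared grid, so that series of different
#' lengths can be averaged pointwise across animals (e.g. learning-rate
#' trends or cumulative accuracy over training).
#'
#' @param series A data frame with columns `animal`, `trial` and `value`, or
#'   a list of numeric vectors (one per animal).
#' @param grid_size Number of grid points (default 100).
#' @return A tibble with columns `animal`, `frac` (position in `[0, 1]`) and
#'   `value`.
#' @export
trial_warp <- function(series, grid_size = 100) {
  if (is.data.frame(series)) {
    series <- split(series$value[order(series$animal, series$trial)],
                    series$animal[order(series$animal, series$trial)])
  }
  if (is.numeric(series)) series <- list(`1` = series)
  if (is.null(names(series))) names(series) <- seq_along(series)
  grid <- seq(0, 1, length.out = grid_size)
  purrr::imap_dfr(series, function(v, nm) {
    v <- as.numeric(v)
    if (length(v) < 2) abort("cannot warp a series of length < 2")
    x <- seq(0, 1, length.out = length(v))
    tibble::tibble(animal = nm, frac = grid, value = approx(x, v, xout = grid)$y)
  })
}

#' @rdname trial_warp
#' @description `warp_average()` warps and then averages pointwise across
#'   animals, returning the cohort mean and standard error per grid point.
#' @export
warp_average <- function(series, grid_size = 100) {
  trial_warp(series, grid_size) |>
    dplyr::group_by(.data$frac) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
}
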