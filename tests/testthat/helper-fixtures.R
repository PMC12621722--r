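# Shared fixtures: small trial tables built in code.

toy_trials <- function() {
  tibble::tibble(
    session = c(1L, 1L, 2L),
    trial = 0:2,
    contrast_left = c(1, 0, 0),
    contrast_right = c(0, 0, 0.5),
    correct_side = c("L", "L", "R"),
    choice = c("R", "L", "R"),
    reward = c(0, 1, 1)
  )
}

# 5-trial table whose regressor matrix is computed by hand in tests
hand_trials <- function() {
  tibble::tibble(
    session = c(1L, 1L, 1L, 2L, 2L),
    trial = 0:4,
    contrast_left = c(0.25, 0, 0, 1, 0),
    contrast_right = c(0, 0.5, 0, 0, 0.0625),
    correct_side = c("L", "R", "L", "L", "R"),
    choice = c("R", "R", "L", "L", "L"),
    reward = c(0, 1, 1, 1, 0)
  )
}

quick_curriculum <- function(sessions = 4, trials_per_session = 100, ...) {
  make_curriculum(sessions = sessions, trials_per_session = trials_per_session, ...)
}

# deterministic uniform-curriculum simulation used by several tests
quick_sim <- function(params, T_ = 400, seed = 1, sessions = 4) {
  simulate_pg(params, quick_curriculum(sessions, T_ / sessions), seed = seed)
}
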