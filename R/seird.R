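#' Parameters of the age-structured SEIRD model
#'
#' @param beta intrinsic infectivity (dimensionless multiplier on daily
#'   contacts); use [calibrate_beta()] to hit a target R0.
#' @param gamma_E E-to-I rate /day (inverse incubation period).
#' @param gamma_I I-exit rate /day (inverse disease duration).
#' @param m vector of age-specific mortality probabilities in \[0, 1\];
#'   deaths do not feed back into transmission. Defaults to
#'   [default_mortality()], a smooth age-increasing placeholder documented
#'   as user-replaceable.
#' @param mixing a `mixing_set`; its dimension must match `m`.
#' @export
seird_params <- function(beta, gamma_E = 1 / 7, gamma_I = 1 / 14, m = NULL,
                         mixing) {
  stopifnot(inherits(mixing, "mixing_set"), beta > 0, gamma_E > 0, gamma_I > 0)
  if (is.null(m)) m <- default_mortality(mixing$n_groups)
  if (length(m) != mixing$n_groups)
    stop("mortality vector length must match the number of age groups")
  if (any(m < 0 | m > 1)) stop("mortality probabilities must lie in [0, 1]")
  structure(list(beta = beta, gamma_E = gamma_E, gamma_I = gamma_I,
                 m = m, mixing = mixing),
            class = "seird_params")
}

#' Placeholder age-profile of infection mortality
#'
#' Logistic-in-age probabilities rising from ~1e-4 in the youngest band to
#' ~8% in the oldest; a stand-in profile so the package is self-contained.
#' Replace with externally sourced rates for any substantive mortality work
#' (mortality does not affect transmission in this model).
#' @param n_groups number of age bands.
#' @export
default_mortality <- function(n_groups = 18) {
  x <- seq(0, 1, length.out = n_groups)
  0.08 * stats::plogis(10 * (x - 0.8)) + 1e-4
}

#' Age-structured SEIRD model handle
#'
#' Per age group i:
#' \deqn{\dot S_i = -\beta S_i \sum_j C_{ij} I_j/N_j,\quad
#'       \dot E_i = \beta S_i \sum_j C_{ij} I_j/N_j - \gamma_E E_i,}
#' \deqn{\dot I_i = \gamma_E E_i - \gamma_I I_i,\quad
#'       \dot R_i = (1-m_i)\gamma_I I_i,\quad \dot D_i = m_i\gamma_I I_i,}
#' with C the total mixing matrix. The intervention target
#' `"matrix_scenario"` replaces the in-window mixing set by
#' `scenario_mixing()` of the scenario stored on the handle; target
#' `"global"` scales the total matrix by alpha.
#'
#' @param params a [seird_params()].
#' @param seeds initially exposed individuals: either a total count spread
#'   proportionally to group sizes (default 100) or a vector per group.
#' @param scenario optional scenario name used when running with target
#'   `"matrix_scenario"` (see [scenario_mixing()]).
#' @param uniform_factor factor for the `"uniform_scaling"` scenario.
#' @return an `epi_model` handle (counts scale = total population).
#' @export
seird_model <- function(params, seeds = 100, scenario = NULL,
                        uniform_factor = NULL) {
  stopifnot(inherits(params, "seird_params"))
  mix <- params$mixing
  n <- mix$n_groups
  Npop <- mix$populations
  N <- sum(Npop)
  if (length(seeds) == 1) seeds <- seeds * Npop / N
  if (length(seeds) != n) stop("seeds must be scalar or one per age group")
  y0 <- c(S = Npop - seeds, E = seeds, I = rep(0, n), R = rep(0, n),
          D = rep(0, n))
  iS <- 1:n; iE <- n + 1:n; iI <- 2 * n + 1:n; iR <- 3 * n + 1:n
  iD <- 4 * n + 1:n
  make_rhs <- function(C) {
    force(C)
    function(t, y) {
      S <- y[iS]; E <- y[iE]; I <- y[iI]
      foi <- params$beta * S * as.numeric(C %*% (I / Npop))
      c(-foi, foi - params$gamma_E * E,
        params$gamma_E * E - params$gamma_I * I,
        (1 - params$m) * params$gamma_I * I,
        params$m * params$gamma_I * I)
    }
  }
  C0 <- mixing_total(mix)
  rhs_factory <- function(alpha = 1, target = "global") {
    if (identical(target, "matrix_scenario") && alpha != 1) {
      if (is.null(scenario))
        stop("model has no scenario set; pass `scenario` to seird_model()")
      mix2 <- scenario_mixing(mix, scenario, uniform_factor = uniform_factor,
                              beta = params$beta, gamma_I = params$gamma_I)
      make_rhs(mixing_total(mix2))
    } else {
      make_rhs(C0 * alpha)
    }
  }
  new_epi_model(
    name = "age_seird", N = N, y0 = y0, rhs_factory = rhs_factory,
    cum_inc = function(y) N - sum(y[iS]),
    prev = function(y) sum(y[iI]),
    susceptible = function(y) sum(y[iS]),
    recovered = function(y) sum(y[iR]) + sum(y[iD]),
    targets = c("global", "matrix_scenario"),
    rtol = 1e-10, atol = 1e-6,
    extra = list(params = params, n_groups = n, Npop = Npop,
                 idx = list(S = iS, E = iE, I = iI, R = iR, D = iD)))
}

#' In-intervention mixing set for a named scenario
#'
#' * `school_closure`: school component zeroed.
#' * `school_closure_social_distancing`: school zeroed and the contacts at
#'   other locations between school-going individuals (first four age
#'   groups, both endpoints) halved.
#' * `work_distancing`: work component halved.
#' * `uniform_scaling`: total matrix scaled by `uniform_factor`; when the
#'   factor is `NULL` it is matched to `reference_scenario`'s R0 via
#'   [matched_uniform_scaling()] (requires `beta` and `gamma_I`).
#'
#' A function `mixing_set -> mixing_set` may be passed instead of a name for
#' custom structural interventions (e.g. zeroing a single component).
#'
#' @param mset baseline `mixing_set`.
#' @param scenario scenario name or modifier function.
#' @param uniform_factor optional scalar for `uniform_scaling`.
#' @param reference_scenario scenario whose R0 the uniform scaling matches.
#' @param beta,gamma_I epidemic parameters used for the R0 matching.
#' @export
scenario_mixing <- function(mset, scenario, uniform_factor = NULL,
                            reference_scenario = NULL, beta = NULL,
                            gamma_I = NULL) {
  if (is.function(scenario)) return(scenario(mset))
  switch(scenario,
    school_closure = scale_component(mset, "school", 0),
    school_closure_social_distancing =
      scale_block(scale_component(mset, "school", 0), "other", 1:4, 1:4, 0.5),
    work_distancing = scale_component(mset, "work", 0.5),
    uniform_scaling = {
      if (is.null(uniform_factor)) {
        if (is.null(reference_scenario) || is.null(beta) || is.null(gamma_I))
          stop("uniform_scaling needs `uniform_factor` or a ",
               "`reference_scenario` plus beta and gamma_I")
        uniform_factor <- matched_uniform_scaling(
          mset, scenario_mixing(mset, reference_scenario), beta, gamma_I)
      }
      scale_component(mset, "all", uniform_factor)
    },
    stop("unknown scenario: ", scenario))
}

#' Run an intervention scenario of the age-structured model
#'
#' Free dynamics outside the window; within `window = c(start, start +
#' duration)` the mixing set is replaced according to `scenario` (switching
#' is discontinuous, matching an instantaneous lockdown). For
#' `uniform_scaling` the factor defaults to the R0-matched scaling of
#' `reference_scenario`.
#'
#' @inheritParams seird_model
#' @param scenario one of `school_closure`,
#'   `school_closure_social_distancing`, `work_distancing`,
#'   `uniform_scaling`.
#' @param window `c(start_day, duration_days)`; default `c(260, 150)`.
#' @param times output grid; default daily out to day 700.
#' @param reference_scenario for `uniform_scaling` without a factor.
#' @return trajectory data.frame (see [integrate_model()]); per-age states
#'   in `attr(,"states")`.
#' @export
run_scenario <- function(params, scenario, window = c(260, 150),
                         seeds = 100, uniform_factor = NULL,
                         reference_scenario = NULL, times = seq(0, 700)) {
  if (identical(scenario, "uniform_scaling") && is.null(uniform_factor)) {
    if (is.null(reference_scenario))
      stop("uniform_scaling needs `uniform_factor` or `reference_scenario`")
    uniform_factor <- matched_uniform_scaling(
      params$mixing, scenario_mixing(params$mixing, reference_scenario),
      params$beta, params$gamma_I)
  }
  model <- seird_model(params, seeds = seeds, scenario = scenario,
                       uniform_factor = uniform_factor)
  integrate_model(model, times, alpha = 0,  # alpha ignored by matrix_scenario
                  window = c(window[1], window[1] + window[2]),
                  target = "matrix_scenario")
}

#' Tidy per-age trajectory of a SEIRD run
#'
#' @param model the `seird_model` handle (or a run's model).
#' @param traj result of [integrate_model()]/[run_scenario()].
#' @return data.frame: time, group, S, E, I, R, D.
#' @export
age_trajectory <- function(model, traj) {
  out <- attr(traj, "states")
  idx <- model$idx
  do.call(rbind, lapply(seq_len(model$n_groups), function(g) {
    data.frame(time = out[, 1], group = g,
               S = out[, 1 + idx$S[g]], E = out[, 1 + idx$E[g]],
               I = out[, 1 + idx$I[g]], R = out[, 1 + idx$R[g]],
               D = out[, 1 + idx$D[g]])
  }))
}
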