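#' Parameters of the household edge-based compartmental model
#'
#' The population is partitioned into households of size 4 with complete
#' within-household mixing at per-pair rate `beta_h`; in addition every
#' individual has community contacts drawn from `community_degree`
#' (configuration model), transmitting at per-edge rate `beta_c`; recovery
#' at rate `gamma`. A warning is issued when `beta_h/beta_c` falls outside
#' the band \[3, 5\] used for the shipped configurations.
#'
#' @param beta_h within-household per-pair transmission rate /day.
#' @param beta_c community per-edge transmission rate /day.
#' @param gamma recovery rate /day.
#' @param community_degree a `degree_dist` for the community degree.
#' @param rho initially infected fraction (uniform at random).
#' @export
ebcm_params <- function(beta_h, beta_c, gamma, community_degree, rho = 1e-4) {
  stopifnot(beta_h >= 0, beta_c >= 0, gamma > 0, rho >= 0, rho < 1,
            inherits(community_degree, "degree_dist"))
  if (beta_c > 0) {
    r <- beta_h / beta_c
    if (r < 3 || r > 5)
      warning(sprintf(
        "beta_h/beta_c = %.2f lies outside the household-to-community band [3, 5]", r))
  }
  structure(list(beta_h = beta_h, beta_c = beta_c, gamma = gamma,
                 community_degree = community_degree, rho = rho,
                 household_size = 4L),
            class = "ebcm_params")
}

# Household cavity states (s, i): s susceptible and i infected among the 3
# housemates of a test individual (the remainder recovered). Enumerated once.
ebcm_cavity_states <- local({
  g <- expand.grid(s = 0:3, i = 0:3)
  g[g$s + g$i <= 3, ]
})

#' Edge-based compartmental model with households and community links
#'
#' Cavity construction: theta is the probability that a random community
#' partner has not yet transmitted to the test individual, and the household
#' block f(s, i) is the joint probability that the test individual's three
#' housemates are in state (s susceptible, i infected) *and* none of them
#' has yet transmitted to the test individual. Housemates are infected from
#' the community at the pgf-averaged hazard
#' \eqn{\lambda = \beta_c \Phi_I \psi'(\theta)/\psi(\theta)} and from within
#' the household at rate `beta_h` per infective. The test individual is then
#' susceptible with probability \eqn{S = (1-\rho)\,\psi(\theta)\,h},
#' \eqn{h = \sum f}. With no community contacts the construction is exact
#' for isolated 4-person households.
#'
#' Intervention targets: `"global"` scales both rates by alpha,
#' `"community_only"` scales `beta_c` alone.
#'
#' @param params an [ebcm_params()].
#' @param N nominal population size (fractions are integrated; N only sets
#'   the counts scale of the handle).
#' @return an `epi_model` handle.
#' @export
ebcm_model <- function(params, N = 6.65e6) {
  stopifnot(inherits(params, "ebcm_params"))
  dist <- params$community_degree
  rho <- params$rho
  cs <- ebcm_cavity_states
  nf <- nrow(cs)
  fmap <- matrix(NA_integer_, 4, 4)  # 1-based [s+1, i+1] -> index
  for (r in seq_len(nf)) fmap[cs$s[r] + 1, cs$i[r] + 1] <- r
  psi1_at_1 <- dd_pgf(dist, 1, 1)
  # state: theta, PhiI, f(nf), I, R
  f0 <- numeric(nf)
  for (j in 0:3) f0[fmap[3 - j + 1, j + 1]] <- choose(3, j) * rho^j * (1 - rho)^(3 - j)
  y0 <- c(theta = 1, PhiI = rho, f = f0, I = rho, R = 0)
  i_th <- 1L; i_phi <- 2L; i_f <- 2L + seq_len(nf); i_I <- 3L + nf; i_R <- 4L + nf

  rhs_factory <- function(alpha = 1, target = "global") {
    ac <- alpha
    ah <- if (identical(target, "community_only")) 1 else alpha
    bc <- ac * params$beta_c
    bh <- ah * params$beta_h
    g <- params$gamma
    function(t, y) {
      th <- min(max(y[i_th], 1e-12), 1)
      PhiI <- y[i_phi]
      f <- y[i_f]
      psi0 <- dd_pgf(dist, th, 0)
      psi1 <- dd_pgf(dist, th, 1)
      psi2 <- dd_pgf(dist, th, 2)
      lam <- if (psi0 > 0) bc * PhiI * psi1 / psi0 else 0
      df <- numeric(nf); dh_trans <- 0
      for (r in seq_len(nf)) {
        s <- cs$s[r]; i <- cs$i[r]; fr <- f[r]
        out_rate <- lam * s + bh * s * i + g * i + bh * i
        df[r] <- df[r] - out_rate * fr
        dh_trans <- dh_trans + bh * i * fr
        if (s >= 1)  # infection of a housemate
          df[fmap[s, i + 2]] <- df[fmap[s, i + 2]] + (lam + bh * i) * s * fr
        if (i >= 1)  # recovery of a housemate
          df[fmap[s + 1, i]] <- df[fmap[s + 1, i]] + g * i * fr
      }
      h <- sum(f)
      dtheta <- -bc * PhiI
      ddh <- -dh_trans  # = sum(df): survival lost to transmission to the test node
      dS <- (1 - rho) * (psi1 * dtheta * h + psi0 * ddh)
      dPhiS <- if (psi1_at_1 > 0)
        (1 - rho) * (ddh * psi1 + h * psi2 * dtheta) / psi1_at_1 else 0
      dPhiI <- -dPhiS - (bc + g) * PhiI
      dI <- -dS - g * y[i_I]
      dR <- g * y[i_I]
      out <- numeric(length(y))
      out[i_th] <- dtheta; out[i_phi] <- dPhiI; out[i_f] <- df
      out[i_I] <- dI; out[i_R] <- dR
      out
    }
  }
  S_of <- function(y) (1 - rho) * dd_pgf(dist, min(max(y[i_th], 0), 1), 0) *
    sum(y[i_f])
  new_epi_model(
    name = "ebcm", N = N, y0 = y0, rhs_factory = rhs_factory,
    cum_inc = function(y) N * (1 - S_of(y)),
    prev = function(y) N * y[i_I],
    susceptible = function(y) N * S_of(y),
    recovered = function(y) N * y[i_R],
    targets = c("global", "community_only"),
    rtol = 1e-9, atol = 1e-11,
    extra = list(params = params, theta_of = function(y) y[i_th],
                 idx = list(theta = i_th, PhiI = i_phi, f = i_f,
                            I = i_I, R = i_R)))
}

#' Integrate the EBCM under a schedule of interventions
#'
#' @param params an [ebcm_params()].
#' @param times output time grid (days).
#' @param schedule `NULL` for a free epidemic, or a list/data.frame with
#'   fields `start_day`, `duration_days`, `alpha`,
#'   `target` (`"global"` or `"community_only"`). Windows must not overlap.
#' @param N counts scale.
#' @return data.frame time, susceptible, prevalence, recovered, cumulative,
#'   theta (fractions of N in counts columns); full states in
#'   `attr(,"states")`.
#' @export
integrate_ebcm <- function(params, times, schedule = NULL, N = 6.65e6) {
  model <- ebcm_model(params, N = N)
  if (is.null(schedule)) {
    df <- integrate_model(model, times)
  } else {
    sched <- as.data.frame(schedule)
    if (nrow(sched) != 1) {
      o <- order(sched$start_day)
      sched <- sched[o, ]
      ends <- sched$start_day + sched$duration_days
      if (any(sched$start_day[-1] < ends[-nrow(sched)]))
        stop("intervention windows overlap")
      if (nrow(sched) > 1)
        stop("only a single one-shot window is supported")
    }
    df <- integrate_model(model, times, alpha = sched$alpha[1],
                          window = c(sched$start_day[1],
                                     sched$start_day[1] + sched$duration_days[1]),
                          target = sched$target[1])
  }
  st <- attr(df, "states")
  df$theta <- st[, 1 + model$idx$theta]
  if (any(diff(df$theta) > 1e-8))
    warning("theta increased along the trajectory beyond tolerance")
  df
}

#' Final epidemic size of the EBCM
#'
#' Integrates until prevalence has fallen below `tol` with a negative
#' derivative, extending the horizon as needed, and returns the recovered
#' fraction.
#'
#' @inheritParams integrate_ebcm
#' @param tol prevalence threshold (fraction).
#' @param t_max hard horizon; non-convergence raises an error carrying the
#'   partial result.
#' @export
ebcm_final_size <- function(params, schedule = NULL, tol = 1e-10,
                            t_max = 20000) {
  t_end <- if (is.null(schedule)) 1000 else
    max(1000, max(schedule$start_day + schedule$duration_days) + 500)
  repeat {
    df <- integrate_ebcm(params, seq(0, t_end, by = 1), schedule, N = 1)
    n <- nrow(df)
    decreasing <- df$prevalence[n] < df$prevalence[n - 1]
    if (df$prevalence[n] < tol && decreasing) return(df$recovered[n])
    if (t_end >= t_max) {
      cond <- simpleError(sprintf(
        "EBCM final size did not converge by t = %g (prevalence %.3g)",
        t_end, df$prevalence[n]))
      cond$partial <- df$recovered[n]
      stop(cond)
    }
    t_end <- min(2 * t_end, t_max)
  }
}
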