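#' Basic reproduction number of the heterogeneous mean-field model
#'
#' \eqn{R_0 = \tau \langle k^2\rangle / (\gamma \langle k\rangle)} with
#' moments from the truncated pmf.
#' @param tau per-link transmission rate /day.
#' @param gamma recovery rate /day.
#' @param dist a `degree_dist`.
#' @export
r0_hmf <- function(tau, gamma, dist) {
  mo <- dd_moments(dist)
  if (mo$mean <= 0) stop("degenerate degree distribution: mean degree 0")
  tau * mo$second_moment / (gamma * mo$mean)
}

#' Basic reproduction number of the heterogeneous pairwise model
#'
#' \eqn{R_0 = \frac{\tau}{\tau+\gamma}\,
#'            \frac{\langle k^2\rangle - \langle k\rangle}{\langle k\rangle}}.
#' @inheritParams r0_hmf
#' @export
r0_pairwise <- function(tau, gamma, dist) {
  mo <- dd_moments(dist)
  if (mo$mean <= 0) stop("degenerate degree distribution: mean degree 0")
  (tau / (tau + gamma)) * (mo$second_moment - mo$mean) / mo$mean
}

#' Expected generation sizes of the within-household epidemic
#'
#' Household of size 4, one primary case (generation 0) and 3 susceptibles.
#' Generations follow a Reed-Frost chain binomial: each infective of the
#' current generation independently fails to infect each remaining
#' susceptible with escape probability
#' \eqn{\varphi_I = \gamma/(\beta_h+\gamma)}, so a susceptible exposed to i
#' infectives is infected with probability \eqn{1-\varphi_I^{\,i}}. Returns
#' the exact expected numbers infected in generations 0..3, by enumeration
#' over the full outcome tree.
#'
#' @param beta_h within-household per-pair transmission rate /day.
#' @param gamma recovery rate /day.
#' @param household_size must be 4 (the only case treated).
#' @return numeric `c(mu0, mu1, mu2, mu3)`.
#' @export
household_generation_sizes <- function(beta_h, gamma, household_size = 4) {
  if (household_size != 4)
    stop("only households of size 4 are supported")
  stopifnot(beta_h >= 0, gamma > 0)
  phi_I <- gamma / (beta_h + gamma)
  mu <- numeric(4)
  # walk(s, i, g, prob): i infectives of generation g among s susceptibles
  walk <- function(s, i, g, prob) {
    mu[g + 1] <<- mu[g + 1] + prob * i
    if (g == 3 || s == 0 || i == 0) return(invisible())
    p_inf <- 1 - phi_I^i
    for (j in 0:s) {
      pj <- stats::dbinom(j, s, p_inf)
      if (pj > 0 && j > 0) walk(s - j, j, g + 1, prob * pj)
    }
  }
  walk(3, 1, 0, 1)
  mu
}

#' Household next-generation matrix and its R0
#'
#' Assembles the 4x4 next-generation matrix of the household EBCM,
#' \deqn{A = \begin{pmatrix} \tilde\mu_c\mu_0 & 1 & 0 & 0\\
#'   \mu_c\mu_1 & 0 & 1 & 0\\ \mu_c\mu_2 & 0 & 0 & 1\\
#'   \mu_c\mu_3 & 0 & 0 & 0\end{pmatrix},}
#' with \eqn{\tilde\mu_c = \frac{\beta_c}{\beta_c+\gamma}E[\tilde D]} and
#' \eqn{\mu_c = \frac{\beta_c}{\beta_c+\gamma}E[D]}, where \eqn{E[\tilde D]
#' = \langle k^2\rangle/\langle k\rangle - 1} is the mean excess degree (the
#' left-over edges of a node reached by following a random edge) and
#' \eqn{E[D] = \langle k\rangle}. R0 is the Perron root.
#'
#' @param beta_c community per-edge transmission rate /day.
#' @inheritParams household_generation_sizes
#' @param dist community `degree_dist`.
#' @return object of class `household_ngm`: `mu_tilde_c`, `mu_c`, `mu`,
#'   `matrix`, `r0`.
#' @export
r0_household <- function(beta_c, beta_h, gamma, dist) {
  mo <- dd_moments(dist)
  ED_tilde <- mo$second_moment / mo$mean - 1
  ED <- mo$mean
  mu_tilde_c <- beta_c / (beta_c + gamma) * ED_tilde
  mu_c <- beta_c / (beta_c + gamma) * ED
  mu <- household_generation_sizes(beta_h, gamma)
  A <- matrix(c(mu_tilde_c * mu[1], 1, 0, 0,
                mu_c * mu[2], 0, 1, 0,
                mu_c * mu[3], 0, 0, 1,
                mu_c * mu[4], 0, 0, 0),
              nrow = 4, byrow = TRUE)
  structure(list(mu_tilde_c = mu_tilde_c, mu_c = mu_c, mu = mu,
                 matrix = A, r0 = leading_eigenvalue(A)),
            class = "household_ngm")
}

#' @export
print.household_ngm <- function(x, ...) {
  cat(sprintf("household NGM: mu = (%s); mu_c = %.4f, mu~_c = %.4f; R0 = %.4f\n",
              paste(sprintf("%.4f", x$mu), collapse = ", "),
              x$mu_c, x$mu_tilde_c, x$r0))
  invisible(x)
}

# Perron root of a nonnegative matrix: the eigenvalue of maximum modulus is
# real and nonnegative; returned as a real scalar.
leading_eigenvalue <- function(A) {
  if (any(A < 0)) stop("matrix must be nonnegative")
  ev <- eigen(A, only.values = TRUE)$values
  max(Re(ev), 0)
}

#' Basic reproduction number of the age-structured SEIRD model
#'
#' Leading eigenvalue of \eqn{(\beta/\gamma_I) K} with
#' \eqn{K_{ij} = (N_i/N_j) C_{ij}} and C the total mixing matrix; the
#' \eqn{N_i/N_j} weighting comes from linearising about the fully
#' susceptible state.
#'
#' @param beta intrinsic infectivity.
#' @param gamma_I I-exit rate /day.
#' @param mixing a `mixing_set`.
#' @export
age_r0 <- function(beta, gamma_I, mixing) {
  stopifnot(inherits(mixing, "mixing_set"))
  C <- mixing_total(mixing)
  if (all(C == 0)) stop("empty mixing matrix")
  N <- mixing$populations
  K <- outer(N, 1 / N) * C
  (beta / gamma_I) * leading_eigenvalue(K)
}

#' Uniform scaling factor matching a structural scenario's R0
#'
#' The scalar s such that s * baseline has the same R0 (during the
#' intervention) as the structurally modified matrix set; exact by linearity
#' of R0 in a global scaling: `s = age_r0(modified)/age_r0(baseline)`.
#'
#' @param baseline,modified `mixing_set` objects.
#' @inheritParams age_r0
#' @export
matched_uniform_scaling <- function(baseline, modified, beta, gamma_I) {
  r0_base <- age_r0(beta, gamma_I, baseline)
  if (r0_base <= 0) stop("baseline R0 is zero")
  age_r0(beta, gamma_I, modified) / r0_base
}

#' Calibrate the SEIRD infectivity to a target R0
#'
#' Exact by linearity of [age_r0()] in beta.
#' @inheritParams age_r0
#' @param target_R0 desired basic reproduction number (> 0).
#' @export
calibrate_beta <- function(mixing, gamma_I, target_R0) {
  stopifnot(target_R0 > 0)
  r0_unit <- age_r0(1, gamma_I, mixing)
  if (r0_unit <= 0) stop("degenerate mixing matrix: R0 at unit beta is 0")
  target_R0 / r0_unit
}
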