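#' Degree-based (heterogeneous) mean-field SIR model
#'
#' ODEs for the expected numbers of susceptible, infected and recovered
#' individuals per degree class k:
#' \deqn{\dot S_k = -\tau k S_k \pi_I,\quad
#'       \dot I_k = \tau k S_k \pi_I - \gamma I_k,\quad
#'       \dot R_k = \gamma I_k,}
#' with the degree-weighted prevalence
#' \eqn{\pi_I = \sum_\ell \ell I_\ell / \sum_\ell \ell N_\ell}. The
#' denominator is the initial stub count, fixed along the trajectory
#' (annealed-network closure at the level of individuals; class sizes are
#' constant in SIR).
#'
#' @param dist a [degree_dist()] giving the degree classes and their masses.
#' @param tau per-link transmission rate per day.
#' @param gamma recovery rate per day.
#' @param N population size; class sizes are `N * pmf`.
#' @param seeds initial infected counts per degree class: either a vector of
#'   length `length(dist$degrees)` or the default
#'   `seed_class(dist, N, k = 10, count = 5)` placing 5 infected in the
#'   class nearest degree 10.
#' @param rtol,atol integrator tolerances (atol in individuals; defaults to
#'   `1e-10 * N`).
#' @return an `epi_model` handle; intervention target `"global"` scales tau.
#' @export
hmf_model <- function(dist, tau, gamma, N = 6.65e6,
                      seeds = seed_class(dist, N, k = 10, count = 5),
                      rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(dist, "degree_dist"), tau > 0, gamma > 0)
  k <- dist$degrees
  M <- length(k)
  Nk <- N * dist$pmf
  if (length(seeds) != M) stop("seeds must have one entry per degree class")
  if (any(seeds < 0) || any(seeds > Nk))
    stop("seed counts must lie in [0, N_k] per class")
  stub_den <- sum(k * Nk)  # fixed at the initial stub count
  y0 <- c(S = Nk - seeds, I = seeds, R = rep(0, M))
  iS <- 1:M; iI <- M + 1:M; iR <- 2 * M + 1:M
  rhs_factory <- function(alpha = 1, target = "global") {
    tau_eff <- alpha * tau
    function(t, y) {
      S <- y[iS]; I <- y[iI]
      pi_I <- sum(k * I) / stub_den
      inf <- tau_eff * k * S * pi_I
      rec <- gamma * I
      c(-inf, inf - rec, rec)
    }
  }
  new_epi_model(
    name = "hmf", N = N, y0 = y0, rhs_factory = rhs_factory,
    rtol = rtol, atol = atol,
    cum_inc = function(y) N - sum(y[iS]),
    prev = function(y) sum(y[iI]),
    susceptible = function(y) sum(y[iS]),
    recovered = function(y) sum(y[iR]),
    extra = list(dist = dist, tau = tau, gamma = gamma, Nk = Nk,
                 idx = list(S = iS, I = iI, R = iR)))
}

#' Seed vector with a fixed count in the class nearest a given degree
#' @param dist a `degree_dist`.
#' @param N population size (bounds check only).
#' @param k degree to seed at (nearest class used).
#' @param count number of initially infected individuals.
#' @export
seed_class <- function(dist, N, k = 10, count = 5) {
  s <- numeric(length(dist$degrees))
  s[which.min(abs(dist$degrees - k))] <- count
  s
}

#' Integrate the heterogeneous mean-field model
#'
#' @param model an `epi_model` from [hmf_model()] (any handle works).
#' @param times increasing output time grid (days).
#' @param alpha transmission multiplier applied on `[window[1], window[2]]`;
#'   `NULL` window means a free epidemic.
#' @param window lockdown window `c(start, end)` or `NULL`.
#' @param target intervention target passed to the model's `rhs_factory`.
#' @return data.frame: time, susceptible, prevalence, recovered, cumulative,
#'   with the full state matrix in `attr(, "states")`.
#' @export
integrate_model <- function(model, times, alpha = 1, window = NULL,
                            target = model$targets[1]) {
  stopifnot(inherits(model, "epi_model"), !is.unsorted(times))
  free <- model$rhs_factory(1, target)
  if (is.null(window) || alpha == 1) {
    fun <- function(t, y, parms) list(free(t, y))
    out <- deSolve::ode(model$y0, times, fun, NULL, method = model$method,
                        rtol = model$rtol, atol = model$atol)
  } else {
    ctrl <- model$rhs_factory(alpha, target)
    segs <- list(c(times[1], window[1]), c(window[1], window[2]),
                 c(window[2], times[length(times)]))
    fns <- list(free, ctrl, free)
    y <- model$y0; pieces <- list()
    for (i in 1:3) {
      tt <- unique(c(segs[[i]][1], times[times > segs[[i]][1] & times < segs[[i]][2]],
                     segs[[i]][2]))
      if (length(tt) < 2 || segs[[i]][2] <= segs[[i]][1]) next
      fi <- fns[[i]]
      fun <- function(t, y, parms) list(fi(t, y))
      out <- deSolve::ode(y, tt, fun, NULL, method = model$method,
                          rtol = model$rtol, atol = model$atol)
      pieces[[length(pieces) + 1]] <- out
      y <- out[nrow(out), -1]
    }
    out <- do.call(rbind, lapply(seq_along(pieces), function(i)
      if (i == 1) pieces[[i]] else pieces[[i]][-1, , drop = FALSE]))
  }
  df <- measure_frame(model, out)
  attr(df, "states") <- out
  df
}

#' @rdname integrate_model
#' @param ... passed to [integrate_model()].
#' @export
integrate_hmf <- function(model, times, ...) integrate_model(model, times, ...)

#' Per-degree-class trajectory in tidy long format
#'
#' @param model the `epi_model` the trajectory came from (HMF or pairwise).
#' @param traj result of [integrate_model()].
#' @return data.frame with columns time, degree_class, S, I, R.
#' @export
class_trajectory <- function(model, traj) {
  out <- attr(traj, "states")
  if (is.null(out)) stop("trajectory has no stored states")
  k <- model$dist$degrees
  idx <- model$idx
  do.call(rbind, lapply(seq_along(k), function(j) {
    data.frame(time = out[, 1], degree_class = k[j],
               S = out[, 1 + idx$S[j]], I = out[, 1 + idx$I[j]],
               R = out[, 1 + idx$R[j]])
  }))
}
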