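# Independent oracles used across test files. Each reimplements the target
# quantity by a different route than the package (closed forms, exact
# enumeration, brute-force summation, Monte Carlo) so agreement is evidence,
# not tautology.

# Final-size fixed point of the classical SIR model with initial
# susceptible fraction s0: log(s_inf/s0) = -(R0) (1 - s_inf).
sir_final_size <- function(R0, s0 = 1 - 1e-9) {
  g <- function(z) 1 - s0 * exp(-R0 * z) - z
  stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
}

# Independent homogeneous (single degree class) pairwise SIR: the classical
# five-equation system, written from scratch.
hom_pairwise_traj <- function(k, tau, gamma, N, I0, times) {
  den <- k * N
  y0 <- c(S = N - I0, I = I0,
          SI = k * (N - I0) * k * I0 / den,
          SS = (k * (N - I0))^2 / den,
          II = (k * I0)^2 / den)
  f <- function(t, y, p) {
    S <- y[1]; I <- y[2]; SI <- y[3]; SS <- y[4]; II <- y[5]
    kk <- (k - 1) / k
    T1 <- kk * SS * SI / S
    T2 <- kk * SI * SI / S
    list(c(-tau * SI, tau * SI - gamma * I,
           -gamma * SI + tau * (T1 - T2 - SI),
           -2 * tau * T1,
           -2 * gamma * II + tau * (2 * T2 + 2 * SI)))
  }
  deSolve::ode(y0, times, f, NULL, rtol = 1e-10, atol = 1e-8)
}

# Brute-force RHS of the heterogeneous pairwise system: every triple summed
# explicitly through close_triple(), O(M^3); used to pin the C++ kernel.
brute_pairwise_rhs <- function(st, k, tau, gamma, phi, normalized = FALSE,
                               stub_total = NULL) {
  M <- length(k)
  S <- st$S; I <- st$I; SI <- st$SI; SS <- st$SS; II <- st$II
  ct <- function(AB, BC, CA, A, B, C, l, da, dc) {
    if (normalized)
      close_triple(AB, BC, CA, A, B, C, l, phi,
                   deg_a = da, deg_c = dc, stub_total = stub_total)
    else close_triple(AB, BC, CA, A, B, C, l, phi)
  }
  dSI <- matrix(0, M, M); dSS <- dSI; dII <- dSI
  for (K in 1:M) for (L in 1:M) {
    ssi <- 0; isi <- 0; iks <- 0; ksl <- 0
    for (A in 1:M) {
      ssi <- ssi + ct(SS[K, L], SI[L, A], SI[K, A], S[K], S[L], I[A], k[L], k[K], k[A])
      isi <- isi + ct(SI[K, A], SI[K, L], II[L, A], I[A], S[K], I[L], k[K], k[A], k[L])
      iks <- iks + ct(SI[K, A], SS[K, L], SI[L, A], I[A], S[K], S[L], k[K], k[A], k[L])
      ksl <- ksl + ct(SI[L, K], SI[L, A], II[K, A], I[K], S[L], I[A], k[L], k[K], k[A])
    }
    dSI[K, L] <- -gamma * SI[K, L] + tau * (ssi - isi - SI[K, L])
    dSS[K, L] <- -tau * (ssi + iks)
    dII[K, L] <- -2 * gamma * II[K, L] +
      tau * (isi + ksl + SI[K, L] + SI[L, K])
  }
  c(-tau * rowSums(SI), tau * rowSums(SI) - gamma * I, gamma * I,
    as.numeric(dSI), as.numeric(dSS), as.numeric(dII))
}

# Exact escape probability of a tagged member of a 4-person household SIR
# (continuous time, per-pair rate beta, recovery gamma), by first-step
# analysis on the jump chain over (susceptible, infected) counts among the
# 3 housemates.
household_escape_prob <- function(j_init, beta, gamma) {
  memo <- new.env(parent = emptyenv())
  esc <- function(s, i) {
    if (i == 0) return(1)
    key <- paste(s, i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- beta * s * i + beta * i + gamma * i
    p <- (gamma * i / tot) * esc(s, i - 1)
    if (s > 0) p <- p + (beta * s * i / tot) * esc(s - 1, i + 1)
    memo[[key]] <- p
    p
  }
  esc(3 - j_init, j_init)
}

# Expected final-size fraction of the 4-person household SIR with binomial
# seeding at fraction rho, via the exact escape probabilities.
household_final_size_exact <- function(beta, gamma, rho) {
  pesc <- sum(vapply(0:3, function(j)
    stats::dbinom(j, 3, rho) * household_escape_prob(j, beta, gamma),
    numeric(1)))
  1 - (1 - rho) * pesc
}

# Chain-binomial (Reed-Frost) Monte Carlo of the generation-based household
# epidemic: 1 primary + 3 susceptibles, escape probability phi_I per
# infective-susceptible pair per generation. Returns mean generation sizes
# and their standard errors over n_rep replicates.
chain_binomial_mc <- function(beta_h, gamma, n_rep = 1e6, seed = 1) {
  phi_I <- gamma / (beta_h + gamma)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    s <- rep(3L, n_rep); i <- rep(1L, n_rep)
    gens <- matrix(0, n_rep, 4)
    gens[, 1] <- 1
    for (g in 2:4) {
      p_inf <- 1 - phi_I^i
      newi <- stats::rbinom(n_rep, s, p_inf)
      s <- s - newi; i <- newi
      gens[, g] <- newi
    }
    list(mean = colMeans(gens),
         se = apply(gens, 2, stats::sd) / sqrt(n_rep))
  })
}

# Tiny mixing-set builder for matrix-algebra tests.
toy_mixing <- function(n = 4, seed = 3) {
  dihi:::with_preserved_seed(seed, {
    comps <- lapply(1:4, function(i) matrix(stats::runif(n * n, 0.2, 2), n))
    mixing_set(comps[[1]], comps[[2]], comps[[3]], comps[[4]],
               populations = stats::runif(n, 0.5, 2) * 1e5)
  })
}
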