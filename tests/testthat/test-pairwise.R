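test_that("close_triple reproduces its limiting forms", {
  # phi = 0: standard unclustered closure
  expect_equal(close_triple(4, 6, 99, 1, 3, 1, l = 5, phi = 0),
               (4 / 5) * 4 * 6 / 3)
  # degree-1 centre supports no triples
  expect_equal(close_triple(4, 6, 2, 1, 3, 1, l = 1, phi = 0.7), 0)
  # direct substitution, fully clustered printed form
  expect_equal(close_triple(1, 1, 1, 1, 1, 1, l = 2, phi = 1), 0.5)
  # normalised form reduces to the printed one when the correction is 1
  expect_equal(close_triple(2, 3, 5, 2, 4, 3, l = 3, phi = 0.4,
                            deg_a = 2, deg_c = 3, stub_total = 6),
               close_triple(2, 3, 5, 2, 4, 3, l = 3, phi = 0.4))
  # degenerate denominators contribute nothing
  expect_equal(close_triple(1, 1, 1, 0, 0, 0, l = 2, phi = 1), 0)
})

test_that("initial conditions satisfy pair symmetry and edge conservation", {
  d <- degree_dist(c(2, 5, 9), c(0.5, 0.3, 0.2))
  N <- 1e5
  # fully susceptible: all pairs SS with row sums k*N_k
  st0 <- pairwise_initial_conditions(d, N, c(0, 0, 0))
  expect_equal(rowSums(st0$SS), d$degrees * N * d$pmf, tolerance = 1e-9)
  expect_equal(st0$SS, t(st0$SS))
  expect_true(all(st0$SI == 0) && all(st0$II == 0))
  # seeded: SI mass proportional to k N_k on (k, seeded class) pairs
  seeds <- c(0, 0, 5)
  st <- pairwise_initial_conditions(d, N, seeds)
  den <- sum(d$degrees * N * d$pmf)
  expect_equal(st$SI[, 3], d$degrees * st$S * 9 * 5 / den, tolerance = 1e-9)
  expect_equal(st$SI[, 1], rep(0, 3))
  tot <- rowSums(st$SS) + rowSums(st$SI) + colSums(st$SI) + rowSums(st$II)
  expect_equal(tot, d$degrees * N * d$pmf, tolerance = 1e-8)
  expect_error(pairwise_initial_conditions(d, N, c(0, 0, N)), "exceed")
})

test_that("all-susceptible and all-I-zero states are equilibria of the rhs", {
  d <- degree_dist(c(3, 6), c(0.5, 0.5))
  m <- pairwise_model(d, 0.05, 0.1, phi = 0.3, N = 1e4,
                      seeds = c(0, 0))
  expect_equal(max(abs(pairwise_rhs(m))), 0)
})

test_that("C++ kernel matches the brute-force triple-sum oracle in both closure modes", {
  d <- degree_dist(c(3, 6, 10), c(0.3, 0.5, 0.2))
  N <- 1e5
  m0 <- pairwise_model(d, 0.04, 1 / 14, phi = 0, N = N,
                       seeds = list(k = 6, count = 50))
  tr <- integrate_model(m0, seq(0, 40, by = 5))
  y <- attr(tr, "states")[9, -1]
  st <- dihi:::unpack_pairwise_state(y, 3, FALSE)
  stub_total <- sum(d$degrees * N * d$pmf)
  for (phi in c(0, 0.4, 1)) for (cl in c("printed", "normalized")) {
    mp <- pairwise_model(d, 0.04, 1 / 14, phi = phi, N = N,
                         seeds = list(k = 6, count = 50), eps = 1e-300,
                         closure = cl)
    got <- pairwise_rhs(mp, y)
    want <- brute_pairwise_rhs(st, d$degrees, 0.04, 1 / 14, phi,
                               normalized = cl == "normalized",
                               stub_total = stub_total)
    expect_lt(max(abs(got - want) / (abs(want) + 1e-8)), 1e-12)
  }
})

test_that("phi=0 single-class system matches the independent homogeneous oracle", {
  N <- 1e5; I0 <- 10; k <- 6
  times <- seq(0, 300, by = 1)
  or <- hom_pairwise_traj(k, 0.04, 1 / 14, N, I0, times)
  m <- pairwise_model(delta_dist(k), 0.04, 1 / 14, phi = 0, N = N,
                      seeds = list(k = k, count = I0))
  tr <- integrate_model(m, times)
  expect_lt(max(abs(tr$prevalence - or[, "I"])) / N, 1e-6)
  expect_lt(max(abs(tr$susceptible - or[, "S"])) / N, 1e-6)
})

test_that("symmetry and per-class edge conservation persist along trajectories", {
  d <- named_degree_dist("normal-like")
  N <- 6.65e6
  m <- pairwise_model(d, 0.016, 1 / 14, phi = 0.5, N = N,
                      track_full_pairs = TRUE)
  tr <- integrate_model(m, seq(0, 500, by = 50))
  st <- attr(tr, "states")
  M <- length(m$dist$degrees)
  kNk <- m$dist$degrees * m$Nk
  for (i in c(2, 6, nrow(st))) {
    y <- st[i, -1]
    s <- dihi:::unpack_pairwise_state(y, M, TRUE)
    expect_lt(max(abs(s$SS - t(s$SS))) / max(abs(s$SS)), 1e-8)
    expect_lt(max(abs(s$II - t(s$II))) / max(abs(s$II) + 1e-12), 1e-8)
    tot <- dihi:::pairwise_edge_totals(m, y)
    expect_lt(max(abs(tot - kNk) / kNk), 1e-6)
    # singles conservation
    expect_lt(max(abs(s$S + s$I + s$R - m$Nk)) / N, 1e-8)
  }
})

test_that("clustering lowers and delays the epidemic peak at matched moments", {
  d <- negbin_for_moments(6, 12, shift = 1)
  N <- 6.65e6
  run <- function(phi) {
    m <- pairwise_model(d, 0.04, 1 / 14, phi = phi, N = N)
    tr <- integrate_model(m, seq(0, 700, by = 1))
    c(peak = max(tr$prevalence) / N,
      t_peak = tr$time[which.max(tr$prevalence)])
  }
  r0 <- run(0); r5 <- run(0.5)
  expect_lt(r5["peak"], r0["peak"])
  expect_gt(r5["t_peak"], r0["t_peak"])
})

test_that("results are insensitive to the regularisation scale over two decades", {
  d <- negbin_for_moments(6, 20, shift = 1)
  N <- 6.65e6
  # the scalar closure's regularisation vanishes as eps -> 0
  args <- list(AB = 3, BC = 5, CA = 2, A = 4, B = 6, C = 2, l = 4, phi = 0.3)
  exact <- do.call(close_triple, args)
  for (eps in c(1e-3, 1e-6, 1e-9))
    expect_equal(do.call(close_triple, c(args, eps = eps)), exact,
                 tolerance = eps)
  # time-shift-invariant outcomes agree across two decades of eps: the
  # completed epidemic's final size
  fs <- function(eps) {
    m <- pairwise_model(d, 0.04, 1 / 14, phi = 0.25, N = N, eps = eps)
    tail(integrate_model(m, seq(0, 700, by = 10))$cumulative, 1) / N
  }
  base <- fs(1e-9 * N)
  expect_equal(fs(1e-10 * N), base, tolerance = 1e-4)
  expect_equal(fs(1e-8 * N), base, tolerance = 1e-4)
})

test_that("HMF produces a larger epidemic than pairwise on the same network", {
  d <- named_degree_dist("normal-like")
  N <- 6.65e6
  times <- seq(0, 1200, by = 2)
  fs_h <- integrate_model(hmf_model(d, 0.016, 1 / 14, N = N), times)
  fs_p <- integrate_model(pairwise_model(d, 0.016, 1 / 14, phi = 0, N = N), times)
  expect_gt(fs_h$cumulative[nrow(fs_h)], fs_p$cumulative[nrow(fs_p)])
})

test_that("pair-level dump is consistent with the packed state", {
  d <- degree_dist(c(3, 6), c(0.5, 0.5))
  m <- pairwise_model(d, 0.05, 0.1, N = 1e4, seeds = c(0, 5))
  tr <- integrate_model(m, c(0, 10))
  pd <- pair_trajectory(m, tr)
  expect_setequal(unique(pd$type), c("SI", "SS", "II"))
  ss0 <- pd[pd$time == 0 & pd$type == "SS" & pd$k == 3 & pd$l == 3, "count"]
  expect_equal(ss0, dihi:::unpack_pairwise_state(m$y0, 2)$SS[1, 1],
               tolerance = 1e-12)
})
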