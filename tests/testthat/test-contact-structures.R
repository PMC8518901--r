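test_that("truncated negative binomial pmf normalises and matches closed-form moments", {
  cases <- list(list(n = 1, p = 0.5, shift = 0), list(n = 3.86, p = 0.31, shift = 1),
                list(n = 1.07, p = 0.107, shift = 1), list(n = 1, p = 0.99, shift = 9))
  for (cs in cases) {
    d <- negbin_pmf(cs$n, cs$p, shift = cs$shift)
    expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
    expect_true(all(d$pmf >= 0))
    expect_identical(min(d$degrees), as.numeric(cs$shift))
    mo <- dd_moments(d)
    mu <- cs$n * (1 - cs$p) / cs$p
    expect_equal(mo$mean, mu + cs$shift, tolerance = 1e-6)
    expect_equal(mo$variance, mu / cs$p, tolerance = 1e-6)
    expect_equal(mo$second_moment, mo$variance + mo$mean^2, tolerance = 1e-10)
    # truncation mass beyond the default support is below the quantile rule
    expect_lt(stats::pnbinom(d$support_max - cs$shift, cs$n, cs$p,
                             lower.tail = FALSE), 1e-9)
  }
})

test_that("delta-like configuration gives the near-degenerate distribution", {
  d <- negbin_pmf(1, 0.99, shift = 9, support_max = 30)
  expect_equal(d$pmf[1], 0.99, tolerance = 1e-9)
  expect_equal(dd_moments(d)$mean, 9.0101, tolerance = 1e-4)
})

test_that("geometric special case and shift property hold", {
  d <- negbin_pmf(1, 0.5, shift = 0, support_max = 80)
  expect_equal(d$pmf[1], 0.5, tolerance = 1e-10)
  expect_equal(dd_moments(d)$mean, 1, tolerance = 1e-10)
  m0 <- dd_moments(negbin_pmf(2.5, 0.4, shift = 0))
  m3 <- dd_moments(negbin_pmf(2.5, 0.4, shift = 3))
  expect_equal(m3$mean, m0$mean + 3, tolerance = 1e-9)
  expect_equal(m3$variance, m0$variance, tolerance = 1e-8)
})

test_that("degenerate distribution has exact moments", {
  expect_equal(dd_moments(delta_dist(10)),
               list(mean = 10, variance = 0, second_moment = 100))
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(negbin_pmf(0, 0.5), "dispersion")
  expect_error(negbin_pmf(1, 1.2), "probability")
  expect_error(negbin_pmf(1, 0.5, shift = 5, support_max = 5), "support_max")
  expect_error(negbin_for_moments(6, 4, shift = 1), "variance")
})

test_that("every named configuration row is loadable and nominally mean 10", {
  for (nm in c("delta-like", "normal-like", "scale-free-like")) {
    d <- named_degree_dist(nm)
    expect_s3_class(d, "degree_dist")
    expect_equal(attr(d, "tau"), 0.016)
    expect_equal(dd_moments(d)$mean, 10, tolerance = 0.11)
  }
  expect_error(named_degree_dist("nope"), "unknown")
})

test_that("negbin_for_moments round-trips the requested moments", {
  d <- negbin_for_moments(6, 55, shift = 1)
  mo <- dd_moments(d)
  expect_equal(mo$mean, 6, tolerance = 1e-6)
  expect_equal(mo$variance, 55, tolerance = 1e-4)
})

test_that("binning preserves mass and mean and converges in the second moment", {
  d <- prune_degree_dist(negbin_for_moments(6, 90, shift = 1))
  b1 <- bin_degree_dist(d, exact_max = 30, n_tail_bins = 18)
  b2 <- bin_degree_dist(d, exact_max = 40, n_tail_bins = 30)
  expect_equal(sum(b1$pmf), 1, tolerance = 1e-12)
  expect_equal(dd_moments(b1)$mean, dd_moments(d)$mean, tolerance = 1e-9)
  m2 <- dd_moments(d)$second_moment
  expect_equal(dd_moments(b1)$second_moment, m2, tolerance = 0.02 * m2)
  expect_lt(abs(dd_moments(b2)$second_moment - m2),
            abs(dd_moments(b1)$second_moment - m2) + 1e-9)
})

test_that("pgf evaluation matches direct summation and derivative limits", {
  d <- negbin_pmf(2, 0.4, shift = 1)
  x <- 0.7
  expect_equal(dd_pgf(d, x), sum(d$pmf * x^d$degrees), tolerance = 1e-12)
  expect_equal(dd_pgf(d, 1, deriv = 1), dd_moments(d)$mean, tolerance = 1e-10)
  h <- 1e-6
  expect_equal(dd_pgf(d, x, deriv = 1),
               (dd_pgf(d, x + h) - dd_pgf(d, x - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("component scaling operations are non-mutating and compose", {
  ms <- toy_mixing()
  ms2 <- scale_component(ms, "school", 0)
  expect_true(all(ms2$components$school == 0))
  expect_identical(ms2$components$work, ms$components$work)
  expect_gt(sum(ms$components$school), 0)  # original untouched
  expect_equal(scale_component(ms, "all", 1), ms)
  half_work <- scale_component(ms, "work", 0.5)
  expect_equal(half_work$components$work, ms$components$work * 0.5)
  expect_error(scale_component(ms, "gym", 2), "unknown component")
})

test_that("block scaling touches only the requested block and is linear", {
  ms <- toy_mixing()
  msb <- scale_block(ms, "other", 1:2, 1:2, 0.5)
  expect_equal(msb$components$other[1:2, 1:2],
               ms$components$other[1:2, 1:2] * 0.5)
  expect_equal(msb$components$other[3:4, ], ms$components$other[3:4, ])
  expect_equal(scale_block(ms, "other", 1:2, 1:2, 1), ms)
  expect_error(scale_block(ms, "other", 1:9, 1:2, 0.5), "out of range")
  # scaling a block then summing equals summing then scaling that region
  tot_direct <- mixing_total(msb)
  tot_manual <- mixing_total(ms)
  tot_manual[1:2, 1:2] <- tot_manual[1:2, 1:2] -
    0.5 * ms$components$other[1:2, 1:2]
  expect_equal(tot_direct, tot_manual, tolerance = 1e-12)
})

test_that("equalize uniformises populations, matches component sums, and is idempotent", {
  ms <- toy_mixing()
  eq <- equalize(ms)
  sums <- vapply(eq$components, sum, numeric(1))
  expect_lt(max(sums) - min(sums), 1e-10)
  expect_equal(sums[["other"]], sum(ms$components$other), tolerance = 1e-10)
  expect_equal(eq$populations, rep(sum(ms$populations) / 4, 4))
  expect_equal(equalize(eq), eq, tolerance = 1e-12)
  expect_equal(unname(component_shares(eq)), rep(0.25, 4), tolerance = 1e-10)
})

test_that("synthetic mixing components are deterministic, assortative and plateaued", {
  a <- synthetic_mixing_components(18, seed = 11)
  b <- synthetic_mixing_components(18, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, synthetic_mixing_components(18, seed = 12)))
  # >50% of school mass on the diagonal band for default strength
  band <- abs(outer(1:18, 1:18, `-`)) <= 1
  sch <- a$components$school
  expect_gt(sum(sch[band]) / sum(sch), 0.5)
  # work plateau approximately constant on its block
  wp <- a$components$work[6:13, 6:13]
  expect_lt(stats::sd(wp) / mean(wp), 0.2)
  expect_true(all(mixing_total(a) >= 0))
  # zero assortativity degrades the deterministic structure towards uniform
  u <- synthetic_mixing_components(6, seed = 5, assortativity_strength = 0)
  for (comp in u$components)
    expect_lt(stats::sd(comp) / mean(comp), 0.16)  # only the seeded noise left
})

test_that("mixing CSV round-trip preserves matrices and populations", {
  ms <- toy_mixing()
  td <- withr::local_tempdir()
  paths <- list()
  for (nm in names(ms$components)) {
    paths[[nm]] <- file.path(td, paste0(nm, ".csv"))
    write_mixing_component(ms$components[[nm]], paths[[nm]])
  }
  pop_path <- file.path(td, "pop.csv")
  utils::write.csv(data.frame(age_band = paste0("G", 1:4),
                              population = ms$populations),
                   pop_path, row.names = FALSE)
  back <- read_mixing_set(paths, pop_path)
  for (nm in names(ms$components))
    expect_equal(unname(back$components[[nm]]), unname(ms$components[[nm]]),
                 tolerance = 1e-12)
  expect_equal(back$populations, ms$populations, tolerance = 1e-12)
})
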