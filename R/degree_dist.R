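#' Shifted, truncated negative-binomial degree distribution
#'
#' Builds the finite degree distribution used throughout the package: a
#' negative binomial with dispersion `n` and success probability `p`,
#' shifted by an integer `shift` (so the minimum degree is `shift`) and
#' truncated at `support_max`, then renormalised over the retained support.
#' The unshifted pmf is \eqn{P_{n,p}(k) \propto \binom{k+n-1}{n-1} p^n (1-p)^k}.
#'
#' When `support_max` is omitted it is chosen as the smallest degree with
#' upper-tail mass below `tail_tol` (capped at 2000), so that the truncation
#' error is negligible relative to integrator tolerances.
#'
#' @param n dispersion parameter (> 0).
#' @param p success probability in (0, 1).
#' @param shift integer >= 0 added to every degree.
#' @param support_max largest retained degree; `NULL` for the quantile rule.
#' @param tail_tol upper-tail mass allowed beyond `support_max` under the
#'   default rule.
#' @return An object of class `degree_dist` with fields `degrees`, `pmf`,
#'   `base_n`, `base_p`, `shift`, `support_max`.
#' @examples
#' d <- negbin_pmf(1, 0.99, shift = 9)
#' dd_moments(d)$mean  # ~ 9.0101
#' @export
negbin_pmf <- function(n, p, shift = 0L, support_max = NULL, tail_tol = 1e-9) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n <= 0)
    stop("dispersion parameter `n` must be a positive number")
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("success probability `p` must lie strictly in (0, 1)")
  if (shift < 0 || shift != round(shift))
    stop("`shift` must be a non-negative integer")
  shift <- as.integer(shift)
  if (is.null(support_max)) {
    # smallest M with P(K > M - shift) < tail_tol, capped at 2000
    m <- stats::qnbinom(tail_tol, size = n, prob = p, lower.tail = FALSE)
    while (stats::pnbinom(m, size = n, prob = p, lower.tail = FALSE) >= tail_tol &&
           m + shift < 2000) m <- m + 1
    support_max <- min(shift + m, 2000L)
  }
  if (support_max <= shift)
    stop("`support_max` must exceed `shift`")
  ks <- shift:support_max
  pm <- stats::dnbinom(ks - shift, size = n, prob = p)
  pm <- pm / sum(pm)
  new_degree_dist(ks, pm, base_n = n, base_p = p, shift = shift)
}

new_degree_dist <- function(degrees, pmf, base_n = NA_real_, base_p = NA_real_,
                            shift = NA_integer_) {
  stopifnot(length(degrees) == length(pmf), all(pmf >= 0))
  structure(
    list(degrees = as.numeric(degrees), pmf = as.numeric(pmf / sum(pmf)),
         base_n = base_n, base_p = base_p, shift = shift,
         support_max = max(degrees)),
    class = "degree_dist")
}

#' Degree distribution from an arbitrary finite pmf
#'
#' @param degrees vector of degrees (need not be integer: binned classes use
#'   mass-weighted representative degrees).
#' @param pmf probabilities, renormalised internally.
#' @export
degree_dist <- function(degrees, pmf) new_degree_dist(degrees, pmf)

#' Degenerate (delta) degree distribution at a single degree
#' @param k the common degree.
#' @export
delta_dist <- function(k) new_degree_dist(k, 1)

#' Negative binomial parameters matching a target mean and variance
#'
#' Solves for (n, p) such that the shifted negative binomial has the
#' requested mean and variance: with mu = mean - shift, p = mu/variance and
#' n = mu p/(1 - p). Requires variance > mean - shift.
#'
#' @inheritParams negbin_pmf
#' @param mean,variance target moments of the shifted distribution.
#' @export
negbin_for_moments <- function(mean, variance, shift = 0L, support_max = NULL) {
  mu <- mean - shift
  if (mu <= 0) stop("mean must exceed shift")
  if (variance <= mu)
    stop("negative binomial requires variance > mean - shift (got variance = ",
         variance, ", mean - shift = ", mu, ")")
  p <- mu / variance
  n <- mu * p / (1 - p)
  negbin_pmf(n, p, shift = shift, support_max = support_max)
}

#' Moments of a degree distribution
#'
#' Mean, variance and second moment computed by direct summation over the
#' truncated pmf.
#'
#' @param dist a `degree_dist`.
#' @return list with `mean`, `variance`, `second_moment`.
#' @export
dd_moments <- function(dist) {
  stopifnot(inherits(dist, "degree_dist"))
  m1 <- sum(dist$degrees * dist$pmf)
  m2 <- sum(dist$degrees^2 * dist$pmf)
  list(mean = m1, variance = m2 - m1^2, second_moment = m2)
}

#' @export
print.degree_dist <- function(x, ...) {
  mo <- dd_moments(x)
  cat(sprintf(
    "degree distribution on [%g, %g] (%d classes); mean %.4f, variance %.4f\n",
    min(x$degrees), max(x$degrees), length(x$degrees), mo$mean, mo$variance))
  invisible(x)
}

#' Collapse a degree distribution into fewer classes
#'
#' Keeps low degrees exact and pools the tail into geometrically spaced bins,
#' each represented by its mass-weighted mean degree. Preserves total mass
#' and the mean exactly; the second moment converges quickly in the number
#' of bins. Used to bound the O(M^2) pair system of the heterogeneous
#' pairwise model.
#'
#' @param dist a `degree_dist`.
#' @param exact_max largest degree kept as its own class.
#' @param n_tail_bins number of geometric bins covering the tail.
#' @export
bin_degree_dist <- function(dist, exact_max = 30, n_tail_bins = 18) {
  kd <- dist$degrees; pm <- dist$pmf
  lo <- kd <= exact_max
  degrees <- kd[lo]; mass <- pm[lo]
  if (any(!lo)) {
    tk <- kd[!lo]; tp <- pm[!lo]
    edges <- unique(round(exp(seq(log(exact_max), log(max(tk) + 1),
                                  length.out = n_tail_bins + 1))))
    idx <- cut(tk, breaks = edges, include.lowest = TRUE, right = TRUE)
    for (lev in levels(idx)) {
      sel <- idx == lev
      if (!any(sel) || sum(tp[sel]) <= 0) next
      w <- tp[sel]
      degrees <- c(degrees, sum(tk[sel] * w) / sum(w))
      mass <- c(mass, sum(w))
    }
  }
  keep <- mass > 0
  new_degree_dist(degrees[keep], mass[keep])
}

#' Drop classes with negligible mass
#'
#' Classes with pmf mass below `tol` are removed and the pmf renormalised;
#' used before building per-degree-pair state so the pair system stays
#' tractable for long-tailed distributions.
#' @param dist a `degree_dist`.
#' @param tol mass threshold.
#' @export
prune_degree_dist <- function(dist, tol = 1e-9) {
  keep <- dist$pmf > tol
  new_degree_dist(dist$degrees[keep], dist$pmf[keep])
}

#' Probability generating function of a degree distribution
#'
#' Returns psi(x) = sum_k p_k x^k and its first two derivatives, evaluated by
#' direct summation over the truncated support.
#' @param dist a `degree_dist`.
#' @param x evaluation point (scalar or vector).
#' @param deriv 0, 1 or 2.
#' @export
dd_pgf <- function(dist, x, deriv = 0) {
  k <- dist$degrees; p <- dist$pmf
  vapply(x, function(xx) {
    switch(as.character(deriv),
      "0" = sum(p * xx^k),
      "1" = sum(p * k * xx^pmax(k - 1, 0) * (k >= 1)),
      "2" = sum(p * k * (k - 1) * xx^pmax(k - 2, 0) * (k >= 2)),
      stop("deriv must be 0, 1 or 2"))
  }, numeric(1))
}

#' Named degree distributions of increasing variance
#'
#' Loads the three canonical contact scenarios (delta-like, normal-like,
#' scale-free-like) from the packaged YAML config. All three share a nominal
#' mean degree of 10 and per-link transmission rate tau = 0.016; the shift is
#' 9 for the delta-like distribution and 1 otherwise.
#'
#' @param name one of `"delta-like"`, `"normal-like"`, `"scale-free-like"`.
#' @param path optional path to a YAML file with the same schema
#'   (list of blocks with keys name, n, p, shift, and optionally tau).
#' @return a `degree_dist`; the row's transmission rate is attached as
#'   attribute `"tau"`.
#' @export
named_degree_dist <- function(name, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "degree_distributions.yaml", package = "dihi")
  cfg <- yaml::read_yaml(path)
  nm <- vapply(cfg, function(b) b$name, character(1))
  i <- match(tolower(name), tolower(nm))
  if (is.na(i)) stop("unknown degree distribution name: ", name,
                     " (available: ", paste(nm, collapse = ", "), ")")
  b <- cfg[[i]]
  # YAML 1.1 parses an unquoted key `n` as a boolean; accept both spellings
  nn <- if (!is.null(b$n)) b$n else b[["FALSE"]]
  d <- negbin_pmf(nn, b$p, shift = b$shift)
  attr(d, "tau") <- if (!is.null(b$tau)) b$tau else NA_real_
  d
}
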