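#' Clustered triple closure
#'
#' Approximates the expected number of triples \eqn{[A_k B_\ell C_m]} from
#' pair and single counts:
#' \deqn{[A_kB_\ell C_m] \approx \frac{\ell-1}{\ell}\left[(1-\varphi)
#'   \frac{[A_kB_\ell][B_\ell C_m]}{[B_\ell]} + \varphi
#'   \frac{[A_kB_\ell][B_\ell C_m][C_mA_k]}{[A_k][B_\ell][C_m]}\right],}
#' where \eqn{\varphi} is the global clustering coefficient and \eqn{\ell}
#' the degree of the centre node. Divisions are regularised as
#' `x/D -> x*D/(D^2+eps^2)` so degenerate (empty) compartments contribute
#' nothing; the regularisation vanishes as `eps -> 0`.
#'
#' When `deg_a`, `deg_c` and `stub_total` are all supplied the clustered
#' term is instead the proportional-mixing-normalised (dimensionally
#' consistent) form used by default in [pairwise_model()]: the base closure
#' `AB*BC/B` is multiplied by
#' \eqn{\varphi\,[CA]\,\langle k\rangle N/(d_A d_C [A][C])}, i.e. the ratio
#' of the closing pair to its expectation under proportional mixing.
#'
#' @param AB,BC,CA pair counts (`CA` only enters the clustered term).
#' @param A,B,C single counts.
#' @param l centre-node degree (>= 1).
#' @param phi clustering coefficient in \[0, 1\].
#' @param eps regularisation scale (0 = exact division).
#' @param deg_a,deg_c degrees of the flanking (A and C) classes and
#' @param stub_total total stub count \eqn{\langle k\rangle N}; all three
#'   must be given to select the normalised clustered term.
#' @export
close_triple <- function(AB, BC, CA, A, B, C, l, phi, eps = 0,
                         deg_a = NULL, deg_c = NULL, stub_total = NULL) {
  stopifnot(l >= 1, phi >= 0, phi <= 1)
  rinv <- function(d) if (eps > 0) 1 / pmax(d, eps) else ifelse(d == 0, 0, 1 / d)
  norm <- if (!is.null(deg_a) && !is.null(deg_c) && !is.null(stub_total))
    stub_total / (deg_a * deg_c) else 1
  ((l - 1) / l) * ((1 - phi) * AB * BC * rinv(B) +
                   phi * norm * AB * BC * CA * rinv(A) * rinv(B) * rinv(C))
}

#' Initial conditions for the heterogeneous pairwise model
#'
#' Singles from the seed vector; pairs by proportional (degree-weighted)
#' mixing, \eqn{[A_kB_\ell](0) = k A_k(0)\,\ell B_\ell(0)/\sum_j j N_j},
#' which satisfies the per-class edge-count invariant at t = 0 and makes the
#' SS and II blocks symmetric by construction.
#'
#' @param dist a `degree_dist` (its classes define the system).
#' @param N population size.
#' @param seeds vector of initial infected counts per class.
#' @param full_pairs also allocate the SR/RI/RR blocks (for conservation
#'   checks).
#' @return named list with S, I, R vectors and SI, SS, II (and optionally
#'   SR, RI, RR) matrices.
#' @export
pairwise_initial_conditions <- function(dist, N, seeds, full_pairs = FALSE) {
  k <- dist$degrees
  Nk <- N * dist$pmf
  if (length(seeds) != length(k)) stop("seeds must have one entry per class")
  if (any(seeds < 0) || any(seeds - Nk > 1e-9 * N))
    stop("seed counts exceed class sizes")
  S <- Nk - seeds; I <- seeds
  den <- sum(k * Nk)
  kS <- k * S; kI <- k * I
  st <- list(S = S, I = I, R = numeric(length(k)),
             SI = outer(kS, kI) / den,
             SS = outer(kS, kS) / den,
             II = outer(kI, kI) / den)
  if (full_pairs) {
    Z <- matrix(0, length(k), length(k))
    st$SR <- Z; st$RI <- Z; st$RR <- Z
  }
  st
}

pack_pairwise_state <- function(st) {
  v <- c(st$S, st$I, st$R, as.numeric(st$SI), as.numeric(st$SS),
         as.numeric(st$II))
  if (!is.null(st$SR)) v <- c(v, as.numeric(st$SR), as.numeric(st$RI),
                              as.numeric(st$RR))
  v
}

unpack_pairwise_state <- function(y, M, full_pairs = FALSE) {
  M2 <- M * M
  st <- list(S = y[1:M], I = y[M + 1:M], R = y[2 * M + 1:M],
             SI = matrix(y[3 * M + 1:M2], M),
             SS = matrix(y[3 * M + M2 + 1:M2], M),
             II = matrix(y[3 * M + 2 * M2 + 1:M2], M))
  if (full_pairs) {
    st$SR <- matrix(y[3 * M + 3 * M2 + 1:M2], M)
    st$RI <- matrix(y[3 * M + 4 * M2 + 1:M2], M)
    st$RR <- matrix(y[3 * M + 5 * M2 + 1:M2], M)
  }
  st
}

#' Heterogeneous pairwise SIR model with clustering
#'
#' ODEs for per-degree-class singles and per-ordered-degree-pair edge counts
#' \eqn{[S_kI_\ell], [S_kS_\ell], [I_kI_\ell]}, with triples closed by
#' [close_triple()]. Long-tailed degree distributions are first pruned of
#' classes below `prune_tol` mass and (optionally) collapsed into binned
#' classes to bound the \eqn{O(M^2)} system size.
#'
#' @inheritParams hmf_model
#' @param phi global clustering coefficient in \[0, 1\].
#' @param seeds either a vector over the processed classes, or a list
#'   `list(k = 10, count = 5)` placing `count` infected in the class nearest
#'   degree `k` (the default mirrors the HMF seeding).
#' @param bin collapse the support via [bin_degree_dist()] when it exceeds
#'   `exact_max + n_tail_bins` classes.
#' @param exact_max,n_tail_bins binning parameters.
#' @param track_full_pairs also integrate the SR/RI/RR blocks so the
#'   per-class edge-count invariant can be verified exactly.
#' @param eps regularisation scale for degenerate denominators (default
#'   `1e-9 * N`).
#' @param closure `"normalized"` (default) weights the clustered triangle
#'   term by the proportional-mixing normalisation
#'   \eqn{\langle k\rangle N/(d_A d_C)}, which keeps the triple count
#'   extensive in N; `"printed"` uses the bare
#'   \eqn{\varphi\,AB\,BC\,CA/(A B C)} term. See [close_triple()]. The two
#'   coincide for `phi = 0`.
#' @return an `epi_model` handle; intervention target `"global"` scales tau.
#' @export
pairwise_model <- function(dist, tau, gamma, phi = 0, N = 6.65e6,
                           seeds = list(k = 10, count = 5), bin = TRUE,
                           exact_max = 30, n_tail_bins = 18,
                           track_full_pairs = FALSE, eps = 1e-9 * N,
                           closure = c("normalized", "printed")) {
  closure <- match.arg(closure)
  stopifnot(inherits(dist, "degree_dist"), tau > 0, gamma > 0,
            phi >= 0, phi <= 1)
  d <- prune_degree_dist(dist, 1e-9)
  if (bin && length(d$degrees) > exact_max + n_tail_bins)
    d <- bin_degree_dist(d, exact_max = exact_max, n_tail_bins = n_tail_bins)
  k <- d$degrees
  M <- length(k)
  if (is.list(seeds)) {
    seeds <- seed_class(d, N, k = seeds$k, count = seeds$count)
  }
  st0 <- pairwise_initial_conditions(d, N, seeds, full_pairs = track_full_pairs)
  y0 <- pack_pairwise_state(st0)
  kNtot <- sum(k * N * d$pmf)
  normalized <- closure == "normalized"
  rhs_factory <- function(alpha = 1, target = "global") {
    tau_eff <- alpha * tau
    function(t, y) pairwise_rhs_cpp(y, k, tau_eff, gamma, phi, eps,
                                    track_full_pairs, normalized, kNtot)
  }
  iS <- 1:M; iI <- M + 1:M; iR <- 2 * M + 1:M
  new_epi_model(
    name = sprintf("pairwise(phi=%g)", phi), N = N, y0 = y0,
    rhs_factory = rhs_factory,
    cum_inc = function(y) N - sum(y[iS]),
    prev = function(y) sum(y[iI]),
    susceptible = function(y) sum(y[iS]),
    recovered = function(y) sum(y[iR]),
    method = "adams",
    extra = list(dist = d, tau = tau, gamma = gamma, phi = phi,
                 Nk = N * d$pmf, full_pairs = track_full_pairs,
                 closure = closure, stub_total = kNtot,
                 idx = list(S = iS, I = iI, R = iR)))
}

#' Derivative of the pairwise state (exposed for testing)
#'
#' @param model an `epi_model` from [pairwise_model()].
#' @param y packed state vector (defaults to the initial state).
#' @param alpha transmission multiplier.
#' @export
pairwise_rhs <- function(model, y = model$y0, alpha = 1) {
  model$rhs_factory(alpha)(0, y)
}

#' @rdname integrate_model
#' @export
integrate_pairwise <- function(model, times, ...) integrate_model(model, times, ...)

#' Pair-level dump of a pairwise trajectory
#'
#' @param model the `pairwise_model` handle.
#' @param traj result of [integrate_model()].
#' @return long data.frame: time, k, l, type (SI/SS/II), count.
#' @export
pair_trajectory <- function(model, traj) {
  out <- attr(traj, "states")
  if (is.null(out)) stop("trajectory has no stored states")
  k <- model$dist$degrees
  M <- length(k)
  M2 <- M * M
  grid <- expand.grid(k = k, l = k)
  res <- lapply(seq_len(nrow(out)), function(i) {
    y <- out[i, -1]
    do.call(rbind, lapply(seq_along(c("SI", "SS", "II")), function(b) {
      data.frame(time = unname(out[i, 1]), k = grid$k, l = grid$l,
                 type = c("SI", "SS", "II")[b],
                 count = unname(y[3 * M + (b - 1) * M2 + 1:M2]))
    }))
  })
  do.call(rbind, res)
}

# Per-class edge bookkeeping: total ordered pairs attached to class k over
# all tracked states. Equals k*N_k at all times when full pairs are tracked.
pairwise_edge_totals <- function(model, y) {
  M <- length(model$dist$degrees)
  st <- unpack_pairwise_state(y, M, full_pairs = model$full_pairs)
  tot <- rowSums(st$SS) + rowSums(st$SI) + colSums(st$SI) + rowSums(st$II)
  if (model$full_pairs)
    tot <- tot + rowSums(st$SR) + colSums(st$SR) + rowSums(st$RI) +
      colSums(st$RI) + rowSums(st$RR)
  tot
}
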