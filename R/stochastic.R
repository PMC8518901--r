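#' Explicit household + configuration-model network
#'
#' Households of size 4 (complete graphs) plus community edges obtained by
#' drawing a community degree for every node i.i.d. from `dist` and pairing
#' the stubs uniformly at random. An odd leftover stub is discarded, as are
#' self-loops and duplicate community edges (discarded, not rewired: the
#' bias is O(1/N) and discarding keeps the construction deterministic for a
#' fixed seed).
#'
#' @param n_households number of 4-person households.
#' @param dist community `degree_dist` (degrees rounded to integers).
#' @param seed integer seed (local RNG stream; the caller's RNG state is
#'   preserved).
#' @return object of class `explicit_network`: node count, edge data.frame
#'   (`from`, `to`, `type`), realised community degrees.
#' @export
build_network <- function(n_households, dist, seed = 1) {
  stopifnot(n_households >= 1, inherits(dist, "degree_dist"))
  n <- 4L * n_households
  hh <- rep(seq_len(n_households), each = 4L)
  combs <- utils::combn(4L, 2L)
  h_from <- as.integer(outer((hh[seq(1, n, by = 4)] - 1) * 4, combs[1, ], `+`))
  h_to <- as.integer(outer((hh[seq(1, n, by = 4)] - 1) * 4, combs[2, ], `+`))
  with_preserved_seed(seed, {
    degs <- round(dist$degrees)[sample.int(length(dist$degrees), n,
                                           replace = TRUE, prob = dist$pmf)]
    stubs <- rep(seq_len(n), degs)
    stubs <- sample(stubs)
    if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
    half <- length(stubs) / 2
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    dup <- duplicated(lo * (n + 1) + hi)
    lo <- lo[!dup]; hi <- hi[!dup]
    edges <- rbind(
      data.frame(from = h_from, to = h_to,
                 type = rep("household", length(h_from)),
                 stringsAsFactors = FALSE),
      data.frame(from = lo, to = hi, type = rep("community", length(lo)),
                 stringsAsFactors = FALSE))
    realised <- tabulate(c(lo, hi), nbins = n)
    structure(list(n_nodes = n, n_households = n_households, edges = edges,
                   degrees = realised, target_dist = dist),
              class = "explicit_network")
  })
}

#' @export
print.explicit_network <- function(x, ...) {
  cat(sprintf(
    "explicit_network: %d nodes in %d households; %d community edges (mean degree %.3f)\n",
    x$n_nodes, x$n_households, sum(x$edges$type == "community"),
    mean(x$degrees)))
  invisible(x)
}

#' Export the edge list as a plain two-column file
#' @param net an `explicit_network`.
#' @param path output path (whitespace-separated `from to`).
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges[, c("from", "to")], path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# CSR-style adjacency (0-based) for the C++ core.
network_adjacency <- function(net) {
  e <- net$edges
  type_code <- ifelse(e$type == "household", 0L, 1L)
  from <- c(e$from, e$to); to <- c(e$to, e$from); cl <- c(type_code, type_code)
  o <- order(from)
  from <- from[o]; to <- to[o]; cl <- cl[o]
  cnt <- tabulate(from, nbins = net$n_nodes)
  ptr <- c(0L, cumsum(cnt))
  list(ptr = as.integer(ptr), adj = as.integer(to - 1L), cls = as.integer(cl))
}

#' Exact stochastic SIR on an explicit network
#'
#' Gillespie simulation with per-edge transmission at `beta_h` on household
#' edges and `beta_c` on community edges and recovery at `gamma`.
#' Intervention windows scale the two rate classes to match the EBCM
#' targets: `"global"` scales both, `"community_only"` scales `beta_c` only.
#'
#' @param net an `explicit_network` from [build_network()].
#' @param beta_h,beta_c,gamma rates per day.
#' @param seed integer seed for the single per-run RNG stream.
#' @param schedule `NULL` or data.frame with `start_day`, `duration_days`,
#'   `alpha`, `target`.
#' @param initial_infected node indices to seed, or an integer count
#'   (uniformly random seeds).
#' @param t_max simulation horizon (days).
#' @param bin_width width of the binned trajectory output.
#' @return list: `events` (time, event_type in {infection, recovery}, node),
#'   `daily` (binned S/I/R), `final_size` (count ever infected).
#' @export
gillespie_sir <- function(net, beta_h, beta_c, gamma, seed = 1,
                          schedule = NULL, initial_infected = 10L,
                          t_max = 1000, bin_width = 1) {
  stopifnot(inherits(net, "explicit_network"), gamma > 0,
            beta_h >= 0, beta_c >= 0)
  a <- network_adjacency(net)
  if (is.null(schedule)) {
    ws <- numeric(0); we <- numeric(0); mh <- numeric(0); mc <- numeric(0)
  } else {
    ws <- schedule$start_day
    we <- schedule$start_day + schedule$duration_days
    mh <- ifelse(schedule$target == "community_only", 1, schedule$alpha)
    mc <- schedule$alpha
  }
  with_preserved_seed(seed, {
    seeds <- if (length(initial_infected) == 1)
      sample.int(net$n_nodes, initial_infected) else as.integer(initial_infected)
    res <- gillespie_sir_cpp(a$ptr, a$adj, a$cls, as.integer(seeds - 1L),
                             beta_h, beta_c, gamma, ws, we, mh, mc,
                             t_max, bin_width)
    res$events$event_type <- c("infection", "recovery")[res$events$event_type + 1]
    res$events$node <- res$events$node + 1L
    res$seeds <- sort(seeds)
    res
  })
}

#' Mean major-outbreak final size over stochastic replicates
#'
#' Runs `n_rep` Gillespie replicates (seeds `seed + 1:n_rep`), discards
#' minor outbreaks (final size below `5 * seed count`, since the mean-field
#' models describe major outbreaks), and returns the mean, Monte Carlo
#' standard error and per-replicate values of the final-size fraction.
#'
#' @inheritParams gillespie_sir
#' @param n_rep number of replicates.
#' @export
gillespie_final_sizes <- function(net, beta_h, beta_c, gamma, n_rep = 50,
                                  seed = 1, schedule = NULL,
                                  initial_infected = 10L, t_max = 2000) {
  fs <- vapply(seq_len(n_rep), function(r) {
    gillespie_sir(net, beta_h, beta_c, gamma, seed = seed + r,
                  schedule = schedule, initial_infected = initial_infected,
                  t_max = t_max, bin_width = t_max)$final_size
  }, numeric(1))
  n_seed <- if (length(initial_infected) == 1) initial_infected else
    length(initial_infected)
  major <- fs[fs >= 5 * n_seed]
  frac <- major / net$n_nodes
  list(mean = mean(frac), se = stats::sd(frac) / sqrt(length(frac)),
       n_major = length(major), all = fs / net$n_nodes)
}
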