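#' Age-banded mixing-matrix set
#'
#' Container for the four contact components (home, school, work, other) and
#' the age-band population vector. Entry (i, j) of a component is the mean
#' number of daily contacts an individual in age group i makes with
#' individuals in age group j at that location (per-capita convention, as
#' published contact matrices are).
#'
#' @param home,school,work,other square numeric matrices, same dimension.
#' @param populations vector of age-group sizes, length matching the
#'   matrices.
#' @return an object of class `mixing_set`.
#' @export
mixing_set <- function(home, school, work, other, populations) {
  comps <- list(home = as.matrix(home), school = as.matrix(school),
                work = as.matrix(work), other = as.matrix(other))
  n <- nrow(comps$home)
  for (nm in names(comps)) {
    m <- comps[[nm]]
    if (nrow(m) != n || ncol(m) != n)
      stop("component '", nm, "' is not ", n, "x", n)
    if (any(m < 0)) stop("component '", nm, "' has negative entries")
  }
  populations <- as.numeric(populations)
  if (length(populations) != n)
    stop("`populations` must have length ", n)
  if (any(populations <= 0)) stop("populations must be positive")
  structure(list(components = comps, populations = populations, n_groups = n),
            class = "mixing_set")
}

#' Total contact matrix (sum of the four components)
#' @param mset a `mixing_set`.
#' @export
mixing_total <- function(mset) {
  stopifnot(inherits(mset, "mixing_set"))
  Reduce(`+`, mset$components)
}

#' @export
print.mixing_set <- function(x, ...) {
  sums <- vapply(x$components, sum, numeric(1))
  cat(sprintf("mixing_set: %d age groups, population %.4g\n",
              x$n_groups, sum(x$populations)))
  cat("  component sums:",
      paste(sprintf("%s=%.3f", names(sums), sums), collapse = ", "), "\n")
  invisible(x)
}

component_names <- c("home", "school", "work", "other")

#' Scale one component (or all) of a mixing set
#'
#' Returns a copy with the named component multiplied elementwise by
#' `factor`; `component = "all"` scales every component. School closure is
#' `scale_component(mset, "school", 0)`; work distancing is
#' `scale_component(mset, "work", 0.5)`.
#'
#' @param mset a `mixing_set`.
#' @param component one of `"home"`, `"school"`, `"work"`, `"other"`, `"all"`.
#' @param factor non-negative scalar.
#' @export
scale_component <- function(mset, component, factor) {
  stopifnot(inherits(mset, "mixing_set"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0)
    stop("`factor` must be a non-negative scalar")
  if (identical(component, "all")) {
    mset$components <- lapply(mset$components, function(m) m * factor)
    return(mset)
  }
  if (!component %in% component_names)
    stop("unknown component name: ", component)
  mset$components[[component]] <- mset$components[[component]] * factor
  mset
}

#' Scale a block of one component
#'
#' Only entries (i, j) with i in `row_groups` and j in `col_groups` of the
#' named component are multiplied by `factor`. The "school closure and social
#' distancing" scenario combines `scale_component(mset, "school", 0)` with
#' `scale_block(mset, "other", 1:4, 1:4, 0.5)`.
#'
#' @inheritParams scale_component
#' @param row_groups,col_groups integer group indices within 1..n_groups.
#' @export
scale_block <- function(mset, component, row_groups, col_groups, factor) {
  stopifnot(inherits(mset, "mixing_set"))
  if (!component %in% component_names)
    stop("unknown component name: ", component)
  n <- mset$n_groups
  if (any(row_groups < 1 | row_groups > n) || any(col_groups < 1 | col_groups > n))
    stop("group indices out of range 1..", n)
  m <- mset$components[[component]]
  m[row_groups, col_groups] <- m[row_groups, col_groups] * factor
  mset$components[[component]] <- m
  mset
}

#' Remove demographic and contact-volume confounders from a mixing set
#'
#' Sets every age group to the same size (1/n of the original total) and
#' rescales each component by a scalar so that all four components have the
#' same elementwise sum. The default target sum is the original sum of the
#' `other` component. Idempotent.
#'
#' @param mset a `mixing_set`.
#' @param target_component_sum scalar; defaults to `sum(other)`.
#' @export
equalize <- function(mset, target_component_sum = NULL) {
  stopifnot(inherits(mset, "mixing_set"))
  sums <- vapply(mset$components, sum, numeric(1))
  if (any(sums <= 0)) stop("cannot equalize: a component has zero sum")
  if (is.null(target_component_sum)) target_component_sum <- sums[["other"]]
  mset$components <- lapply(mset$components, function(m) m * (target_component_sum / sum(m)))
  mset$populations <- rep(sum(mset$populations) / mset$n_groups, mset$n_groups)
  mset
}

#' Share of total contacts contributed by each component
#'
#' Population-weighted: component share = sum_i N_i sum_j M_ij over the same
#' for the total matrix.
#' @param mset a `mixing_set`.
#' @export
component_shares <- function(mset) {
  w <- mset$populations
  tot <- vapply(mset$components, function(m) sum(w * rowSums(m)), numeric(1))
  tot / sum(tot)
}

#' Synthetic age-banded mixing components
#'
#' Generates a deterministic (seeded) mixing set emulating the qualitative
#' structure of empirical contact-diary matrices: home, school and other are
#' assortative (diagonally dominant), with school contacts confined to the
#' youngest `school_groups`; the work component instead features a wide,
#' approximately constant contact plateau over the working-age
#' `work_plateau_groups`. `assortativity_strength = 0` degrades all
#' components to uniform matrices.
#'
#' @param n_groups number of age bands (>= 2), default 18.
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @param assortativity_strength inverse bandwidth of the diagonal kernels
#'   (0 = uniform).
#' @param work_plateau_groups indices of the working-age plateau block.
#' @param school_groups indices of the school-age block.
#' @return a `mixing_set` with mildly heterogeneous populations.
#' @export
synthetic_mixing_components <- function(n_groups = 18, seed = 1,
                                        assortativity_strength = 2,
                                        work_plateau_groups = NULL,
                                        school_groups = NULL) {
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (is.null(work_plateau_groups))
    work_plateau_groups <- seq(max(2, ceiling(n_groups * 0.28)),
                               min(n_groups, ceiling(n_groups * 0.72)))
  if (is.null(school_groups))
    school_groups <- seq_len(max(2, min(4, n_groups - 1)))
  a <- assortativity_strength
  ij <- abs(outer(seq_len(n_groups), seq_len(n_groups), `-`))
  kern <- function(width) exp(-a * ij / width)
  with_preserved_seed(seed, {
    noise <- function() matrix(exp(stats::rnorm(n_groups^2, sd = 0.05)), n_groups)
    home <- 4 * kern(1.5) * noise()
    school <- matrix(0.02, n_groups, n_groups)
    school[school_groups, school_groups] <-
      school[school_groups, school_groups] +
      8 * exp(-2 * a * ij[school_groups, school_groups, drop = FALSE])
    school <- school * noise()
    other <- 3 * kern(3) * noise()
    work <- matrix(0.02, n_groups, n_groups)
    work[work_plateau_groups, work_plateau_groups] <- 3
    if (a == 0) {
      school[] <- mean(school); work[] <- mean(work)
    }
    work <- work * noise()
    pops <- exp(stats::rnorm(n_groups, sd = 0.15))
    pops <- pops / sum(pops) * 6.65e6
    mixing_set(home, school, work, other, pops)
  })
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Read / write a mixing component as CSV
#'
#' Comma-separated with a header row and a leading label column of age-band
#' names; row i holds the contacts of group i with each group j.
#' @param path CSV file path.
#' @export
read_mixing_component <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_mixing_component
#' @param m matrix to write.
#' @param labels age-band labels; defaults to existing rownames or G1..Gn.
#' @export
write_mixing_component <- function(m, path, labels = NULL) {
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("G", seq_len(nrow(m)))
  df <- data.frame(age_band = labels, m, check.names = FALSE)
  colnames(df) <- c("age_band", labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a full mixing set from per-component CSV files plus populations
#'
#' @param paths named list/vector with entries home, school, work, other.
#' @param population_path CSV with columns `age_band`, `population`.
#' @export
read_mixing_set <- function(paths, population_path) {
  comps <- lapply(paths[component_names], read_mixing_component)
  pop <- utils::read.csv(population_path)
  mixing_set(comps$home, comps$school, comps$work, comps$other,
             pop$population)
}
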