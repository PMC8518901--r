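# Shared infrastructure: every mean-field model in the package is wrapped in
# an `epi_model` handle exposing the same surface, so the lockdown-experiment
# machinery (triggers, optimal-alpha search, DIHI) is model-agnostic.
#
# A handle provides:
#   y0           initial state vector
#   rhs_factory(alpha, target) -> function(t, y) giving dy/dt with the
#                intervention multiplier applied (alpha = 1: free dynamics)
#   cum_inc(y)   ever-infected count (I + R, plus E and D where present)
#   prev(y)      current infected count
#   susceptible(y), recovered(y)
#   N            population size (counts scale)
#   rtol, atol, method   integrator settings

new_epi_model <- function(name, N, y0, rhs_factory, cum_inc, prev,
                          susceptible, recovered, targets = "global",
                          rtol = 1e-8, atol = NULL, method = "lsoda",
                          extra = list()) {
  if (is.null(atol)) atol <- 1e-10 * max(N, 1)
  structure(
    c(list(name = name, N = N, y0 = y0, rhs_factory = rhs_factory,
           cum_inc = cum_inc, prev = prev, susceptible = susceptible,
           recovered = recovered, targets = targets,
           rtol = rtol, atol = atol, method = method,
           cache = new.env(parent = emptyenv())),
      extra),
    class = "epi_model")
}

#' @export
print.epi_model <- function(x, ...) {
  cat(sprintf("epi_model '%s': %d state variables, N = %.4g\n",
              x$name, length(x$y0), x$N))
  invisible(x)
}

# Integrate one phase of the dynamics. `rootfun`, if given, stops the
# integration at its sign change (event detection, not grid snapping).
ode_phase <- function(model, f, y0, from, to, step = 1, rootfun = NULL) {
  if (to <= from) stop("empty integration phase [", from, ", ", to, "]")
  times <- seq(from, to, by = step)
  if (times[length(times)] < to) times <- c(times, to)
  fun <- function(t, y, parms) list(f(t, y))
  if (is.null(rootfun)) {
    out <- deSolve::ode(y = y0, times = times, func = fun, parms = NULL,
                        method = model$method, rtol = model$rtol,
                        atol = model$atol)
  } else {
    out <- deSolve::lsodar(y = y0, times = times, func = fun, parms = NULL,
                           rootfunc = function(t, y, parms) rootfun(t, y),
                           rtol = model$rtol, atol = model$atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure in model '", model$name, "' (istate = ",
         attr(out, "istate")[1], ") on [", from, ", ", to, "]")
  out
}

# Standardised trajectory data.frame from a deSolve matrix.
measure_frame <- function(model, out) {
  Y <- out[, -1, drop = FALSE]
  data.frame(
    time = out[, 1],
    susceptible = apply(Y, 1, model$susceptible),
    prevalence = apply(Y, 1, model$prev),
    recovered = apply(Y, 1, model$recovered),
    cumulative = apply(Y, 1, model$cum_inc))
}

# Duration of the free epidemic (time for prevalence to fall back below the
# initial seed level after the peak), memoised on the model handle. Used to
# size the post-lockdown horizon.
free_epidemic_duration <- function(model, t_max = 2000) {
  if (!is.null(model$cache$free_duration)) return(model$cache$free_duration)
  f <- model$rhs_factory(1, model$targets[1])
  p0 <- max(model$prev(model$y0), 1e-12 * model$N)
  started <- FALSE
  rootf <- function(t, y) {
    p <- model$prev(y)
    if (p > 2 * p0) started <<- TRUE
    if (started) p - min(p0, 1e-9 * model$N) else 1
  }
  out <- ode_phase(model, f, model$y0, 0, t_max, step = 1, rootfun = rootf)
  dur <- out[nrow(out), 1]
  model$cache$free_duration <- dur
  dur
}

#' Write a standardised trajectory to CSV
#'
#' Columns: time, susceptible, prevalence, recovered, cumulative (counts).
#' @param run a run object from [run_with_policy()] or a measure data.frame.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(run, path) {
  df <- if (is.data.frame(run)) run else run$trajectory
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
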