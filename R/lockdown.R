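#' One-shot lockdown policy
#'
#' Exactly one trigger kind must be given: a cumulative-incidence fraction
#' (`trigger_fraction`, e.g. 0.005 for "0.5% ever infected" or 0.025 for
#' "I + R reaches 2.5% of N") located by event detection, or a fixed
#' `start_day`. During the window of `duration` days the model's
#' transmission is scaled by `alpha` (or the contact structure is switched,
#' depending on `target`); afterwards all parameters return instantly to
#' their pre-lockdown values.
#'
#' @param trigger_fraction cumulative-incidence fraction of N, or `NULL`.
#' @param start_day fixed start day, or `NULL`.
#' @param duration lockdown length in days (> 0).
#' @param alpha multiplier in \[0, 1\].
#' @param target intervention target understood by the model
#'   (`"global"`, `"community_only"`, `"matrix_scenario"`).
#' @export
lockdown_policy <- function(trigger_fraction = NULL, start_day = NULL,
                            duration = 130, alpha = 1, target = "global") {
  if (is.null(trigger_fraction) == is.null(start_day))
    stop("exactly one of `trigger_fraction` and `start_day` must be set")
  stopifnot(duration > 0, alpha >= 0, alpha <= 1)
  structure(list(trigger_fraction = trigger_fraction, start_day = start_day,
                 duration = duration, alpha = alpha, target = target),
            class = "lockdown_policy")
}

model_gamma <- function(model) {
  g <- model$gamma
  if (is.null(g) && !is.null(model$params)) {
    g <- model$params$gamma
    if (is.null(g)) g <- model$params$gamma_I
  }
  if (is.null(g)) 1 / 14 else g
}

# Locate the trigger: integrate the free dynamics until the cumulative
# incidence crosses the threshold (lsodar root finding, not grid snapping).
# Memoised on the model handle.
locate_trigger <- function(model, policy, t_search_max = 5000) {
  if (!is.null(policy$start_day)) {
    f <- model$rhs_factory(1, policy$target)
    if (policy$start_day <= 0)
      return(list(t0 = 0, y0 = model$y0, fired = TRUE, pre = NULL))
    out <- ode_phase(model, f, model$y0, 0, policy$start_day, step = 1)
    return(list(t0 = policy$start_day, y0 = out[nrow(out), -1], fired = TRUE,
                pre = out))
  }
  key <- sprintf("trig_%.10g", policy$trigger_fraction)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  threshold <- policy$trigger_fraction * model$N
  f <- model$rhs_factory(1, policy$target)
  out <- ode_phase(model, f, model$y0, 0, t_search_max, step = 1,
                   rootfun = function(t, y) model$cum_inc(y) - threshold)
  t0 <- out[nrow(out), 1]
  fired <- t0 < t_search_max - 1e-9
  res <- list(t0 = t0, y0 = out[nrow(out), -1], fired = fired, pre = out)
  model$cache[[key]] <- res
  res
}

#' Run a model under a one-shot lockdown policy
#'
#' Free dynamics until the trigger fires, scaled dynamics for
#' `policy$duration` days, then free dynamics again out to a horizon long
#' enough to expose any slow rebound (at least the greater of three free
#' epidemic durations and ten mean infectious periods past lifting), with
#' automatic extension until prevalence has died down.
#'
#' @param model an `epi_model` handle.
#' @param policy a [lockdown_policy()].
#' @param step output resolution in days.
#' @param trigger optional precomputed result of the internal trigger
#'   search (used by [optimal_alpha()] to share the free phase across
#'   alpha values).
#' @return object of class `policy_run`: `trajectory` (standard measure
#'   frame), `window = c(t_start, t_end)` (NA if the trigger never fired),
#'   `fired`, `final_size` and `dihi` (fractions of N), `policy`.
#' @export
run_with_policy <- function(model, policy, step = 1, trigger = NULL) {
  stopifnot(inherits(model, "epi_model"), inherits(policy, "lockdown_policy"))
  if (is.null(trigger)) trigger <- locate_trigger(model, policy)
  gam <- model_gamma(model)
  free <- model$rhs_factory(1, policy$target)
  if (!trigger$fired) {
    df <- measure_frame(model, trigger$pre)
    n <- nrow(df)
    return(structure(list(trajectory = df, window = c(NA_real_, NA_real_),
                          fired = FALSE, policy = policy,
                          final_size = df$cumulative[n] / model$N,
                          dihi = df$cumulative[n] / model$N),
                     class = "policy_run"))
  }
  t0 <- trigger$t0
  t_end <- t0 + policy$duration
  ctrl <- model$rhs_factory(policy$alpha, policy$target)
  mid <- ode_phase(model, ctrl, trigger$y0, t0, t_end, step = step)
  horizon <- max(3 * t0, t_end + 10 / gam)
  y <- mid[nrow(mid), -1]
  post <- ode_phase(model, free, y, t_end, horizon, step = step)
  # extend until the epidemic has completed: prevalence small *and* falling,
  # so that a deeply suppressed but slowly rebounding epidemic is not missed
  t_cap <- 20000
  repeat {
    nr <- nrow(post)
    p_now <- model$prev(post[nr, -1])
    p_prev <- model$prev(post[nr - 1, -1])
    done <- p_now < 1e-9 * model$N && p_now <= p_prev
    if (done || post[nr, 1] >= t_cap) break
    y <- post[nr, -1]
    from <- post[nr, 1]
    ext <- ode_phase(model, free, y, from, min(from + max(from, 200), t_cap),
                     step = step)
    post <- rbind(post, ext[-1, , drop = FALSE])
  }
  pre <- trigger$pre
  out <- rbind(if (!is.null(pre)) pre[pre[, 1] < t0, , drop = FALSE],
               mid, post[-1, , drop = FALSE])
  df <- measure_frame(model, out)
  i_end <- which.min(abs(df$time - t_end))
  structure(list(trajectory = df, window = c(t0, t_end), fired = TRUE,
                 policy = policy,
                 final_size = df$cumulative[nrow(df)] / model$N,
                 dihi = df$cumulative[i_end] / model$N),
            class = "policy_run")
}

#' @export
print.policy_run <- function(x, ...) {
  if (x$fired)
    cat(sprintf(
      "policy_run: window [%.2f, %.2f], alpha = %g, DIHI = %.4f, final size = %.4f\n",
      x$window[1], x$window[2], x$policy$alpha, x$dihi, x$final_size))
  else
    cat(sprintf("policy_run: trigger never fired; final size = %.4f\n",
                x$final_size))
  invisible(x)
}

#' Detect a post-lockdown second wave
#'
#' A run is flagged as producing a second wave iff prevalence at some time
#' after lifting exceeds the prevalence at the moment of lifting by more
#' than a relative tolerance; equivalently, the post-lift epidemic is
#' subcritical iff prevalence is non-increasing after lifting.
#'
#' @param run a `policy_run`, or a data.frame with `time` and `prevalence`.
#' @param t_end_lockdown end of the window (taken from the run by default).
#' @param rel_tol relative tolerance on the prevalence comparison.
#' @param N population scale (taken from the run's trajectory by default).
#' @return list: `second_wave` flag and `post_peak` prevalence.
#' @export
detect_second_wave <- function(run, t_end_lockdown = NULL, rel_tol = 1e-6,
                               N = NULL) {
  df <- if (inherits(run, "policy_run")) run$trajectory else run
  if (is.null(t_end_lockdown)) {
    if (!inherits(run, "policy_run") || !run$fired)
      stop("t_end_lockdown must be supplied for a non-run trajectory")
    t_end_lockdown <- run$window[2]
  }
  if (is.null(N)) N <- max(df$cumulative)
  gam_window <- max(df$time) - t_end_lockdown
  if (gam_window <= 0)
    stop("trajectory must extend beyond the end of lockdown; extend the run")
  p_end <- stats::approx(df$time, df$prevalence, t_end_lockdown)$y
  post <- df$prevalence[df$time > t_end_lockdown]
  peak <- if (length(post)) max(post) else p_end
  list(second_wave = peak > p_end * (1 + rel_tol) + 1e-12 * N,
       post_peak = peak)
}

#' Optimal intervention strength and the DIHI level
#'
#' Evaluates `run_with_policy` over `alpha_grid`, keeps the runs whose
#' post-lift epidemic is subcritical (no second wave), selects the alpha
#' minimising the final size among them, and refines the subcriticality
#' boundary by bisection to `refine_tol`. The DIHI is the cumulative
#' infected fraction at the end of lockdown under the optimal alpha.
#'
#' @param model an `epi_model`.
#' @param policy_template a [lockdown_policy()]; its `alpha` is overridden.
#' @param alpha_grid grid in \[0, 1\] (>= 10 points).
#' @param refine_tol bisection tolerance on alpha.
#' @param step trajectory output resolution (days).
#' @return object of class `dihi_result`: `alpha_star`, `dihi`,
#'   `final_size`, `second_wave`, and the full `scan` table
#'   (alpha, final_size, second_wave, dihi). When no alpha on the grid is
#'   subcritical, `alpha_star` is NA and the scan records the unconstrained
#'   minimum (the short-lockdown regime).
#' @export
optimal_alpha <- function(model, policy_template,
                          alpha_grid = seq(0, 1, by = 0.05),
                          refine_tol = 1e-3, step = 1) {
  stopifnot(length(alpha_grid) >= 10, all(alpha_grid >= 0 & alpha_grid <= 1))
  trigger <- locate_trigger(model, policy_template)
  if (!trigger$fired) {
    run <- run_with_policy(model, policy_template, step = step,
                           trigger = trigger)
    scan <- data.frame(alpha = 1, final_size = run$final_size,
                       second_wave = FALSE, dihi = run$dihi)
    return(structure(list(alpha_star = 1, dihi = run$dihi,
                          final_size = run$final_size, second_wave = FALSE,
                          scan = scan, fired = FALSE),
                     class = "dihi_result"))
  }
  eval_alpha <- function(a) {
    pol <- policy_template
    pol$alpha <- a
    run <- run_with_policy(model, pol, step = step, trigger = trigger)
    sw <- detect_second_wave(run, N = model$N)
    data.frame(alpha = a, final_size = run$final_size,
               second_wave = sw$second_wave, dihi = run$dihi)
  }
  scan <- do.call(rbind, lapply(sort(alpha_grid), eval_alpha))
  sub <- scan[!scan$second_wave, ]
  if (nrow(sub) == 0) {
    i <- which.min(scan$final_size)
    return(structure(list(alpha_star = NA_real_, dihi = NA_real_,
                          final_size = scan$final_size[i],
                          second_wave = TRUE, scan = scan, fired = TRUE),
                     class = "dihi_result"))
  }
  best <- sub[which.min(sub$final_size), ]
  # refine the subcritical boundary just below the best alpha
  lower_sw <- scan$alpha[scan$second_wave & scan$alpha < best$alpha]
  if (length(lower_sw) > 0) {
    lo <- max(lower_sw)
    hi <- best$alpha
    while (hi - lo > refine_tol) {
      midv <- (lo + hi) / 2
      row <- eval_alpha(midv)
      scan <- rbind(scan, row)
      if (row$second_wave) lo <- midv
      else {
        hi <- midv
        if (row$final_size < best$final_size) best <- row
      }
    }
  }
  scan <- scan[order(scan$alpha), ]
  structure(list(alpha_star = best$alpha, dihi = best$dihi,
                 final_size = best$final_size, second_wave = FALSE,
                 scan = scan, fired = TRUE),
            class = "dihi_result")
}

#' @export
print.dihi_result <- function(x, ...) {
  if (is.na(x$alpha_star))
    cat(sprintf(
      "dihi_result: no subcritical alpha on the grid; min final size %.4f (second wave)\n",
      x$final_size))
  else
    cat(sprintf(
      "dihi_result: alpha* = %.3f, DIHI = %.4f, final size = %.4f (%d evaluations)\n",
      x$alpha_star, x$dihi, x$final_size, nrow(x$scan)))
  invisible(x)
}

#' Min-over-alpha final sizes on a start x duration grid
#'
#' Runs [optimal_alpha()] in every cell of the grid (fixed-start policies).
#' Cells where no alpha is subcritical record the unconstrained minimum and
#' are flagged.
#'
#' @param model an `epi_model`.
#' @param start_values,duration_values grid axes (days).
#' @param policy_template template policy (its trigger and duration are
#'   overridden per cell).
#' @param ... passed to [optimal_alpha()].
#' @return list: `final_size` and `alpha_star` matrices
#'   (start x duration), logical `constrained` matrix (TRUE where a
#'   subcritical alpha existed), `results` list-matrix.
#' @export
scenario_grid <- function(model, start_values, duration_values,
                          policy_template, ...) {
  ns <- length(start_values); nd <- length(duration_values)
  fs <- matrix(NA_real_, ns, nd, dimnames = list(start_values, duration_values))
  as_ <- fs; ok <- matrix(NA, ns, nd)
  results <- vector("list", ns * nd)
  dim(results) <- c(ns, nd)
  for (i in seq_len(ns)) for (j in seq_len(nd)) {
    pol <- policy_template
    pol$trigger_fraction <- NULL
    pol$start_day <- start_values[i]
    pol$duration <- duration_values[j]
    res <- optimal_alpha(model, pol, ...)
    fs[i, j] <- res$final_size
    as_[i, j] <- res$alpha_star
    ok[i, j] <- !is.na(res$alpha_star)
    results[[i, j]] <- res
  }
  list(final_size = fs, alpha_star = as_, constrained = ok,
       results = results)
}

#' DIHI versus degree variance for the clustered pairwise model
#'
#' The variance-scan protocol: shifted negative-binomial degree
#' distributions at fixed mean degree, a 100-day lockdown triggered when
#' I + R reaches 2.5% of the population, and an optimal-alpha search per
#' (variance, clustering) cell.
#'
#' @param variances degree-distribution variances (shifted scale).
#' @param phis clustering coefficients.
#' @param mean_degree mean degree (shift 1 negative binomials).
#' @param tau,gamma epidemic rates /day.
#' @param N population size.
#' @param trigger_fraction,duration lockdown protocol.
#' @param alpha_grid,step passed to [optimal_alpha()].
#' @return data.frame: variance, phi, alpha_star, dihi, final_size.
#' @export
dihi_variance_scan <- function(variances = c(7, 12, 20, 33, 55, 90),
                               phis = c(0, 0.25, 0.5), mean_degree = 6,
                               tau = 0.04, gamma = 1 / 14, N = 6.65e6,
                               trigger_fraction = 0.025, duration = 100,
                               alpha_grid = seq(0, 1, by = 0.05), step = 2) {
  grid <- expand.grid(variance = variances, phi = phis)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    v <- grid$variance[r]; ph <- grid$phi[r]
    dist <- negbin_for_moments(mean_degree, v, shift = 1)
    model <- pairwise_model(dist, tau = tau, gamma = gamma, phi = ph, N = N)
    pol <- lockdown_policy(trigger_fraction = trigger_fraction,
                           duration = duration, alpha = 1)
    res <- optimal_alpha(model, pol, alpha_grid = alpha_grid, step = step)
    data.frame(variance = v, phi = ph, alpha_star = res$alpha_star,
               dihi = res$dihi, final_size = res$final_size)
  })
  do.call(rbind, rows)
}
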