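#' Integrate the delayed tumor-immune model
#'
#' For a positive delay the model is integrated by the method of steps: the
#' step size is chosen as `h = delta / n` with `n = ceiling(delta/max_step)`
#' so that breakpoints at integer multiples of the delay (where derivative
#' discontinuities propagate) are mesh points, and each step is a classical
#' fourth-order Runge-Kutta step whose delayed-stage values come from
#' stored nodes or from a cubic Hermite interpolant of the stored solution
#' (locally O(h^4), consistent with the scheme's order). `h <= delta`
#' guarantees every delayed lookup refers to already-computed solution (the
#' final stage of a step needs the delayed state no later than the current
#' node). For `delta = 0` the system is an ODE and is integrated with
#' [deSolve::lsoda()] under `rtol`/`atol` control.
#'
#' Histories with nonnegative components yield trajectories whose `y` and
#' `z` components stay (numerically) nonnegative; this is checked by the
#' package tests rather than enforced, since `x` is a scaled deviation and
#' may legitimately be negative.
#'
#' Unbounded growth (the immune-escape regime) is a reported outcome, not
#' an error: when any component exceeds `overflow` the trajectory is
#' truncated and flagged `diverged`.
#'
#' @param p a [ti_params()] object (or coercible); `p$delta` is the lag.
#' @param history history specification accepted by [as_history()];
#'   default: the co-axial equilibrium (tumor-free if E2 does not exist)
#'   perturbed by `+0.01` in every component, held constant over
#'   `[-delta, 0]`.
#' @param t_end integration horizon (> 0).
#' @param max_step upper bound on the mesh width (default 0.01; the actual
#'   step is `delta/ceiling(delta/max_step)` when `delta > 0`).
#' @param out_dt approximate spacing of returned samples (default 0.1).
#' @param rtol,atol tolerances for the `delta = 0` ODE path.
#' @param overflow divergence guard on `max(abs(state))` (default 1e8).
#' @return An object of class `ti_trajectory`: list with `times`, `states`
#'   (matrix with columns `x`, `y`, `z`), `params`, `history`, `diverged`,
#'   `min_y`, `min_z`, and `solver` metadata.
#' @examples
#' p <- ti_params(0.3, 0.6, 0.5, 0.7, delta = 0.01)
#' traj <- dde_solve(p, t_end = 50)
#' tail(traj$states, 3)  # approaches E1 = (0, a3/a2, 0)
#' @export
dde_solve <- function(p, history = NULL, t_end = 100, max_step = 0.01,
                      out_dt = 0.1, rtol = 1e-8, atol = 1e-10,
                      overflow = 1e8) {
  p <- as_ti_params(p)
  stopifnot(t_end > 0, max_step > 0, out_dt > 0)
  if (is.null(history)) history <- default_history(p)
  history <- as_history(history)

  if (p$delta == 0) {
    y0 <- unname(history(0))
    times <- seq(0, t_end, by = out_dt)
    func <- function(t, y, parms) list(ti_rhs(y, y, p))
    sol <- try(suppressWarnings(
      deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 50000)), silent = TRUE)
    if (inherits(sol, "try-error")) {
      states <- matrix(y0, 1, 3)
      out <- list(times = 0, states = states, diverged = TRUE)
    } else {
      sol <- as.matrix(sol)
      states <- sol[, 2:4, drop = FALSE]
      finite <- apply(is.finite(states), 1, all) &
        apply(abs(states) <= overflow, 1, all)
      nkeep <- if (all(finite)) nrow(states) else max(1, which(!finite)[1] - 1)
      out <- list(times = sol[seq_len(nkeep), 1],
                  states = states[seq_len(nkeep), , drop = FALSE],
                  diverged = nkeep < nrow(states) || sol[nrow(sol), 1] < t_end)
    }
    miny <- min(out$states[, 2]); minz <- min(out$states[, 3])
    meta <- list(method = "lsoda", rtol = rtol, atol = atol)
  } else {
    n_lag <- max(1L, as.integer(ceiling(p$delta / max_step)))
    h <- p$delta / n_lag
    n_steps <- ceiling(t_end / h - 1e-9)
    out_every <- max(1L, as.integer(round(out_dt / h)))
    theta <- seq(-p$delta, 0, length.out = n_lag + 1)
    hv <- t(vapply(theta, function(th) unname(history(th)), numeric(3)))
    if (any(!is.finite(hv)))
      stop("history is not finite on [-delta, 0]", call. = FALSE)
    if (identical(attr(history, "kind"), "constant")) {
      hs <- matrix(0, n_lag + 1, 3)
    } else {
      eps <- h / 64
      hs <- t(vapply(theta, function(th) {
        lo <- max(th - eps, -p$delta); hi <- min(th + eps, 0)
        (unname(history(hi)) - unname(history(lo))) / (hi - lo)
      }, numeric(3)))
    }
    raw <- .dde_rk4_cpp(c(p$a1, p$a2, p$a3, p$a4), h, n_lag,
                        as.double(n_steps), hv, hs, out_every, overflow)
    out <- list(times = raw$times, states = raw$states, diverged = raw$diverged)
    miny <- raw$min_y; minz <- raw$min_z
    meta <- list(method = "rk4-steps", h = h, n_lag = n_lag,
                 steps = raw$steps)
  }
  colnames(out$states) <- c("x", "y", "z")
  structure(list(times = out$times, states = out$states, params = p,
                 history = history, diverged = isTRUE(out$diverged),
                 min_y = miny, min_z = minz, solver = meta),
            class = "ti_trajectory")
}

# constant history at the relevant equilibrium plus a small perturbation;
# the scenario figures state no history, so this is the package default
default_history <- function(p, perturb = 0.01) {
  pt <- equilibrium_point(p, "E2")
  if (is.null(pt)) pt <- equilibrium_point(p, "E1")
  const_history(pt[1] + perturb, pt[2] + perturb, pt[3] + perturb)
}

#' @export
print.ti_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples over t in [0, %.4g]%s (delay %.4g, %s)\n",
              length(x$times), max(x$times),
              if (x$diverged) " [diverged, truncated]" else "",
              x$params$delta, x$solver$method))
  invisible(x)
}

#' @export
as.data.frame.ti_trajectory <- function(x, ...) {
  data.frame(t = x$times, x = x$states[, 1], y = x$states[, 2],
             z = x$states[, 3])
}

#' Characterize a trajectory as steady, oscillatory, or divergent
#'
#' Analyzes the final portion of a trajectory (after discarding an initial
#' transient): per-component amplitude (`max - min` over the window), the
#' window mean (`attractor_mean`), and the oscillation period estimated as
#' the mean spacing of prominent peaks in `z` (requires at least 3 peaks).
#' A trajectory is `divergent` if it was truncated by the overflow guard or
#' still exceeds a large bound in the window, `steady` if the largest
#' component amplitude is below `eps_osc` relative to the attractor norm,
#' and `oscillatory` otherwise.
#'
#' @param traj a `ti_trajectory` from [dde_solve()].
#' @param transient_fraction fraction of the trajectory discarded as
#'   transient (default 0.5, i.e. the final half is analyzed).
#' @param eps_osc steady/oscillatory amplitude threshold, relative to
#'   `max(1e-8, ||attractor_mean||)` (default 1e-4).
#' @param prominence peak prominence threshold as a fraction of the window
#'   range of `z` (default 0.01).
#' @return An object of class `ti_summary`: list with `classification`,
#'   `amplitude` (named, per component), `period`, `n_peaks`,
#'   `attractor_mean`.
#' @export
summarize_trajectory <- function(traj, transient_fraction = 0.5,
                                 eps_osc = 1e-4, prominence = 0.01) {
  stopifnot(inherits(traj, "ti_trajectory"))
  tt <- traj$times
  t_cut <- max(tt) * transient_fraction
  keep <- tt >= t_cut
  if (sum(keep) < 3)
    stop("analysis window shorter than 3 samples", call. = FALSE)
  w <- traj$states[keep, , drop = FALSE]
  amp <- apply(w, 2, function(v) diff(range(v)))
  mu <- colMeans(w)
  scale <- max(1e-8, sqrt(sum(mu^2)))
  if (traj$diverged || max(abs(w)) > 1e6) {
    cls <- "divergent"
  } else if (max(amp) < eps_osc * scale) {
    cls <- "steady"
  } else {
    cls <- "oscillatory"
  }
  pk <- find_peaks(w[, 3], prominence * max(amp[3], .Machine$double.eps))
  period <- NA_real_
  if (length(pk) >= 3) period <- mean(diff(tt[keep][pk]))
  structure(list(classification = cls,
                 amplitude = setNames(amp, c("x", "y", "z")),
                 period = period, n_peaks = length(pk),
                 attractor_mean = setNames(mu, c("x", "y", "z"))),
            class = "ti_summary")
}

#' @export
print.ti_summary <- function(x, ...) {
  cat(sprintf("Classification: %s\n", x$classification))
  cat(sprintf("Amplitude (x, y, z): %.4g, %.4g, %.4g\n",
              x$amplitude[1], x$amplitude[2], x$amplitude[3]))
  if (!is.na(x$period))
    cat(sprintf("Period estimate: %.4g (%d peaks)\n", x$period, x$n_peaks))
  cat(sprintf("Attractor mean: (%.4g, %.4g, %.4g)\n",
              x$attractor_mean[1], x$attractor_mean[2], x$attractor_mean[3]))
  invisible(x)
}

# indices of local maxima of v whose rise from the surrounding minima is at
# least `prom` on both sides
find_peaks <- function(v, prom) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    j <- cand[i]
    left_min <- min(v[max(1, if (i == 1) 1 else cand[i - 1]):j])
    right_min <- min(v[j:(if (i == length(cand)) n else cand[i + 1])])
    keep[i] <- (v[j] - left_min >= prom) && (v[j] - right_min >= prom)
  }
  cand[keep]
}
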