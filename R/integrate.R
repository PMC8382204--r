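#' Integrate a model system
#'
#' Wraps `deSolve::ode()` (stiff-capable `lsoda` by default) and
#' `deSolve::dede()` for delayed systems. Delayed systems use a constant
#' history equal to the initial condition for `t < t0`. When the system
#' carries a [parameter_schedule()], the time span is split at every window
#' boundary and the integrator restarts with the window parameter values;
#' output times fall on a uniform grid of step `dt`.
#'
#' @param system A [model_system()].
#' @param init Named (or positional) initial state; defaults to the all-low
#'   state (all variables 0).
#' @param t_span Length-2 numeric `c(t0, t1)` (minutes for the dimensional
#'   systems).
#' @param dt Output step; defaults to `diff(t_span)/2000` (keep it well
#'   below the oscillation period when extrema matter).
#' @param rtol,atol Solver tolerances.
#' @param method Integration method passed to `deSolve::ode()`.
#' @return Object of class `trajectory`: list with `time`, `state` (matrix,
#'   one column per variable), `system`, and the solver settings.
#' @export
integrate_system <- function(system, init = NULL, t_span, dt = NULL,
                             rtol = 1e-6, atol = 1e-8, method = "lsoda") {
  stopifnot(inherits(system, "model_system"), length(t_span) == 2L,
            t_span[2L] > t_span[1L])
  nv <- length(system$vars)
  if (is.null(init)) init <- stats::setNames(rep(0, nv), system$vars)
  if (length(init) != nv)
    stop("`init` must have ", nv, " entries (",
         paste(system$vars, collapse = ", "), ")", call. = FALSE)
  init <- stats::setNames(as.numeric(init), system$vars)
  if (!is.null(system$check_init)) system$check_init(init)
  if (is.null(dt)) dt <- diff(t_span) / 2000

  segments <- schedule_segments(system, t_span)
  times_all <- NULL; state_all <- NULL
  y0 <- init; t0 <- t_span[1L]
  hist_t0 <- t_span[1L]; hist_y0 <- init  # constant DDE history
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    p <- segment_params(system, seg)
    times <- seq(t0, seg$t_end, by = dt)
    if (times[length(times)] < seg$t_end - 1e-9 * dt)
      times <- c(times, seg$t_end)
    if (length(times) < 2L) times <- c(t0, seg$t_end)
    if (system$has_delay) {
      lagfun <- function(t) {
        if (t <= hist_t0) hist_y0 else deSolve::lagvalue(t)
      }
      func <- function(t, y, parms)
        list(system$rhs(t, y, parms, lag = lagfun))
      out <- deSolve::dede(y = y0, times = times, func = func, parms = p,
                           rtol = rtol, atol = atol)
    } else {
      func <- function(t, y, parms) list(system$rhs(t, y, parms))
      out <- deSolve::ode(y = y0, times = times, func = func, parms = p,
                          method = method, rtol = rtol, atol = atol)
    }
    out <- unclass(out)
    if (any(!is.finite(out)))
      stop("integration failed (non-finite state); last valid time ~ ",
           signif(max(out[stats::complete.cases(out), 1L]), 6),
           call. = FALSE)
    keep <- if (i == 1L) seq_len(nrow(out)) else -1L
    times_all <- c(times_all, out[keep, 1L])
    state_all <- rbind(state_all, out[keep, -1L, drop = FALSE])
    y0 <- out[nrow(out), -1L]
    t0 <- seg$t_end
  }
  colnames(state_all) <- system$vars
  structure(list(time = times_all, state = state_all, system = system,
                 init = init, dt = dt, rtol = rtol, atol = atol,
                 method = method),
            class = "trajectory")
}

# split [t0, t1] at schedule-window boundaries; each row knows which
# windows are active
schedule_segments <- function(system, t_span) {
  brk <- t_span
  if (!is.null(system$schedule)) {
    w <- system$schedule$windows
    brk <- c(brk, w$t_start, w$t_end)
  }
  brk <- sort(unique(pmin(pmax(brk, t_span[1L]), t_span[2L])))
  data.frame(t_start = brk[-length(brk)], t_end = brk[-1L])
}

segment_params <- function(system, seg) {
  p <- system$params
  if (is.null(system$schedule)) return(p)
  w <- system$schedule$windows
  mid <- (seg$t_start + seg$t_end) / 2
  act <- w[w$t_start <= mid & mid < w$t_end, , drop = FALSE]
  for (j in seq_len(nrow(act))) {
    nm <- act$param[j]
    p[[nm]] <- if (act$mode[j] == "multiply")
      p[[nm]] * act$value[j] else act$value[j]
  }
  p
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d samples on [%g, %g], dt = %g\n",
              x$system$name, length(x$time), min(x$time), max(x$time),
              x$dt))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$time, x$state, check.names = FALSE)
}

#' Extract one state variable from a trajectory
#'
#' @param traj A trajectory.
#' @param var Variable name.
#' @return Numeric vector.
#' @export
traj_var <- function(traj, var) {
  stopifnot(inherits(traj, "trajectory"))
  if (!var %in% colnames(traj$state))
    stop("no state variable '", var, "' in trajectory", call. = FALSE)
  traj$state[, var]
}
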