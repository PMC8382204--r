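# first upward crossing time of `var` through `level` (linear interpolation)
first_crossing <- function(traj, var, level, after = -Inf) {
  s <- traj_var(traj, var); t <- traj$time
  idx <- which(s[-1L] > level & s[-length(s)] <= level & t[-1L] > after)
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  t[i] + (level - s[i]) / (s[i + 1L] - s[i]) * (t[i + 1L] - t[i])
}

all_crossings <- function(traj, var, level) {
  s <- traj_var(traj, var); t <- traj$time
  idx <- which(s[-1L] > level & s[-length(s)] <= level)
  t[idx] + (level - s[idx]) / (s[idx + 1L] - s[idx]) * (t[idx + 1L] - t[idx])
}

# reference (unperturbed) somatic run with onset bookkeeping
baseline_run <- function(params, t_span = c(0, 6000), dt = 2) {
  sys <- build_interlinked(params)
  traj <- integrate_system(sys, t_span = t_span, dt = dt)
  list(traj = traj,
       e2f_on = all_crossings(traj, "E2F", 0.95),
       apc_on = all_crossings(traj, "APC", 0.95))
}

#' Restriction-point scenario: reduce CycD synthesis after E2F activation
#'
#' Runs the somatic model with the CycD synthesis rate divided by
#' `reduction_factor` inside a time window that must start after the first
#' E2F activation of the unperturbed run (the classical restriction-point
#' experiment: growth-factor withdrawal after commitment). The run is
#' `completed` when APC/C still reaches its M-phase level (> 0.95) in the
#' started cycle.
#'
#' @param params A [somatic_params()] object.
#' @param reduction_factor Division factor for `d_syn` (default 10, the
#'   midpoint of the 4-20-fold CycD induction range under growth-factor
#'   stimulation).
#' @param window `c(t_start, t_end)` of the reduction, minutes.
#' @param t_span Simulation span (minutes).
#' @param dt Output step.
#' @return List with `traj`, `completed`, `baseline` bookkeeping.
#' @export
restriction_point_run <- function(params = somatic_params(),
                                  reduction_factor = 10, window,
                                  t_span = c(0, 6000), dt = 2) {
  base <- baseline_run(params, t_span, dt)
  if (!length(base$e2f_on))
    stop("unperturbed run never activates E2F in t_span", call. = FALSE)
  if (window[1L] <= base$e2f_on[1L])
    stop("window must start after the first E2F activation (t = ",
         signif(base$e2f_on[1L], 5), " min); an earlier window is a ",
         "different experiment", call. = FALSE)
  sched <- parameter_schedule(data.frame(
    t_start = window[1L], t_end = window[2L], param = "d_syn",
    value = 1 / reduction_factor, mode = "multiply"))
  sys <- apply_schedule(build_interlinked(params), sched)
  traj <- integrate_system(sys, t_span = t_span, dt = dt)
  # the started cycle: E2F activation preceding the window
  commit <- max(base$e2f_on[base$e2f_on < window[1L]])
  apc_after <- first_crossing(traj, "APC", 0.95, after = commit)
  completed <- is.finite(apc_after)
  list(traj = traj, completed = completed,
       commit_time = commit, apc_time = apc_after, baseline = base)
}

#' DNA damage in G1: transiently increased basal CycD degradation
#'
#' Multiplies the basal degradation offset `delta_d` by `delta_d_factor`
#' inside the window (damage present), which holds CycD below the E2F
#' activation threshold until repair. Interphase elongation is the
#' increase, relative to baseline, of the interval between the successive
#' APC/C activation onsets that bracket the damage window.
#'
#' @param params A [somatic_params()] object.
#' @param delta_d_factor Multiplier on `delta_d` (default 3).
#' @param window Damage window `c(t_start, t_end)`, minutes.
#' @param t_span,dt Simulation settings.
#' @return List with `traj`, `elongation` (minutes), `baseline`.
#' @export
dna_damage_g1 <- function(params = somatic_params(), delta_d_factor = 3,
                          window, t_span = c(0, 8000), dt = 2) {
  base <- baseline_run(params, t_span, dt)
  if (window[2L] <= window[1L])
    return(list(traj = base$traj, elongation = 0, baseline = base))
  sched <- parameter_schedule(data.frame(
    t_start = window[1L], t_end = window[2L], param = "delta_d",
    value = delta_d_factor, mode = "multiply"))
  sys <- apply_schedule(build_interlinked(params), sched)
  traj <- integrate_system(sys, t_span = t_span, dt = dt)
  elong <- cycle_elongation(base, traj, window)
  list(traj = traj, elongation = elong, baseline = base)
}

#' DNA damage in G2: transiently widened Cdk1 switch
#'
#' Sets the Cdk1-switch bend parameter to `alpha_damage` inside the window
#' (Wee1 active: the Cdk1 activation threshold shifts to higher CycB
#' levels). Reports the CycB level at Cdk1 activation — activation taken
#' as the upward crossing of Cdk1/CycB through 0.5 — and the interphase
#' elongation relative to baseline; elongation is zero when the damage is
#' repaired before CycB reaches the unperturbed activation threshold.
#'
#' @param params A [somatic_params()] object.
#' @param alpha_damage Bend strength during damage (default 30, chosen
#'   so the standing CycB level sits below the shifted threshold).
#' @param window Damage window `c(t_start, t_end)`, minutes.
#' @param t_span,dt Simulation settings.
#' @return List with `traj`, `elongation` (minutes), `mitotic_cycb`,
#'   `baseline_mitotic_cycb`, `baseline`.
#' @export
dna_damage_g2 <- function(params = somatic_params(), alpha_damage = 30,
                          window, t_span = c(0, 8000), dt = 2) {
  # the widened switch must keep a positive activation branch: xi > 0 on
  # the lower-branch outputs (large alpha may push xi negative at mid
  # outputs, which the dynamics never dwell on, so only the activation
  # side is constrained)
  if (alpha_damage < 0)
    stop("alpha_damage must be >= 0", call. = FALSE)
  ylo <- seq(0, 0.5, length.out = 501L)
  if (min(1 + alpha_damage * ylo * (ylo - 1) * (ylo - params$r)) <= 0)
    stop("alpha_damage destroys the activation branch (non-positive ",
         "scaled threshold on the lower branch)", call. = FALSE)
  base <- baseline_run(params, t_span, dt)
  sched <- parameter_schedule(data.frame(
    t_start = window[1L], t_end = window[2L], param = "alpha_cdk",
    value = alpha_damage, mode = "set"))
  sys <- apply_schedule(build_interlinked(params), sched)
  traj <- integrate_system(sys, t_span = t_span, dt = dt)
  mito <- cycb_at_cdk_activation(traj, after = window[1L])
  mito_base <- cycb_at_cdk_activation(base$traj, after = window[1L])
  elong <- cycle_elongation(base, traj, window)
  list(traj = traj, elongation = elong, mitotic_cycb = mito,
       baseline_mitotic_cycb = mito_base, baseline = base)
}

cycb_at_cdk_activation <- function(traj, after = -Inf) {
  ratio <- traj$state[, "Cdk1"] / pmax(traj$state[, "CycB"], 1e-12)
  rt <- list(time = traj$time,
             state = cbind(ratio = ratio, CycB = traj$state[, "CycB"]),
             system = traj$system)
  class(rt) <- "trajectory"
  t_act <- first_crossing(rt, "ratio", 0.5, after = after)
  if (!is.finite(t_act)) return(NA_real_)
  stats::approx(traj$time, traj$state[, "CycB"], xout = t_act)$y
}

# elongation of the cycle containing the perturbation window: perturbed
# and baseline runs share their history up to the window start, so the
# elongation is the delay of the next APC/C activation onset relative to
# baseline
cycle_elongation <- function(base, traj, window) {
  apc_on <- all_crossings(traj, "APC", 0.95)
  b_on <- base$apc_on
  nxt_b <- b_on[b_on > window[1L]]
  if (!length(nxt_b)) return(NA_real_)
  nxt_p <- apc_on[apc_on > window[1L]]
  if (!length(nxt_p)) return(Inf)  # arrest within the simulated span
  nxt_p[1L] - nxt_b[1L]
}

#' Simulate the circadian-forced somatic cell cycle
#'
#' Integrates the interlinked model with the Cdk1-switch bend parameter
#' driven sinusoidally between its basal level and `alpha_cdk + 2 A_cdk`.
#' With `A_cdk = 0` the trajectory equals the autonomous model's.
#'
#' @param params A [somatic_params()] object.
#' @param forcing A [forcing_spec()].
#' @param t_span Simulation span (minutes).
#' @param dt Output step (minutes).
#' @return A trajectory.
#' @export
circadian_run <- function(params = somatic_params(), forcing,
                          t_span, dt = 2) {
  stopifnot(inherits(forcing, "forcing_spec"))
  sys <- build_interlinked(params, forcing = forcing)
  integrate_system(sys, t_span = t_span, dt = dt)
}

#' Tune the unforced cell-cycle period via the CycD synthesis rate
#'
#' Secant search on `d_syn` (all other parameters at their defaults) until
#' the autonomous period matches `target_h` hours within `tol` (relative).
#' The CycD synthesis rate is the somatic model's primary period knob: it
#' sets how fast CycD reaches the E2F activation threshold and thereby the
#' G1 duration.
#'
#' @param target_h Target period in hours.
#' @param params Base [somatic_params()].
#' @param tol Relative period tolerance (default 0.01).
#' @param n_periods Number of target periods to simulate per evaluation.
#' @param max_iter Secant iteration cap.
#' @return List with `params` (tuned), `d_syn`, `period_h` (achieved).
#' @export
tune_natural_period <- function(target_h, params = somatic_params(),
                                tol = 0.01, n_periods = 16, max_iter = 12L) {
  period_h_at <- function(d_syn) {
    p <- params; p$d_syn <- d_syn
    sys <- build_interlinked(p)
    tmax <- n_periods * target_h * 60
    traj <- integrate_system(sys, t_span = c(0, tmax), dt = tmax / 12000)
    om <- oscillation_metrics(traj, var = "APC")
    if (!om$sustained)
      stop("model does not oscillate at d_syn = ", d_syn, call. = FALSE)
    om$period / 60
  }
  # warm start from the default-period scaling (period ~ 1/d_syn)
  d1 <- params$d_syn * 23.5 / target_h
  d2 <- d1 * 1.1
  f1 <- period_h_at(d1) - target_h
  f2 <- period_h_at(d2) - target_h
  for (i in seq_len(max_iter)) {
    if (abs(f2) < tol * target_h) break
    d3 <- d2 - f2 * (d2 - d1) / (f2 - f1)
    d3 <- max(d3, 1e-4)
    d1 <- d2; f1 <- f2
    d2 <- d3; f2 <- period_h_at(d3) - target_h
  }
  p <- params; p$d_syn <- d2
  list(params = p, d_syn = d2, period_h = target_h + f2)
}

#' Detect p:q phase locking from a forced trajectory
#'
#' Finds a repeating pattern in the forced Cdk1 series by comparing the
#' post-transient series with time-shifted copies of itself (akin to an
#' autocorrelation): the repeat period is the smallest shift whose
#' normalized RMS mismatch falls below `mismatch_tol`. The ratio of repeat
#' period to forcing period is matched against integers q in
#' `1..qmax` within `ratio_tol`; p is the number of Cdk1 peaks inside one
#' repeat window, so the locked cell-cycle period is `repeat_period / p`.
#' Quasiperiodic or drifting trajectories yield no qualifying shift and
#' are reported unlocked.
#'
#' @param traj Forced trajectory (spanning at least `min_span_periods`
#'   forcing periods).
#' @param forcing The [forcing_spec()] used for the run.
#' @param var Series to analyze (default `"Cdk1"`).
#' @param transient_frac Fraction of the span discarded (default 0.5).
#' @param mismatch_tol Normalized RMS threshold (default 0.01).
#' @param ratio_tol Relative tolerance on the period ratio (default 0.02).
#' @param qmax Largest q considered (default 5).
#' @param min_span_periods Required trajectory span in forcing periods
#'   (default 40).
#' @return Object of class `locking_result`: `locked`, `p`, `q`,
#'   `repeat_period`, `cell_period` (both in the trajectory time unit),
#'   `mismatch`, `forcing_period`.
#' @export
detect_locking <- function(traj, forcing, var = "Cdk1",
                           transient_frac = 0.5, mismatch_tol = 0.01,
                           ratio_tol = 0.02, qmax = 5L,
                           min_span_periods = 40) {
  stopifnot(inherits(forcing, "forcing_spec"))
  Tf <- forcing$period_min
  t <- traj$time
  span <- t[length(t)] - t[1L]
  if (span < min_span_periods * Tf)
    stop("trajectory spans only ", signif(span / Tf, 4),
         " forcing periods; >= ", min_span_periods, " required",
         call. = FALSE)
  s <- traj_var(traj, var)
  keep <- t >= t[1L] + transient_frac * span
  t <- t[keep]; s <- s[keep]
  dt <- t[2L] - t[1L]
  rng <- diff(range(s))
  if (rng <= 0)
    return(structure(list(locked = FALSE, p = NA_integer_,
                          q = NA_integer_, repeat_period = NA_real_,
                          cell_period = NA_real_, mismatch = NA_real_,
                          forcing_period = Tf), class = "locking_result"))
  s0 <- (s - mean(s)) / rng
  shifts <- seq(0.25 * Tf, (qmax + 0.25) * Tf, by = dt)
  best_shift <- NA_real_; best_mis <- NA_real_
  for (sh in shifts) {
    k <- round(sh / dt)
    nlen <- length(s0) - k
    if (nlen < round(2 * Tf / dt)) break
    mis <- sqrt(mean((s0[seq_len(nlen)] - s0[k + seq_len(nlen)])^2))
    if (mis < mismatch_tol) {
      # walk down to the local mismatch minimum for an unbiased period
      repeat {
        k2 <- k + 1L
        nlen2 <- length(s0) - k2
        if (nlen2 < round(2 * Tf / dt)) break
        mis2 <- sqrt(mean((s0[seq_len(nlen2)] - s0[k2 + seq_len(nlen2)])^2))
        if (mis2 >= mis) break
        k <- k2; mis <- mis2
      }
      best_shift <- k * dt; best_mis <- mis
      break
    }
  }
  if (!is.finite(best_shift))
    return(structure(list(locked = FALSE, p = NA_integer_,
                          q = NA_integer_, repeat_period = NA_real_,
                          cell_period = NA_real_, mismatch = NA_real_,
                          forcing_period = Tf), class = "locking_result"))
  qr <- best_shift / Tf
  qi <- as.integer(round(qr))
  locked <- qi >= 1L && qi <= qmax && abs(qr - qi) / qi <= ratio_tol
  pp <- NA_integer_
  if (locked) {
    win <- s[t <= t[1L] + best_shift + dt / 2]
    ex <- local_extrema(win)
    pk <- ex$max[win[ex$max] > min(s) + 0.5 * rng]
    pp <- max(length(pk), 1L)
  }
  structure(list(locked = locked, p = pp, q = if (locked) qi else NA_integer_,
                 repeat_period = best_shift,
                 cell_period = if (locked) best_shift / pp else NA_real_,
                 mismatch = best_mis, forcing_period = Tf),
            class = "locking_result")
}

#' @export
print.locking_result <- function(x, ...) {
  if (x$locked)
    cat(sprintf("<locking> %d:%d, cell-cycle period %g (forcing %g)\n",
                x$p, x$q, x$cell_period, x$forcing_period))
  else cat("<locking> unlocked\n")
  invisible(x)
}

#' Scan coupling strengths for a locked cell cycle
#'
#' Runs the forced somatic model over a ladder of coupling amplitudes and
#' returns the first (and all) locking results. Used for the
#' frequency-locking experiments where the natural period is tuned first
#' and the coupling strength is unknown.
#'
#' @param params Tuned [somatic_params()].
#' @param natural_period_h Unforced period (hours) used for the
#'   above-natural filter.
#' @param A_values Coupling-amplitude ladder.
#' @param forcing_period_h Forcing period in hours (default 24).
#' @param n_periods Forcing periods per run (default 40).
#' @param require_above_natural Keep only locks whose cell-cycle period
#'   exceeds the natural period by > 2%.
#' @param dt Output step (minutes).
#' @return List with `locked_period_h` (first qualifying lock; `NA` if
#'   none), `A_locked`, and `results` (one [detect_locking()] record per
#'   amplitude, named by amplitude).
#' @export
scan_locking <- function(params, natural_period_h,
                         A_values = c(2, 5, 10, 15, 20, 30, 40),
                         forcing_period_h = 24, n_periods = 40,
                         require_above_natural = TRUE, dt = 2) {
  results <- list()
  locked_period_h <- NA_real_; A_locked <- NA_real_
  for (A in A_values) {
    fs <- forcing_spec(A, period_h = forcing_period_h)
    traj <- circadian_run(params, fs,
                          t_span = c(0, n_periods * fs$period_min),
                          dt = dt)
    lk <- detect_locking(traj, fs, min_span_periods = n_periods)
    results[[as.character(A)]] <- lk
    ok <- lk$locked &&
      (!require_above_natural ||
         lk$cell_period / 60 > natural_period_h * 1.02)
    if (ok && !is.finite(locked_period_h)) {
      locked_period_h <- lk$cell_period / 60
      A_locked <- A
      break
    }
  }
  list(locked_period_h = locked_period_h, A_locked = A_locked,
       results = results)
}

#' Map p:q locking regions (Arnold tongues)
#'
#' Grid over the ratio of the natural cell-cycle frequency to the forcing
#' frequency and the coupling amplitude; each cell runs the forced model
#' and records the locking state. Cells where the unforced model does not
#' oscillate are marked not applicable.
#'
#' @param params [somatic_params()] whose unforced model oscillates.
#' @param ratio_values Values of \eqn{\omega_{cdk} / \omega_{circadian}}.
#' @param A_values Coupling amplitudes.
#' @param n_periods Forcing periods per run.
#' @param dt Output step (minutes).
#' @return Long-format data frame: `ratio`, `A_cdk`, `locked`, `p`, `q`,
#'   `cell_period_h`, `forcing_period_h`.
#' @export
arnold_map <- function(params = somatic_params(),
                       ratio_values = c(2 / 3, 1, 4 / 3),
                       A_values = c(0, 5, 15), n_periods = 40, dt = 2) {
  sys <- build_interlinked(params)
  base <- integrate_system(sys, t_span = c(0, 2e4), dt = 4)
  om <- oscillation_metrics(base, var = "Cdk1")
  if (!om$sustained)
    stop("unforced model does not oscillate; arnold_map not applicable",
         call. = FALSE)
  omega_cdk <- om$natural_frequency  # rad/min
  rows <- list()
  for (ratio in ratio_values) for (A in A_values) {
    omega_circ <- omega_cdk / ratio
    Tf_h <- 2 * pi / omega_circ / 60
    fs <- forcing_spec(A, period_h = Tf_h)
    lk <- tryCatch({
      traj <- circadian_run(params, fs,
                            t_span = c(0, n_periods * fs$period_min),
                            dt = dt)
      detect_locking(traj, fs, min_span_periods = n_periods)
    }, error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      ratio = ratio, A_cdk = A,
      locked = if (is.null(lk)) NA else lk$locked,
      p = if (is.null(lk)) NA_integer_ else lk$p,
      q = if (is.null(lk)) NA_integer_ else lk$q,
      cell_period_h = if (is.null(lk) || !lk$locked) NA_real_
        else lk$cell_period / 60,
      forcing_period_h = Tf_h)
  }
  out <- do.call(rbind, rows)
  attr(out, "natural_period_h") <- om$period / 60
  out
}
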