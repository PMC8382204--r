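# interior local maxima / minima indices of a series
local_extrema <- function(s) {
  d <- diff(s)
  sg <- sign(d)
  sg[sg == 0] <- 1
  chg <- diff(sg)
  list(max = which(chg == -2) + 1L, min = which(chg == 2) + 1L)
}

# parabolic refinement of an extremum position on a uniform grid
refine_peak <- function(t, s, i) {
  if (i <= 1L || i >= length(s)) return(t[i])
  denom <- s[i - 1L] - 2 * s[i] + s[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(t[i])
  dt <- t[2L] - t[1L]
  off <- 0.5 * (s[i - 1L] - s[i + 1L]) / denom * dt
  # plateau tops have a vanishing curvature estimate; stay on the grid
  if (!is.finite(off) || abs(off) > dt) off <- 0
  t[i] + off
}

#' Oscillation period, amplitude and regularity from a trajectory
#'
#' Discards an initial transient, locates interior local extrema of the
#' reference variable, and decides whether the oscillation is sustained:
#' at least `min_cycles` post-transient maxima whose heights stay within
#' `height_tol` (relative) of their median and whose amplitude exceeds `amp_tol` of
#' the variable's observed range. Damped or small-amplitude oscillations
#' fail these filters. The period is the mean inter-maximum interval
#' (parabolically refined peak times); the oscillation is `regular` when
#' the coefficient of variation of the intervals is below `cv_tol`.
#' Amplitudes are reported per state variable as max - min over the
#' post-transient window.
#'
#' @param traj A trajectory from [integrate_system()] (or any list with
#'   `time` and `state`).
#' @param var Reference variable for peak finding (default first column).
#' @param transient_frac Fraction of the span discarded as transient
#'   (default 0.5).
#' @param min_cycles Minimum number of post-transient maxima (default 5).
#' @param height_tol Relative peak-height variation allowed for a
#'   sustained call (default 0.01).
#' @param amp_tol Minimum amplitude as a fraction of the observed range
#'   (default 0.01).
#' @param cv_tol Coefficient-of-variation threshold for regularity
#'   (default 0.05).
#' @return Object of class `oscillation_summary`: `sustained`, `period`,
#'   `amplitude` (named vector), `regular`, `natural_frequency` (rad per
#'   time unit), `n_peaks`, `peak_times`.
#' @export
oscillation_metrics <- function(traj, var = NULL, transient_frac = 0.5,
                                min_cycles = 5L, height_tol = 0.01,
                                amp_tol = 0.01, cv_tol = 0.05) {
  t <- traj$time; st <- traj$state
  if (is.null(var)) var <- colnames(st)[1L]
  if (length(t) < 20L)
    stop("trajectory too short for oscillation analysis", call. = FALSE)
  keep <- t >= t[1L] + transient_frac * (t[length(t)] - t[1L])
  if (sum(keep) < 10L)
    stop("insufficient post-transient data", call. = FALSE)
  tt <- t[keep]; ss <- st[keep, , drop = FALSE]
  s <- ss[, var]
  full_range <- diff(range(st[, var]))
  ex <- local_extrema(s)
  # ignore numerically insignificant wiggles (e.g. round-off ripple on a
  # plateau): a countable peak must rise above a quarter of the observed
  # band
  if (length(ex$max))
    ex$max <- ex$max[s[ex$max] >= min(s) + 0.25 * diff(range(s))]
  amp <- apply(ss, 2L, function(x) diff(range(x)))
  not_sustained <- function() {
    structure(list(sustained = FALSE, period = NA_real_, amplitude = amp,
                   regular = FALSE, natural_frequency = NA_real_,
                   n_peaks = length(ex$max), peak_times = tt[ex$max],
                   var = var),
              class = "oscillation_summary")
  }
  if (length(ex$max) < min_cycles || full_range <= 0) return(not_sustained())
  # parabolic height refinement damps grid-sampling jitter on sharp peaks
  heights <- vapply(ex$max, function(i) {
    if (i <= 1L || i >= length(s)) return(s[i])
    denom <- s[i - 1L] - 2 * s[i] + s[i + 1L]
    if (abs(denom) < .Machine$double.eps) return(s[i])
    corr <- -(s[i - 1L] - s[i + 1L])^2 / (8 * denom)
    # refine only near-symmetric tops: a corner (steep rise onto a
    # plateau) is not locally parabolic and must not be extrapolated
    g1 <- abs(s[i] - s[i - 1L]); g2 <- abs(s[i] - s[i + 1L])
    if (!is.finite(corr) || min(g1, g2) < 0.25 * max(g1, g2) ||
        abs(corr) > min(g1, g2)) corr <- 0
    s[i] + corr
  }, numeric(1L))
  h_med <- stats::median(heights)
  h_spread <- max(abs(heights - h_med)) / max(abs(h_med), 1e-12)
  mins_after <- ex$min[ex$min > min(ex$max)]
  low <- if (length(mins_after)) stats::median(s[mins_after])
         else if (length(ex$min)) stats::median(s[ex$min]) else min(s)
  osc_amp <- stats::median(heights) - low
  if (h_spread > height_tol || osc_amp < amp_tol * full_range)
    return(not_sustained())
  pk <- vapply(ex$max, function(i) refine_peak(tt, s, i), numeric(1L))
  iv <- diff(pk)
  period <- mean(iv)
  cv <- stats::sd(iv) / period
  structure(list(sustained = TRUE, period = period, amplitude = amp,
                 regular = is.finite(cv) && cv < cv_tol,
                 natural_frequency = 2 * pi / period,
                 n_peaks = length(pk), peak_times = pk, var = var),
            class = "oscillation_summary")
}

#' @export
print.oscillation_summary <- function(x, ...) {
  if (x$sustained)
    cat(sprintf("<oscillation> sustained, period = %g (%s), %s, %d peaks\n",
                x$period, x$var,
                if (x$regular) "regular" else "irregular", x$n_peaks))
  else cat("<oscillation> not sustained\n")
  invisible(x)
}

#' Segment a somatic-cycle trajectory into cell-cycle phases
#'
#' Per-sample labels by activity thresholds: M phase wherever
#' `APC > 0.95`; G1 wherever `E2F < 0.95` and `APC < 0.95`; S/G2 wherever
#' `E2F > 0.95` and `APC < 0.95` (ties at exactly 0.95 resolve to G1).
#' Per-cycle phase durations are accumulated between successive G1 onsets.
#'
#' @param traj Trajectory with `E2F` and `APC` state variables.
#' @param threshold Activity threshold (default 0.95).
#' @return Object of class `phase_segmentation`: `labels` (factor per
#'   sample), `durations` (data frame with one row per complete cycle and
#'   columns `G1`, `SG2`, `M`, `period`).
#' @export
segment_phases <- function(traj, threshold = 0.95) {
  st <- traj$state
  if (!all(c("E2F", "APC") %in% colnames(st)))
    stop("phase segmentation needs E2F and APC state variables",
         call. = FALSE)
  e2f <- st[, "E2F"]; apc <- st[, "APC"]; t <- traj$time
  lab <- ifelse(apc > threshold, "M",
                ifelse(e2f > threshold, "SG2", "G1"))
  # complete cycles delimited by G1 onsets (M -> G1 transitions)
  onset <- which(lab[-1L] == "G1" & lab[-length(lab)] == "M") + 1L
  durations <- NULL
  if (length(onset) >= 2L) {
    dt <- c(diff(t), t[length(t)] - t[length(t) - 1L])
    for (k in seq_len(length(onset) - 1L)) {
      idx <- onset[k]:(onset[k + 1L] - 1L)
      durations <- rbind(durations, data.frame(
        G1 = sum(dt[idx][lab[idx] == "G1"]),
        SG2 = sum(dt[idx][lab[idx] == "SG2"]),
        M = sum(dt[idx][lab[idx] == "M"]),
        period = t[onset[k + 1L]] - t[onset[k]]))
    }
  }
  structure(list(labels = factor(lab, levels = c("G1", "SG2", "M")),
                 time = t, durations = durations),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation>", length(x$labels), "samples;",
      if (is.null(x$durations)) 0 else nrow(x$durations),
      "complete cycles\n")
  if (!is.null(x$durations)) print(utils::head(x$durations))
  invisible(x)
}

#' Two-parameter sweep of regime and oscillation metrics
#'
#' Evaluates a grid of systems built by `build_fn(v1, v2)` and collects the
#' regime label, period and per-variable amplitudes in a long-format data
#' frame. Cells whose construction or analysis fails are recorded with
#' regime `"Error"` rather than aborting the sweep; rows are independent of
#' evaluation order.
#'
#' @param build_fn `function(v1, v2)` returning a [model_system()].
#' @param axis1,axis2 Lists `list(name = <label>, values = <numeric>)`.
#' @param out_var Reference variable for oscillation metrics.
#' @param t_span,dt Simulation settings passed through to the classifier.
#' @param ... Passed to [classify_regime()].
#' @return Data frame with columns `axis1`, `axis2` (named after the axes),
#'   `regime`, `period`, and `amp_<var>` columns.
#' @export
sweep2d <- function(build_fn, axis1, axis2, out_var = "APC",
                    t_span = NULL, ...) {
  grid <- expand.grid(v1 = axis1$values, v2 = axis2$values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v1 <- grid$v1[i]; v2 <- grid$v2[i]
    res <- tryCatch({
      sys <- build_fn(v1, v2)
      lab <- classify_regime(sys, out_var = out_var, t_span = t_span, ...)
      om <- attr(lab, "oscillation")
      amps <- if (!is.null(om)) om$amplitude else
        stats::setNames(rep(NA_real_, length(sys$vars)), sys$vars)
      c(list(regime = as.character(lab),
             period = if (!is.null(om)) om$period else NA_real_),
        stats::setNames(as.list(amps), paste0("amp_", names(amps))))
    }, error = function(e) list(regime = "Error", period = NA_real_))
    c(stats::setNames(list(v1, v2), c(axis1$name, axis2$name)), res)
  })
  cols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols], check.names = FALSE)
  }))
  class(out) <- c("sweep_grid", class(out))
  out
}
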