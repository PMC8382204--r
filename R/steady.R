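# damped Newton iteration with a forward-difference Jacobian; small dense
# systems only
newton_solve <- function(f, x0, tol = 1e-12, maxit = 60L, lower = NULL,
                         upper = NULL) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (!all(is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    J <- num_jacobian(f, x, fx)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      if (!is.null(lower)) xn <- pmax(xn, lower)
      if (!is.null(upper)) xn <- pmin(xn, upper)
      fn <- f(xn)
      if (all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(fx)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    if (max(abs(xn - x)) < 1e-15) {
      x <- xn
      break
    }
    x <- xn
  }
  fx <- f(x)
  if (all(is.finite(fx)) && max(abs(fx)) < 1e-9) x else NULL
}

num_jacobian <- function(f, x, fx = f(x)) {
  n <- length(x); m <- length(fx)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - fx) / h
  }
  J
}

rhs_at <- function(system, state, t = 0) {
  y <- stats::setNames(as.numeric(state), system$vars)
  # for delayed systems this is the tau = 0 reduction: the lagged state
  # equals the current one (delays do not move equilibria)
  as.numeric(system$rhs(t, y, system$params, lag = function(tt) y))
}

#' Locate the steady states of a system
#'
#' Multi-start damped-Newton root finding of the right-hand side over a
#' deterministic grid spanning the system's state box, with duplicate
#' solutions merged. Stability is judged from the eigenvalues of a
#' numerically differentiated Jacobian: all real parts below `-stab_tol`
#' means stable, any real part above `stab_tol` unstable, otherwise
#' marginal. For delayed systems the equilibria of the `tau = 0` reduction
#' are reported (delays do not move equilibria) and the result is flagged.
#'
#' @param system A [model_system()].
#' @param n_starts Approximate number of Newton starts.
#' @param stab_tol Eigenvalue tolerance for the stability call.
#' @return Data frame (class `steady_states`) with one row per equilibrium:
#'   the state variables, `stability`, and `max_re` (largest eigenvalue
#'   real part). Attribute `delay_ignored` marks delayed systems.
#' @export
steady_states <- function(system, n_starts = 60L, stab_tol = 1e-8) {
  stopifnot(inherits(system, "model_system"))
  box <- system$state_box
  if (is.null(box))
    box <- stats::setNames(rep(list(c(0, 1)), length(system$vars)),
                           system$vars)
  nv <- length(system$vars)
  levels_per_dim <- max(2L, ceiling(n_starts^(1 / nv)))
  grids <- lapply(system$vars, function(v)
    seq(box[[v]][1L], box[[v]][2L], length.out = levels_per_dim + 2L)[
      seq_len(levels_per_dim) + 1L])
  starts <- as.matrix(expand.grid(grids))
  lower <- vapply(system$vars, function(v) box[[v]][1L], numeric(1L))
  upper <- vapply(system$vars, function(v) box[[v]][2L], numeric(1L))
  # allow roots slightly outside the seeding box
  span <- upper - lower
  lower2 <- lower - 0.05 * span; upper2 <- upper + 2 * span
  lower2[system$vars %in% system$starred] <- -0.001
  upper2[system$vars %in% system$starred] <- 1.001
  f <- function(x) rhs_at(system, x)
  scale <- pmax(span, 1e-6)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_solve(f, starts[i, ], lower = lower2, upper = upper2)
    if (is.null(r)) next
    dup <- any(vapply(roots, function(q) max(abs(q - r) / scale) < 1e-6,
                      logical(1L)))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots)) {
    res <- as.data.frame(matrix(numeric(0), 0, nv,
                                dimnames = list(NULL, system$vars)))
    res$stability <- character(0); res$max_re <- numeric(0)
  } else {
    st <- do.call(rbind, roots)
    colnames(st) <- system$vars
    stab <- character(nrow(st)); mre <- numeric(nrow(st))
    for (i in seq_len(nrow(st))) {
      J <- num_jacobian(f, st[i, ])
      re <- Re(eigen(J, only.values = TRUE)$values)
      mre[i] <- max(re)
      stab[i] <- if (max(re) < -stab_tol) "stable"
                 else if (max(re) > stab_tol) "unstable" else "marginal"
    }
    res <- data.frame(st, stability = stab, max_re = mre,
                      check.names = FALSE)
    res <- res[order(res[[1L]]), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "delay_ignored") <- isTRUE(system$has_delay)
  class(res) <- c("steady_states", class(res))
  res
}

#' Classify the dynamical regime of a system
#'
#' Combines [steady_states()] with probe simulations:
#' \describe{
#'   \item{`Bi`}{two or more stable equilibria (reported as `Bi+Osc` if a
#'     sustained limit cycle coexists with a stable equilibrium).}
#'   \item{`Osc`}{a sustained oscillation is found and no probe settles on
#'     a stable equilibrium.}
#'   \item{`MonoLow` / `MonoTop`}{a single stable equilibrium whose
#'     switch-output coordinate lies below the lower fold output / above
#'     the upper fold output of the reference switch response (below/above
#'     0.5 for a fold-less, purely ultrasensitive switch).}
#'   \item{`Irregular`}{sustained variation whose cycle-to-cycle intervals
#'     fail the regularity filter (intermittent branch-sticking).}
#' }
#'
#' @param system A [model_system()].
#' @param ref_module The [switch_module()] whose response curve supplies
#'   the fold outputs for the Mono labels; defaults to a module rebuilt
#'   from the system's APC/C-switch parameters.
#' @param out_var Name of the switch-output state variable (default
#'   `"APC"`).
#' @param probe_inits List of initial states; default low and high corners.
#' @param t_span Simulation span for the probes (system time units).
#' @param n_starts Newton starts for the steady-state search.
#' @param ... Passed to [oscillation_metrics()].
#' @return Character regime label with attributes `steady_states` and
#'   `oscillation`.
#' @export
classify_regime <- function(system, ref_module = NULL, out_var = "APC",
                            probe_inits = NULL, t_span = NULL,
                            n_starts = 60L, ...) {
  stopifnot(inherits(system, "model_system"))
  ss <- steady_states(system, n_starts = n_starts)
  stable <- ss[ss$stability == "stable", , drop = FALSE]
  p <- system$params
  if (is.null(ref_module))
    ref_module <- switch_module(
      K = p$K_apc %||% p$K_cdk_apc, n = p$n_apc %||% p$n,
      xi = scaling_function("cubic", p$alpha_apc, p$r),
      epsilon = p$eps_apc)
  if (is.null(t_span)) {
    tscale <- if (!is.null(p$b_deg)) 1 / p$b_deg else 1
    t_span <- c(0, 150 * tscale)
  }
  box <- system$state_box
  if (is.null(probe_inits)) {
    lo <- vapply(system$vars, function(v) box[[v]][1L], numeric(1L))
    hi <- vapply(system$vars, function(v) box[[v]][2L], numeric(1L))
    probe_inits <- list(lo + 0.01 * (hi - lo), lo + 0.6 * (hi - lo))
  }
  osc <- NULL; attracted <- FALSE; irregular <- FALSE
  for (ini in probe_inits) {
    traj <- integrate_system(system, init = ini, t_span = t_span,
                             dt = diff(t_span) / 8000)
    om <- tryCatch(oscillation_metrics(traj, var = out_var, ...),
                   error = function(e) NULL)
    if (!is.null(om) && om$sustained) {
      if (is.null(osc)) osc <- om
      if (!om$regular) irregular <- TRUE
      # without any stable equilibrium a sustained cycle settles the call
      if (nrow(stable) == 0L) break
    } else {
      fin <- traj$state[nrow(traj$state), ]
      if (nrow(stable) &&
          any(apply(stable[, system$vars, drop = FALSE], 1L, function(s)
            max(abs(as.numeric(s) - fin) /
                  pmax(abs(as.numeric(s)), 1e-3)) < 1e-2)))
        attracted <- TRUE
    }
  }
  label <-
    if (nrow(stable) >= 2L) {
      if (!is.null(osc)) "Bi+Osc" else "Bi"
    } else if (!is.null(osc) && !attracted) {
      if (irregular) "Irregular" else "Osc"
    } else if (nrow(stable) == 1L) {
      fa <- fold_analysis(ref_module, grid_n = 2000L, ytol = 1e-10)
      yout <- stable[[out_var]][1L]
      if (fa$bistable) {
        yf <- sort(fa$folds$output)
        if (yout < yf[1L]) "MonoLow" else if (yout > yf[2L]) "MonoTop"
        else "MonoMid"
      } else {
        if (yout < 0.5) "MonoLow" else "MonoTop"
      }
    } else "Irregular"
  attr(label, "steady_states") <- ss
  attr(label, "oscillation") <- osc
  label
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp one state variable of a system to a constant
#'
#' Returns a reduced system in which `var` is held at `value` (treated as
#' a parameter); used for clamped-input response curves and as the
#' multi-start oracle against continuation.
#'
#' @param system A [model_system()].
#' @param var State variable to clamp.
#' @param value Clamped value.
#' @return A [model_system()] over the remaining variables.
#' @export
clamp_system <- function(system, var, value) {
  iv <- match(var, system$vars)
  if (is.na(iv)) stop("unknown state variable '", var, "'", call. = FALSE)
  free <- setdiff(seq_along(system$vars), iv)
  parent_rhs <- system$rhs
  rhs <- function(t, y, p, lag = NULL) {
    yfull <- numeric(length(free) + 1L)
    yfull[iv] <- value; yfull[free] <- y
    parent_rhs(t, yfull, p)[free]
  }
  model_system(paste0(system$name, "_clamped_", var),
               system$vars[free], system$params, rhs,
               state_box = system$state_box[system$vars[free]],
               starred = intersect(system$starred, system$vars[free]))
}
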