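#' Trace a steady-state response curve by pseudo-arclength continuation
#'
#' Follows the solution branch of \eqn{F(u, \lambda) = 0} through folds,
#' where \eqn{\lambda} is the clamped input (e.g. Cdk1 for the mass-action
#' APC/C response) and \eqn{u} the remaining states at steady state. A
#' secant predictor and a Newton corrector on the arclength-augmented
#' system are used, with the step size adapted within
#' `[step_min, step_max]` (normalized units); folds are detected by sign
#' changes of the input direction along the arc.
#'
#' The method variants:
#' \describe{
#'   \item{`continuation_curve.switch_module`}{continues the scalar
#'     fixed-point equation of a phenomenological switch; the result
#'     coincides with the analytic [invert_response()] sweep.}
#'   \item{`continuation_curve.model_system`}{clamps `clamp_var` and
#'     continues the steady state of the remaining equations.}
#' }
#'
#' @param x A [switch_module()] or [model_system()].
#' @param ... Passed to methods.
#' @return Object of class `response_curve`: data frame `points` with
#'   columns `input`, `output` (plus auxiliary states), ordered along the
#'   arc, a `folds` data frame, and a `truncated` flag set when the step
#'   size underflows before the input range is exhausted.
#' @export
continuation_curve <- function(x, ...) UseMethod("continuation_curve")

#' @rdname continuation_curve
#' @param input_range Length-2 range of the clamped input.
#' @param output_var Name of the reported output state.
#' @param step_min,step_max Normalized arclength step bounds.
#' @param max_points Hard cap on curve points.
#' @export
continuation_curve.model_system <- function(x, clamp_var, input_range,
                                            output_var = "APC",
                                            step_min = 1e-4,
                                            step_max = 1e-1,
                                            max_points = 5000L, ...) {
  system <- x
  iv <- match(clamp_var, system$vars)
  if (is.na(iv)) stop("unknown clamp variable", call. = FALSE)
  free <- setdiff(seq_along(system$vars), iv)
  Ffun <- function(u, lambda) {
    y <- numeric(length(system$vars))
    y[iv] <- lambda; y[free] <- u
    rhs_at(system, y)[free]
  }
  # initial point: solve at the left end from a low start
  box <- system$state_box
  u0 <- vapply(system$vars[free], function(v) box[[v]][1L], numeric(1L))
  scale_u <- vapply(system$vars[free], function(v) diff(box[[v]]),
                    numeric(1L))
  run_continuation(Ffun, u0, input_range, scale_u,
                   out_index = match(output_var, system$vars[free]),
                   aux_names = system$vars[free],
                   step_min = step_min, step_max = step_max,
                   max_points = max_points)
}

#' @rdname continuation_curve
#' @param clamp_var (model_system method) name of the clamped state.
#' @export
continuation_curve.switch_module <- function(x, input_range = NULL,
                                             step_min = 1e-4,
                                             step_max = 1e-1,
                                             max_points = 5000L, ...) {
  module <- x
  if (is.null(input_range)) input_range <- c(0, 3 * module$K)
  Ffun <- function(u, lambda) {
    module$correction * lambda^module$n /
      ((xi_eval(module$xi, u) * module$K)^module$n + lambda^module$n) - u
  }
  run_continuation(Ffun, 0, input_range, 1,
                   out_index = 1L, aux_names = "output",
                   step_min = step_min, step_max = step_max,
                   max_points = max_points)
}

run_continuation <- function(Ffun, u0, input_range, scale_u, out_index,
                             aux_names, step_min, step_max, max_points) {
  lam0 <- input_range[1L]; lam1 <- input_range[2L]
  scale_l <- abs(lam1 - lam0)
  solve_at <- function(u_init, lambda)
    newton_solve(function(u) Ffun(u, lambda), u_init)
  u <- solve_at(u0, lam0)
  if (is.null(u)) stop("continuation failed to locate the starting point",
                       call. = FALSE)
  pts <- list(c(lam0, u))
  # second point: small parameter step
  dl <- step_max / 10 * scale_l
  u2 <- solve_at(u, lam0 + dl)
  while (is.null(u2) && dl > 1e-12 * scale_l) {
    dl <- dl / 2
    u2 <- solve_at(u, lam0 + dl)
  }
  if (is.null(u2)) stop("continuation failed on the first step",
                        call. = FALSE)
  pts[[2L]] <- c(lam0 + dl, u2)
  h <- step_max / 5
  truncated <- FALSE
  norm_vec <- function(v) c(v[1L] / scale_l, v[-1L] / scale_u)
  for (k in 3:max_points) {
    a <- pts[[length(pts) - 1L]]; b <- pts[[length(pts)]]
    tan_n <- norm_vec(b - a)
    tan_n <- tan_n / sqrt(sum(tan_n^2))
    ok <- FALSE
    while (!ok) {
      pred <- c(b[1L] + h * scale_l * tan_n[1L],
                b[-1L] + h * scale_u * tan_n[-1L])
      # corrector: Newton on F augmented with the arclength condition
      g <- function(z) {
        zn <- norm_vec(z - b)
        c(Ffun(z[-1L], z[1L]), sum(zn * tan_n) - h)
      }
      sol <- newton_solve(g, pred)
      if (!is.null(sol)) {
        ok <- TRUE
      } else {
        h <- h / 2
        if (h < step_min) { truncated <- TRUE; break }
      }
    }
    if (!ok) break
    pts[[length(pts) + 1L]] <- sol
    h <- min(h * 1.3, step_max)
    if (sol[1L] > max(lam0, lam1) || sol[1L] < min(lam0, lam1) - 1e-12)
      break
  }
  mat <- do.call(rbind, pts)
  colnames(mat) <- c("input", aux_names)
  pts_df <- as.data.frame(mat)
  pts_df$output <- pts_df[[aux_names[out_index]]]
  # folds: sign change of the input direction along the arc
  dlam <- diff(pts_df$input)
  sg <- sign(dlam); sg[sg == 0] <- 1
  fold_idx <- which(diff(sg) != 0) + 1L
  folds <- pts_df[fold_idx, c("input", "output"), drop = FALSE]
  # parabolic refinement of each fold along the arc (input is locally
  # quadratic in arc index at a fold)
  for (k in seq_along(fold_idx)) {
    i <- fold_idx[k]
    if (i <= 1L || i >= nrow(pts_df)) next
    li <- pts_df$input[(i - 1L):(i + 1L)]
    denom <- li[1L] - 2 * li[2L] + li[3L]
    if (abs(denom) < .Machine$double.eps) next
    dstar <- 0.5 * (li[1L] - li[3L]) / denom
    folds$input[k] <- li[2L] - 0.25 * (li[1L] - li[3L]) * dstar
    lo <- pts_df$output[(i - 1L):(i + 1L)]
    folds$output[k] <- lo[2L] +
      0.5 * dstar * (lo[3L] - lo[1L]) +
      0.5 * dstar^2 * (lo[1L] - 2 * lo[2L] + lo[3L])
  }
  rownames(folds) <- NULL
  # branch segmentation between folds
  seg <- cumsum(c(1L, as.integer(diff(sg) != 0)))
  pts_df$branch_id <- c(seg[1L], seg)
  structure(list(points = pts_df, folds = folds, truncated = truncated),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %d points, %d fold(s)%s\n",
              nrow(x$points), nrow(x$folds),
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Analytic steady-state response sweep of a switch module
#'
#' The exact multivalued response obtained by sweeping the output and
#' applying [invert_response()]; the reference against which the numerical
#' continuation is checked.
#'
#' @param module A [switch_module()].
#' @param n_points Number of output samples.
#' @return A `response_curve` object (no `branch_id`).
#' @export
switch_response_curve <- function(module, n_points = 400L) {
  cc <- module$correction
  y <- seq(cc * 1e-4, cc * (1 - 1e-4), length.out = n_points)
  x <- invert_response(y, module)
  fa <- fold_analysis(module, grid_n = 2000L, ytol = 1e-10)
  structure(list(points = data.frame(input = x, output = y),
                 folds = fa$folds[fa$folds$input > 0, , drop = FALSE],
                 truncated = FALSE),
            class = "response_curve")
}

#' Number of steady-state branches covering an input value
#'
#' Counts how many monotone arcs of a continuation curve span the given
#' clamped input — i.e. the number of coexisting steady states there.
#'
#' @param curve A `response_curve` with `branch_id`.
#' @param input Clamped input value(s).
#' @return Integer count per input.
#' @export
curve_branch_count <- function(curve, input) {
  pts <- curve$points
  if (is.null(pts$branch_id)) pts$branch_id <- 1L
  vapply(input, function(x0) {
    n <- 0L
    for (b in unique(pts$branch_id)) {
      rng <- range(pts$input[pts$branch_id == b])
      if (x0 >= rng[1L] && x0 <= rng[2L]) n <- n + 1L
    }
    n
  }, integer(1L))
}
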