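#' Fit a piecewise-linear scaling function to a steady-state response curve
#'
#' Given a tabulated (possibly multivalued) steady-state input/output curve
#' — e.g. the APC/C response of the mass-action PP2A-ENSA-GWL model, or an
#' experimentally measured S-curve — estimate the parameters
#' `(x_max, x_min, xi_max, xi_min)` of a piecewise-linear scaling function
#' plus a multiplicative `correction` on the Hill term, such that the
#' inverted response of the fitted module matches the target curve.
#'
#' The objective is the sum of squared input-axis (horizontal) residuals
#' between `invert_response()` of the candidate module and the target
#' points, minimized by derivative-free Nelder-Mead from a moment-based
#' initial guess (an empirical \eqn{\xi} profile computed point-wise from
#' the target). Horizontal residuals match how branch positions are
#' compared visually; the choice of a least-squares criterion is this
#' package's own (any deterministic criterion is acceptable for what is, in
#' origin, a by-eye fit).
#'
#' @param curve Data frame with columns `input` and `output` (output
#'   normalized to \eqn{[0, 1)}); a `branch` column is allowed and ignored.
#' @param n Hill exponent of the fitted module (the mass-action fit uses
#'   `n = 5`).
#' @param K Threshold of the fitted module (default 1, non-dimensional).
#' @param fit_correction If `FALSE` the correction is pinned at 1.
#' @return List with `xi` (a piecewise [scaling_function()], or a cubic
#'   `alpha = 0` function when the fit degenerates), `correction`,
#'   `residual` (root-mean-square input-axis residual), `degenerate`
#'   (`TRUE`, with a warning, when the target is monostable and the fitted
#'   bend is negligible), and `par` (the raw parameter vector).
#' @export
fit_piecewise_xi <- function(curve, n, K = 1, fit_correction = TRUE) {
  curve <- as.data.frame(curve)
  if (!all(c("input", "output") %in% names(curve)))
    stop("`curve` needs columns `input` and `output`", call. = FALSE)
  x <- as.numeric(curve$input); y <- as.numeric(curve$output)
  keep <- is.finite(x) & is.finite(y) & y > 1e-6 & y < 1 - 1e-9 & x > 0
  x <- x[keep]; y <- y[keep]
  if (length(y) < 8L) stop("too few usable curve points", call. = FALSE)

  # moment-based initial guess: empirical xi profile at a provisional
  # correction, extrema of the profile locate the breakpoints
  corr0 <- if (fit_correction) min(1, max(y) + 0.02) else 1
  emp <- function(corr) x / (K * (y / (corr - y))^(1 / n))
  e0 <- emp(corr0)
  lo_half <- y < stats::median(y); hi_half <- !lo_half
  i_max <- which.max(replace(e0, hi_half, -Inf))
  i_min <- which.min(replace(e0, lo_half, Inf))
  p0 <- c(x_max = min(max(y[i_max], 0.05), 0.45),
          x_min = min(max(y[i_min], 0.55), 0.95),
          xi_max = max(e0[i_max], 1.001),
          xi_min = min(e0[i_min], 0.999),
          correction = corr0)

  obj <- function(p) {
    xmx <- p[1L]; xmn <- p[2L]; ximx <- p[3L]; ximn <- p[4L]
    corr <- if (fit_correction) p[5L] else 1
    if (xmx <= 0.01 || xmn >= 0.99 || xmx >= xmn - 0.01 ||
        ximx < 1 || ximn > 1 || ximn <= 0.05 ||
        corr <= max(y) + 1e-9 || corr > 1)
      return(1e6)
    s1 <- (ximx - 1) / xmx
    s2 <- (ximn - ximx) / (xmn - xmx)
    s3 <- (1 - ximn) / (1 - xmn)
    xiv <- ifelse(y <= xmx, s1 * y + 1,
                  ifelse(y <= xmn, s2 * (y - xmx) + ximx,
                         s3 * (y - xmn) + ximn))
    xhat <- xiv * K * (y / (corr - y))^(1 / n)
    sum((xhat - x)^2)
  }
  par0 <- if (fit_correction) p0 else p0[1:4]
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  p <- fit$par
  corr <- if (fit_correction) unname(p[5L]) else 1
  rms <- sqrt(fit$value / length(y))

  degenerate <- (p[3L] - 1) < 0.005 && (1 - p[4L]) < 0.005
  if (degenerate) {
    warning("target curve appears monostable; returning xi == 1",
            call. = FALSE)
    xi <- scaling_function("cubic", 0)
  } else {
    xi <- scaling_function("piecewise", x_max = unname(p[1L]),
                           x_min = unname(p[2L]), xi_max = unname(p[3L]),
                           xi_min = unname(p[4L]))
  }
  list(xi = xi, correction = corr, residual = rms,
       degenerate = degenerate, par = p)
}
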