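#' Hill response
#'
#' The ultrasensitive module: \eqn{\mathrm{Out} = In^n / (K^n + In^n)}.
#'
#' @param input Non-negative input concentration(s).
#' @param K Activation threshold (> 0), same units as `input`.
#' @param n Hill exponent (>= 1); larger `n` gives a steeper response.
#' @return Fraction(s) in \eqn{[0, 1]}, monotone increasing in `input`.
#' @examples
#' hill_response(20, K = 20, n = 15)  # 0.5 at the threshold
#' @export
hill_response <- function(input, K, n) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0)
    stop("`K` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single number >= 1", call. = FALSE)
  if (any(input < 0)) stop("`input` must be non-negative", call. = FALSE)
  xn <- (input / K)^n
  xn / (1 + xn)
}

#' One input-output switch module
#'
#' Bundles the parameters of a single functional module: the activation
#' threshold `K`, Hill exponent `n`, the scaling function `xi` bending the
#' threshold (use `alpha = 0` / the default for a purely ultrasensitive
#' module), the relaxation time constant `epsilon` of the associated ODE
#' \eqn{\epsilon\, d\mathrm{Out}/dt = H(\mathrm{In}; \xi(\mathrm{Out}) K, n) -
#' \mathrm{Out}}, an optional multiplicative `correction` on the Hill term
#' (0.95 is used when matching the mass-action response curve), the
#' `multiply_by_input` flag of the CycB-to-Cdk1 switch whose output is a
#' concentration rather than a fraction, and an optional delay specification.
#'
#' @param K Activation threshold (> 0, typically nM).
#' @param n Hill exponent (>= 1), default 15.
#' @param xi A [scaling_function()]; default cubic with `alpha = 0`.
#' @param epsilon Relaxation time constant (> 0). In the non-dimensional
#'   systems the product \eqn{\epsilon^* = \epsilon\, b_{deg}} defaults to
#'   0.01.
#' @param multiply_by_input Logical; if `TRUE` the Hill term is multiplied by
#'   the input so the steady output is a concentration (CycB -> Cdk1 switch).
#' @param correction Multiplier on the Hill term, in (0, 1]; default 1.
#' @param delay Optional [delay_spec()].
#' @return An object of class `switch_module`.
#' @export
switch_module <- function(K, n = 15, xi = scaling_function("cubic", 0),
                          epsilon = 0.1, multiply_by_input = FALSE,
                          correction = 1, delay = NULL) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0)
    stop("`K` must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  if (!inherits(xi, "scaling_fn"))
    stop("`xi` must be a scaling_function()", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("`epsilon` must be positive", call. = FALSE)
  if (!is.numeric(correction) || correction <= 0 || correction > 1)
    stop("`correction` must lie in (0, 1]", call. = FALSE)
  if (!is.null(delay) && !inherits(delay, "delay_spec"))
    stop("`delay` must be a delay_spec()", call. = FALSE)
  structure(list(K = K, n = n, xi = xi, epsilon = epsilon,
                 multiply_by_input = isTRUE(multiply_by_input),
                 correction = correction, delay = delay),
            class = "switch_module")
}

#' @export
print.switch_module <- function(x, ...) {
  cat(sprintf("<switch_module> K = %g, n = %g, epsilon = %g, correction = %g\n",
              x$K, x$n, x$epsilon, x$correction))
  cat("  xi: "); print(x$xi)
  if (x$multiply_by_input) cat("  output scaled by input (concentration out)\n")
  if (!is.null(x$delay))
    cat(sprintf("  delay: tau1 = %g, tau2 = %g, p = %g\n",
                x$delay$tau1, x$delay$tau2, x$delay$p))
  invisible(x)
}

#' Invert an S-shaped response
#'
#' The S-shaped steady-state relation \eqn{y = c\, x^n / ((\xi(y) K)^n + x^n)}
#' is single-valued in the other direction: for each output fraction `y`
#' there is exactly one input \eqn{x = \xi(y)\, K\, (y / (c - y))^{1/n}}
#' (with `c` the module's correction factor, 1 by default). Sweeping `y`
#' traces the full S-curve, including the unstable middle branch.
#'
#' @param y Output fraction(s), strictly inside (0, correction).
#' @param module A [switch_module()].
#' @return Input value(s) on the input axis of the module.
#' @export
invert_response <- function(y, module) {
  stopifnot(inherits(module, "switch_module"))
  cc <- module$correction
  if (any(y <= 0) || any(y >= cc))
    stop("`y` must lie strictly inside (0, ", cc,
         ") (the inverse is 0 at 0 and diverges at the correction level)",
         call. = FALSE)
  xi_eval(module$xi, y) * module$K * (y / (cc - y))^(1 / module$n)
}

#' Steady-state output values of a switch module
#'
#' Finds all fixed points \eqn{y \in [0, 1]} of
#' \eqn{y = c\, x^n / ((\xi(y) K)^n + x^n)} for a clamped input `x`.
#' Generically 1 or 3 solutions exist; they are labeled
#' `lower` / `middle` / `upper` by output ordering (a single solution is
#' labeled by its position relative to the fold outputs when the module is
#' bistable, else `lower`).
#'
#' @param module A [switch_module()].
#' @param input Clamped non-negative input value.
#' @param grid_n Number of bracketing grid points on \eqn{[0, 1]}.
#' @return Data frame with columns `output` and `branch`.
#' @export
steady_response_values <- function(module, input, grid_n = 2000L) {
  stopifnot(inherits(module, "switch_module"), input >= 0)
  g <- function(y)
    module$correction * input^module$n /
      ((xi_eval(module$xi, y) * module$K)^module$n + input^module$n) - y
  ys <- seq(0, 1, length.out = grid_n + 1L)
  gv <- vapply(ys, g, numeric(1L))
  roots <- ys[abs(gv) < 1e-14]
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    rt <- stats::uniroot(g, c(ys[i], ys[i + 1L]), tol = 1e-14)$root
    roots <- c(roots, rt)
  }
  roots <- sort(unique(round(roots, 12)))
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 1e-9)]
  branch <- rep("lower", length(roots))
  if (length(roots) == 3L) branch <- c("lower", "middle", "upper")
  if (length(roots) == 2L) branch <- c("lower", "upper")
  if (length(roots) == 1L) {
    fa <- fold_analysis(module)
    if (fa$bistable) {
      yf <- sort(fa$folds$output)
      branch <- if (roots > yf[2L]) "upper" else if (roots > yf[1L]) "middle"
                else "lower"
    }
  }
  data.frame(output = roots, branch = branch, stringsAsFactors = FALSE)
}

#' Fold points and width of an S-shaped response
#'
#' Locates the local extrema of the inverted response \eqn{x(y)} of a switch
#' module on \eqn{y \in (0, 1)}: the roots of \eqn{dx/dy}. The input-axis
#' distance between the two extrema is the width of the bistable region
#' (0 for a monostable / purely ultrasensitive module). Roots are bracketed
#' on a uniform grid and refined by bisection to `ytol` in `y`.
#'
#' If more than two sign changes of \eqn{dx/dy} are found, all folds are
#' reported and the result is flagged `non_canonical` (no silent truncation).
#'
#' @param module A [switch_module()].
#' @param grid_n Bracketing grid size (default 1e4).
#' @param ytol Bisection tolerance in `y` (default 1e-12).
#' @return An object of class `fold_analysis`: list with `width` (input
#'   units), `folds` (data frame `input`, `output`), `bistable`,
#'   `non_canonical`.
#' @export
fold_analysis <- function(module, grid_n = 1e4L, ytol = 1e-12) {
  stopifnot(inherits(module, "switch_module"))
  cc <- module$correction
  eps <- cc * 1e-7
  xfun <- function(y) invert_response(y, module)
  dx <- function(y) {
    h <- 1e-8 * cc
    (xfun(y + h) - xfun(y - h)) / (2 * h)
  }
  ys <- seq(eps * 2, cc - 2 * eps, length.out = grid_n)
  dv <- vapply(ys, dx, numeric(1L))
  sgn <- sign(dv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  folds <- NULL
  for (i in idx) {
    lo <- ys[i]; hi <- ys[i + 1L]
    flo <- dv[i]
    while (hi - lo > ytol) {
      mid <- (lo + hi) / 2
      fm <- dx(mid)
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    yr <- (lo + hi) / 2
    folds <- rbind(folds, data.frame(input = xfun(yr), output = yr))
  }
  if (is.null(folds))
    folds <- data.frame(input = numeric(0), output = numeric(0))
  pos <- folds[folds$input > 0, , drop = FALSE]
  non_canonical <- nrow(pos) > 2L
  bistable <- nrow(pos) == 2L
  width <- if (bistable) abs(diff(pos$input)) else
    if (non_canonical) abs(max(pos$input) - min(pos$input)) else 0
  structure(list(width = width, folds = folds, bistable = bistable,
                 non_canonical = non_canonical),
            class = "fold_analysis")
}

#' @export
print.fold_analysis <- function(x, ...) {
  cat(sprintf("<fold_analysis> width = %g, %s\n", x$width,
              if (x$bistable) "bistable" else
                if (x$non_canonical) "non-canonical (extra folds)" else
                  "monostable"))
  if (nrow(x$folds)) print(x$folds)
  invisible(x)
}

#' Convert a bend strength to the width of the bistable region
#'
#' Convenience wrapper for sweeps parameterized by width rather than by the
#' bend parameter `alpha`: builds the cubic-scaled module and measures the
#' input-axis distance between its folds. With `K = 1` the width is on the
#' non-dimensional input axis.
#'
#' @param alpha Bend strength(s).
#' @param K,n,r Module parameters (defaults: non-dimensional `K = 1`,
#'   `n = 15`, `r = 0.5`).
#' @return Width(s), same length as `alpha`.
#' @export
alpha_to_width <- function(alpha, K = 1, n = 15, r = 0.5) {
  vapply(alpha, function(a) {
    m <- switch_module(K = K, n = n, xi = scaling_function("cubic", a, r))
    fold_analysis(m, grid_n = 2000L, ytol = 1e-10)$width
  }, numeric(1L))
}

#' Inverse of [alpha_to_width()]: bend strength giving a requested width
#'
#' Solved by monotone bisection on `alpha`.
#'
#' @param width Requested width (>= 0) on the input axis.
#' @param K,n,r As in [alpha_to_width()].
#' @param alpha_max Upper bracket for the search.
#' @return Bend strength `alpha`.
#' @export
width_to_alpha <- function(width, K = 1, n = 15, r = 0.5, alpha_max = NULL) {
  # largest alpha keeping xi > 0 on [0, 1]
  yg <- seq(0, 1, length.out = 2001L)
  neg <- max(-yg * (yg - 1) * (yg - r))
  a_hi <- min(alpha_max %||% Inf, 0.999 / neg)
  w_hi <- alpha_to_width(a_hi, K, n, r)
  vapply(width, function(w) {
    if (w <= 0) return(0)
    if (w > w_hi)
      stop("requested width ", w, " exceeds the maximum ", signif(w_hi, 4),
           " attainable with a positive cubic scaling function",
           call. = FALSE)
    f <- function(a) alpha_to_width(a, K, n, r) - w
    stats::uniroot(f, c(1e-6, a_hi), tol = 1e-8)$root
  }, numeric(1L))
}
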