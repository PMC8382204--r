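#' Scaling functions for bending a Hill threshold into an S-shape
#'
#' A scaling function \eqn{\xi(y)} multiplies the threshold \eqn{K} of a Hill
#' response so that the steady-state input--output curve becomes S-shaped
#' (bistable) instead of merely ultrasensitive. Several functional forms are
#' supported:
#'
#' \describe{
#'   \item{`cubic`}{\eqn{\xi(y) = 1 + \alpha\, y (y - 1)(y - r)}. The default,
#'     analogous to the cubic nullcline of the FitzHugh--Nagumo oscillator.
#'     Anchored so that \eqn{\xi(0) = \xi(r) = \xi(1) = 1}; \eqn{\alpha}
#'     controls the width of the bistable region and \eqn{r} its asymmetry.}
#'   \item{`quadratic`}{\eqn{\xi(y) = 1 + \alpha (y - 1)(y - r)}.}
#'   \item{`linear`}{\eqn{\xi(y) = 1 - \alpha/(r - 1)\,(y - 1) + \alpha}.}
#'   \item{`piecewise`}{Three linear segments through
#'     \eqn{(0, 1)}, \eqn{(x_{max}, \xi_{max})}, \eqn{(x_{min}, \xi_{min})},
#'     \eqn{(1, 1)}, used when fitting a measured or mass-action response
#'     curve. Requires `x_max < x_min`, `xi_max >= 1`, `xi_min <= 1`.}
#'   \item{`tabulated`}{Monotone piecewise-cubic interpolation
#'     (`stats::splinefun`, method `"monoH.FC"`) of a user-supplied
#'     `(y, xi)` table; constant extrapolation beyond the table range.}
#' }
#'
#' Outside \eqn{[0, 1]} the analytic kinds are evaluated by the same
#' polynomial and the piecewise kind by extending its terminal segments; this
#' keeps right-hand sides smooth when a ratio argument such as
#' \eqn{[\mathrm{Cdk1}]/[\mathrm{CycB}]} transiently exceeds 1.
#'
#' The constructor rejects parameter combinations for which
#' \eqn{\min_{y \in [0,1]} \xi(y) \le 0}: the bent threshold
#' \eqn{\xi(y) K} must remain positive for the response to make sense.
#'
#' @param kind One of `"cubic"`, `"quadratic"`, `"linear"`, `"piecewise"`,
#'   `"tabulated"`.
#' @param alpha Dimensionless bend strength \eqn{\alpha \ge 0}
#'   (cubic/quadratic/linear kinds). `alpha = 0` gives \eqn{\xi \equiv 1},
#'   i.e. a plain ultrasensitive response.
#' @param r Asymmetry parameter in (0, 1); default 0.5 (symmetric bend).
#' @param x_max,x_min Breakpoints of the piecewise kind, both in (0, 1) with
#'   `x_max < x_min`.
#' @param xi_max,xi_min Levels of the piecewise kind at the breakpoints.
#' @param table Two-column data frame or matrix `(y, xi)` for the tabulated
#'   kind; `y` must be strictly increasing and all `xi > 0`.
#' @return An object of class `scaling_fn`.
#' @examples
#' xi <- scaling_function("cubic", alpha = 5)
#' xi_eval(xi, c(0, 0.25, 0.5, 1))
#' @export
scaling_function <- function(kind = c("cubic", "quadratic", "linear",
                                      "piecewise", "tabulated"),
                             alpha = 0, r = 0.5,
                             x_max = NULL, x_min = NULL,
                             xi_max = NULL, xi_min = NULL,
                             table = NULL) {
  kind <- match.arg(kind)
  sf <- structure(list(kind = kind), class = "scaling_fn")
  if (kind %in% c("cubic", "quadratic", "linear")) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
      stop("`alpha` must be a single number >= 0", call. = FALSE)
    if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1)
      stop("`r` must lie strictly inside (0, 1)", call. = FALSE)
    sf$alpha <- alpha
    sf$r <- r
  } else if (kind == "piecewise") {
    for (nm in c("x_max", "x_min", "xi_max", "xi_min")) {
      v <- get(nm)
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("piecewise kind requires numeric `", nm, "`", call. = FALSE)
    }
    if (x_max <= 0 || x_min >= 1 || x_max >= x_min)
      stop("piecewise breakpoints need 0 < x_max < x_min < 1", call. = FALSE)
    if (xi_max < 1 || xi_min > 1)
      stop("piecewise levels need xi_max >= 1 and xi_min <= 1", call. = FALSE)
    sf[c("x_max", "x_min", "xi_max", "xi_min")] <-
      list(x_max, x_min, xi_max, xi_min)
  } else { # tabulated
    tab <- as.data.frame(table)
    if (ncol(tab) < 2L || nrow(tab) < 2L)
      stop("tabulated kind requires a (y, xi) table with >= 2 rows",
           call. = FALSE)
    y <- as.numeric(tab[[1L]]); v <- as.numeric(tab[[2L]])
    if (any(diff(y) <= 0))
      stop("tabulated y grid must be strictly increasing", call. = FALSE)
    if (any(v <= 0))
      stop("tabulated xi values must be positive", call. = FALSE)
    sf$table <- data.frame(y = y, xi = v)
    sf$interp <- stats::splinefun(y, v, method = "monoH.FC")
  }
  ymin <- min(xi_eval(sf, seq(0, 1, length.out = 2001L)))
  if (ymin <= 0)
    stop("scaling function is non-positive on [0, 1]; ",
         "reduce `alpha` (the bent threshold must stay > 0)", call. = FALSE)
  sf
}

#' Evaluate a scaling function
#'
#' @param sf A [scaling_function()] object.
#' @param y Numeric vector of (normalized) output values; values outside
#'   \eqn{[0, 1]} are evaluated by the polynomial / terminal-segment
#'   extension (see [scaling_function()]).
#' @return Numeric vector \eqn{\xi(y)}.
#' @export
xi_eval <- function(sf, y) {
  stopifnot(inherits(sf, "scaling_fn"))
  y <- as.numeric(y)
  switch(sf$kind,
    cubic     = 1 + sf$alpha * y * (y - 1) * (y - sf$r),
    quadratic = 1 + sf$alpha * (y - 1) * (y - sf$r),
    linear    = 1 - sf$alpha / (sf$r - 1) * (y - 1) + sf$alpha,
    piecewise = {
      xmx <- sf$x_max; xmn <- sf$x_min
      s1 <- (sf$xi_max - 1) / xmx
      s2 <- (sf$xi_min - sf$xi_max) / (xmn - xmx)
      s3 <- (1 - sf$xi_min) / (1 - xmn)
      ifelse(y <= xmx, s1 * y + 1,
             ifelse(y <= xmn, s2 * (y - xmx) + sf$xi_max,
                    s3 * (y - xmn) + sf$xi_min))
    },
    tabulated = {
      lo <- sf$table$y[1L]; hi <- sf$table$y[nrow(sf$table)]
      sf$interp(pmin(pmax(y, lo), hi))
    })
}

#' @export
print.scaling_fn <- function(x, ...) {
  cat("<scaling_fn>", x$kind)
  if (x$kind %in% c("cubic", "quadratic", "linear"))
    cat(sprintf("  alpha = %g, r = %g", x$alpha, x$r))
  if (x$kind == "piecewise")
    cat(sprintf("  x_max = %g (xi %g), x_min = %g (xi %g)",
                x$x_max, x$xi_max, x$x_min, x$xi_min))
  if (x$kind == "tabulated")
    cat(sprintf("  %d knots on [%g, %g]", nrow(x$table),
                x$table$y[1L], x$table$y[nrow(x$table)]))
  cat("\n")
  invisible(x)
}
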