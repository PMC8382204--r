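# dense-grid oracle for the width of the bistable region: scan the
# inverted response on a fine output grid and take the local extrema
brute_force_width <- function(module, n = 1e6) {
  cc <- module$correction
  y <- seq(cc * 1e-6, cc * (1 - 1e-6), length.out = n)
  x <- invert_response(y, module)
  d <- diff(x)
  sg <- sign(d); sg[sg == 0] <- 1
  chg <- which(diff(sg) != 0) + 1L
  ext <- x[chg]
  ext <- ext[ext > 0]
  if (length(ext) < 2L) return(0)
  abs(max(ext) - min(ext))
}

# wrap a bare (time, value) series as a trajectory for the analysis ops
synthetic_traj <- function(time, ..., name = "synthetic") {
  st <- cbind(...)
  structure(list(time = time, state = st,
                 system = list(name = name, params = list()),
                 init = st[1L, ], dt = time[2L] - time[1L],
                 rtol = NA_real_, atol = NA_real_, method = "synthetic"),
            class = "trajectory")
}

# non-dimensional two-variable embryonic system (K = 1, b_deg = 1): the
# relative synthesis c is then b_syn itself
nd_embryonic <- function(c_, alpha, ...) {
  build_embryonic(embryonic_params(b_syn = c_, b_deg = 1, K_cdk_apc = 1,
                                   alpha_apc = alpha, ...))
}

# count nullcline intersections of system (i-b) from the scalar equation
# invert(y) * y = c * K; grid chosen to avoid landing on exact roots
count_intersections <- function(c_, alpha, K = 20, n = 15) {
  m <- switch_module(K = K, n = n, xi = scaling_function("cubic", alpha))
  g <- function(y) invert_response(y, m) * y - c_ * K
  ys <- seq(1e-5, 1 - 1e-5, length.out = 20011L)
  gv <- vapply(ys, g, numeric(1L))
  sg <- sign(gv)
  # exact zeros on the grid count as roots (e.g. the symmetric midpoint)
  sum(sg[-1L] * sg[-length(sg)] < 0) + sum(gv == 0)
}
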