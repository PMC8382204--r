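known_systems <- c("ia", "ib", "ii", "iiia", "iiib", "iiic",
                   "interlinked", "mass_action")

config_blocks <- c("system", "params", "solver", "analysis", "schedule",
                   "seed")

#' Load and validate a model configuration
#'
#' Reads a YAML configuration naming one of the built-in systems plus
#' optional parameter overrides, solver settings, analysis thresholds and
#' a perturbation schedule. Unknown top-level keys and unknown parameter
#' names are rejected; omitted parameters take the built-in defaults.
#' Times are minutes throughout; circadian entries may use hours with an
#' explicit `_h` suffix (e.g. `forcing: {A_cdk: 10, period_h: 24}`).
#'
#' @param path Path to a YAML file.
#' @return Object of class `model_config`: validated list with `system`,
#'   `params`, `solver`, `analysis`, `schedule`, `seed`, and `defaulted`
#'   (names of parameters filled from defaults).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param raw A list with the same structure as the YAML file.
#' @export
validate_config <- function(raw) {
  unknown <- setdiff(names(raw), config_blocks)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$system))
    stop("config must name a `system`", call. = FALSE)
  if (!raw$system %in% known_systems)
    stop("unknown system '", raw$system, "'; expected one of ",
         paste(known_systems, collapse = ", "), call. = FALSE)
  defaults <- default_params_for(raw$system)
  over <- raw$params %||% list()
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown parameter(s) for system ", raw$system, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  params <- utils::modifyList(defaults, over)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.numeric(v) && !startsWith(nm, "delta_") && !startsWith(nm, "tau") &&
        !nm %in% c("alpha_apc", "alpha_cdk", "alpha_e2f", "A_cdk", "phase") &&
        v < 0)
      stop("parameter out of domain: ", nm, " = ", v, call. = FALSE)
    if (nm %in% c("b_deg", "d_deg", "b_syn", "d_syn", "K_cdk_apc",
                  "K_cyc_cdk", "K_cyc_e2f") && is.numeric(v) && v <= 0)
      stop("parameter out of domain: ", nm, " = ", v, call. = FALSE)
  }
  sched <- NULL
  if (!is.null(raw$schedule)) {
    sched <- parameter_schedule(do.call(rbind, lapply(raw$schedule,
                                                      as.data.frame)))
  }
  structure(list(system = raw$system, params = params,
                 solver = raw$solver %||% list(rtol = 1e-6, atol = 1e-8),
                 analysis = raw$analysis %||% list(),
                 schedule = sched, seed = raw$seed %||% NULL,
                 defaulted = setdiff(names(defaults), names(over))),
            class = "model_config")
}

default_params_for <- function(system) {
  switch(system,
    ia = list(b_syn = 1, b_deg = 0.1, alpha_apc = 0, K_cdk_apc = 20,
              n = 15, r = 0.5, eps_apc_star = 0.01),
    ib = list(b_syn = 1, b_deg = 0.1, alpha_apc = 5, K_cdk_apc = 20,
              n = 15, r = 0.5, eps_apc_star = 0.01),
    ii = list(b_syn = 1, b_deg = 0.1, alpha_apc = 5, K_cdk_apc = 20,
              n = 15, r = 0.5, eps_apc_star = 0.01,
              tau1 = 5, tau2 = 5, tau_p = 5),
    iiia = list(b_syn = 1, b_deg = 0.1, alpha_apc = 5, alpha_cdk = 0,
                K_cdk_apc = 20, K_cyc_cdk = 40, n = 15, r = 0.5,
                eps_apc_star = 0.01, eps_cdk_star = 0.01),
    iiib = list(b_syn = 1, b_deg = 0.1, alpha_apc = 0, alpha_cdk = 5,
                K_cdk_apc = 20, K_cyc_cdk = 40, n = 15, r = 0.5,
                eps_apc_star = 0.01, eps_cdk_star = 0.01),
    iiic = list(b_syn = 1, b_deg = 0.1, alpha_apc = 5, alpha_cdk = 5,
                K_cdk_apc = 20, K_cyc_cdk = 40, n = 15, r = 0.5,
                eps_apc_star = 0.01, eps_cdk_star = 0.01),
    interlinked = c(unclass(somatic_params()),
                    list(A_cdk = 0, period_h = 24, phase = 0)),
    mass_action = list(b_syn = 1, b_deg = 0.1, k_pg = 0.07, k_dg = 7.08,
                       k_pe = 3.98, k_pa = 0.63, k_da = 1.58,
                       k_ass = 5.01, k_dis = 28.18, k_cat = 15.85,
                       GWL_tot = 40, ENSA_tot = 200, PP2A_tot = 40,
                       rate_divisor = 1))
}

#' Build the configured model system
#'
#' @param config A `model_config` from [load_config()].
#' @return A [model_system()], with any configured schedule attached.
#' @export
build_from_config <- function(config) {
  stopifnot(inherits(config, "model_config"))
  p <- config$params
  sys <- switch(config$system,
    ia = , ib = build_embryonic(embryonic_params(
      b_syn = p$b_syn, b_deg = p$b_deg,
      alpha_apc = if (config$system == "ia") 0 else p$alpha_apc,
      K_cdk_apc = p$K_cdk_apc, n = p$n, r = p$r,
      eps_apc_star = p$eps_apc_star)),
    ii = build_delayed(embryonic_params(
      b_syn = p$b_syn, b_deg = p$b_deg, alpha_apc = p$alpha_apc,
      K_cdk_apc = p$K_cdk_apc, n = p$n, r = p$r,
      eps_apc_star = p$eps_apc_star,
      delay = delay_spec(p$tau1, p$tau2, p$tau_p))),
    iiia = , iiib = , iiic = build_embryonic(embryonic_params(
      b_syn = p$b_syn, b_deg = p$b_deg, alpha_apc = p$alpha_apc,
      alpha_cdk = p$alpha_cdk, K_cdk_apc = p$K_cdk_apc,
      K_cyc_cdk = p$K_cyc_cdk, n = p$n, r = p$r,
      eps_apc_star = p$eps_apc_star, eps_cdk_star = p$eps_cdk_star)),
    interlinked = {
      sp <- do.call(somatic_params,
                    p[intersect(names(p), names(formals(somatic_params)))])
      fs <- if ((p$A_cdk %||% 0) > 0)
        forcing_spec(p$A_cdk, p$period_h %||% 24, p$phase %||% 0)
      build_interlinked(sp, forcing = fs)
    },
    mass_action = build_mass_action(do.call(mass_action_params,
      p[intersect(names(p), names(formals(mass_action_params)))])))
  if (!is.null(config$schedule)) sys <- apply_schedule(sys, config$schedule)
  sys
}

#' Save a configuration back to YAML
#'
#' @param config A `model_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  out <- list(system = config$system, params = config$params,
              solver = config$solver)
  if (length(config$analysis)) out$analysis <- config$analysis
  if (!is.null(config$schedule)) {
    w <- config$schedule$windows
    out$schedule <- lapply(seq_len(nrow(w)), function(i) as.list(w[i, ]))
  }
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write / read a trajectory as annotated TSV
#'
#' The file carries a commented header (`# key: value`) echoing the system
#' name, every effective parameter, the initial state and the solver
#' settings, followed by a tab-separated table `time` plus one column per
#' state variable, at full double precision; `read_trajectory()` restores
#' the arrays exactly.
#'
#' @param traj A trajectory.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- vapply(traj$system$params, is.numeric, logical(1L))
  hdr <- c(sprintf("# system: %s", traj$system$name),
           sprintf("# units: time=min"),
           vapply(names(traj$system$params)[num], function(nm)
             sprintf("# param %s: %.17g", nm, traj$system$params[[nm]]),
             character(1L)),
           sprintf("# init %s: %.17g", names(traj$init), traj$init),
           sprintf("# solver: method=%s rtol=%.3g atol=%.3g dt=%.17g",
                   traj$method, traj$rtol, traj$atol, traj$dt))
  writeLines(hdr, con)
  df <- data.frame(time = traj$time, traj$state, check.names = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory()` returns a `trajectory` (with the header
#'   echoed in attribute `header`; the system slot holds only the recorded
#'   name and parameters).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  dat <- utils::read.table(text = body[-1L], sep = "\t",
                           col.names = cols, check.names = FALSE)
  if (!"time" %in% cols)
    stop("malformed trajectory file: missing column `time`", call. = FALSE)
  need <- setdiff(cols, "time")
  st <- as.matrix(dat[, need, drop = FALSE])
  nm <- sub("^# system: ", "",
            grep("^# system: ", hdr, value = TRUE)[1L])
  pl <- grep("^# param ", hdr, value = TRUE)
  params <- list()
  for (ln in pl) {
    m <- regmatches(ln, regexec("^# param ([^:]+): (.+)$", ln))[[1L]]
    params[[m[2L]]] <- as.numeric(m[3L])
  }
  sys <- model_system(nm %||% "recorded", need, params,
                      rhs = function(t, y, p, lag = NULL)
                        stop("recorded trajectory has no dynamics"))
  structure(list(time = dat$time, state = st, system = sys,
                 init = st[1L, ], dt = NA_real_, rtol = NA_real_,
                 atol = NA_real_, method = "recorded", header = hdr),
            class = "trajectory")
}

#' Write / read a response curve as TSV with branch labels
#'
#' @param curve A `response_curve`.
#' @param path File path.
#' @export
write_response_curve <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  df <- curve$points
  if (is.null(df$branch_id)) df$branch_id <- 1L
  utils::write.table(df[, c("input", "output", "branch_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_curve
#' @export
read_response_curve <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("input", "output") %in% names(df)))
    stop("malformed response-curve file: need columns input, output",
         call. = FALSE)
  structure(list(points = df,
                 folds = data.frame(input = numeric(0),
                                    output = numeric(0)),
                 truncated = FALSE),
            class = "response_curve")
}

#' Deterministic synthetic fixtures for testing the analysis machinery
#'
#' Generates small data sets with known ground truth: S-shaped response
#' curves from a configured scaling function (optionally with seeded
#' multiplicative noise), and periodic / damped / quasiperiodic / sawtooth
#' time series. The same `spec` (including `seed`) always returns the
#' identical object.
#'
#' @param kind One of `"response_curve"`, `"periodic_series"`,
#'   `"damped_series"`, `"quasiperiodic_series"`, `"sawtooth_series"`.
#' @param ... Shape parameters: `response_curve` takes `xi`
#'   (a [scaling_function()]), `K`, `n`, `correction`, `n_points`,
#'   `noise` (multiplicative sd), `seed`; the series kinds take `period`
#'   (and `period2` for the quasiperiodic kind), `t_max`, `dt`, `decay`
#'   (fractional amplitude loss per cycle, damped kind), `noise`, `seed`.
#' @return Data frame (`input`/`output` or `time`/`value`) with the
#'   generating parameters attached as attribute `ground_truth`.
#' @export
make_fixture <- function(kind = c("response_curve", "periodic_series",
                                  "damped_series", "quasiperiodic_series",
                                  "sawtooth_series"), ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  seed <- opts$seed %||% 1L
  noise <- opts$noise %||% 0
  rng <- local_rng(seed)
  out <- switch(kind,
    response_curve = {
      xi <- opts$xi %||% scaling_function("cubic", 5)
      K <- opts$K %||% 1; n <- opts$n %||% 15
      corr <- opts$correction %||% 1
      n_points <- opts$n_points %||% 200L
      y <- seq(corr * 1e-3, corr * (1 - 1e-3), length.out = n_points)
      x <- xi_eval(xi, y) * K * (y / (corr - y))^(1 / n)
      if (noise > 0) x <- x * exp(rng$rnorm(n_points, 0, noise))
      data.frame(input = x, output = y)
    },
    periodic_series = {
      period <- opts$period %||% 100
      t <- seq(0, opts$t_max %||% (20 * period), by = opts$dt %||%
                 (period / 100))
      v <- sin(2 * pi * t / period)
      if (noise > 0) v <- v + rng$rnorm(length(t), 0, noise)
      data.frame(time = t, value = v)
    },
    damped_series = {
      period <- opts$period %||% 100
      decay <- opts$decay %||% 0.05  # fractional loss per cycle
      t <- seq(0, opts$t_max %||% (20 * period), by = opts$dt %||%
                 (period / 100))
      v <- (1 - decay)^(t / period) * sin(2 * pi * t / period)
      if (noise > 0) v <- v + rng$rnorm(length(t), 0, noise)
      data.frame(time = t, value = v)
    },
    quasiperiodic_series = {
      period <- opts$period %||% 100
      period2 <- opts$period2 %||% (period * sqrt(2))
      t <- seq(0, opts$t_max %||% (40 * period), by = opts$dt %||%
                 (period / 100))
      v <- sin(2 * pi * t / period) + sin(2 * pi * t / period2)
      if (noise > 0) v <- v + rng$rnorm(length(t), 0, noise)
      data.frame(time = t, value = v)
    },
    sawtooth_series = {
      period <- opts$period %||% 100
      t <- seq(0, opts$t_max %||% (20 * period), by = opts$dt %||%
                 (period / 100))
      v <- (t %% period) / period
      if (noise > 0) v <- v + rng$rnorm(length(t), 0, noise)
      data.frame(time = t, value = v)
    })
  attr(out, "ground_truth") <- c(list(kind = kind), opts)
  out
}

# seeded RNG that leaves the global stream untouched
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env$rnorm <- function(n, mean = 0, sd = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- stats::rnorm(n, mean, sd)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  env
}
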