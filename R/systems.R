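#' Delay specification for a switch module
#'
#' Activation/inactivation lag of the APC/C response to Cdk1. With
#' `tau1 == tau2` the delay is constant; otherwise the effective delay
#' blends the activation delay `tau1` (low APC/C) into the inactivation
#' delay `tau2` (high APC/C) through a Hill switch centered at 0.5:
#' \deqn{\tau([\mathrm{APC}]^*) = \tau_1 + (\tau_2 - \tau_1)
#'   \frac{{[\mathrm{APC}]^*}^p}{0.5^p + {[\mathrm{APC}]^*}^p}.}
#' The blend is evaluated at the *current* APC/C activity.
#'
#' @param tau1 Activation delay (time units, >= 0).
#' @param tau2 Inactivation delay (>= 0); defaults to `tau1`.
#' @param p Hill exponent of the state-dependent blend (default 5).
#' @return Object of class `delay_spec`.
#' @export
delay_spec <- function(tau1, tau2 = tau1, p = 5) {
  if (tau1 < 0 || tau2 < 0) stop("delays must be >= 0", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, p = p), class = "delay_spec")
}

effective_tau <- function(spec, apc) {
  spec$tau1 + (spec$tau2 - spec$tau1) * apc^spec$p / (0.5^spec$p + apc^spec$p)
}

#' Parameters of the embryonic cell-cycle oscillators
#'
#' Parameter set for the two-variable (Cdk1, APC/C) and three-variable
#' (CycB, Cdk1, APC/C) negative-feedback oscillators. Defaults follow the
#' standard values for Xenopus laevis extracts: `b_deg` = 0.1/min,
#' `K_cdk_apc` = 20 nM, `n` = 15 and relaxation constants chosen so that
#' \eqn{\epsilon b_{deg} = 0.01}. The second (CycB -> Cdk1) switch, with
#' threshold `K_cyc_cdk` = 40 nM, is included only when `alpha_cdk` is
#' non-`NULL` (or an explicit `cdk_switch` is supplied); that switch's Hill
#' term is multiplied by the CycB input and its scaling function takes the
#' ratio Cdk1/CycB as argument.
#'
#' @param b_syn CycB(-Cdk1) synthesis rate (nM/min).
#' @param b_deg First-order degradation rate (1/min).
#' @param alpha_apc Bend strength of the Cdk1 -> APC/C switch (0 gives the
#'   purely ultrasensitive system (i-a)).
#' @param alpha_cdk Bend strength of the CycB -> Cdk1 switch, or `NULL` for
#'   the two-variable systems.
#' @param K_cdk_apc,K_cyc_cdk Activation thresholds (nM).
#' @param n Hill exponent.
#' @param r Asymmetry of the cubic scaling functions.
#' @param eps_apc_star,eps_cdk_star Dimensionless relaxation constants
#'   \eqn{\epsilon b_{deg}}.
#' @param delay Optional [delay_spec()] (minutes) for the APC/C equation.
#' @param apc_switch,cdk_switch Optional explicit [switch_module()]s
#'   overriding the scalar shortcuts above (e.g. a module fitted to a
#'   measured curve, with a piecewise scaling function and correction).
#' @return Object of class `embryonic_params`.
#' @export
embryonic_params <- function(b_syn, b_deg = 0.1,
                             alpha_apc = 0, alpha_cdk = NULL,
                             K_cdk_apc = 20, K_cyc_cdk = 40,
                             n = 15, r = 0.5,
                             eps_apc_star = 0.01, eps_cdk_star = 0.01,
                             delay = NULL,
                             apc_switch = NULL, cdk_switch = NULL) {
  if (b_syn <= 0 || b_deg <= 0) stop("rates must be positive", call. = FALSE)
  if (is.null(apc_switch))
    apc_switch <- switch_module(K = K_cdk_apc, n = n,
                                xi = scaling_function("cubic", alpha_apc, r),
                                epsilon = eps_apc_star / b_deg)
  if (is.null(cdk_switch) && !is.null(alpha_cdk))
    cdk_switch <- switch_module(K = K_cyc_cdk, n = n,
                                xi = scaling_function("cubic", alpha_cdk, r),
                                epsilon = eps_cdk_star / b_deg,
                                multiply_by_input = TRUE)
  if (!is.null(cdk_switch) && !cdk_switch$multiply_by_input)
    stop("the CycB -> Cdk1 switch must have multiply_by_input = TRUE ",
         "(its output is a concentration, not a fraction)", call. = FALSE)
  if (!is.null(delay) && !inherits(delay, "delay_spec"))
    stop("`delay` must be a delay_spec()", call. = FALSE)
  structure(list(b_syn = b_syn, b_deg = b_deg, apc_switch = apc_switch,
                 cdk_switch = cdk_switch, delay = delay),
            class = "embryonic_params")
}

#' Parameters of the somatic cell cycle of interlinked switches
#'
#' Default values reproduce the five-variable somatic model: CycD synthesis
#' drives the E2F switch, E2F drives CycB synthesis, CycB drives the Cdk1
#' switch, Cdk1 drives the APC/C switch, and active APC/C degrades both
#' cyclins (with small APC/C-independent offsets `delta_d`, `delta_b`).
#'
#' @param d_syn CycD synthesis rate (nM/min).
#' @param d_deg CycD degradation rate (1/min).
#' @param delta_d,delta_b Basal (APC/C-independent) degradation offsets.
#' @param b_syn,b_deg CycB synthesis (nM/min) and degradation (1/min).
#' @param K_cyc_e2f,K_cyc_cdk,K_cdk_apc Switch thresholds (nM).
#' @param alpha_e2f,alpha_cdk,alpha_apc Bend strengths.
#' @param eps_e2f,eps_cdk,eps_apc Relaxation time constants (min).
#' @param n,r Hill exponent and asymmetry.
#' @return Object of class `somatic_params`.
#' @export
somatic_params <- function(d_syn = 0.15, d_deg = 0.009, delta_d = 0.05,
                           b_syn = 0.03, b_deg = 0.003, delta_b = 0.05,
                           K_cyc_e2f = 120, K_cyc_cdk = 40, K_cdk_apc = 20,
                           alpha_e2f = 5, alpha_cdk = 5, alpha_apc = 5,
                           eps_e2f = 0.01, eps_cdk = 0.01, eps_apc = 0.01,
                           n = 15, r = 0.5) {
  vals <- c(d_deg = d_deg, b_deg = b_deg,
            K_cyc_e2f = K_cyc_e2f, K_cyc_cdk = K_cyc_cdk,
            K_cdk_apc = K_cdk_apc, eps_e2f = eps_e2f, eps_cdk = eps_cdk,
            eps_apc = eps_apc, n = n)
  if (any(vals <= 0))
    stop("non-positive parameter: ",
         paste(names(vals)[vals <= 0], collapse = ", "), call. = FALSE)
  # zero synthesis is a legitimate experiment (production switched off)
  if (d_syn < 0 || b_syn < 0 || delta_d < 0 || delta_b < 0 ||
      alpha_e2f < 0 || alpha_cdk < 0 || alpha_apc < 0)
    stop("synthesis, delta and alpha parameters must be >= 0",
         call. = FALSE)
  structure(mget(names(formals())), class = "somatic_params")
}

#' Parameters of the mass-action PP2A-ENSA-GWL oscillator
#'
#' Kinetic constants of the PP2A-ENSA-GWL double-negative feedback network
#' extended with CycB-Cdk1 synthesis and APC/C-mediated degradation.
#' Defaults are the experimentally grounded reference set (total ENSA
#' five-fold the total PP2A). The synthesis/degradation pair has no
#' established reference value and must
#' be supplied. `rate_divisor` uniformly divides the eight kinetic
#' constants — but not synthesis or degradation — to reduce the timescale
#' separation between the switch reactions and the cyclin turnover.
#'
#' @param b_syn,b_deg Cdk1 synthesis (nM/min) and degradation (1/min).
#' @param k_pg,k_dg,k_pe,k_pa,k_da,k_ass Second-order rate constants
#'   (1/(nM min)).
#' @param k_dis,k_cat First-order rate constants (1/min).
#' @param GWL_tot,ENSA_tot,PP2A_tot Conserved totals (nM).
#' @param rate_divisor Divisor (>= 1) applied to the eight kinetic
#'   constants.
#' @return Object of class `mass_action_params`.
#' @export
mass_action_params <- function(b_syn, b_deg,
                               k_pg = 0.07, k_dg = 7.08, k_pe = 3.98,
                               k_pa = 0.63, k_da = 1.58, k_ass = 5.01,
                               k_dis = 28.18, k_cat = 15.85,
                               GWL_tot = 40, ENSA_tot = 200, PP2A_tot = 40,
                               rate_divisor = 1) {
  vals <- c(b_syn = b_syn, b_deg = b_deg, k_pg = k_pg, k_dg = k_dg,
            k_pe = k_pe, k_pa = k_pa, k_da = k_da, k_ass = k_ass,
            k_dis = k_dis, k_cat = k_cat, GWL_tot = GWL_tot,
            ENSA_tot = ENSA_tot, PP2A_tot = PP2A_tot)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all mass-action parameters must be positive", call. = FALSE)
  if (rate_divisor < 1) stop("rate_divisor must be >= 1", call. = FALSE)
  structure(c(as.list(vals), list(rate_divisor = rate_divisor)),
            class = "mass_action_params")
}

#' Assemble a dynamical system by hand
#'
#' Low-level constructor behind the `build_*()` functions, exported so that
#' custom variants (e.g. a switch with its input clamped) can be built and
#' passed to the same integration and analysis machinery.
#'
#' @param name System name.
#' @param vars Character vector of state-variable names.
#' @param params Flat named list of numeric parameters (schedulable) plus
#'   any fixed objects the right-hand side closes over.
#' @param rhs `function(t, y, p, lag)` returning the derivative vector;
#'   `lag(t)` returns the lagged state vector (delayed systems only).
#' @param has_delay Logical.
#' @param tau_fun Optional `function(y, p)` returning the current delay.
#' @param state_box Named list of `c(lo, hi)` ranges used to seed
#'   steady-state searches.
#' @param starred Character vector of the variables that are activity
#'   fractions confined to \eqn{[0, 1]}.
#' @param check_init Optional `function(y)` validating initial conditions.
#' @param conserved Optional `function(y, p)` returning named conserved
#'   totals along trajectories.
#' @return Object of class `model_system`.
#' @export
model_system <- function(name, vars, params, rhs, has_delay = FALSE,
                         tau_fun = NULL, state_box = NULL, starred = character(),
                         check_init = NULL, conserved = NULL) {
  stopifnot(is.character(vars), is.function(rhs))
  structure(list(name = name, vars = vars, params = params, rhs = rhs,
                 has_delay = has_delay, tau_fun = tau_fun,
                 state_box = state_box, starred = starred,
                 check_init = check_init, conserved = conserved,
                 schedule = NULL),
            class = "model_system")
}

#' @export
print.model_system <- function(x, ...) {
  cat(sprintf("<model_system> %s: %d state variables (%s)%s\n", x$name,
              length(x$vars), paste(x$vars, collapse = ", "),
              if (x$has_delay) ", delayed" else ""))
  if (!is.null(x$schedule))
    cat(sprintf("  schedule: %d perturbation window(s)\n",
                nrow(x$schedule$windows)))
  invisible(x)
}

# closure evaluating a switch's scaling function; cubic bends read their
# alpha from the live parameter list so schedules/forcing can move them
make_xi_closure <- function(xi, alpha_name) {
  if (xi$kind == "cubic") {
    r <- xi$r
    function(y, p) 1 + p[[alpha_name]] * y * (y - 1) * (y - r)
  } else {
    force(xi)
    function(y, p) xi_eval(xi, y)
  }
}

#' Build the embryonic cell-cycle oscillator
#'
#' Two-variable system when no CycB -> Cdk1 switch is configured:
#' \deqn{d[\mathrm{Cdk1}]/dt = b_{syn} - b_{deg} [\mathrm{Cdk1}]
#'   [\mathrm{APC}]^*,}
#' \deqn{d[\mathrm{APC}]^*/dt = (H([\mathrm{Cdk1}];
#'   \xi([\mathrm{APC}]^*) K, n) - [\mathrm{APC}]^*) / \epsilon_{apc};}
#' with `alpha_apc = 0` this is the ultrasensitive negative-feedback system
#' (one stable steady state), with `alpha_apc > 0` the bistable variant that
#' can sustain relaxation oscillations. When a CycB -> Cdk1 switch is
#' present the three-variable system is returned; its Cdk1 equation
#' multiplies the Hill term by CycB and evaluates the scaling function at
#' the ratio Cdk1/CycB (guarded as Cdk1/max(CycB, 1e-12)).
#'
#' @param params An [embryonic_params()] object.
#' @return A [model_system()].
#' @export
build_embryonic <- function(params) {
  stopifnot(inherits(params, "embryonic_params"))
  ap <- params$apc_switch
  cd <- params$cdk_switch
  xi_apc <- make_xi_closure(ap$xi, "alpha_apc")
  p <- list(b_syn = params$b_syn, b_deg = params$b_deg,
            K_apc = ap$K, n_apc = ap$n, eps_apc = ap$epsilon,
            corr_apc = ap$correction, r = if (ap$xi$kind == "cubic") ap$xi$r else 0.5,
            alpha_apc = if (ap$xi$kind == "cubic") ap$xi$alpha else NA_real_)
  if (is.null(cd)) {
    rhs <- function(t, y, p, lag = NULL) {
      cdk <- y[1L]; apc <- y[2L]
      hn <- cdk^p$n_apc
      h <- p$corr_apc * hn / ((xi_apc(apc, p) * p$K_apc)^p$n_apc + hn)
      c(p$b_syn - p$b_deg * cdk * apc,
        (h - apc) / p$eps_apc)
    }
    model_system("embryonic", c("Cdk1", "APC"), p, rhs,
                 state_box = list(Cdk1 = c(0, 5 * ap$K), APC = c(0, 1)),
                 starred = "APC")
  } else {
    xi_cdk <- make_xi_closure(cd$xi, "alpha_cdk")
    p$K_cdk <- cd$K; p$n_cdk <- cd$n; p$eps_cdk <- cd$epsilon
    p$corr_cdk <- cd$correction
    p$alpha_cdk <- if (cd$xi$kind == "cubic") cd$xi$alpha else NA_real_
    rhs <- function(t, y, p, lag = NULL) {
      cyc <- y[1L]; cdk <- y[2L]; apc <- y[3L]
      ratio <- cdk / max(cyc, 1e-12)
      cn <- cyc^p$n_cdk
      hc <- p$corr_cdk * cn / ((xi_cdk(ratio, p) * p$K_cdk)^p$n_cdk + cn)
      kn <- cdk^p$n_apc
      ha <- p$corr_apc * kn / ((xi_apc(apc, p) * p$K_apc)^p$n_apc + kn)
      c(p$b_syn - p$b_deg * cyc * apc,
        (hc * cyc - cdk) / p$eps_cdk,
        (ha - apc) / p$eps_apc)
    }
    model_system("embryonic3", c("CycB", "Cdk1", "APC"), p, rhs,
                 state_box = list(CycB = c(0, 6 * cd$K),
                                  Cdk1 = c(0, 6 * cd$K), APC = c(0, 1)),
                 starred = "APC")
  }
}

#' Build the delayed embryonic oscillator
#'
#' The two-variable system with the lagged Cdk1 level entering the APC/C
#' equation. The delay is constant (`tau1 == tau2`) or blends activation
#' into inactivation delay through the Hill switch of [delay_spec()],
#' evaluated at the current APC/C activity. With both delays zero the
#' system reduces exactly to [build_embryonic()].
#'
#' @param params An [embryonic_params()] with a `delay` component.
#' @return A [model_system()] (delayed unless both lags are zero).
#' @export
build_delayed <- function(params) {
  stopifnot(inherits(params, "embryonic_params"))
  if (is.null(params$delay))
    stop("`params` carries no delay_spec; use build_embryonic()",
         call. = FALSE)
  if (!is.null(params$cdk_switch))
    stop("the delayed system is the two-variable model; drop the cdk switch",
         call. = FALSE)
  if (params$delay$tau1 == 0 && params$delay$tau2 == 0) {
    sys <- build_embryonic(params)
    sys$name <- "delayed"
    return(sys)
  }
  ap <- params$apc_switch
  xi_apc <- make_xi_closure(ap$xi, "alpha_apc")
  dl <- params$delay
  p <- list(b_syn = params$b_syn, b_deg = params$b_deg,
            K_apc = ap$K, n_apc = ap$n, eps_apc = ap$epsilon,
            corr_apc = ap$correction,
            r = if (ap$xi$kind == "cubic") ap$xi$r else 0.5,
            alpha_apc = if (ap$xi$kind == "cubic") ap$xi$alpha else NA_real_,
            tau1 = dl$tau1, tau2 = dl$tau2, tau_p = dl$p)
  tau_fun <- function(y, p) {
    apc <- y[2L]
    p$tau1 + (p$tau2 - p$tau1) * apc^p$tau_p / (0.5^p$tau_p + apc^p$tau_p)
  }
  rhs <- function(t, y, p, lag) {
    cdk <- y[1L]; apc <- y[2L]
    tau <- tau_fun(y, p)
    cdk_lag <- lag(t - tau)[1L]
    hn <- cdk_lag^p$n_apc
    h <- p$corr_apc * hn / ((xi_apc(apc, p) * p$K_apc)^p$n_apc + hn)
    c(p$b_syn - p$b_deg * cdk * apc,
      (h - apc) / p$eps_apc)
  }
  model_system("delayed", c("Cdk1", "APC"), p, rhs, has_delay = TRUE,
               tau_fun = tau_fun,
               state_box = list(Cdk1 = c(0, 5 * ap$K), APC = c(0, 1)),
               starred = "APC")
}

#' Build the somatic cell cycle of interlinked bistable switches
#'
#' Five-variable system CycD, E2F*, CycB, Cdk1, APC*: a chain of three
#' bistable switches (CycD -> E2F, CycB -> Cdk1, Cdk1 -> APC/C) closed by
#' APC/C-mediated cyclin degradation. Optional sinusoidal circadian forcing
#' moves the Cdk1-switch bend parameter as
#' \eqn{\alpha^*_{cdk}(t) = \alpha_{cdk} + A + A \sin(\omega t + \phi)},
#' i.e. between its basal level and \eqn{\alpha_{cdk} + 2A}.
#'
#' @param params A [somatic_params()] object.
#' @param forcing Optional [forcing_spec()].
#' @return A [model_system()].
#' @export
build_interlinked <- function(params = somatic_params(), forcing = NULL) {
  stopifnot(inherits(params, "somatic_params"))
  if (!is.null(forcing) && !inherits(forcing, "forcing_spec"))
    stop("`forcing` must be a forcing_spec()", call. = FALSE)
  p <- unclass(params)
  p$A_cdk <- if (is.null(forcing)) 0 else forcing$A_cdk
  p$omega_circ <- if (is.null(forcing)) 0 else forcing$omega
  p$phase_circ <- if (is.null(forcing)) 0 else forcing$phase
  rhs <- function(t, y, p, lag = NULL) {
    cycd <- y[1L]; e2f <- y[2L]; cycb <- y[3L]; cdk <- y[4L]; apc <- y[5L]
    a_cdk <- p$alpha_cdk + p$A_cdk +
      p$A_cdk * sin(p$omega_circ * t + p$phase_circ)
    ratio <- cdk / max(cycb, 1e-12)
    n <- p$n; r <- p$r
    dn <- cycd^n
    he <- dn / (((1 + p$alpha_e2f * e2f * (e2f - 1) * (e2f - r)) *
                   p$K_cyc_e2f)^n + dn)
    bn <- cycb^n
    hc <- bn / (((1 + a_cdk * ratio * (ratio - 1) * (ratio - r)) *
                   p$K_cyc_cdk)^n + bn)
    kn <- cdk^n
    ha <- kn / (((1 + p$alpha_apc * apc * (apc - 1) * (apc - r)) *
                   p$K_cdk_apc)^n + kn)
    c(p$d_syn - p$d_deg * cycd * (apc + p$delta_d),
      (he - e2f) / p$eps_e2f,
      p$b_syn * e2f - p$b_deg * cycb * (apc + p$delta_b),
      (hc * cycb - cdk) / p$eps_cdk,
      (ha - apc) / p$eps_apc)
  }
  model_system("interlinked", c("CycD", "E2F", "CycB", "Cdk1", "APC"),
               p, rhs,
               state_box = list(CycD = c(0, 3 * p$K_cyc_e2f),
                                E2F = c(0, 1),
                                CycB = c(0, 6 * p$K_cyc_cdk),
                                Cdk1 = c(0, 6 * p$K_cyc_cdk),
                                APC = c(0, 1)),
               starred = c("E2F", "APC"))
}

#' Build the mass-action PP2A-ENSA-GWL oscillator
#'
#' Five-variable mass-action network (Cdk1, phosphorylated GWL, the
#' ENSA-PP2A complex C, phosphorylated ENSA, APC*) with conservation of the
#' GWL, PP2A and ENSA pools handled algebraically:
#' `GWL = GWL_tot - GWLp`, `PP2A = PP2A_tot - C`,
#' `ENSA = ENSA_tot - ENSAp - C`.
#'
#' @param params A [mass_action_params()] object.
#' @return A [model_system()].
#' @export
build_mass_action <- function(params) {
  stopifnot(inherits(params, "mass_action_params"))
  p <- unclass(params)
  div <- p$rate_divisor
  for (k in c("k_pg", "k_dg", "k_pe", "k_pa", "k_da", "k_ass",
              "k_dis", "k_cat"))
    p[[k]] <- p[[k]] / div
  rhs <- function(t, y, p, lag = NULL) {
    cdk <- y[1L]; gwlp <- y[2L]; cpx <- y[3L]; ensap <- y[4L]; apc <- y[5L]
    gwl <- p$GWL_tot - gwlp
    pp2a <- p$PP2A_tot - cpx
    ensa <- p$ENSA_tot - ensap - cpx
    c(p$b_syn - p$b_deg * cdk * apc,
      p$k_pg * gwl * cdk - p$k_dg * gwlp * pp2a,
      p$k_ass * ensap * pp2a - (p$k_dis + p$k_cat) * cpx,
      p$k_dis * cpx + p$k_pe * ensa * gwlp - p$k_ass * ensap * pp2a,
      p$k_pa * (1 - apc) * cdk - p$k_da * apc * pp2a)
  }
  check_init <- function(y) {
    if (y[3L] < 0 || y[3L] > p$PP2A_tot)
      stop("initial complex C must satisfy 0 <= C <= PP2A_tot",
           call. = FALSE)
    if (y[4L] < 0 || y[4L] + y[3L] > p$ENSA_tot)
      stop("initial ENSAp + C must not exceed ENSA_tot", call. = FALSE)
    if (y[2L] < 0 || y[2L] > p$GWL_tot)
      stop("initial GWLp must satisfy 0 <= GWLp <= GWL_tot", call. = FALSE)
    invisible(TRUE)
  }
  conserved <- function(y, p) {
    # totals reconstructed from the algebraic substitution; reported so
    # tests can confirm the pools stay exactly closed
    c(GWL = (p$GWL_tot - y[2L]) + y[2L],
      PP2A = (p$PP2A_tot - y[3L]) + y[3L],
      ENSA = (p$ENSA_tot - y[4L] - y[3L]) + y[4L] + y[3L])
  }
  model_system("mass_action", c("Cdk1", "GWLp", "C", "ENSAp", "APC"),
               p, rhs,
               state_box = list(Cdk1 = c(0, 60), GWLp = c(0, p$GWL_tot),
                                C = c(0, p$PP2A_tot),
                                ENSAp = c(0, p$ENSA_tot), APC = c(0, 1)),
               starred = "APC", check_init = check_init,
               conserved = conserved)
}

#' Non-dimensionalize an embryonic parameter set
#'
#' Rescales concentrations by the APC/C activation threshold and time by
#' the degradation rate (\eqn{x^* = x / K_{cdk,apc}}, \eqn{t^* = b_{deg}
#' t}), collapsing the parameters into the relative synthesis
#' \eqn{c = b_{syn} / (K_{cdk,apc} b_{deg})}, the threshold ratio
#' \eqn{d = K_{cyc,cdk} / K_{cdk,apc}}, the relaxation constants
#' \eqn{\epsilon^* = \epsilon b_{deg}} and (if delayed)
#' \eqn{\tau^* = b_{deg} \tau}. The relative synthesis of the
#' three-variable system, whose cyclin variable is naturally scaled by
#' `K_cyc_cdk`, equals `c / d`.
#'
#' @param params An [embryonic_params()] object.
#' @return Object of class `nondim_params`: list with the dimensionless
#'   groups (`c`, `d`, `eps_star`, `tau_star`), the non-dimensional
#'   [model_system()] (`$system`), and the transform pair
#'   `$to_dimensionless(traj)` / scaling constants `$K_ref`, `$t_ref`.
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "embryonic_params"))
  ap <- params$apc_switch; cd <- params$cdk_switch
  if (params$b_deg <= 0 || ap$K <= 0) stop("b_deg and K must be positive")
  cc <- params$b_syn / (ap$K * params$b_deg)
  d <- if (!is.null(cd)) cd$K / ap$K else NA_real_
  eps_star <- c(apc = ap$epsilon * params$b_deg)
  if (!is.null(cd)) eps_star <- c(eps_star, cdk = cd$epsilon * params$b_deg)
  tau_star <- if (!is.null(params$delay))
    c(tau1 = params$delay$tau1 * params$b_deg,
      tau2 = params$delay$tau2 * params$b_deg) else NULL
  nd_apc <- switch_module(K = 1, n = ap$n, xi = ap$xi,
                          epsilon = eps_star[["apc"]],
                          correction = ap$correction)
  nd_cdk <- if (!is.null(cd))
    switch_module(K = d, n = cd$n, xi = cd$xi,
                  epsilon = eps_star[["cdk"]],
                  multiply_by_input = TRUE, correction = cd$correction)
  nd_delay <- if (!is.null(params$delay))
    delay_spec(tau_star[["tau1"]], tau_star[["tau2"]], params$delay$p)
  nd_params <- embryonic_params(b_syn = cc, b_deg = 1,
                                apc_switch = nd_apc, cdk_switch = nd_cdk,
                                delay = nd_delay)
  system <- if (!is.null(nd_delay) && is.null(nd_cdk))
    build_delayed(nd_params) else build_embryonic(nd_params)
  K_ref <- ap$K; t_ref <- 1 / params$b_deg
  to_dimensionless <- function(traj) {
    stopifnot(inherits(traj, "trajectory"))
    st <- traj$state
    for (v in colnames(st))
      if (!v %in% c("APC", "E2F")) st[, v] <- st[, v] / K_ref
    traj$time <- traj$time / t_ref
    traj$state <- st
    traj
  }
  structure(list(c = cc, d = d, eps_star = eps_star, tau_star = tau_star,
                 system = system, K_ref = K_ref, t_ref = t_ref,
                 to_dimensionless = to_dimensionless),
            class = "nondim_params")
}

#' Piecewise-constant parameter schedule
#'
#' Time windows during which a named numeric parameter of a system is set
#' to a value or multiplied by a factor; outside all windows the baseline
#' value applies. Windows on the same parameter must not overlap. Used to
#' model transient perturbations such as growth-factor withdrawal or DNA
#' damage.
#'
#' @param windows Data frame with columns `t_start`, `t_end`, `param`,
#'   `value` and optionally `mode` (`"set"` or `"multiply"`, default
#'   `"set"`).
#' @return Object of class `parameter_schedule`.
#' @export
parameter_schedule <- function(windows) {
  windows <- as.data.frame(windows)
  need <- c("t_start", "t_end", "param", "value")
  if (!all(need %in% names(windows)))
    stop("schedule needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(windows$mode)) windows$mode <- rep("set", nrow(windows))
  if (!all(windows$mode %in% c("set", "multiply")))
    stop("schedule mode must be 'set' or 'multiply'", call. = FALSE)
  if (any(windows$t_end < windows$t_start))
    stop("schedule windows need t_end >= t_start", call. = FALSE)
  for (pm in unique(windows$param)) {
    w <- windows[windows$param == pm, , drop = FALSE]
    w <- w[order(w$t_start), , drop = FALSE]
    if (nrow(w) > 1L && any(w$t_start[-1L] < w$t_end[-nrow(w)]))
      stop("overlapping schedule windows for parameter '", pm, "'",
           call. = FALSE)
  }
  structure(list(windows = windows), class = "parameter_schedule")
}

#' Attach a parameter schedule to a system
#'
#' Returns a system whose right-hand side uses the window values inside
#' `[t_start, t_end)` and the baseline elsewhere; [integrate_system()]
#' restarts the integrator at every window boundary. An empty schedule
#' leaves trajectories unchanged.
#'
#' @param system A [model_system()].
#' @param schedule A [parameter_schedule()].
#' @return The system with the schedule attached.
#' @export
apply_schedule <- function(system, schedule) {
  stopifnot(inherits(system, "model_system"),
            inherits(schedule, "parameter_schedule"))
  bad <- setdiff(unique(schedule$windows$param), names(system$params))
  if (length(bad))
    stop("schedule addresses unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (system$has_delay && nrow(schedule$windows) > 0L)
    stop("parameter schedules are not supported for delayed systems",
         call. = FALSE)
  system$schedule <- schedule
  system
}

#' Sinusoidal circadian forcing of the Cdk1 switch
#'
#' Specifies the unidirectional coupling of the cell cycle to the circadian
#' clock: the Cdk1-switch bend parameter oscillates as
#' \eqn{\alpha^*_{cdk}(t) = \alpha_{cdk} + A_{cdk} + A_{cdk}
#' \sin(\omega t + \phi)}, between its basal level and
#' \eqn{\alpha_{cdk} + 2 A_{cdk}} (Wee1 is under circadian control and sets
#' the Cdk1 activation threshold).
#'
#' @param A_cdk Coupling amplitude (>= 0, dimensionless).
#' @param period_h Forcing period in hours (default 24).
#' @param phase Phase offset in radians (default 0).
#' @return Object of class `forcing_spec` with `omega` in rad/min.
#' @export
forcing_spec <- function(A_cdk, period_h = 24, phase = 0) {
  if (A_cdk < 0) stop("A_cdk must be >= 0", call. = FALSE)
  if (period_h <= 0) stop("period_h must be positive", call. = FALSE)
  structure(list(A_cdk = A_cdk, period_h = period_h,
                 period_min = period_h * 60,
                 omega = 2 * pi / (period_h * 60), phase = phase),
            class = "forcing_spec")
}
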