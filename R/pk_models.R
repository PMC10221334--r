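#' @importFrom stats coef lm median qt quantile rnorm runif sd setNames var
NULL

# Relative Ka ~ ke closeness below which the one-compartment solution
# switches to its repeated-root limit form.
.KA_KE_TOL <- 1e-8

# Core closed-form evaluators work on a bare parameter list so the
# population simulator can call them with per-subject perturbed values
# without rebuilding validated spec objects in the Monte Carlo hot path.

.conc_one_cpt <- function(dose, Ka, ClF, V1F, times) {
  ke <- ClF / V1F
  if (abs(Ka - ke) <= .KA_KE_TOL * max(Ka, ke)) {
    conc <- dose * Ka * times / V1F * exp(-Ka * times)
  } else {
    conc <- dose * Ka / (V1F * (Ka - ke)) * (exp(-ke * times) - exp(-Ka * times))
  }
  pmax(conc, 0)
}

.two_cpt_eigen <- function(Ka, ClF, QF, V1F, V2F) {
  k10 <- ClF / V1F
  k12 <- QF / V1F
  k21 <- QF / V2F
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  if (disc < 0) disc <- 0  # cannot occur for real positive micro-constants
  alpha <- (s + sqrt(disc)) / 2
  beta <- (s - sqrt(disc)) / 2
  list(alpha = alpha, beta = beta, k21 = k21)
}

.conc_two_cpt_lag <- function(dose, Tlag, Ka, ClF, QF, V1F, V2F, times) {
  eg <- .two_cpt_eigen(Ka, ClF, QF, V1F, V2F)
  alpha <- eg$alpha; beta <- eg$beta; k21 <- eg$k21
  # degenerate eigenstructure: fall back to the numerical integrator
  tol <- 1e-8 * alpha
  if ((alpha - beta) < tol || abs(Ka - alpha) < tol || abs(Ka - beta) < tol) {
    return(.conc_ode(list(model_kind = "two_compartment_oral_lag", dose = dose,
                          Tlag = Tlag, Ka = Ka, ClF = ClF, QF = QF,
                          V1F = V1F, V2F = V2F), times))
  }
  tt <- pmax(times - Tlag, 0)
  A <- (k21 - alpha) / ((Ka - alpha) * (beta - alpha))
  B <- (k21 - beta) / ((Ka - beta) * (alpha - beta))
  Cc <- (k21 - Ka) / ((alpha - Ka) * (beta - Ka))
  conc <- dose * Ka / V1F *
    (A * exp(-alpha * tt) + B * exp(-beta * tt) + Cc * exp(-Ka * tt))
  conc[times <= Tlag] <- 0
  pmax(conc, 0)
}

.conc_params <- function(spec, params, times) {
  if (spec$model_kind == "one_compartment_oral") {
    .conc_one_cpt(spec$dose, params[["Ka"]], params[["ClF"]], params[["V1F"]],
                  times)
  } else {
    .conc_two_cpt_lag(spec$dose, params[["Tlag"]], params[["Ka"]],
                      params[["ClF"]], params[["QF"]], params[["V1F"]],
                      params[["V2F"]], times)
  }
}

#' Noise-free concentration-time profile (analytic solution)
#'
#' Evaluates the closed-form solution of the spec's compartmental model at
#' the requested times. For the one-compartment oral model this is the
#' Bateman equation
#' \deqn{C(t) = \frac{D\,K_a}{V_1 (K_a-k_e)}\left(e^{-k_e t}-e^{-K_a t}\right)}
#' with \eqn{k_e = Cl/V_1}, switching to the repeated-root limit
#' \eqn{C(t) = D K_a t\, e^{-K_a t} / V_1} when \eqn{K_a \approx k_e}.
#' For the two-compartment oral model with absorption lag it is the
#' standard tri-exponential solution in the disposition eigenvalues
#' \eqn{\alpha,\beta}, time-shifted by `Tlag` (zero before the lag). If the
#' eigenstructure is degenerate (\eqn{\alpha\approx\beta} or
#' \eqn{K_a \approx \alpha,\beta}) the profile is integrated numerically
#' instead.
#'
#' @param spec A [drug_spec()].
#' @param times Numeric vector of times (min), all `>= 0`. Defaults to the
#'   spec's sampling schedule.
#' @return Numeric vector of concentrations (ug/mL), non-negative,
#'   `C(0) = 0`.
#' @seealso [pk_profile_ode()] for the independent numerical solution.
#' @export
pk_profile <- function(spec, times = spec$sampling_times) {
  stopifnot(inherits(spec, "drug_spec"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  .conc_params(spec, spec[c("Tlag", "Ka", "ClF", "QF", "V1F", "V2F")], times)
}

.conc_ode <- function(spec, times, rel_tol = 1e-8) {
  two_cpt <- spec$model_kind == "two_compartment_oral_lag"
  Ka <- spec$Ka; k10 <- spec$ClF / spec$V1F
  k12 <- if (two_cpt) spec$QF / spec$V1F else 0
  k21 <- if (two_cpt) spec$QF / spec$V2F else 0
  Tlag <- if (is.null(spec$Tlag)) 0 else spec$Tlag
  deriv <- function(t, y, p) {
    absorbing <- if (t >= Tlag) 1 else 0
    dA_depot <- -Ka * y[1] * absorbing
    dA_c <- Ka * y[1] * absorbing - (k10 + k12) * y[2] + k21 * y[3]
    dA_p <- k12 * y[2] - k21 * y[3]
    dA_el <- k10 * y[2]
    list(c(dA_depot, dA_c, dA_p, dA_el))
  }
  solve_times <- sort(unique(c(0, Tlag, times)))
  out <- deSolve::ode(y = c(depot = spec$dose, central = 0, peripheral = 0,
                            eliminated = 0),
                      times = solve_times, func = deriv, parms = NULL,
                      method = "ode45", rtol = rel_tol, atol = rel_tol * spec$dose)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed at rel_tol = ", rel_tol, call. = FALSE)
  out
}

#' Numerical ODE solution of the compartmental model
#'
#' Integrates the depot -> central (-> peripheral) first-order system with
#' an adaptive Runge-Kutta scheme (Dormand-Prince 4(5) via
#' \pkg{deSolve}). This is the model-independent cross-check for the
#' closed-form solutions in [pk_profile()]; the two agree to within 0.1%
#' for all shipped parameterizations.
#'
#' @inheritParams pk_profile
#' @param rel_tol Relative integration tolerance.
#' @param full If `TRUE`, return the full compartment-amount matrix
#'   (columns `time`, `depot`, `central`, `peripheral`, `eliminated`, in
#'   mass units) instead of central concentrations.
#' @return Concentrations (ug/mL) at `times`, or the amount matrix when
#'   `full = TRUE`.
#' @export
pk_profile_ode <- function(spec, times = spec$sampling_times,
                           rel_tol = 1e-8, full = FALSE) {
  stopifnot(inherits(spec, "drug_spec"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  out <- .conc_ode(spec, times, rel_tol)
  if (full) return(out)
  idx <- match(times, out[, "time"])
  pmax(out[idx, "central"], 0) / spec$V1F
}

#' Disposition eigenvalues of a two-compartment spec
#'
#' Returns the hybrid rate constants \eqn{\alpha > \beta} of the
#' two-compartment disposition matrix; \eqn{\beta} governs the terminal
#' log-linear decline.
#'
#' @param spec A two-compartment [drug_spec()].
#' @return Named numeric vector `c(alpha, beta)` (1/min).
#' @export
disposition_eigenvalues <- function(spec) {
  stopifnot(inherits(spec, "drug_spec"),
            spec$model_kind == "two_compartment_oral_lag")
  eg <- .two_cpt_eigen(spec$Ka, spec$ClF, spec$QF, spec$V1F, spec$V2F)
  c(alpha = eg$alpha, beta = eg$beta)
}
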