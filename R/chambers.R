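#' Chamber parameter set for a time-varying elastance chamber
#'
#' Bundles the constants of the elastance pressure law for one chamber (or one
#' ventricular territory): a linear end-systolic pressure-volume relationship
#' (ESPVR) with slope \code{Ees} and volume intercept \code{V0}, an
#' exponential end-diastolic pressure-volume relationship (EDPVR) with scale
#' \code{A} and exponent \code{B}, and the activation-time constants
#' \code{Tmax} (time to end systole) and \code{tau} (relaxation time
#' constant).
#'
#' @param Ees maximal chamber elastance (mmHg/ml), > 0.
#' @param V0 volume at zero end-systolic pressure (ml); may be negative for
#'   the left ventricle, where the linear ESPVR extrapolates below the
#'   physiological volume range.
#' @param A EDPVR scale (mmHg), >= 0.
#' @param B EDPVR exponent (1/ml), > 0.
#' @param Tmax time to end systole (s), > 0.
#' @param tau relaxation time constant (s), > 0.
#' @return An object of class \code{chamber_params}.
#' @examples
#' lv <- chamber_params(Ees = 3.18, V0 = -15, A = 12.8, B = 0.015,
#'                      Tmax = 0.2, tau = 0.04)
#' end_systolic_pressure(45, lv)
#' @export
chamber_params <- function(Ees, V0, A, B, Tmax, tau) {
  stopifnot(is.numeric(Ees), is.numeric(V0), is.numeric(A), is.numeric(B),
            is.numeric(Tmax), is.numeric(tau))
  if (Ees <= 0) stop("'Ees' must be positive", call. = FALSE)
  if (A < 0) stop("'A' must be non-negative", call. = FALSE)
  if (B <= 0) stop("'B' must be positive", call. = FALSE)
  if (Tmax <= 0) stop("'Tmax' must be positive", call. = FALSE)
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  structure(list(Ees = Ees, V0 = V0, A = A, B = B, Tmax = Tmax, tau = tau),
            class = "chamber_params")
}

#' Activation schedule: cardiac period and dyssynchrony timing
#'
#' Holds the cardiac period and the three timing controls of the model: the
#' LCX-territory activation delay \code{dt_lcx} (written Delta-t below), the
#' global delay \code{dt_bar} applied to both territories' intramyocardial
#' pressure clocks, and the systolic dyssynchrony index \code{SDI}.  If
#' \code{SDI} is supplied, \code{dt_lcx} is derived as \code{T * SDI}.
#'
#' @param T cardiac period (s); default 0.6 s (100 beats/min pacing).
#' @param dt_lcx LCX activation delay (s) in \code{[0, T)}.
#' @param dt_bar delay of both territories' intramyocardial-pressure
#'   activation clocks relative to the ventricular pressure clock (s).
#' @param SDI systolic dyssynchrony index, fraction of the cycle in
#'   \code{[0, 1)}; when given it overrides \code{dt_lcx}.
#' @param la_offset left-atrial phase advance (s).  The atrial activation
#'   is evaluated at \code{t + la_offset}; the default (0.105 s with the
#'   default atrial \code{Tmax} of 0.125 s) centres the atrial kick just
#'   after ventricular activation onset, so in control the ventricular
#'   pressure rise truncates the kick and delayed activation releases it.
#' @return An object of class \code{activation_schedule}.
#' @examples
#' activation_schedule(T = 0.6, SDI = 0.10)$dt_lcx  # 0.06 s
#' @export
activation_schedule <- function(T = 0.6, dt_lcx = 0, dt_bar = 0, SDI = NULL,
                                la_offset = 0.105) {
  if (T <= 0) stop("cardiac period 'T' must be positive", call. = FALSE)
  if (!is.null(SDI)) dt_lcx <- sdi_to_delay(SDI, T)
  if (dt_lcx < 0 || dt_lcx >= T) stop("'dt_lcx' must lie in [0, T)", call. = FALSE)
  if (dt_bar < 0 || dt_bar >= T) stop("'dt_bar' must lie in [0, T)", call. = FALSE)
  structure(list(T = T, dt_lcx = dt_lcx, dt_bar = dt_bar,
                 SDI = if (is.null(SDI)) dt_lcx / T else SDI,
                 la_offset = la_offset),
            class = "activation_schedule")
}

#' Convert a systolic dyssynchrony index to an activation delay
#'
#' The activation delay of the late territory is the fraction \code{SDI} of
#' one cardiac cycle: \code{dt = T * SDI}.
#'
#' @param SDI dyssynchrony index, fraction in \code{[0, 1)}.
#' @param T cardiac period (s).
#' @return Delay in seconds.
#' @export
sdi_to_delay <- function(SDI, T) {
  if (any(SDI < 0) || any(SDI >= 1))
    stop("'SDI' must lie in [0, 1)", call. = FALSE)
  T * SDI
}

#' Normalized activation function e(t)
#'
#' Piecewise activation in \code{[0, 1]}: a raised half-sine
#' \code{0.5 * (sin(pi * t / Tmax - pi/2) + 1)} up to \code{1.5 * Tmax},
#' followed by exponential relaxation \code{0.5 * exp(-(t - 1.5 * Tmax) / tau)}.
#' The two branches agree (value 0.5) at the switch point.  Time is reduced
#' modulo the cardiac period \code{T} before evaluation so that delayed and
#' advanced clocks are well defined in periodic steady state.
#'
#' @param t time (s), any real; evaluated at \code{t mod T}.
#' @param params a \code{\link{chamber_params}} (only \code{Tmax}, \code{tau}
#'   are used).
#' @param T cardiac period (s) used for the modulo reduction; \code{Inf}
#'   disables wrapping.
#' @return Activation value(s) in \code{[0, 1]}.
#' @examples
#' lv <- chamber_params(3.18, -15, 12.8, 0.015, 0.2, 0.04)
#' activation(c(0, 0.2, 0.3), lv)  # 0, 1, 0.5
#' @export
activation <- function(t, params, T = Inf) {
  Tmax <- params$Tmax
  tau <- params$tau
  if (is.finite(T)) t <- t %% T
  ifelse(t < 1.5 * Tmax,
         0.5 * (sin(pi * t / Tmax - pi / 2) + 1),
         0.5 * exp(-(t - 1.5 * Tmax) / tau))
}

#' End-systolic pressure (linear ESPVR)
#'
#' \code{Pes(V) = Ees * (V - V0)}.  Negative values are possible for
#' \code{V < V0}; the linear ESPVR is used as printed throughout.
#'
#' @param V chamber volume (ml).
#' @param params a \code{\link{chamber_params}}.
#' @return Pressure (mmHg).
#' @export
end_systolic_pressure <- function(V, params) {
  params$Ees * (V - params$V0)
}

#' End-diastolic pressure (exponential EDPVR)
#'
#' \code{Ped(V) = A * (exp(B * (V - V0)) - 1)}; strictly increasing in V.
#'
#' @inheritParams end_systolic_pressure
#' @return Pressure (mmHg).
#' @export
end_diastolic_pressure <- function(V, params) {
  params$A * expm1(params$B * (V - params$V0))
}

#' Atrial pressure from the time-varying elastance law
#'
#' \code{P(V, t) = e(t) * Pes(V) + (1 - e(t)) * Ped(V)}, with the atrial
#' activation evaluated on the atrial clock \code{t + la_offset} (mod T).
#'
#' @param V_la atrial volume (ml).
#' @param t time (s).
#' @param params atrial \code{\link{chamber_params}}.
#' @param sched an \code{\link{activation_schedule}}.
#' @return Pressure (mmHg).
#' @export
atrial_pressure <- function(V_la, t, params, sched) {
  e <- activation(t + sched$la_offset, params, sched$T)
  e * end_systolic_pressure(V_la, params) +
    (1 - e) * end_diastolic_pressure(V_la, params)
}

#' Left-ventricular pressure of the two-compartment territory model
#'
#' The LV cavity is partitioned into an LAD-territory compartment (volume
#' fraction \code{F}) and an LCX-territory compartment that share the cavity
#' pressure but activate on different clocks: the LAD territory at \code{t},
#' the LCX territory delayed by \code{sched$dt_lcx}.  Writing
#' \code{w1 = Ees_LAD * e(t)} and \code{w2 = Ees_LCX * e(t - dt)}, the cavity
#' pressure is
#' \deqn{P = \frac{w_1 w_2 (V - V_0) + P_{ed}(V)\,[F (1-e_1) w_2 + (1-F)(1-e_2) w_1]}
#'            {F w_2 + (1-F) w_1},}
#' which is the closed form of the compartment system (equal pressures,
#' volumes summing to \code{V}) when the end-diastolic pressure is evaluated
#' at the total volume.  With equal elastances and zero delay it reduces
#' exactly to the single-chamber law \code{e*Pes + (1-e)*Ped}.  When both
#' elastance weights fall below a numerical floor (deep diastole) the EDPVR
#' pressure is returned.
#'
#' @param V_lv total LV volume (ml).
#' @param t time (s).
#' @param lad,lcx \code{\link{chamber_params}} of the two territories.  The
#'   shared quantities (\code{V0}, \code{A}, \code{B}, \code{Tmax},
#'   \code{tau}) are taken from \code{lad}.
#' @param F LAD-territory volume fraction in (0, 1).
#' @param sched an \code{\link{activation_schedule}}.
#' @param weight_floor floor on the combined elastance weight (mmHg/ml)
#'   below which the diastolic limit is used.
#' @return Pressure (mmHg).
#' @export
lv_pressure <- function(V_lv, t, lad, lcx, F = 0.5, sched = activation_schedule(),
                        weight_floor = 1e-9) {
  if (F <= 0 || F >= 1) stop("'F' must lie strictly in (0, 1)", call. = FALSE)
  e1 <- activation(t, lad, sched$T)
  e2 <- activation(t - sched$dt_lcx, lad, sched$T)
  w1 <- lad$Ees * e1
  w2 <- lcx$Ees * e2
  ped <- end_diastolic_pressure(V_lv, lad)
  den <- F * w2 + (1 - F) * w1
  num <- w1 * w2 * (V_lv - lad$V0) +
    ped * (F * (1 - e1) * w2 + (1 - F) * (1 - e2) * w1)
  ifelse(den < weight_floor, ped, num / pmax(den, weight_floor))
}

#' Solve the two-compartment partition system numerically
#'
#' Independent route to the cavity pressure of \code{\link{lv_pressure}}:
#' finds the pressure \code{P} and compartment volumes \code{(V1, V2)} such
#' that both compartments (elastances \code{Ees/F} and \code{Ees/(1-F)},
#' rest volumes \code{F*V0} and \code{(1-F)*V0}, shared EDPVR evaluated at
#' total volume) carry the same pressure and the volumes sum to \code{V_lv}.
#' Used to cross-validate the closed form; not called by the simulator.
#'
#' @inheritParams lv_pressure
#' @return A list with \code{P}, \code{V_lad}, \code{V_lcx}.
#' @export
lv_partition_solve <- function(V_lv, t, lad, lcx, F = 0.5,
                               sched = activation_schedule()) {
  e1 <- activation(t, lad, sched$T)
  e2 <- activation(t - sched$dt_lcx, lad, sched$T)
  ped <- end_diastolic_pressure(V_lv, lad)
  # compartment pressure as a function of its volume V1 (LAD):
  #   P1(V1) = e1 * (Ees_LAD / F) * (V1 - F * V0) + (1 - e1) * ped
  #   P2(V2) = e2 * (Ees_LCX / (1-F)) * (V2 - (1-F) * V0) + (1 - e2) * ped
  # solve P1(V1) = P2(V_lv - V1) for V1 (linear in V1)
  a1 <- e1 * lad$Ees / F
  a2 <- e2 * lcx$Ees / (1 - F)
  b1 <- (1 - e1) * ped - a1 * F * lad$V0
  b2 <- (1 - e2) * ped - a2 * (1 - F) * lad$V0
  if (a1 + a2 < 1e-12) {
    return(list(P = ped, V_lad = F * V_lv, V_lcx = (1 - F) * V_lv))
  }
  V1 <- (a2 * V_lv + b2 - b1) / (a1 + a2)
  P <- a1 * V1 + b1
  list(P = P, V_lad = V1, V_lcx = V_lv - V1)
}

#' Compartment-resolved two-territory cavity pressure
#'
#' Alternative cavity pressure law: the two territory compartments share the
#' cavity pressure and their volumes sum to \code{V_lv}, but each
#' compartment's end-diastolic pressure is evaluated at its own volume
#' scaled to the whole-ventricle equivalent, so a relaxed territory retains
#' the finite diastolic stiffness of its EDPVR instead of being absorbed
#' into a shared end-diastolic term.  With equal elastances and zero delay
#' it coincides with the single-chamber law; under dyssynchrony it lets the
#' early territory raise cavity pressure against the passive stiffness of
#' the late one.  Solved by root finding on the compartment volume split.
#'
#' @inheritParams lv_pressure
#' @return Pressure (mmHg).
#' @export
lv_pressure_compartment <- function(V_lv, t, lad, lcx, F = 0.5,
                                    sched = activation_schedule()) {
  e1 <- activation(t, lad, sched$T)
  e2 <- activation(t - sched$dt_lcx, lad, sched$T)
  V0 <- lad$V0; A <- lad$A; B <- lad$B
  one <- function(V, e1i, e2i) {
    p1 <- function(V1) e1i * (lad$Ees / F) * (V1 - F * V0) +
      (1 - e1i) * A * expm1(B * (V1 / F - V0))
    p2 <- function(V2) e2i * (lcx$Ees / (1 - F)) * (V2 - (1 - F) * V0) +
      (1 - e2i) * A * expm1(B * (V2 / (1 - F) - V0))
    g <- function(V1) p1(V1) - p2(V - V1)
    V1 <- stats::uniroot(g, c(V - 1999, 1999), tol = 1e-12)$root
    p1(V1)
  }
  n <- max(length(V_lv), length(e1))
  V_lv <- rep_len(V_lv, n); e1 <- rep_len(e1, n); e2 <- rep_len(e2, n)
  vapply(seq_len(n), function(i) one(V_lv[i], e1[i], e2[i]), numeric(1))
}

#' Fixed-partition (mixture) two-territory cavity pressure
#'
#' Third cavity-pressure variant: the compartment volumes are pinned to the
#' prescribed split (\code{V_lad = F * V_lv}) and the cavity pressure is the
#' volume-weighted mixture of the compartment elastance laws, which reduces
#' to a single-chamber law with the arithmetic-mean activation
#' \code{ebar = F e1 + (1-F) e2} and mean elastance.  Unlike the
#' equal-pressure forms, the early territory raises cavity pressure from
#' activation onset (at reduced slope), so the pressure rise is not delayed
#' by the late territory.
#'
#' @inheritParams lv_pressure
#' @return Pressure (mmHg).
#' @export
lv_pressure_mixture <- function(V_lv, t, lad, lcx, F = 0.5,
                                sched = activation_schedule()) {
  e1 <- activation(t, lad, sched$T)
  e2 <- activation(t - sched$dt_lcx, lad, sched$T)
  ebar <- F * e1 + (1 - F) * e2
  Ebar <- F * lad$Ees + (1 - F) * lcx$Ees
  ebar * Ebar * (V_lv - lad$V0) + (1 - ebar) * end_diastolic_pressure(V_lv, lad)
}
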