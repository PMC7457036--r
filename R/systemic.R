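#' Systemic circulation parameters
#'
#' Resistances and compliances of the closed systemic loop in mmHg-ml-s
#' units, plus the proximal resistances connecting the two coronary networks
#' to the arterial compartment.  There is no pulmonary compartment: venous
#' return feeds the left atrium directly.
#'
#' @param R_ao,R_per,R_ven,R_mv aortic valve, peripheral, venous and mitral
#'   valve resistances (mmHg s/ml), all > 0.
#' @param C_art,C_ven arterial and venous compliances (ml/mmHg), > 0.
#' @param V_art0,V_ven0 arterial and venous resting volumes (ml).
#' @param R_lad,R_lcx proximal coronary inlet resistances (mmHg s/ml), > 0.
#' @return An object of class \code{circ_params}.
#' @export
circ_params <- function(R_ao = 0.02, R_per = 12, R_ven = 0.05, R_mv = 0.08,
                        C_art = 0.7, C_ven = 15, V_art0 = 40, V_ven0 = 100,
                        R_lad = 1.5, R_lcx = 3.0) {
  vals <- c(R_ao = R_ao, R_per = R_per, R_ven = R_ven, R_mv = R_mv,
            C_art = C_art, C_ven = C_ven, R_lad = R_lad, R_lcx = R_lcx)
  bad <- names(vals)[vals <= 0]
  if (length(bad))
    stop("parameters must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(R_ao = R_ao, R_per = R_per, R_ven = R_ven, R_mv = R_mv,
                 C_art = C_art, C_ven = C_ven, V_art0 = V_art0,
                 V_ven0 = V_ven0, R_lad = R_lad, R_lcx = R_lcx),
            class = "circ_params")
}

#' Unidirectional (valve) flow
#'
#' \code{(P_up - P_down) / R} when the upstream pressure is at least the
#' downstream pressure, otherwise zero (no regurgitation).
#'
#' @param P_up,P_down pressures (mmHg).
#' @param R resistance (mmHg s/ml), > 0.
#' @return Flow (ml/s), never negative.
#' @export
valve_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("'R' must be positive", call. = FALSE)
  ifelse(P_up >= P_down, (P_up - P_down) / R, 0)
}

#' Signed resistive flow
#'
#' \code{(P_up - P_down) / R}, signed.
#'
#' @inheritParams valve_flow
#' @return Flow (ml/s).
#' @export
linear_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("'R' must be positive", call. = FALSE)
  (P_up - P_down) / R
}

#' Linear compartment pressure
#'
#' \code{(V - V0) / C} for a storage compartment with resting volume
#' \code{V0} and compliance \code{C}.
#'
#' @param V volume (ml).
#' @param V0 resting volume (ml).
#' @param C compliance (ml/mmHg), > 0.
#' @return Pressure (mmHg).
#' @export
compartment_pressure <- function(V, V0, C) {
  if (any(C <= 0)) stop("'C' must be positive", call. = FALSE)
  (V - V0) / C
}

#' Volume derivatives of the four systemic storage compartments
#'
#' Mass balance of the closed loop.  The arterial compartment loses the
#' coronary network inlet flows; the venous compartment gains the network
#' outlet flows, so that total volume including coronary lumen storage is
#' exactly conserved (the networks store the difference transiently).
#'
#' @param flows named list or vector with elements \code{q_ven}, \code{q_mv},
#'   \code{q_ao}, \code{q_per}, \code{q_lad_in}, \code{q_lad_out},
#'   \code{q_lcx_in}, \code{q_lcx_out} (ml/s).
#' @return Named numeric vector \code{dV_la}, \code{dV_lv}, \code{dV_art},
#'   \code{dV_ven} (ml/s).
#' @export
loop_derivatives <- function(flows) {
  f <- as.list(flows)
  c(dV_la  = f$q_ven - f$q_mv,
    dV_lv  = f$q_mv - f$q_ao,
    dV_art = f$q_ao - f$q_per - f$q_lad_in - f$q_lcx_in,
    dV_ven = f$q_per - f$q_ven + f$q_lad_out + f$q_lcx_out)
}
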