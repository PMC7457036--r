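#' Intramyocardial pressure parameters
#'
#' Weights of the three-component intramyocardial pressure (IMP) model:
#' cavity-induced extracellular pressure (CEP, weight \code{alpha} on LV
#' pressure), time-varying elasticity (VE, weight \code{beta} in ml so that
#' \code{beta * Ees * e} is in mmHg), and shortening-induced intracellular
#' pressure (SIP, scale \code{gamma} in mmHg on \code{1 - SSR}).
#'
#' @param alpha CEP weight, in \code{[0, 1]}; default 0.8.
#' @param beta VE weight (ml), >= 0; default 5.
#' @param gamma SIP scale (mmHg), >= 0; default 20.
#' @return An object of class \code{imp_params}.
#' @export
imp_params <- function(alpha = 0.8, beta = 5, gamma = 20) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]", call. = FALSE)
  if (beta < 0) stop("'beta' must be non-negative", call. = FALSE)
  if (gamma < 0) stop("'gamma' must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "imp_params")
}

#' Myocardial stretch ratio
#'
#' \code{SSR = V_lv / EDV}: instantaneous LV volume relative to the
#' end-diastolic volume (of the previous completed cycle during
#' integration; exact at periodic steady state).  SIP vanishes at end
#' diastole and grows as the ventricle ejects.
#'
#' @param V_lv LV volume (ml).
#' @param EDV end-diastolic volume (ml), > 0.
#' @return Dimensionless stretch ratio.
#' @export
stretch_ratio <- function(V_lv, EDV) {
  if (any(EDV <= 0)) stop("'EDV' must be positive", call. = FALSE)
  V_lv / EDV
}

#' Intramyocardial pressure decomposition for one territory
#'
#' \code{IMP = alpha * P_lv + beta * Ees * e + gamma * (1 - SSR)} with the
#' activation \code{e} evaluated on the territory's (possibly delayed)
#' clock.  Returns the components and their total.
#'
#' @param P_lv LV cavity pressure (mmHg).
#' @param e_territory territory activation value in \code{[0, 1]}.
#' @param Ees_territory territory maximal elastance (mmHg/ml).
#' @param SSR stretch ratio.
#' @param p an \code{\link{imp_params}}.
#' @return A list with \code{CEP}, \code{VE}, \code{SIP}, \code{total}
#'   (mmHg each, vectorized over the inputs).
#' @export
imp <- function(P_lv, e_territory, Ees_territory, SSR, p = imp_params()) {
  CEP <- p$alpha * P_lv
  VE <- p$beta * Ees_territory * e_territory
  SIP <- p$gamma * (1 - SSR)
  list(CEP = CEP, VE = VE, SIP = SIP, total = CEP + VE + SIP)
}

#' Check IMP component constraints over one cycle
#'
#' Computes peak and mean component fractions over one steady-state cycle
#' and flags the configurations the IMP weights are meant to exclude: the
#' peak SIP should stay near 20\% of peak IMP and the sum of peak SIP and
#' peak VE must remain below 30\% of peak IMP.
#'
#' @param CEP,VE,SIP component waveforms over one cycle (mmHg, equal
#'   lengths, uniform sampling).
#' @return A list with \code{peak_sip_frac}, \code{peak_sip_ve_frac},
#'   \code{mean_frac} (named vector of mean component fractions of mean
#'   total IMP, in percent) and logical \code{violated}.
#' @export
imp_constraint_check <- function(CEP, VE, SIP) {
  total <- CEP + VE + SIP
  peak <- max(total)
  if (peak <= 0) stop("total IMP must be positive somewhere", call. = FALSE)
  mean_total <- mean(total)
  res <- list(
    peak_sip_frac = max(SIP) / peak,
    peak_sip_ve_frac = (max(SIP) + max(VE)) / peak,
    mean_frac = c(CEP = mean(CEP), VE = mean(VE), SIP = mean(SIP)) /
      mean_total * 100
  )
  res$violated <- res$peak_sip_ve_frac >= 0.30
  res
}
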