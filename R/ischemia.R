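#' Ischemia (contractility-flow coupling) parameters
#'
#' Encodes the piecewise-linear perfusion-contraction matching relationship
#' per territory: below the transitional cycle flow \code{Qn} (the
#' territory's normal cycle-total flow) the maximal elastance falls along a
#' line of slope \code{k} through the transition point \code{(Qn, Ees_n)};
#' above it the elastance stays at the non-ischemic plateau \code{Ees_n}.
#' For the reference slope \code{k = Ees_n / Qn} the ischemic line passes
#' through the origin.  A slope multiplier steepens the line about the
#' transition point while leaving \code{Qn} and \code{Ees_n} unchanged.
#'
#' @param k_lad,k_lcx ischemic-regime slopes (mmHg/ml^2), > 0.  If
#'   \code{NULL}, derived as \code{Ees_n / Qn} per territory.
#' @param Qn_lad,Qn_lcx transitional cycle flows (ml), > 0.
#' @param Ees_n non-ischemic maximal elastance (mmHg/ml); default 3.18.
#' @param mult_lad,mult_lcx slope multipliers (e.g. 10 for the steep case).
#' @return An object of class \code{ischemia_params}.
#' @examples
#' p <- ischemia_params(Qn_lad = 18.09, Qn_lcx = 9.38)
#' round(c(p$k_lad, p$k_lcx), 2)  # 0.18, 0.34
#' @export
ischemia_params <- function(k_lad = NULL, k_lcx = NULL, Qn_lad, Qn_lcx,
                            Ees_n = 3.18, mult_lad = 1, mult_lcx = 1) {
  if (Qn_lad <= 0 || Qn_lcx <= 0)
    stop("transitional flows must be positive", call. = FALSE)
  if (is.null(k_lad)) k_lad <- Ees_n / Qn_lad
  if (is.null(k_lcx)) k_lcx <- Ees_n / Qn_lcx
  if (k_lad < 0 || k_lcx < 0) stop("slopes must be non-negative", call. = FALSE)
  structure(list(k_lad = k_lad * mult_lad, k_lcx = k_lcx * mult_lcx,
                 Qn_lad = Qn_lad, Qn_lcx = Qn_lcx, Ees_n = Ees_n),
            class = "ischemia_params")
}

#' Maximal elastance from cycle-total coronary flow
#'
#' The perfusion-contraction matching law: at or above the transitional
#' flow the territory elastance is the non-ischemic \code{Ees_n}; below it,
#' the elastance follows the ischemic line
#' \code{Ees_n + k * (Q - Qn)}, clamped at zero.  With the reference slope
#' \code{k = Ees_n / Qn} this is the line through the origin,
#' \code{Ees = k * Q}.
#'
#' @param Q cycle-total flow (ml), >= 0.
#' @param p an \code{\link{ischemia_params}}.
#' @param territory \code{"lad"} or \code{"lcx"}.
#' @return Elastance (mmHg/ml) in \code{[0, Ees_n]}.
#' @examples
#' p <- ischemia_params(k_lcx = 0.34, Qn_lad = 18.09, Qn_lcx = 9.3529)
#' contractility_from_flow(5, p, "lcx")  # ~1.70
#' @export
contractility_from_flow <- function(Q, p, territory = c("lad", "lcx")) {
  territory <- match.arg(territory)
  if (any(Q < 0)) stop("'Q' must be non-negative", call. = FALSE)
  k <- if (territory == "lad") p$k_lad else p$k_lcx
  Qn <- if (territory == "lad") p$Qn_lad else p$Qn_lcx
  pmin(pmax(p$Ees_n + k * (Q - Qn), 0), p$Ees_n)
}
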