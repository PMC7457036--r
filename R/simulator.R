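#' Assemble a coupled cardiac-coronary model
#'
#' Bundles chamber parameters, systemic circulation parameters, IMP weights,
#' the activation schedule, the two coronary trees and solver settings into
#' one model object consumed by \code{\link{run_to_periodic}}.  Defaults are
#' the packaged fixed parameter set (elastance-model constants of the
#' calibration experiments) with calibration-seed values for the per-animal
#' free parameters.
#'
#' @param lv_lad,lv_lcx \code{\link{chamber_params}} of the two LV
#'   territories; they share \code{V0}, \code{A}, \code{B}, \code{Tmax},
#'   \code{tau} (taken from \code{lv_lad}) and may differ in \code{Ees}.
#' @param la atrial \code{\link{chamber_params}}.
#' @param F LAD-territory volume fraction of the LV.
#' @param circ a \code{\link{circ_params}}.
#' @param imp an \code{\link{imp_params}}.
#' @param sched an \code{\link{activation_schedule}}.
#' @param tree_lad,tree_lcx \code{coronary_tree} objects (or paths to tree
#'   files).  Defaults: 400-vessel synthetic trees with seeds 20 (LAD) and
#'   21 (LCX).
#' @param mu effective blood viscosity (mmHg s).
#' @param lv_law cavity pressure law of the two-compartment LV:
#'   \code{"shared"} (closed form with the end-diastolic pressure evaluated
#'   at the total volume) or \code{"compartment"} (each territory's EDPVR
#'   evaluated at its own scaled volume; finite diastolic stiffness of a
#'   relaxed territory, solved numerically).  See the methods vignette.
#' @param ve_cross logical; if \code{TRUE} the VE component of each
#'   territory's intramyocardial pressure uses the other territory's
#'   activation clock (the printed crossed pairing), otherwise its own.
#' @param init named list of initial volumes \code{V_la}, \code{V_lv},
#'   \code{V_art}, \code{V_ven} (ml).
#' @param solver named list: \code{rtol}, \code{atol}, \code{dt_out} (s),
#'   \code{max_cycles}, \code{tol} (periodicity tolerance, relative),
#'   \code{maxsteps}.
#' @return An object of class \code{corosim_model}.
#' @export
corosim_model <- function(lv_lad = chamber_params(3.18, -15, 12.8, 0.015, 0.2, 0.04),
                          lv_lcx = lv_lad,
                          la = chamber_params(1.50, 5, 0.044, 0.049, 0.125, 0.08),
                          F = 0.5,
                          circ = circ_params(),
                          imp = imp_params(),
                          sched = activation_schedule(),
                          tree_lad = NULL, tree_lcx = NULL,
                          mu = blood_viscosity(),
                          lv_law = c("shared", "compartment", "mixture"),
                          ve_cross = FALSE,
                          init = list(V_la = 110, V_lv = 50, V_art = 90,
                                      V_ven = 250),
                          solver = list()) {
  lv_law <- match.arg(lv_law)
  if (is.null(tree_lad)) tree_lad <- generate_tree(morphometry_spec(seed = 20L))
  if (is.null(tree_lcx)) tree_lcx <- generate_tree(morphometry_spec(seed = 21L))
  if (is.character(tree_lad)) tree_lad <- read_tree(tree_lad)
  if (is.character(tree_lcx)) tree_lcx <- read_tree(tree_lcx)
  solver <- utils::modifyList(
    list(rtol = 1e-6, atol = 1e-8, dt_out = 1e-3, max_cycles = 50L,
         tol = 1e-3, maxsteps = 50000L),
    solver)
  m <- structure(list(lv_lad = lv_lad, lv_lcx = lv_lcx, la = la, F = F,
                      circ = circ, imp = imp, sched = sched,
                      tree_lad = tree_lad, tree_lcx = tree_lcx, mu = mu,
                      lv_law = lv_law, ve_cross = isTRUE(ve_cross),
                      init = init, solver = solver),
                 class = "corosim_model")
  m$net_lad <- compile_tree(tree_lad)
  m$net_lcx <- compile_tree(tree_lcx)
  m
}

tree_block <- function(net) {
  c(net$n_nodes, net$L, net$Ap, net$Bp, net$phi_p, net$Cp,
    net$upnode, net$downnode)
}

build_parms <- function(m, Ees_lad, Ees_lcx, EDV_prev, sched = m$sched) {
  ch <- m$lv_lad; la <- m$la; ci <- m$circ; ip <- m$imp
  c(m$net_lad$n, m$net_lcx$n,
    sched$T, ch$Tmax, ch$tau, la$Tmax, la$tau, sched$la_offset,
    Ees_lad, Ees_lcx, ch$V0, ch$A, ch$B,
    la$Ees, la$V0, la$A, la$B,
    m$F, sched$dt_lcx, sched$dt_bar,
    ci$R_ao, ci$R_per, ci$R_ven, ci$R_mv,
    ci$C_art, ci$C_ven, ci$V_art0, ci$V_ven0,
    ci$R_lad, ci$R_lcx,
    ip$alpha, ip$beta, ip$gamma, EDV_prev,
    m$mu, 1e-9,
    switch(m$lv_law, shared = 0, compartment = 1, mixture = 2),
    if (m$ve_cross) 1 else 0,
    tree_block(m$net_lad), tree_block(m$net_lcx))
}

out_names <- c("P_lv", "P_la", "P_art", "P_ven",
               "q_ao", "q_mv", "q_per", "q_ven",
               "q_lad", "q_lad_out", "q_lcx", "q_lcx_out",
               "imp_lad", "imp_lcx", "cep", "ve_lad", "ve_lcx", "sip",
               "e_lad", "e_lcx")

initial_state <- function(m) {
  c(m$init$V_la, m$init$V_lv, m$init$V_art, m$init$V_ven,
    initial_lumen_volumes(m$tree_lad), initial_lumen_volumes(m$tree_lcx))
}

integrate_cycle <- function(m, state, pvec) {
  times <- seq(0, m$sched$T, by = m$solver$dt_out)
  out <- deSolve::ode(y = state, times = times, func = "derivs",
                      parms = pvec, dllname = "corosim",
                      initfunc = "initmod", nout = length(out_names),
                      outnames = out_names, method = "lsodes",
                      rtol = m$solver$rtol, atol = m$solver$atol,
                      maxsteps = m$solver$maxsteps)
  if (attr(out, "istate")[1] < 0)
    stop("cycle integration failed (istate ",
         attr(out, "istate")[1], ")", call. = FALSE)
  out
}

#' Run the coupled model to periodic steady state
#'
#' Integrates the closed-loop system cycle by cycle until the periodicity
#' criterion holds: the relative change between consecutive cycles of
#' end-diastolic volume, peak LV pressure and both cycle-total coronary
#' flows all drop below \code{solver$tol}.  The previous cycle's EDV feeds
#' the stretch-ratio (SIP) term of the IMP during the next cycle.  In the
#' ischemia scenario the territory elastances are additionally updated from
#' the previous cycle's cycle-total flows through the contractility-flow
#' relationship (under-relaxed by \code{relax}) and convergence further
#' requires the elastance update to fall below \code{ees_tol}.
#'
#' @param model a \code{\link{corosim_model}}.
#' @param scenario \code{"con"} (synchronous control), \code{"md"}
#'   (isolated mechanical dyssynchrony) or \code{"md_is"} (dyssynchrony
#'   with flow-dependent contractility).
#' @param sdi systolic dyssynchrony index; overrides the model schedule's
#'   delay via \code{dt = T * SDI} (ignored for \code{"con"}).
#' @param dt_bar IMP clock delay (s) (forced to 0 for \code{"con"}).
#' @param ischemia an \code{\link{ischemia_params}}; required for
#'   \code{"md_is"}.
#' @param relax under-relaxation factor of the elastance update.
#' @param ees_tol convergence tolerance on the elastance update (mmHg/ml).
#' @param init optional initial state vector (as returned in
#'   \code{$state}) to warm-start the run.
#' @param keep_lumen keep per-vessel lumen volumes in the returned
#'   waveforms (default drops them, retaining their total).
#' @return A list of class \code{corosim_run}: \code{waveforms} (last-cycle
#'   data frame at \code{dt_out} sampling), \code{metrics}
#'   (\code{\link{cycle_metrics}}), \code{state} (final state vector),
#'   \code{cycles}, \code{converged}, \code{history} (per-cycle metric
#'   trace), \code{Ees} (final territory elastances).
#' @export
run_to_periodic <- function(model, scenario = c("con", "md", "md_is"),
                            sdi = NULL, dt_bar = NULL, ischemia = NULL,
                            relax = 0.5, ees_tol = 1e-3, init = NULL,
                            keep_lumen = FALSE) {
  scenario <- match.arg(scenario)
  m <- model
  sched <- m$sched
  if (scenario == "con") {
    sched <- activation_schedule(T = sched$T, dt_lcx = 0, dt_bar = 0,
                                 la_offset = sched$la_offset)
  } else {
    if (!is.null(sdi)) sched <- activation_schedule(T = sched$T, SDI = sdi,
                                                    dt_bar = sched$dt_bar,
                                                    la_offset = sched$la_offset)
    if (!is.null(dt_bar)) sched$dt_bar <- dt_bar
  }
  if (scenario == "md_is" && is.null(ischemia))
    stop("scenario 'md_is' requires 'ischemia' parameters", call. = FALSE)
  Ees_lad <- m$lv_lad$Ees
  Ees_lcx <- if (scenario == "con") m$lv_lad$Ees else m$lv_lcx$Ees
  state <- if (is.null(init)) initial_state(m) else init
  EDV_prev <- max(state[2], 1)
  hist <- list()
  prev <- NULL
  converged <- FALSE
  out <- NULL
  for (cyc in seq_len(m$solver$max_cycles)) {
    pvec <- build_parms(m, Ees_lad, Ees_lcx, EDV_prev, sched)
    out <- integrate_cycle(m, state, pvec)
    nstate <- length(state)
    state <- as.numeric(out[nrow(out), 1 + seq_len(nstate)])
    met <- cycle_metrics(run_waveforms(out, nstate), sched$T)
    dees <- 0
    if (scenario == "md_is") {
      tgt_lad <- contractility_from_flow(met$sum_q_lad, ischemia, "lad")
      tgt_lcx <- contractility_from_flow(met$sum_q_lcx, ischemia, "lcx")
      new_lad <- (1 - relax) * Ees_lad + relax * tgt_lad
      new_lcx <- (1 - relax) * Ees_lcx + relax * tgt_lcx
      dees <- max(abs(new_lad - Ees_lad), abs(new_lcx - Ees_lcx))
      Ees_lad <- new_lad
      Ees_lcx <- new_lcx
    }
    hist[[cyc]] <- c(cycle = cyc, EDV = met$EDV, peak_lvp = met$peak_lvp,
                     sum_q_lad = met$sum_q_lad, sum_q_lcx = met$sum_q_lcx,
                     Ees_lad = Ees_lad, Ees_lcx = Ees_lcx)
    EDV_prev <- met$EDV
    if (!is.null(prev)) {
      rel <- abs(c(met$EDV, met$peak_lvp, met$sum_q_lad, met$sum_q_lcx) -
                   prev) / pmax(abs(prev), 1e-12)
      if (all(rel < m$solver$tol) &&
          (scenario != "md_is" || dees < ees_tol)) {
        converged <- TRUE
        break
      }
    }
    prev <- c(met$EDV, met$peak_lvp, met$sum_q_lad, met$sum_q_lcx)
  }
  history <- as.data.frame(do.call(rbind, hist))
  if (!converged)
    warning("periodicity not reached within ", m$solver$max_cycles,
            " cycles; last relative changes: ",
            paste(signif(abs(c(tail_metrics(history))), 3), collapse = ", "),
            call. = FALSE)
  wf <- run_waveforms(out, length(state), keep_lumen = keep_lumen)
  structure(list(waveforms = wf,
                 metrics = cycle_metrics(wf, sched$T),
                 state = state, cycles = cyc, converged = converged,
                 history = history, sched = sched,
                 Ees = c(lad = Ees_lad, lcx = Ees_lcx)),
            class = "corosim_run")
}

tail_metrics <- function(history) {
  n <- nrow(history)
  if (n < 2) return(NA_real_)
  a <- unlist(history[n, 2:5]); b <- unlist(history[n - 1, 2:5])
  (a - b) / pmax(abs(b), 1e-12)
}

# convert a deSolve matrix into the documented waveform data frame
run_waveforms <- function(out, nstate, keep_lumen = FALSE) {
  df <- as.data.frame(out)
  names(df)[1] <- "t"
  names(df)[2:5] <- c("V_la", "V_lv", "V_art", "V_ven")
  lumen_cols <- 5 + seq_len(nstate - 4)
  df$vol_cor <- rowSums(df[, lumen_cols, drop = FALSE])
  if (!keep_lumen) df <- df[, -lumen_cols]
  df
}

#' Per-cycle summary metrics
#'
#' Extracts the scalar cycle summaries used by calibration, the ischemia
#' feedback and scenario comparisons from one cycle of waveforms: volumes
#' (EDV, ESV), LV and arterial pressure extrema and means, the dP/dt
#' extrema (centred differences on the output grid), cycle-total coronary
#' flows (trapezoidal integral of the inlet flows) and IMP extrema/means
#' per territory.
#'
#' @param waveforms data frame with columns \code{t}, \code{V_lv},
#'   \code{P_lv}, \code{P_art} and (optionally) \code{q_lad}, \code{q_lcx},
#'   \code{imp_lad}, \code{imp_lcx} covering exactly one cycle.
#' @param T cardiac period (s).
#' @return A list of named scalars.
#' @export
cycle_metrics <- function(waveforms, T) {
  w <- waveforms
  dpdt <- diff_central(w$t, w$P_lv)
  # cycle means drop the final sample when it aliases phase 0 (t = T), so a
  # periodic waveform is not double-counted at the wrap
  keep <- if (abs(w$t[nrow(w)] - w$t[1] - T) < 1e-9) -nrow(w) else TRUE
  met <- list(
    EDV = max(w$V_lv), ESV = min(w$V_lv),
    peak_lvp = max(w$P_lv), mean_lvp = mean(w$P_lv[keep]),
    peak_part = max(w$P_art), mean_part = mean(w$P_art[keep]),
    dpdt_max = max(dpdt), dpdt_min = min(dpdt))
  if (!is.null(w$q_lad)) {
    met$sum_q_lad <- cycle_flow_total(w$t, w$q_lad, T)
    met$sum_q_lcx <- cycle_flow_total(w$t, w$q_lcx, T)
  }
  if (!is.null(w$imp_lad)) {
    met$peak_imp_lad <- max(w$imp_lad)
    met$mean_imp_lad <- mean(w$imp_lad[keep])
    met$peak_imp_lcx <- max(w$imp_lcx)
    met$mean_imp_lcx <- mean(w$imp_lcx[keep])
  }
  met
}

diff_central <- function(t, x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  (x[c(2:n, n)] - x[c(1, 1:(n - 1))]) / (t[c(2:n, n)] - t[c(1, 1:(n - 1))])
}

#' Percent change of cycle metrics between two runs
#'
#' \code{100 * (variant - reference) / reference} per shared scalar metric;
#' metrics with a zero reference are returned as \code{NA} and flagged.
#'
#' @param reference,variant metric lists from \code{\link{cycle_metrics}}.
#' @return Named numeric vector of percent changes.
#' @export
compare_scenarios <- function(reference, variant) {
  keys <- intersect(names(reference), names(variant))
  out <- vapply(keys, function(k) {
    r <- reference[[k]]; v <- variant[[k]]
    if (!is.finite(r) || r == 0) return(NA_real_)
    100 * (v - r) / r
  }, numeric(1))
  if (anyNA(out))
    warning("undefined percent change (zero reference) for: ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Pure-R right-hand side of the coupled system
#'
#' Reference implementation of the full coupled derivative used to
#' cross-check the compiled core on small problems: identical model
#' semantics built from the exported module functions
#' (\code{\link{lv_pressure}}, \code{\link{atrial_pressure}},
#' \code{\link{valve_flow}}, \code{\link{network_rhs}}, \code{\link{imp}}).
#'
#' @param t time (s).
#' @param state state vector as in \code{\link{run_to_periodic}}.
#' @param model a \code{\link{corosim_model}}.
#' @param Ees_lad,Ees_lcx territory elastances (mmHg/ml).
#' @param EDV_prev reference EDV for the stretch ratio (ml).
#' @param sched an \code{\link{activation_schedule}}.
#' @return List with \code{dstate} and the auxiliary outputs.
#' @export
coupled_rhs_r <- function(t, state, model, Ees_lad = model$lv_lad$Ees,
                          Ees_lcx = model$lv_lcx$Ees,
                          EDV_prev = model$init$V_lv, sched = model$sched) {
  m <- model
  V_la <- state[1]; V_lv <- state[2]; V_art <- state[3]; V_ven <- state[4]
  n1 <- m$net_lad$n
  vol_lad <- state[4 + seq_len(n1)]
  vol_lcx <- state[4 + n1 + seq_len(m$net_lcx$n)]
  lad_ch <- m$lv_lad; lad_ch$Ees <- Ees_lad
  lcx_ch <- m$lv_lad; lcx_ch$Ees <- Ees_lcx
  P_lv <- switch(m$lv_law,
    compartment = lv_pressure_compartment(V_lv, t, lad_ch, lcx_ch, m$F, sched),
    mixture = lv_pressure_mixture(V_lv, t, lad_ch, lcx_ch, m$F, sched),
    lv_pressure(V_lv, t, lad_ch, lcx_ch, m$F, sched))
  P_la <- atrial_pressure(V_la, t, m$la, sched)
  P_art <- compartment_pressure(V_art, m$circ$V_art0, m$circ$C_art)
  P_ven <- compartment_pressure(V_ven, m$circ$V_ven0, m$circ$C_ven)
  q_ao <- valve_flow(P_lv, P_art, m$circ$R_ao)
  q_mv <- valve_flow(P_la, P_lv, m$circ$R_mv)
  q_per <- linear_flow(P_art, P_ven, m$circ$R_per)
  q_ven <- linear_flow(P_ven, P_la, m$circ$R_ven)
  ssr <- stretch_ratio(V_lv, EDV_prev)
  if (m$ve_cross) {
    e_lad_imp <- activation(t - sched$dt_lcx - sched$dt_bar, m$lv_lad, sched$T)
    e_lcx_imp <- activation(t - sched$dt_bar, m$lv_lad, sched$T)
  } else {
    e_lad_imp <- activation(t - sched$dt_bar, m$lv_lad, sched$T)
    e_lcx_imp <- activation(t - sched$dt_lcx - sched$dt_bar, m$lv_lad, sched$T)
  }
  i_lad <- imp(P_lv, e_lad_imp, Ees_lad, ssr, m$imp)
  i_lcx <- imp(P_lv, e_lcx_imp, Ees_lcx, ssr, m$imp)
  r_lad <- network_rhs(vol_lad, m$net_lad, P_art, P_ven, i_lad$total,
                       m$circ$R_lad, m$mu)
  r_lcx <- network_rhs(vol_lcx, m$net_lcx, P_art, P_ven, i_lcx$total,
                       m$circ$R_lcx, m$mu)
  dloop <- loop_derivatives(list(q_ven = q_ven, q_mv = q_mv, q_ao = q_ao,
                                 q_per = q_per,
                                 q_lad_in = r_lad$q_in,
                                 q_lad_out = r_lad$q_out,
                                 q_lcx_in = r_lcx$q_in,
                                 q_lcx_out = r_lcx$q_out))
  list(dstate = c(dloop, r_lad$dvol, r_lcx$dvol),
       P_lv = P_lv, P_la = P_la, P_art = P_art, P_ven = P_ven,
       q_ao = q_ao, q_mv = q_mv, q_per = q_per, q_ven = q_ven,
       q_lad = r_lad$q_in, q_lad_out = r_lad$q_out,
       q_lcx = r_lcx$q_in, q_lcx_out = r_lcx$q_out,
       imp_lad = i_lad$total, imp_lcx = i_lcx$total)
}
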