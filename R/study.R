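#' Default study model for the packaged experiments
#'
#' Builds the model at the packaged study conditions: 100 beats/min pacing,
#' the fixed elastance constants, IMP weights 0.8/5/20, and 400-vessel
#' synthetic coronary trees whose generation seeds are derived from
#' \code{seed}.  Per-animal free parameters start from the packaged
#' calibration seeds and are meant to be fitted with \code{\link{calibrate}}.
#'
#' @param seed integer; the two tree seeds are derived from it, so the
#'   whole study is reproducible from this one number.
#' @param ... overrides passed on to \code{\link{corosim_model}}.
#' @return A \code{\link{corosim_model}}.
#' @export
study_model <- function(seed = 1L, ...) {
  seed <- as.integer(seed) %% 1000000L
  corosim_model(
    tree_lad = generate_tree(morphometry_spec(seed = seed * 1000L + 20L)),
    tree_lcx = generate_tree(morphometry_spec(seed = seed * 1000L + 21L)),
    ...)
}

#' Calibrate and run the full dyssynchrony / ischemia scenario set
#'
#' For each animal in the packaged measurement table: calibrates the model
#' to the four measured targets, then runs (warm-started from the
#' calibrated control) isolated mechanical dyssynchrony at the requested
#' SDI levels, the IMP-delay variant (SDI = 10\% with \code{dt_bar}), and
#' the two ischemia-feedback cases (per-animal slopes derived as
#' \code{Ees_n / Q_measured}, and the same with the LCX slope multiplied
#' tenfold).  Percent changes are computed against the calibrated control
#' (and, for the ischemia runs, against the isolated-dyssynchrony run).
#'
#' @param animals integer vector of rows of the targets table to process.
#' @param seed integer seed forwarded to \code{\link{study_model}}.
#' @param targets data frame as returned by \code{\link{swine_targets}}.
#' @param sdi_levels SDI values for the isolated-dyssynchrony runs.
#' @param dt_bar IMP delay (s) of the delay variant.
#' @param run_ischemia logical; run the feedback scenarios.
#' @param verbose print progress.
#' @return A list with one element per animal (fit, runs, percent-change
#'   vectors) plus \code{summary}, a data frame of the headline percent
#'   changes with a three-animal mean row.
#' @export
run_study <- function(animals = 1:3, seed = 1L, targets = swine_targets(),
                      sdi_levels = c(0.05, 0.10, 0.15), dt_bar = 0.07,
                      run_ischemia = TRUE, verbose = FALSE) {
  out <- list()
  rows <- list()
  for (a in animals) {
    if (verbose) message("animal ", a, ": calibrating")
    tg <- calibration_targets(targets$sum_q_lad[a], targets$sum_q_lcx[a],
                              targets$lv_edv[a], targets$peak_lvp[a])
    fit <- calibrate(study_model(seed), tg)
    m <- fit$model
    con <- fit$run
    res <- list(fit = fit, con = con, md = list())
    for (s in sdi_levels) {
      if (verbose) message("animal ", a, ": MD at SDI = ", s)
      run <- suppressWarnings(run_to_periodic(m, "md", sdi = s,
                                              init = con$state))
      res$md[[paste0("sdi", round(100 * s))]] <-
        list(run = run, pc = compare_scenarios(con$metrics, run$metrics))
    }
    if (!is.null(dt_bar)) {
      run <- suppressWarnings(run_to_periodic(m, "md", sdi = 0.10,
                                              dt_bar = dt_bar,
                                              init = con$state))
      res$md_dtbar <- list(run = run,
                           pc = compare_scenarios(con$metrics, run$metrics))
    }
    if (run_ischemia) {
      md10 <- res$md$sdi10$run
      isc <- ischemia_params(Qn_lad = con$metrics$sum_q_lad,
                             Qn_lcx = con$metrics$sum_q_lcx,
                             Ees_n = m$lv_lad$Ees)
      if (verbose) message("animal ", a, ": MD+IS")
      mdis <- suppressWarnings(run_to_periodic(m, "md_is", sdi = 0.10,
                                               ischemia = isc,
                                               init = md10$state))
      isc10 <- ischemia_params(Qn_lad = con$metrics$sum_q_lad,
                               Qn_lcx = con$metrics$sum_q_lcx,
                               Ees_n = m$lv_lad$Ees, mult_lcx = 10)
      if (verbose) message("animal ", a, ": MD+IS (10x LCX slope)")
      mdis10 <- suppressWarnings(run_to_periodic(m, "md_is", sdi = 0.10,
                                                 ischemia = isc10,
                                                 init = md10$state))
      res$ischemia <- list(
        params = isc, params10 = isc10,
        mdis = mdis, mdis10 = mdis10,
        pc_vs_md = compare_scenarios(md10$metrics, mdis$metrics),
        pc10_vs_md = compare_scenarios(md10$metrics, mdis10$metrics))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      animal = a,
      cal_err_edv = unname(fit$errors["lv_edv"]),
      cal_err_peak_lvp = unname(fit$errors["peak_lvp"]),
      edv_model = con$metrics$EDV,
      dq_lad_sdi10 = res$md$sdi10$pc[["sum_q_lad"]],
      dq_lcx_sdi10 = res$md$sdi10$pc[["sum_q_lcx"]],
      dq_lad_sdi15 = if ("sdi15" %in% names(res$md))
        res$md$sdi15$pc[["sum_q_lad"]] else NA_real_,
      dq_lcx_sdi15 = if ("sdi15" %in% names(res$md))
        res$md$sdi15$pc[["sum_q_lcx"]] else NA_real_,
      dq_lad_dtbar = if (!is.null(res$md_dtbar))
        res$md_dtbar$pc[["sum_q_lad"]] else NA_real_,
      dq_lcx_dtbar = if (!is.null(res$md_dtbar))
        res$md_dtbar$pc[["sum_q_lcx"]] else NA_real_,
      dq_lcx_is_vs_md = if (run_ischemia)
        res$ischemia$pc_vs_md[["sum_q_lcx"]] else NA_real_,
      dq_lad_is_vs_md = if (run_ischemia)
        res$ischemia$pc_vs_md[["sum_q_lad"]] else NA_real_,
      dpdt_red_is10 = if (run_ischemia)
        -res$ischemia$pc10_vs_md[["dpdt_max"]] else NA_real_)
    out[[paste0("animal", a)]] <- res
  }
  summary <- do.call(rbind, rows)
  mean_row <- summary[1, ]
  mean_row$animal <- NA
  for (j in names(summary)[-1]) mean_row[[j]] <- mean(summary[[j]])
  out$summary <- rbind(summary, mean_row)
  out
}

#' Mean IMP component fractions of a control run
#'
#' Time-mean of each IMP component over one steady-state cycle, expressed
#' as a percentage of the mean total IMP (LAD territory; identical to the
#' LCX in control).
#'
#' @param run a control \code{corosim_run}.
#' @return Named vector (percent): \code{CEP}, \code{VE}, \code{SIP}.
#' @export
imp_mean_fractions <- function(run) {
  w <- run$waveforms
  keep <- -nrow(w)
  chk <- imp_constraint_check(w$cep[keep], w$ve_lad[keep], w$sip[keep])
  chk$mean_frac
}
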