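# Integration tests on a reduced model (two ~21-vessel trees): the physics
# and conservation properties are size-independent, and the compiled core is
# cross-checked against the pure-R module composition.

test_that("compiled derivative matches the pure-R module composition", {
  m <- small_model()
  state <- corosim:::initial_state(m)
  set.seed(33)
  state <- state * runif(length(state), 0.97, 1.03)
  sched <- activation_schedule(T = 0.6, SDI = 0.1, dt_bar = 0.03,
                               la_offset = m$sched$la_offset)
  pvec <- corosim:::build_parms(m, 3.18, 2.5, EDV_prev = 52, sched = sched)
  for (t in c(0.01, 0.13, 0.31, 0.55)) {
    rr <- coupled_rhs_r(t, state, m, Ees_lad = 3.18, Ees_lcx = 2.5,
                        EDV_prev = 52, sched = sched)
    # drive the compiled core through a zero-length integration at t
    cc <- deSolve::ode(y = state, times = c(t, t + 1e-9), func = "derivs",
                       parms = pvec, dllname = "corosim",
                       initfunc = "initmod", nout = 20,
                       outnames = corosim:::out_names, method = "lsodes")
    # compare auxiliary outputs at the initial time
    expect_equal(unname(cc[1, "P_lv"]), unname(rr$P_lv), tolerance = 1e-10)
    expect_equal(unname(cc[1, "P_la"]), unname(rr$P_la), tolerance = 1e-10)
    expect_equal(unname(cc[1, "q_lad"]), unname(rr$q_lad), tolerance = 1e-8)
    expect_equal(unname(cc[1, "q_lcx"]), unname(rr$q_lcx), tolerance = 1e-8)
    expect_equal(unname(cc[1, "imp_lad"]), unname(rr$imp_lad),
                 tolerance = 1e-10)
    expect_equal(unname(cc[1, "imp_lcx"]), unname(rr$imp_lcx),
                 tolerance = 1e-10)
  }
})

test_that("whole-loop volume is conserved over ten cycles", {
  m <- small_model(solver = list(max_cycles = 10L, tol = 0,
                                 rtol = 1e-7, atol = 1e-9))
  run <- suppressWarnings(run_to_periodic(m, "con"))
  expect_equal(run$cycles, 10L)
  state0 <- corosim:::initial_state(m)
  total0 <- sum(state0)
  total1 <- sum(run$state)
  expect_lt(abs(total1 - total0), 1e-3)
  # and within the returned cycle, sample by sample (solver-tolerance bound)
  w <- run$waveforms
  tot <- w$V_la + w$V_lv + w$V_art + w$V_ven + w$vol_cor
  expect_lt(max(abs(tot - total0)), 5e-3)
})

test_that("control run converges to a physiological periodic state", {
  m <- small_model()
  run <- run_to_periodic(m, "con")
  expect_true(run$converged)
  met <- run$metrics
  expect_gt(met$EDV, met$ESV)
  expect_gt(met$sum_q_lad, 0)
  expect_gt(met$sum_q_lcx, 0)
  w <- run$waveforms
  # valve flows never negative
  expect_true(all(w$q_ao >= 0))
  expect_true(all(w$q_mv >= 0))
  # conservation through the LV at periodicity: inflow equals outflow
  sv_in <- cycle_flow_total(w$t, w$q_mv, m$sched$T)
  sv_out <- cycle_flow_total(w$t, w$q_ao, m$sched$T)
  expect_equal(sv_in, sv_out, tolerance = 0.02)
  # two consecutive post-convergence cycles agree in EDV
  n <- nrow(run$history)
  expect_lt(abs(run$history$EDV[n] - run$history$EDV[n - 1]) /
              run$history$EDV[n - 1], m$solver$tol)
})

test_that("coronary flow is diastolic-dominant with an early-systolic dip", {
  m <- small_model()
  run <- run_to_periodic(m, "con")
  w <- run$waveforms
  Tmax <- m$lv_lad$Tmax
  systole <- w$t <= 1.5 * Tmax
  early <- w$t <= 0.06
  late_diastole <- w$t >= 0.45 & w$t <= 0.58
  # peak flow falls in diastole, early-systolic flow dips below it
  expect_gt(max(w$q_lad[late_diastole]), max(w$q_lad[early]))
  expect_lt(min(w$q_lad[early]), min(w$q_lad[late_diastole]))
  expect_gt(w$t[which.max(w$q_lad)], 1.5 * Tmax)
})

test_that("cycle metrics recover closed-form features of synthetic waveforms", {
  t <- seq(0, 0.6, by = 1e-3)
  w <- data.frame(t = t,
                  V_lv = 35 + 15 * cos(2 * pi * t / 0.6),
                  P_lv = 60 - 50 * cos(2 * pi * t / 0.6),
                  P_art = 90 + 10 * sin(2 * pi * t / 0.6))
  met <- cycle_metrics(w, 0.6)
  expect_equal(met$EDV, 50)
  expect_equal(met$ESV, 20)
  expect_equal(met$peak_lvp, 110)
  expect_equal(met$mean_lvp, 60, tolerance = 1e-6)
  # max dP/dt of A*(1-cos) is A*2*pi/T
  expect_equal(met$dpdt_max, 50 * 2 * pi / 0.6, tolerance = 1e-3)
  # a linear ramp has constant derivative
  w2 <- data.frame(t = t, V_lv = 40 + t, P_lv = 10 + 100 * t, P_art = 80)
  m2 <- cycle_metrics(w2, 0.6)
  expect_equal(m2$dpdt_max, 100, tolerance = 1e-9)
  expect_equal(m2$dpdt_min, 100, tolerance = 1e-9)
})

test_that("percent-change comparison is zero on identity and flags zeros", {
  m <- list(EDV = 50, peak_lvp = 110, sum_q_lad = 18)
  expect_equal(unname(compare_scenarios(m, m)), c(0, 0, 0))
  v <- list(EDV = 55, peak_lvp = 110, sum_q_lad = 9)
  pc <- compare_scenarios(m, v)
  expect_equal(unname(pc["EDV"]), 10)
  expect_equal(unname(pc["sum_q_lad"]), -50)
  z <- list(EDV = 0, peak_lvp = 110, sum_q_lad = 18)
  expect_warning(pc2 <- compare_scenarios(z, v), "zero reference")
  expect_true(is.na(pc2["EDV"]))
})

test_that("dyssynchrony delays the systolic rise and enlarges the LV", {
  m <- small_model()
  con <- run_to_periodic(m, "con")
  md <- suppressWarnings(run_to_periodic(m, "md", sdi = 0.10,
                                         init = con$state))
  t_peak_con <- con$waveforms$t[which.max(con$waveforms$P_lv)]
  t_peak_md <- md$waveforms$t[which.max(md$waveforms$P_lv)]
  expect_gt(t_peak_md, t_peak_con)
  expect_gt(md$metrics$EDV, con$metrics$EDV)
  # dP/dt-max occurs later under dyssynchrony
  d_con <- corosim:::diff_central(con$waveforms$t, con$waveforms$P_lv)
  d_md <- corosim:::diff_central(md$waveforms$t, md$waveforms$P_lv)
  expect_gt(md$waveforms$t[which.max(d_md)], con$waveforms$t[which.max(d_con)])
})

test_that("in control the two territory IMPs are identical", {
  m <- small_model()
  run <- run_to_periodic(m, "con")
  w <- run$waveforms
  expect_equal(w$imp_lad, w$imp_lcx, tolerance = 1e-12)
  # peak IMP exceeds peak CEP when beta, gamma > 0
  expect_gt(max(w$imp_lad), max(w$cep))
  # with delays, only the VE timing differs between territories
  md <- suppressWarnings(run_to_periodic(m, "md", sdi = 0.10,
                                         init = run$state))
  wm <- md$waveforms
  expect_equal(wm$imp_lad - wm$ve_lad, wm$imp_lcx - wm$ve_lcx,
               tolerance = 1e-12)
  expect_gt(max(abs(wm$ve_lad - wm$ve_lcx)), 1)
})

test_that("ischemia feedback: zero-slope reduces to isolated dyssynchrony", {
  m <- small_model()
  con <- run_to_periodic(m, "con")
  isc0 <- ischemia_params(k_lad = 0, k_lcx = 0,
                          Qn_lad = con$metrics$sum_q_lad,
                          Qn_lcx = con$metrics$sum_q_lcx)
  md <- suppressWarnings(run_to_periodic(m, "md", sdi = 0.10,
                                         init = con$state))
  mdis <- suppressWarnings(run_to_periodic(m, "md_is", sdi = 0.10,
                                           ischemia = isc0,
                                           init = con$state))
  expect_equal(mdis$Ees[["lad"]], m$lv_lad$Ees)
  expect_equal(mdis$Ees[["lcx"]], m$lv_lcx$Ees)
  expect_equal(mdis$metrics$sum_q_lcx, md$metrics$sum_q_lcx,
               tolerance = 5e-3)
})

test_that("ischemia feedback converges to a fixed point below the plateau", {
  m <- small_model()
  con <- run_to_periodic(m, "con")
  isc <- ischemia_params(Qn_lad = con$metrics$sum_q_lad,
                         Qn_lcx = con$metrics$sum_q_lcx, mult_lcx = 10)
  mdis <- suppressWarnings(run_to_periodic(m, "md_is", sdi = 0.10,
                                           ischemia = isc,
                                           init = con$state))
  expect_lte(mdis$Ees[["lad"]], m$lv_lad$Ees + 1e-12)
  expect_lte(mdis$Ees[["lcx"]], m$lv_lcx$Ees + 1e-12)
  # fixed point: the elastance implied by the converged flows matches the
  # converged elastances within the update tolerance
  expect_lt(abs(contractility_from_flow(mdis$metrics$sum_q_lcx, isc, "lcx") -
                  mdis$Ees[["lcx"]]), 0.05)
})
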