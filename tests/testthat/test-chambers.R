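test_that("activation is 0 at onset, 1 at Tmax, continuous at the branch point", {
  p <- lv_pars()
  expect_equal(activation(0, p), 0)
  expect_equal(activation(p$Tmax, p), 1)
  eps <- 1e-9
  left <- activation(1.5 * p$Tmax - eps, p)
  right <- activation(1.5 * p$Tmax + eps, p)
  expect_lt(abs(left - right), 1e-7)
  expect_equal(activation(1.5 * p$Tmax, p), 0.5)
})

test_that("activation stays in [0,1] and wraps modulo the period", {
  p <- lv_pars()
  t <- seq(-1.2, 2.4, by = 0.001)
  e <- activation(t, p, T = 0.6)
  expect_true(all(e >= 0 & e <= 1))
  expect_equal(activation(0.25, p, T = 0.6), activation(0.25 + 3 * 0.6, p, T = 0.6))
  expect_equal(activation(0.25, p, T = 0.6), activation(0.25 - 0.6, p, T = 0.6))
})

test_that("pressure laws evaluate and scale as closed forms", {
  p <- chamber_params(Ees = 3.18, V0 = 10, A = 12.8, B = 0.015,
                      Tmax = 0.2, tau = 0.04)
  expect_equal(end_systolic_pressure(10, p), 0)
  expect_equal(end_systolic_pressure(70, p), 190.8)
  expect_equal(end_systolic_pressure(p$V0 + 120, p),
               2 * end_systolic_pressure(p$V0 + 60, p))
  expect_equal(end_diastolic_pressure(10, p), 0)
  expect_equal(end_diastolic_pressure(70, p), 12.8 * (exp(0.9) - 1),
               tolerance = 1e-12)
  v <- seq(0, 100, by = 5)
  expect_true(all(diff(end_diastolic_pressure(v, p)) > 0))
})

test_that("atrial pressure interpolates between ESPVR and EDPVR", {
  la <- la_pars()
  sched <- activation_schedule(T = 0.6, la_offset = 0)
  # atrial clock: e = 1 at t = Tmax, e ~ 0 at t = 0
  V <- 40
  expect_equal(atrial_pressure(V, la$Tmax, la, sched),
               end_systolic_pressure(V, la))
  expect_equal(atrial_pressure(V, 0, la, sched),
               end_diastolic_pressure(V, la))
})

test_that("parameter validation rejects non-physical constants", {
  expect_error(chamber_params(-1, 0, 1, 0.01, 0.2, 0.04), "Ees")
  expect_error(chamber_params(1, 0, 1, 0.01, -0.2, 0.04), "Tmax")
  expect_error(sdi_to_delay(1.2, 0.6), "SDI")
  expect_error(activation_schedule(T = 0.6, dt_lcx = 0.7), "dt_lcx")
})

test_that("SDI converts to a delay as a fraction of the cycle", {
  expect_equal(sdi_to_delay(0.10, 0.6), 0.06)
  expect_equal(sdi_to_delay(0, 0.6), 0)
  expect_equal(sdi_to_delay(0.15, 0.6), 0.09)
  expect_equal(activation_schedule(T = 0.6, SDI = 0.10)$dt_lcx, 0.06)
})

test_that("two-compartment pressure reduces to the single-chamber law", {
  lad <- lv_pars(); lcx <- lv_pars()
  sched <- activation_schedule(T = 0.6, dt_lcx = 0)
  t <- seq(0, 0.6, by = 0.002)
  for (F in c(0.3, 0.5, 0.7)) {
    p2 <- lv_pressure(55, t, lad, lcx, F = F, sched = sched)
    e <- activation(t, lad, 0.6)
    p1 <- e * end_systolic_pressure(55, lad) +
      (1 - e) * end_diastolic_pressure(55, lad)
    expect_equal(p2, p1, tolerance = 1e-9)
  }
})

test_that("two-compartment pressure matches the partition-system solution", {
  lad <- lv_pars(3.18); lcx <- lv_pars(2.2)
  sched <- activation_schedule(T = 0.6, SDI = 0.10)
  for (t in seq(0.0, 0.58, by = 0.02)) {
    for (V in c(25, 45, 60)) {
      closed <- lv_pressure(V, t, lad, lcx, F = 0.4, sched = sched)
      part <- lv_partition_solve(V, t, lad, lcx, F = 0.4, sched = sched)
      expect_equal(closed, part$P, tolerance = 1e-9)
      expect_equal(part$V_lad + part$V_lcx, V, tolerance = 1e-9)
    }
  }
})

test_that("lv pressure is invariant under swapping territory labels", {
  lad <- lv_pars(3.18); lcx <- lv_pars(2.0)
  T <- 0.6; dt <- 0.06
  # interior times only: the activation wrap at t = 0 is a branch point
  # where opposite-side floating rounding of the clock arguments differs
  t <- seq(0.005, 0.595, by = 0.01)
  # original: LAD activates at t, LCX at t - dt, LAD fraction F
  p_orig <- lv_pressure(50, t, lad, lcx, F = 0.35,
                        sched = activation_schedule(T = T, dt_lcx = dt))
  # swapped: treat LCX as the reference territory (activates at t) and LAD
  # as delayed; evaluating the swapped system at t' = t - dt reproduces the
  # same physical instant
  p_swap <- lv_pressure(50, t - dt, lcx, lad, F = 1 - 0.35,
                        sched = activation_schedule(T = T, dt_lcx = T - dt))
  expect_equal(p_orig, p_swap, tolerance = 1e-9)
})

test_that("delayed activation shifts the systolic pressure rise", {
  lad <- lv_pars(); lcx <- lv_pars()
  t <- seq(0, 0.6, by = 0.001)
  p0 <- lv_pressure(50, t, lad, lcx, sched = activation_schedule(T = 0.6))
  p1 <- lv_pressure(50, t, lad, lcx,
                    sched = activation_schedule(T = 0.6, SDI = 0.10))
  t_rise0 <- t[which.max(diff(p0))]
  t_rise1 <- t[which.max(diff(p1))]
  expect_gt(t_rise1, t_rise0)
  # F -> 1: the LAD compartment alone governs the pressure (away from the
  # guarded near-singular region where both elastance weights vanish)
  keep <- activation(t - 0.06, lad, 0.6) > 1e-3
  p_f1 <- lv_pressure(50, t[keep], lad, lv_pars(0.5), F = 1 - 1e-9,
                      sched = activation_schedule(T = 0.6, SDI = 0.10))
  e <- activation(t[keep], lad, 0.6)
  p_single <- e * end_systolic_pressure(50, lad) +
    (1 - e) * end_diastolic_pressure(50, lad)
  expect_equal(p_f1, p_single, tolerance = 1e-6)
})

test_that("deep-diastole weight floor falls back to the EDPVR", {
  lad <- lv_pars(); lcx <- lv_pars()
  # exactly zero activation on both clocks only at isolated instants; force
  # it with a degenerate schedule evaluated at t = 0 and dt = 0
  p <- lv_pressure(50, 0, lad, lcx, sched = activation_schedule(T = 0.6))
  expect_equal(p, end_diastolic_pressure(50, lad))
})
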