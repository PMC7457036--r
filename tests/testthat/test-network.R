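test_that("diameter law hits its closed-form anchor points", {
  v <- test_vessel
  expect_equal(vessel_diameter(v$phi_p, v$Ap, v$Bp, v$phi_p, v$Cp),
               v$Ap + v$Bp)
  expect_equal(vessel_diameter(1e9, v$Ap, v$Bp, v$phi_p, v$Cp), 2 * v$Ap,
               tolerance = 1e-6)
  expect_equal(vessel_diameter(-1e9, v$Ap, v$Bp, v$phi_p, v$Cp), 2 * v$Bp,
               tolerance = 1e-6)
  dp <- seq(-200, 200, by = 5)
  D <- vessel_diameter(dp, v$Ap, v$Bp, v$phi_p, v$Cp)
  expect_true(all(diff(D) > 0))
  expect_true(all(D > 2 * v$Bp & D < 2 * v$Ap))
  # inverse consistency
  expect_equal(corosim:::vessel_dp_from_diameter(D, v$Ap, v$Bp, v$phi_p, v$Cp),
               dp, tolerance = 1e-8)
  expect_error(vessel_diameter(0, 0.01, 0.02, 45, 20), "Ap")
})

test_that("half-resistance follows the fourth-power Poiseuille law", {
  expect_equal(vessel_resistance(1, pi / 64, mu = 1), 1)
  expect_equal(vessel_resistance(0.1, 0.5, mu = 2e-5) /
                 vessel_resistance(0.2, 0.5, mu = 2e-5), 16)
  expect_error(vessel_resistance(-0.1, 1), "positive")
})

test_that("analytic capacitance matches a finite-difference of lumen volume", {
  v <- test_vessel
  h <- 1e-4
  for (dp in c(-60, -10, v$phi_p, 30, 120)) {
    fd <- (lumen_volume(dp + h, v$Ap, v$Bp, v$phi_p, v$Cp, v$L) -
             lumen_volume(dp - h, v$Ap, v$Bp, v$phi_p, v$Cp, v$L)) / (2 * h)
    an <- vessel_capacitance(dp, v$Ap, v$Bp, v$phi_p, v$Cp, v$L)
    expect_equal(an, fd, tolerance = 1e-6)
    expect_gt(an, 0)
  }
  # the diameter-law slope is maximal exactly at the sigmoid midpoint; the
  # volume capacitance (pi*L*D/2 times that slope) peaks just above it
  dp <- seq(-150, 250, by = 1)
  slope <- vessel_capacitance(dp, v$Ap, v$Bp, v$phi_p, v$Cp, v$L) /
    (pi * v$L / 2 * vessel_diameter(dp, v$Ap, v$Bp, v$phi_p, v$Cp))
  expect_equal(dp[which.max(slope)], v$phi_p)
  cc <- vessel_capacitance(dp, v$Ap, v$Bp, v$phi_p, v$Cp, v$L)
  expect_gte(dp[which.max(cc)], v$phi_p)
  expect_lte(dp[which.max(cc)], v$phi_p + v$Cp / 2)
})

test_that("network at matched boundaries is a zero-flow equilibrium", {
  tr <- small_tree(3)
  P <- 60
  vol <- initial_lumen_volumes(tr, dP = P - P)  # dP = 0 at P_T = P_in = P_out
  r <- network_rhs(vol, tr, P_in = P, P_out = P, P_T = P, R_prox = 1)
  expect_equal(r$dvol, rep(0, nrow(tr)), tolerance = 1e-10)
  expect_equal(r$q_in, 0, tolerance = 1e-10)
  expect_equal(r$q_out, 0, tolerance = 1e-10)
})

test_that("volume bookkeeping: inlet minus outlet equals total lumen rate", {
  set.seed(101)
  tr <- small_tree(5, n_trif = 1)
  vol <- initial_lumen_volumes(tr)
  for (imp in c(0, 40)) {
    r <- network_rhs(vol * runif(length(vol), 0.95, 1.05), tr,
                     P_in = 95, P_out = 8, P_T = imp, R_prox = 0.8)
    expect_equal(r$q_in - r$q_out, sum(r$dvol), tolerance = 1e-10)
  }
})

test_that("junction flows balance at every node", {
  set.seed(102)
  tr <- small_tree(4, n_trif = 1, seed = 9L)
  net <- corosim:::compile_tree(tr)
  vol <- initial_lumen_volumes(tr) * runif(net$n, 0.9, 1.1)
  r <- network_rhs(vol, tr, P_in = 90, P_out = 10, P_T = 20, R_prox = 1)
  # node 1: inlet flow in, root vessel inflow out
  root <- which(net$upnode == 1L)
  expect_equal(r$q_in, sum(r$Q_in_vessel[root]), tolerance = 1e-10)
  for (nd in 2:net$n_nodes) {
    parent <- which(net$downnode == nd)
    children <- which(net$upnode == nd)
    expect_equal(sum(r$Q_out_vessel[parent]), sum(r$Q_in_vessel[children]),
                 tolerance = 1e-10)
  }
})

test_that("three-vessel bifurcation steady flows match series/parallel algebra", {
  tr <- small_tree(1, seed = 2L)
  # drive to steady state with constant boundaries
  bc <- data.frame(t = c(0, 5), P_in = 80, P_out = 10, P_T = 0)
  out <- simulate_network(tr, bc, R_prox = 0.5, dt_out = 0.05,
                          rtol = 1e-10, atol = 1e-12)
  n <- nrow(out)
  expect_equal(out$q_in[n], out$q_out[n], tolerance = 1e-6)
  # independent route: frozen diameters at the converged state must satisfy
  # the hand-computed series/parallel resistance formula
  net <- corosim:::compile_tree(tr)
  # recover converged volumes by one more integration step is overkill;
  # instead solve the algebraic steady state directly from the linear
  # network with diameters iterated to self-consistency
  mu <- blood_viscosity()
  D <- net$tree$diameter
  for (i in 1:200) {
    lin <- linear_network_flows(tr, D, P_in = 80, P_out = 10, R_prox = 0.5,
                                mu = mu)
    D_new <- vessel_diameter(lin$P_mid - 0, net$Ap, net$Bp, net$phi_p, net$Cp)
    if (max(abs(D_new - D)) < 1e-12) break
    D <- D_new
  }
  Rh <- vessel_resistance(D, net$L, mu)
  kids <- which(net$upnode == 2L)
  R_par <- 1 / sum(1 / (2 * Rh[kids]))
  R_tot <- 0.5 + 2 * Rh[net$downnode == 2L] + R_par
  q_hand <- (80 - 10) / R_tot
  expect_equal(lin$q_in, q_hand, tolerance = 1e-10)
  expect_equal(out$q_in[n], q_hand, tolerance = 1e-5)
})

test_that("steady nonlinear network flows match the linear nodal oracle", {
  tr <- small_tree(6, n_trif = 1, seed = 12L)
  bc <- data.frame(t = c(0, 5), P_in = 90, P_out = 8, P_T = 15)
  vol0 <- initial_lumen_volumes(tr)
  net <- corosim:::compile_tree(tr)
  deriv <- function(t, y, p) list(network_rhs(y, net, 90, 8, 15, 1)$dvol)
  out <- deSolve::ode(vol0, c(0, 10), deriv, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  vol <- as.numeric(out[2, -1])
  r <- network_rhs(vol, net, 90, 8, 15, 1)
  D <- sqrt(4 * vol / (pi * net$L))
  lin <- linear_network_flows(tr, D, 90, 8, 1)
  expect_equal(r$q_in, lin$q_in, tolerance = 1e-8)
  expect_equal(r$q_out, lin$q_out, tolerance = 1e-8)
  expect_equal(r$Q_in_vessel, lin$Q, tolerance = 1e-8)
})

test_that("raising extravascular pressure impedes cycle flow", {
  tr <- small_tree(4, seed = 5L)
  T <- 0.6
  tt <- seq(0, 3 * T, by = 0.01)
  base <- data.frame(t = tt, P_in = 90 + 10 * sin(2 * pi * tt / T),
                     P_out = 8, P_T = 0)
  q0 <- simulate_network(tr, base, R_prox = 1)
  hi <- base; hi$P_T <- 30
  q1 <- simulate_network(tr, hi, R_prox = 1)
  last_cycle <- function(res) {
    keep <- res$t >= 2 * T
    cycle_flow_total(res$t[keep], res$q_in[keep], T)
  }
  expect_lt(last_cycle(q1), last_cycle(q0))
})

test_that("cycle flow integral handles constant, zero and short inputs", {
  t <- seq(0, 0.6, by = 0.01)
  expect_equal(cycle_flow_total(t, rep(1, length(t)), 0.6), 0.6)
  expect_equal(cycle_flow_total(t, rep(0, length(t)), 0.6), 0)
  expect_error(cycle_flow_total(t[t < 0.3], rep(1, 30), 0.6), "shorter")
})
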