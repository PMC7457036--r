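# Shared fixtures: tiny trees and reduced models keep most tests fast; the
# full-size study configuration lives in test-acceptance.R only.

lv_pars <- function(Ees = 3.18) {
  chamber_params(Ees = Ees, V0 = -15, A = 12.8, B = 0.015,
                 Tmax = 0.2, tau = 0.04)
}

la_pars <- function() {
  chamber_params(Ees = 1.50, V0 = 5, A = 0.044, B = 0.049,
                 Tmax = 0.125, tau = 0.04)
}

# deterministic small tree: n_bif bifurcations (+ optional trifurcations)
small_tree <- function(n_bif = 3, n_trif = 0, seed = 7L) {
  generate_tree(morphometry_spec(n_bif = n_bif, n_trif = n_trif, seed = seed))
}

# reduced coupled model for integration tests: two ~21-vessel trees
small_model <- function(..., n_bif = 10, seed_lad = 7L, seed_lcx = 8L) {
  corosim_model(tree_lad = small_tree(n_bif, seed = seed_lad),
                tree_lcx = small_tree(n_bif, seed = seed_lcx),
                ...)
}

# single-vessel constants used in vessel-law tests
test_vessel <- list(Ap = 0.065, Bp = 0.035, phi_p = 45, Cp = 24, L = 0.5)
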