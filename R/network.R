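#' Sigmoidal passive diameter law
#'
#' Vessel diameter as a function of transvascular pressure
#' \code{dP = P_mid - P_T}:
#' \deqn{D(\Delta P) = 2 \{ B_p + \frac{A_p - B_p}{\pi}
#'       [\frac{\pi}{2} + \arctan(\frac{\Delta P - \varphi_p}{C_p})] \},}
#' strictly increasing and bounded in \code{(2 Bp, 2 Ap)}; equals
#' \code{Ap + Bp} at \code{dP = phi_p}.
#'
#' @param dP transvascular pressure (mmHg).
#' @param Ap,Bp asymptotic maximal/minimal radius (cm), \code{Ap > Bp > 0}.
#' @param phi_p transvascular pressure at the mean radius (mmHg).
#' @param Cp passive bandwidth (mmHg), > 0.
#' @return Diameter (cm).
#' @export
vessel_diameter <- function(dP, Ap, Bp, phi_p, Cp) {
  if (any(Ap <= Bp)) stop("'Ap' must exceed 'Bp'", call. = FALSE)
  if (any(Cp <= 0)) stop("'Cp' must be positive", call. = FALSE)
  2 * (Bp + (Ap - Bp) / pi * (pi / 2 + atan((dP - phi_p) / Cp)))
}

# inverse of the diameter law: transvascular pressure at diameter D
vessel_dp_from_diameter <- function(D, Ap, Bp, phi_p, Cp) {
  u <- (D / 2 - Bp) / (Ap - Bp)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  phi_p + Cp * tan(pi * u - pi / 2)
}

#' Poiseuille half-resistance of a vessel
#'
#' Each half of the three-element Windkessel vessel has resistance
#' \code{64 mu L / (pi D^4)} (the two halves are equal).
#'
#' @param D diameter (cm), > 0.
#' @param L length (cm).
#' @param mu effective blood viscosity (mmHg s).
#' @return Resistance (mmHg s/ml).
#' @export
vessel_resistance <- function(D, L, mu = blood_viscosity()) {
  if (any(D <= 0)) stop("'D' must be positive", call. = FALSE)
  64 * mu * L / (pi * D^4)
}

#' Effective blood viscosity in mmHg s
#'
#' @param cP viscosity in centipoise; default 3.5 cP.
#' @return Viscosity in mmHg s (1 mmHg = 133.322 Pa).
#' @export
blood_viscosity <- function(cP = 3.5) {
  cP * 1e-3 / 133.322
}

#' Lumen volume and nonlinear capacitance of a vessel
#'
#' The lumen volume is \code{V = pi D(dP)^2 L / 4}; the capacitance is its
#' analytic derivative with respect to the transvascular pressure,
#' \code{C(dP) = dV/d(dP) = (pi L D / 2) * dD/d(dP)}, strictly positive.
#' The diameter-law slope \code{dD/d(dP)} is maximal exactly at
#' \code{dP = phi_p}; the capacitance, which weights that slope by the
#' current diameter, peaks marginally above it.
#'
#' @inheritParams vessel_diameter
#' @param L vessel length (cm).
#' @return Volume (ml) / capacitance (ml/mmHg).
#' @export
lumen_volume <- function(dP, Ap, Bp, phi_p, Cp, L) {
  D <- vessel_diameter(dP, Ap, Bp, phi_p, Cp)
  pi * D^2 * L / 4
}

#' @rdname lumen_volume
#' @export
vessel_capacitance <- function(dP, Ap, Bp, phi_p, Cp, L) {
  D <- vessel_diameter(dP, Ap, Bp, phi_p, Cp)
  dD <- 2 * (Ap - Bp) / pi * (1 / Cp) / (1 + ((dP - phi_p) / Cp)^2)
  pi * L * D / 2 * dD
}

# ---- network topology compilation -----------------------------------------

# Compile a validated tree into index arrays for the flow solver.  Nodes:
# node 1 is the inlet node (fed from P_art through the proximal resistance);
# every vessel with children owns one downstream junction node.  Terminal
# vessels drain through their own outlet half-resistance to P_out directly.
compile_tree <- function(tree) {
  validate_tree(tree)
  n <- nrow(tree)
  ord <- order(is.na(tree$parent_id), decreasing = TRUE)  # root first
  # reindex so parents precede children (creation order already does for
  # generated trees; enforce generally by topological sort)
  pidx <- match(tree$parent_id, tree$id)
  depth <- integer(n)
  for (v in seq_len(n)) {
    d <- 0L; cur <- v
    while (!is.na(pidx[cur])) { cur <- pidx[cur]; d <- d + 1L }
    depth[v] <- d
  }
  ord <- order(depth)
  tr <- tree[ord, , drop = FALSE]
  pidx <- match(tr$parent_id, tr$id)
  has_kids <- tabulate(pidx[!is.na(pidx)], nbins = n) > 0L
  downnode <- integer(n)               # 0 = terminal (drains to P_out)
  downnode[has_kids] <- seq_len(sum(has_kids)) + 1L
  upnode <- ifelse(is.na(pidx), 1L, downnode[ifelse(is.na(pidx), 1L, pidx)])
  list(n = n, tree = tr,
       upnode = as.integer(upnode), downnode = as.integer(downnode),
       n_nodes = 1L + sum(has_kids),
       L = tr$length, Ap = tr$Ap, Bp = tr$Bp,
       phi_p = tr$phi_p, Cp = tr$Cp)
}

#' Network right-hand side: lumen-volume dynamics under given boundaries
#'
#' Reference (R) implementation of the coronary network dynamics used by the
#' coupled simulator's compiled core.  State is one lumen volume per vessel;
#' mid-node pressures are recovered by inverting the diameter law, junction
#' pressures are eliminated by a local Kirchhoff balance at each node, and
#' each vessel's volume rate is the difference of its inlet and outlet half
#' flows.  This makes the capacitive term of the Windkessel exact (volume is
#' the integrated quantity) and conserves volume identically:
#' inlet flow - outlet flow = d/dt (total lumen volume).
#'
#' @param vol vector of lumen volumes (ml), one per vessel.
#' @param net a compiled tree from \code{compile_tree} (internal) or a
#'   \code{coronary_tree} (compiled on the fly).
#' @param P_in inlet (arterial) pressure upstream of the proximal
#'   resistance (mmHg).
#' @param P_out outlet (venous) pressure (mmHg).
#' @param P_T intramyocardial pressure, homogeneous over the territory
#'   (mmHg).
#' @param R_prox proximal inlet resistance (mmHg s/ml).
#' @param mu effective blood viscosity (mmHg s).
#' @return List with \code{dvol} (ml/s per vessel), \code{q_in},
#'   \code{q_out} (ml/s), \code{P_mid}, \code{P_node}, \code{Q_in_vessel},
#'   \code{Q_out_vessel}.
#' @export
network_rhs <- function(vol, net, P_in, P_out, P_T, R_prox,
                        mu = blood_viscosity()) {
  if (inherits(net, "coronary_tree")) net <- compile_tree(net)
  D <- sqrt(4 * vol / (pi * net$L))
  dP <- vessel_dp_from_diameter(D, net$Ap, net$Bp, net$phi_p, net$Cp)
  P_mid <- dP + P_T
  Rh <- vessel_resistance(D, net$L, mu)
  g <- 1 / Rh
  S <- numeric(net$n_nodes)
  G <- numeric(net$n_nodes)
  S[1] <- P_in / R_prox
  G[1] <- 1 / R_prox
  # children side: each vessel contributes to its upstream node through R1
  for (i in seq_len(net$n)) {
    u <- net$upnode[i]
    S[u] <- S[u] + g[i] * P_mid[i]
    G[u] <- G[u] + g[i]
    d <- net$downnode[i]
    if (d > 0L) {
      S[d] <- S[d] + g[i] * P_mid[i]
      G[d] <- G[d] + g[i]
    }
  }
  if (any(G <= 0))
    stop("singular junction system: a node has no finite conductance",
         call. = FALSE)
  P_node <- S / G
  Q_in <- (P_node[net$upnode] - P_mid) * g
  P_down <- ifelse(net$downnode > 0L, P_node[pmax(net$downnode, 1L)], P_out)
  Q_out <- (P_mid - P_down) * g
  list(dvol = Q_in - Q_out,
       q_in = (P_in - P_node[1]) / R_prox,
       q_out = sum(Q_out[net$downnode == 0L]),
       P_mid = P_mid, P_node = P_node,
       Q_in_vessel = Q_in, Q_out_vessel = Q_out)
}

#' Equilibrium lumen volumes at a uniform transvascular pressure
#'
#' Convenience initializer: volumes such that every vessel sits at
#' transvascular pressure \code{dP} (no flow when boundaries match).
#'
#' @param tree a \code{coronary_tree}.
#' @param dP transvascular pressure (mmHg); default each vessel's
#'   \code{phi_p}.
#' @return Vector of lumen volumes in the compiled (depth) vessel order.
#' @export
initial_lumen_volumes <- function(tree, dP = NULL) {
  net <- compile_tree(tree)
  if (is.null(dP)) dP <- net$phi_p
  lumen_volume(dP, net$Ap, net$Bp, net$phi_p, net$Cp, net$L)
}

#' Open-loop network simulation under tabulated boundary pressures
#'
#' Standalone driver: integrates the network dynamics with prescribed
#' time series of inlet, outlet and intramyocardial pressures (linearly
#' interpolated).  Used for open-loop studies and testing; the coupled
#' simulator uses the compiled core instead.
#'
#' @param tree a \code{coronary_tree} or path to a tree file.
#' @param boundary data frame with columns \code{t}, \code{P_in},
#'   \code{P_out}, \code{P_T}.
#' @param R_prox proximal inlet resistance (mmHg s/ml).
#' @param mu effective blood viscosity (mmHg s).
#' @param vol0 initial lumen volumes; default equilibrium at \code{phi_p}.
#' @param dt_out output time step (s).
#' @param rtol,atol solver tolerances.
#' @return Data frame with time, inlet/outlet flow and total lumen volume.
#' @export
simulate_network <- function(tree, boundary, R_prox = 1,
                             mu = blood_viscosity(), vol0 = NULL,
                             dt_out = 1e-3, rtol = 1e-6, atol = 1e-8) {
  if (is.character(tree)) tree <- read_tree(tree)
  req <- c("t", "P_in", "P_out", "P_T")
  if (!all(req %in% names(boundary)))
    stop("boundary table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (diff(range(boundary$t)) <= 0)
    stop("boundary table must span a positive time interval", call. = FALSE)
  net <- compile_tree(tree)
  fin <- stats::approxfun(boundary$t, boundary$P_in, rule = 2)
  fout <- stats::approxfun(boundary$t, boundary$P_out, rule = 2)
  fT <- stats::approxfun(boundary$t, boundary$P_T, rule = 2)
  if (is.null(vol0)) vol0 <- initial_lumen_volumes(tree)
  deriv <- function(t, y, p) {
    r <- network_rhs(y, net, fin(t), fout(t), fT(t), R_prox, mu)
    list(r$dvol, c(q_in = r$q_in, q_out = r$q_out, vol_total = sum(y)))
  }
  times <- seq(min(boundary$t), max(boundary$t), by = dt_out)
  out <- deSolve::ode(vol0, times, deriv, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  data.frame(t = out[, "time"], q_in = out[, "q_in"],
             q_out = out[, "q_out"], vol_total = out[, "vol_total"])
}

#' Time integral of an inlet flow waveform over one cycle
#'
#' Trapezoidal integral of the flow over exactly one cardiac period,
#' yielding the cycle-total flow (ml per cycle).
#'
#' @param t sample times (s), covering at least one period.
#' @param q flow samples (ml/s).
#' @param T cardiac period (s).
#' @return Cycle-total flow (ml).
#' @export
cycle_flow_total <- function(t, q, T) {
  if (length(t) != length(q)) stop("'t' and 'q' lengths differ", call. = FALSE)
  if (diff(range(t)) < T - 1e-9)
    stop("waveform shorter than one period", call. = FALSE)
  keep <- t <= min(t) + T + 1e-12
  tt <- t[keep]; qq <- q[keep]
  sum(diff(tt) * (utils::head(qq, -1) + utils::tail(qq, -1)) / 2)
}

#' Steady flows of the frozen-diameter (linear) resistor network
#'
#' Independent nodal-analysis oracle: with diameters (hence resistances)
#' frozen and capacitive flow ignored, solves the full linear system for all
#' mid-node and junction pressures and returns the resulting flows.  Used to
#' cross-check the nonlinear network at steady state, where the capacitive
#' currents vanish and the two routes must agree.
#'
#' @param tree a \code{coronary_tree}.
#' @param D vector of frozen diameters (cm), in compiled (depth) order.
#' @param P_in,P_out boundary pressures (mmHg).
#' @param R_prox proximal inlet resistance (mmHg s/ml).
#' @param mu effective blood viscosity (mmHg s).
#' @return List with \code{q_in}, \code{q_out}, per-vessel flows \code{Q},
#'   and the node pressure vector.
#' @export
linear_network_flows <- function(tree, D, P_in, P_out, R_prox,
                                 mu = blood_viscosity()) {
  net <- compile_tree(tree)
  n <- net$n
  Rh <- vessel_resistance(D, net$L, mu)
  # unknowns: junction node pressures (n_nodes) then mid pressures (n)
  m <- net$n_nodes + n
  A <- matrix(0, m, m)
  b <- numeric(m)
  gp <- 1 / R_prox
  add <- function(i, j, v) A[i, j] <<- A[i, j] + v
  # node equations
  add(1, 1, gp); b[1] <- b[1] + gp * P_in
  for (i in seq_len(n)) {
    g <- 1 / Rh[i]
    u <- net$upnode[i]; mid <- net$n_nodes + i
    add(u, u, g); add(u, mid, -g)
    # mid-node equation: (P_up - P_mid) g + (P_down - P_mid) g = 0
    add(mid, u, g); add(mid, mid, -2 * g)
    d <- net$downnode[i]
    if (d > 0L) {
      add(mid, d, g)
      add(d, d, g); add(d, mid, -g)
    } else {
      b[mid] <- b[mid] - g * P_out
    }
  }
  x <- solve(A, b)
  P_node <- x[seq_len(net$n_nodes)]
  P_mid <- x[net$n_nodes + seq_len(n)]
  Q <- (P_node[net$upnode] - P_mid) / Rh
  list(q_in = (P_in - P_node[1]) / R_prox,
       q_out = sum(((P_mid - P_out) / Rh)[net$downnode == 0L]),
       Q = Q, P_node = P_node, P_mid = P_mid)
}
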