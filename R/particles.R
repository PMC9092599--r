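# Lagrangian particle force balance: drag (via the particle relaxation
# time), buoyancy and gravity. The velocity ODE
#   du_p/dt = (u - u_p)/tau_r + g (rho_p - rho)/rho_p
# is linear for frozen fluid velocity, so each substep uses the exact
# exponential update rather than an explicit Runge-Kutta step: tau_r is
# ~1.4e-5 s for a 15 um cell, which makes the ODE stiff relative to the
# transport time scales of interest.

#' Cell phenotype
#'
#' Defaults describe an endothelial cell modeled as a rigid sphere of
#' diameter 15 um and density 1050 kg/m^3.
#'
#' @param diameter particle diameter, m.
#' @param density particle density, kg/m^3.
#' @return A `cell_phenotype` list.
#' @export
cell_phenotype <- function(diameter = 15e-6, density = 1050) {
  if (diameter <= 0 || density <= 0)
    stop("diameter and density must be positive", call. = FALSE)
  structure(list(diameter = diameter, density = density),
            class = "cell_phenotype")
}

#' Drag correction factor f = Cd Re / 24
#'
#' Ratio of the actual drag to Stokes drag at the slip Reynolds number
#' `Re = rho |u - u_p| d_p / mu`. The default Schiller-Naumann correlation
#' `f = 1 + 0.15 Re^0.687` is valid for Re < 1000; cell slip Reynolds
#' numbers here are ~0.1 or less. `law = "stokes"` forces `f = 1`.
#'
#' @param Re slip Reynolds number (>= 0); vectorized.
#' @param law `"schiller_naumann"` (default) or `"stokes"`.
#' @return Drag factor `f >= 1`.
#' @export
drag_factor <- function(Re, law = c("schiller_naumann", "stokes")) {
  law <- match.arg(law)
  if (any(Re < 0)) stop("Re must be >= 0", call. = FALSE)
  if (law == "stokes") rep(1, length(Re)) else 1 + 0.15 * Re^0.687
}

#' Particle relaxation time
#'
#' `tau_r = rho_p d_p^2 / (18 mu f(Re))`: the characteristic time for a
#' particle to relax to the surrounding fluid velocity under drag. Equals
#' the Stokes value `rho_p d_p^2 / (18 mu)` in the Re -> 0 limit.
#'
#' @param phenotype a [cell_phenotype()].
#' @param fluid a [fluid_properties()].
#' @param slip_speed |u - u_p|, m/s (>= 0); vectorized.
#' @param law drag closure passed to [drag_factor()].
#' @return Relaxation time, s.
#' @export
relaxation_time <- function(phenotype, fluid, slip_speed = 0,
                            law = c("schiller_naumann", "stokes")) {
  if (any(slip_speed < 0)) stop("slip_speed must be >= 0", call. = FALSE)
  Re <- fluid$density * slip_speed * phenotype$diameter / fluid$viscosity
  phenotype$density * phenotype$diameter^2 /
    (18 * fluid$viscosity * drag_factor(Re, law))
}

#' Particle state
#'
#' @param id integer particle id.
#' @param position,velocity 3-vectors (m, m/s).
#' @param segment current segment id.
#' @param status one of `"suspended"`, `"deposited"`, `"exited"`.
#' @param time_injected injection time, s.
#' @return A `particle_state` list.
#' @export
particle_state <- function(id, position, velocity, segment,
                           status = "suspended", time_injected = 0) {
  stopifnot(status %in% c("suspended", "deposited", "exited"))
  structure(list(id = id, position = as.numeric(position),
                 velocity = as.numeric(velocity), segment = segment,
                 status = status, time_injected = time_injected),
            class = "particle_state")
}

# Exact exponential update of the frozen-coefficient force balance.
# pos/vel/u are n x 3 matrices, tau a length-n vector, g_buoy a 3-vector
# (already scaled by (rho_p - rho)/rho_p). Returns list(pos, vel).
#' @keywords internal
.exp_update <- function(pos, vel, u, tau, dt, g_buoy) {
  u_eff <- u + tau %o% g_buoy
  E <- exp(-dt / tau)
  dv <- vel - u_eff
  list(pos = pos + u_eff * dt + (tau * (1 - E)) * dv,
       vel = u_eff + E * dv)
}

#' Advance a particle by one substep
#'
#' Exact exponential update of the linear force-balance ODE with the fluid
#' velocity frozen over the substep: with
#' `u_eff = u + tau_r g (rho_p - rho)/rho_p`,
#' `u_p(t+dt) = u_eff + (u_p - u_eff) exp(-dt/tau_r)` and the position
#' advanced by the analytic integral of the same expression. The relaxation
#' time is evaluated at the slip speed at the start of the substep.
#'
#' @param state a [particle_state()].
#' @param fluid_velocity local fluid velocity `u`, 3-vector m/s (frozen over
#'   the substep).
#' @param dt substep, s (> 0).
#' @param gravity gravity vector, m/s^2 (default `c(0, 0, -9.81)`).
#' @param phenotype a [cell_phenotype()].
#' @param fluid a [fluid_properties()].
#' @param law drag closure passed to [drag_factor()].
#' @return Updated [particle_state()].
#' @export
step_particle <- function(state, fluid_velocity, dt,
                          gravity = c(0, 0, -9.81),
                          phenotype = cell_phenotype(),
                          fluid = media_fluid(),
                          law = c("schiller_naumann", "stokes")) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  slip <- sqrt(sum((fluid_velocity - state$velocity)^2))
  tau <- relaxation_time(phenotype, fluid, slip, law)
  g_buoy <- gravity * (phenotype$density - fluid$density) / phenotype$density
  upd <- .exp_update(matrix(state$position, 1), matrix(state$velocity, 1),
                     matrix(fluid_velocity, 1), tau, dt, g_buoy)
  state$position <- as.numeric(upd$pos)
  state$velocity <- as.numeric(upd$vel)
  state
}

# Vectorized first crossing of |w0 + t (w1 - w0)| = R_eff for t in [0, 1],
# where w0, w1 are n x 3 radial vectors relative to a fixed axis. Returns
# t (NA when no crossing); particles already at/outside R_eff report t = 0.
#' @keywords internal
.impact_fraction <- function(w0, w1, R_eff) {
  dw <- w1 - w0
  a <- rowSums(dw^2)
  b <- 2 * rowSums(w0 * dw)
  cc <- rowSums(w0^2) - R_eff^2
  t <- rep(NA_real_, nrow(w0))
  t[cc >= 0] <- 0                      # starting on/outside the wall
  disc <- b^2 - 4 * a * cc
  ok <- is.na(t) & disc >= 0 & a > 0
  root <- rep(NA_real_, nrow(w0))
  root[ok] <- (-b[ok] + sqrt(disc[ok])) / (2 * a[ok])  # outward crossing
  hit <- ok & !is.na(root) & root >= 0 & root <= 1
  t[hit] <- root[hit]
  t
}

#' Detect a wall impact along a linearized substep path
#'
#' Reports the first point at which the particle center's radial distance to
#' the local centerline piece reaches `R - d_p/2`, interpolating linearly
#' between the before/after positions. A particle already at the threshold
#' (grazing) reports an impact at fraction 0.
#'
#' @param state_before,state_after [particle_state()]s in the same segment.
#' @param segment one-row slice of the network's `segments` table.
#' @param network the [vascular_network()].
#' @param phenotype a [cell_phenotype()] (for the particle radius).
#' @return `NULL` when there is no impact, otherwise a list with `position`
#'   (3-vector), `fraction` (in [0, 1]) and `normal` (outward unit radial
#'   vector at the impact point).
#' @export
detect_wall_impact <- function(state_before, state_after, segment, network,
                               phenotype = cell_phenotype()) {
  pieces <- .network_pieces(network)
  seg_idx <- which(network$segments$id == segment$id)
  cand <- which(pieces$seg == seg_idx)
  # piece containing the starting position (by axial projection)
  pk <- NA_integer_
  for (k in cand) {
    a <- sum((state_before$position - pieces$start[k, ]) * pieces$dir[k, ])
    if (a >= -1e-12 && a <= pieces$len[k] + 1e-12) { pk <- k; break }
  }
  if (is.na(pk)) pk <- cand[1]
  axis0 <- pieces$start[pk, ]; dirv <- pieces$dir[pk, ]
  R_eff <- segment$diameter / 2 - phenotype$diameter / 2
  radial <- function(p) { rel <- p - axis0; rel - sum(rel * dirv) * dirv }
  w0 <- matrix(radial(state_before$position), 1)
  w1 <- matrix(radial(state_after$position), 1)
  t <- .impact_fraction(w0, w1, R_eff)
  if (is.na(t)) return(NULL)
  pos <- state_before$position +
    t * (state_after$position - state_before$position)
  n <- radial(pos)
  list(position = pos, fraction = t, normal = n / sqrt(sum(n^2)))
}

#' Specular reflection off the vessel wall
#'
#' Negates the wall-normal velocity component, preserves the tangential
#' component (kinetic energy is conserved), and nudges the position inward
#' by `1e-3 * d_p` to avoid an immediate re-impact.
#'
#' @param state a [particle_state()] at the wall.
#' @param wall_normal outward unit normal at the impact point.
#' @param phenotype a [cell_phenotype()].
#' @return Updated [particle_state()].
#' @export
reflect_particle <- function(state, wall_normal,
                             phenotype = cell_phenotype()) {
  n <- wall_normal / sqrt(sum(wall_normal^2))
  state$velocity <- state$velocity - 2 * sum(state$velocity * n) * n
  state$position <- state$position - 1e-3 * phenotype$diameter * n
  state
}

# Outgoing (flow-leaving) segments at a node, with routing probabilities
# proportional to the outgoing flow rate. Returns data.frame(seg_row, flow).
#' @keywords internal
.outgoing_flows <- function(node, network, flow) {
  segs <- network$segments
  fs <- flow$segments
  out_fwd <- which(segs$from == node & fs$Q_up > 0)
  out_bwd <- which(segs$to == node & fs$Q_down < 0)
  data.frame(seg_row = c(out_fwd, out_bwd),
             flow = c(fs$Q_up[out_fwd], -fs$Q_down[out_bwd]))
}

#' Route a particle through a junction
#'
#' At the downstream end of a segment, the next segment is chosen with
#' probability proportional to the outgoing flow rate (one uniform draw from
#' the current RNG stream); at the network outlet the particle exits.
#'
#' @param state a [particle_state()] that has crossed its segment's
#'   downstream end.
#' @param node the junction node id.
#' @param flow a `flow_solution`.
#' @param network the [vascular_network()].
#' @return The chosen next segment id, or the string `"exited"` at the
#'   outlet. Errors if the node has no outgoing flow.
#' @export
route_at_junction <- function(state, node, flow, network) {
  if (node == network$outlet) return("exited")
  out <- .outgoing_flows(node, network, flow)
  if (nrow(out) == 0 || sum(out$flow) <= 0)
    stop("node ", node, " has no outgoing flow", call. = FALSE)
  pr <- out$flow / sum(out$flow)
  k <- findInterval(stats::runif(1), cumsum(pr), rightmost.closed = TRUE) + 1L
  k <- min(k, nrow(out))
  network$segments$id[out$seg_row[k]]
}

# Flow-weighted radial sampling on the inlet disc: axial Poiseuille profile
# ~ (1 - (r/R)^2), area element ~ r dr, truncated at r <= R_eff. With
# x = (r/R)^2 the CDF is (2x - x^2)/(2 xm - xm^2); inverted in closed form.
#' @keywords internal
.sample_inlet_radius <- function(n, R, R_eff) {
  xm <- (R_eff / R)^2
  Fm <- 2 * xm - xm^2
  x <- 1 - sqrt(1 - stats::runif(n) * Fm)
  R * sqrt(x)
}

#' Inject particles over one time step
#'
#' The expected injection count is `concentration * Vdot * dt`; the realized
#' count is deterministic via an accumulated fractional remainder, so over
#' any n steps the total differs from `n * expected` by less than one.
#' Radial positions on the inlet cross-section are sampled flow-weighted
#' (density proportional to the local axial velocity); initial velocity
#' equals the local fluid velocity.
#'
#' @param network a [vascular_network()].
#' @param flow a `flow_solution`.
#' @param bc a [boundary_conditions()].
#' @param concentration cell concentration, cells per m^3.
#' @param dt time step, s (> 0).
#' @param phenotype a [cell_phenotype()].
#' @param carry fractional remainder carried from the previous step.
#' @param t current simulation time (stamped on the new particles).
#' @param next_id id for the first new particle.
#' @return List with `states` (list of [particle_state()]), `carry` (new
#'   remainder) and `next_id`.
#' @export
inject_particles <- function(network, flow, bc, concentration, dt,
                             phenotype = cell_phenotype(), carry = 0,
                             t = 0, next_id = 1L) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  expect <- concentration * bc$inlet_flow * dt + carry
  k <- floor(expect + 1e-9)   # epsilon guards against accumulated fp drift
  carry <- max(0, expect - k)
  if (k == 0) return(list(states = list(), carry = carry, next_id = next_id))
  segs <- network$segments
  root <- which(segs$from == network$inlet)[1]
  pieces <- .network_pieces(network)
  pk <- pieces$first[root]
  R <- segs$diameter[root] / 2
  R_eff <- R - phenotype$diameter / 2
  r <- .sample_inlet_radius(k, R, R_eff)
  phi <- stats::runif(k, 0, 2 * pi)
  dirv <- pieces$dir[pk, ]; e1 <- pieces$e1[pk, ]; e2 <- pieces$e2[pk, ]
  frow <- flow$segments[root, ]
  states <- vector("list", k)
  for (j in seq_len(k)) {
    off <- r[j] * (cos(phi[j]) * e1 + sin(phi[j]) * e2)
    pos <- pieces$start[pk, ] + off
    u_ax <- 2 * frow$ubar * (1 - (r[j] / R)^2)
    v_wall <- frow$Q_leak / (pi * segs$diameter[root] * segs$length[root])
    vel <- u_ax * dirv + if (r[j] > 0) (v_wall * r[j] / R) * (off / r[j]) else 0
    states[[j]] <- particle_state(next_id, pos, vel, segs$id[root],
                                  "suspended", t)
    next_id <- next_id + 1L
  }
  list(states = states, carry = carry, next_id = next_id)
}
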