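# Steady network hydraulics: Hagen-Poiseuille segment conductances, Darcy
# wall leakage to a constant-pressure parenchyma reservoir, and the sparse
# nodal-pressure solve.
#
# Each segment is represented by two half-resistors meeting at a midpoint
# node; the midpoint also connects to the parenchyma reservoir through the
# lumped wall permeance, so leakage is attached at segment midpoints.

#' Fluid properties
#'
#' @param density kg/m^3.
#' @param viscosity dynamic viscosity, Pa.s.
#' @param label free-text label (`"media"`, `"buffer"`, ...).
#' @return A `fluid_properties` list.
#' @export
fluid_properties <- function(density, viscosity, label = "media") {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity, label = label),
            class = "fluid_properties")
}

#' Default perfusates
#'
#' Cell culture media (1000 kg/m^3, 0.94 cP) and phosphate-buffered saline
#' pre-saturation buffer (1005 kg/m^3, 1.02 cP). The steady flow solve uses
#' the media's properties throughout; the <10% viscosity difference between
#' the two fluids is neglected.
#'
#' @return A `fluid_properties` object.
#' @rdname default-fluids
#' @export
media_fluid <- function() fluid_properties(1000, 0.94e-3, "media")

#' @rdname default-fluids
#' @export
buffer_fluid <- function() fluid_properties(1005, 1.02e-3, "buffer")

#' Boundary conditions for a seeding run
#'
#' The canonical low-flow case pairs 3.81 ml/min with a 711 Pa venous
#' outlet pressure; the high-flow case pairs 9.40 ml/min with 2005 Pa.
#'
#' @param inlet_flow inlet volumetric flow rate, m^3/s (> 0).
#' @param outlet_pressure venous outlet pressure, Pa.
#' @param parenchyma_pressure reservoir pressure behind the porous walls,
#'   Pa; `NA` defers to the network's own `p_par`.
#' @return A `boundary_conditions` list.
#' @export
boundary_conditions <- function(inlet_flow, outlet_pressure,
                                parenchyma_pressure = NA_real_) {
  if (inlet_flow <= 0) stop("inlet_flow must be > 0", call. = FALSE)
  structure(list(inlet_flow = inlet_flow, outlet_pressure = outlet_pressure,
                 parenchyma_pressure = parenchyma_pressure),
            class = "boundary_conditions")
}

#' @rdname boundary_conditions
#' @param case `"low"` or `"high"` canonical case.
#' @export
canonical_bc <- function(case = c("low", "high")) {
  case <- match.arg(case)
  if (case == "low") boundary_conditions(3.81e-6 / 60, 711)
  else boundary_conditions(9.40e-6 / 60, 2005)
}

#' Hagen-Poiseuille segment conductance
#'
#' `G = pi d^4 / (128 mu L)` for fully developed laminar flow in a circular
#' tube, so that `Q = G * dp`.
#'
#' @param segment one-row slice of a network's `segments` table (or any list
#'   with `diameter` and `length`).
#' @param fluid a [fluid_properties()].
#' @return Conductance in m^3/(s.Pa).
#' @export
segment_conductance <- function(segment, fluid) {
  d <- segment$diameter; L <- segment$length
  if (is.null(L) || L <= 0) stop("segment length must be > 0", call. = FALSE)
  if (d <= 0) stop("segment diameter must be > 0", call. = FALSE)
  pi * d^4 / (128 * fluid$viscosity * L)
}

#' Lumped Darcy wall permeance
#'
#' Leakage path from a segment's lumen to the parenchyma reservoir:
#' `K = alpha * pi d L / (mu t_w)`, the Darcy law integrated across a wall
#' of thickness `t_w` over the segment's lateral area. `K = 0` (alpha = 0)
#' means an impermeable wall.
#'
#' @inheritParams segment_conductance
#' @return Permeance in m^3/(s.Pa), so `Q_leak = K * (p_lumen - p_par)`.
#' @export
wall_permeance <- function(segment, fluid) {
  if (segment$alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (segment$wall_thickness <= 0) stop("wall_thickness must be > 0", call. = FALSE)
  segment$alpha * pi * segment$diameter * segment$length /
    (fluid$viscosity * segment$wall_thickness)
}

#' Solve steady flow through a network
#'
#' Assembles the sparse symmetric nodal-pressure system (graph Laplacian of
#' half-segment conductances, with wall permeances tying segment midpoints
#' to the parenchyma reservoir), applies the inlet flow and outlet pressure
#' boundary conditions, and solves for all pressures and flows.
#'
#' @param network a [vascular_network()].
#' @param bc a [boundary_conditions()].
#' @param fluid a [fluid_properties()]; typically the media.
#' @return A `flow_solution`: list with `node_pressures` (data.frame `id`,
#'   `p`), `segments` (data.frame `id, Q, Q_up, Q_down, Q_leak, ubar,
#'   tau_w, Re`), `outlet_flow`, `outlet_fraction`, `inlet_pressure`, plus
#'   the `bc` and `fluid` used. `Q` is the mean of the upstream and
#'   downstream half-segment flows; `ubar = 4Q/(pi d^2)`;
#'   `tau_w = 8 mu ubar / d`.
#' @details Emits a warning if any segment Reynolds number exceeds 2000
#'   (laminar closure no longer valid).
#' @export
solve_flow <- function(network, bc, fluid) {
  .validate_topology(network)  # errors name the offending component
  segs <- network$segments
  nodes <- network$nodes
  n <- nrow(nodes); m <- nrow(segs)
  p_par <- if (!is.na(bc$parenchyma_pressure)) bc$parenchyma_pressure else network$p_par

  idx <- seq_len(n)
  names(idx) <- as.character(nodes$id)
  fi <- idx[as.character(segs$from)]
  ti <- idx[as.character(segs$to)]
  mi <- n + seq_len(m)                      # midpoint unknown indices
  N <- n + m

  Gh <- 2 * vapply(seq_len(m), function(i)
    segment_conductance(segs[i, ], fluid), numeric(1))   # half-segment
  K <- vapply(seq_len(m), function(i)
    wall_permeance(segs[i, ], fluid), numeric(1))

  ii <- c(fi, mi, fi, mi, mi, ti, mi, ti, mi)
  jj <- c(fi, mi, mi, fi, mi, ti, ti, mi, mi)
  xx <- c(Gh, Gh, -Gh, -Gh, Gh, Gh, -Gh, -Gh, K)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  b <- numeric(N)
  b[idx[as.character(network$inlet)]] <- bc$inlet_flow
  b[mi] <- b[mi] + K * p_par

  # Dirichlet at the outlet node: eliminate its unknown
  oi <- idx[as.character(network$outlet)]
  keep <- setdiff(seq_len(N), oi)
  b2 <- b[keep] - as.numeric(A[keep, oi]) * bc$outlet_pressure
  p <- numeric(N)
  p[oi] <- bc$outlet_pressure
  sol <- tryCatch(Matrix::solve(A[keep, keep], b2),
                  error = function(e) stop("flow solve failed (singular ",
                                           "system): ", conditionMessage(e),
                                           call. = FALSE))
  p[keep] <- as.numeric(sol)

  p_mid <- p[mi]
  Q_up <- Gh * (p[fi] - p_mid)
  Q_down <- Gh * (p_mid - p[ti])
  Q_leak <- K * (p_mid - p_par)
  Q <- (Q_up + Q_down) / 2
  ubar <- 4 * Q / (pi * segs$diameter^2)
  tau_w <- 8 * fluid$viscosity * abs(ubar) / segs$diameter
  Re <- fluid$density * abs(ubar) * segs$diameter / fluid$viscosity
  if (any(Re > 2000))
    warning("segment Reynolds number exceeds 2000 (max ",
            round(max(Re)), "); laminar closure questionable", call. = FALSE)

  # flow into the outlet node from incident segments
  outlet_flow <- sum(Q_down[ti == oi]) - sum(Q_up[fi == oi])

  structure(list(
    node_pressures = data.frame(id = nodes$id, p = p[seq_len(n)]),
    segments = data.frame(id = segs$id, Q = Q, Q_up = Q_up, Q_down = Q_down,
                          Q_leak = Q_leak, ubar = ubar, tau_w = tau_w,
                          Re = Re),
    outlet_flow = outlet_flow,
    outlet_fraction = outlet_flow / bc$inlet_flow,
    inlet_pressure = p[idx[as.character(network$inlet)]],
    p_par = p_par, bc = bc, fluid = fluid), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> ", nrow(x$segments), " segments\n", sep = "")
  cat(sprintf("  inlet pressure %.4g Pa, outlet fraction %.3f\n",
              x$inlet_pressure, x$outlet_fraction))
  cat(sprintf("  mean velocity range [%.3g, %.3g] m/s, max Re %.0f\n",
              min(abs(x$segments$ubar)), max(abs(x$segments$ubar)),
              max(x$segments$Re)))
  invisible(x)
}

#' Poiseuille wall shear stress of a segment
#'
#' `tau_w = 8 mu ubar / d` for fully developed laminar tube flow.
#'
#' @param segment one-row segment slice (needs `id` and `diameter`).
#' @param flow a `flow_solution` from [solve_flow()].
#' @return Wall shear stress, Pa (>= 0).
#' @export
wall_shear_stress <- function(segment, flow) {
  row <- flow$segments[flow$segments$id == segment$id, ]
  8 * flow$fluid$viscosity * abs(row$ubar) / segment$diameter
}

#' Local fluid velocity at a point inside a segment
#'
#' Axial component follows the Poiseuille profile `2 ubar (1 - (r/R)^2)`
#' along the local centerline tangent; the radial (outward) component is the
#' wall-leakage superficial velocity `Q_leak/(pi d L)` scaled linearly from
#' zero on the axis to its full value at the wall.
#'
#' @param position 3-vector, meters.
#' @param segment one-row slice of the network's `segments` table.
#' @param flow a `flow_solution`.
#' @param network the [vascular_network()] the flow was solved on.
#' @return 3-vector velocity, m/s.
#' @export
local_fluid_velocity <- function(position, segment, flow, network) {
  pieces <- .network_pieces(network)
  seg_idx <- which(network$segments$id == segment$id)
  cand <- which(pieces$seg == seg_idx)
  # nearest piece whose axial projection contains the point
  best <- NA_integer_; best_r <- Inf; best_a <- NA_real_
  for (k in cand) {
    rel <- position - pieces$start[k, ]
    a <- sum(rel * pieces$dir[k, ])
    if (a < -1e-12 || a > pieces$len[k] + 1e-12) next
    w <- rel - a * pieces$dir[k, ]
    r <- sqrt(sum(w^2))
    if (r < best_r) { best <- k; best_r <- r; best_a <- a }
  }
  R <- segment$diameter / 2
  if (is.na(best) || best_r > R)
    stop("position outside segment lumen", call. = FALSE)
  frow <- flow$segments[flow$segments$id == segment$id, ]
  axial <- 2 * frow$ubar * (1 - (best_r / R)^2) * pieces$dir[best, ]
  v_wall <- frow$Q_leak / (pi * segment$diameter * segment$length)
  radial <- if (best_r > 0) {
    rel <- position - pieces$start[best, ]
    w <- rel - best_a * pieces$dir[best, ]
    (v_wall * best_r / R) * (w / best_r)
  } else c(0, 0, 0)
  axial + radial
}

#' Export a flow solution as CSV
#'
#' Writes two CSV files: `<stem>_segments.csv` (one row per segment: id, Q,
#' ubar, tau_w, Q_leak, Re) and `<stem>_nodes.csv` (id, p).
#'
#' @param flow a `flow_solution`.
#' @param stem output path stem (without extension).
#' @return Character vector of the two paths written, invisibly.
#' @export
export_flow_csv <- function(flow, stem) {
  seg_path <- paste0(stem, "_segments.csv")
  node_path <- paste0(stem, "_nodes.csv")
  utils::write.csv(flow$segments[, c("id", "Q", "ubar", "tau_w", "Q_leak",
                                     "Re")], seg_path, row.names = FALSE)
  utils::write.csv(flow$node_pressures, node_path, row.names = FALSE)
  invisible(c(seg_path, node_path))
}
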