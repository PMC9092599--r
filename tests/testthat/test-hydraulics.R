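media <- media_fluid()

test_that("segment conductance follows the d^4/L Poiseuille law", {
  seg <- list(diameter = 200e-6, length = 1e-3)
  # hand evaluation: pi * (2e-4)^4 / (128 * 9.4e-4 * 1e-3)
  expect_equal(segment_conductance(seg, media), 4.177773e-11,
               tolerance = 1e-6)
  expect_equal(segment_conductance(list(diameter = 200e-6, length = 2e-3),
                                   media),
               segment_conductance(seg, media) / 2)
  expect_equal(segment_conductance(list(diameter = 400e-6, length = 1e-3),
                                   media),
               16 * segment_conductance(seg, media))
  expect_error(segment_conductance(list(diameter = 200e-6, length = 0),
                                   media), "length")
})

test_that("wall permeance implements the lumped Darcy leakage path", {
  seg <- list(diameter = 200e-6, length = 1e-3, alpha = 8.9e-13,
              wall_thickness = 50e-6)
  # hand evaluation: 8.9e-13 * pi * 2e-4 * 1e-3 / (9.4e-4 * 5e-5)
  expect_equal(wall_permeance(seg, media), 1.18985e-11, tolerance = 1e-5)
  seg0 <- seg; seg0$alpha <- 0
  expect_equal(wall_permeance(seg0, media), 0)
  seg2 <- seg; seg2$length <- 2e-3
  expect_equal(wall_permeance(seg2, media), 2 * wall_permeance(seg, media))
})

test_that("a single impermeable tube reproduces the analytic resistance", {
  net <- build_tube(1e-3, 200e-6)
  bc <- boundary_conditions(1e-9, 100)
  fl <- solve_flow(net, bc, media)
  G <- segment_conductance(net$segments[1, ], media)
  expect_equal(fl$segments$Q, 1e-9, tolerance = 1e-12)
  expect_equal(fl$inlet_pressure - 100, 1e-9 / G, tolerance = 1e-9)
  expect_equal(fl$outlet_fraction, 1, tolerance = 1e-12)
})

test_that("a symmetric bifurcation splits the flow in half", {
  net <- generate_tree(1, 200e-6, "murray", seed = 3)
  bc <- boundary_conditions(2e-9, 0)
  fl <- solve_flow(net, bc, media)
  kids <- which(net$segments$generation == 1 &
                  net$segments$region == "distal" &
                  net$segments$from %in% net$segments$to[1])
  expect_equal(fl$segments$Q[kids], rep(1e-9, 2), tolerance = 1e-9)
})

test_that("parallel tubes divide flow as a conductance divider", {
  net <- parallel_network(d1 = 200e-6, d2 = 150e-6)
  bc <- boundary_conditions(1e-9, 50)
  fl <- solve_flow(net, bc, media)
  G1 <- segment_conductance(net$segments[2, ], media)
  G2 <- segment_conductance(net$segments[3, ], media)
  expect_equal(fl$segments$Q[2] / fl$segments$Q[3], G1 / G2,
               tolerance = 1e-9)
  # closed-form resistor chain: p = p_out + Q/G accumulated upstream
  Gin <- segment_conductance(net$segments[1, ], media)
  Gout <- segment_conductance(net$segments[4, ], media)
  p3 <- 50 + 1e-9 / Gout
  p2 <- p3 + 1e-9 / (G1 + G2)
  p1 <- p2 + 1e-9 / Gin
  expect_equal(fl$node_pressures$p, c(p1, p2, p3, 50), tolerance = 1e-9)
})

test_that("global mass balance holds on the reference network", {
  for (case in c("low", "high")) {
    bc <- canonical_bc(case)
    fl <- solve_flow(ref_net, bc, media)
    resid <- bc$inlet_flow - fl$outlet_flow - sum(fl$segments$Q_leak)
    expect_lt(abs(resid) / bc$inlet_flow, 1e-9)
    # interior-node balance via the half-segment flows
    for (nd in setdiff(ref_net$nodes$id, c(ref_net$inlet, ref_net$outlet))) {
      inflow <- sum(fl$segments$Q_down[ref_net$segments$to == nd])
      outflow <- sum(fl$segments$Q_up[ref_net$segments$from == nd])
      expect_lt(abs(inflow - outflow) / bc$inlet_flow, 1e-9)
    }
  }
})

test_that("outlet fraction is 1 for impermeable walls and falls with alpha", {
  bc <- canonical_bc("low")
  fracs <- vapply(c(0, 1e-13, 8.9e-13, 5e-12), function(a) {
    net <- generate_tree(4, 300e-6, "murray", seed = 42, alpha = a,
                         wall_thickness = 1.2e-3)
    solve_flow(net, bc, media)$outlet_fraction
  }, numeric(1))
  expect_equal(fracs[1], 1, tolerance = 1e-9)
  expect_true(all(diff(fracs) < 0))
})

test_that("flow solve is deterministic", {
  a <- solve_flow(ref_net, canonical_bc("low"), media)
  b <- solve_flow(ref_net, canonical_bc("low"), media)
  expect_identical(a$segments, b$segments)
  expect_identical(a$node_pressures, b$node_pressures)
})

test_that("wall shear stress follows the 8 mu u / d closure", {
  tw <- tube_with_velocity(0.05)  # 5 cm/s in a 200 um tube
  expect_equal(wall_shear_stress(tw$net$segments[1, ], tw$flow), 1.88,
               tolerance = 1e-6)
  tw2 <- tube_with_velocity(0.10)
  expect_equal(wall_shear_stress(tw2$net$segments[1, ], tw2$flow), 2 * 1.88,
               tolerance = 1e-6)
  expect_equal(8 * media$viscosity * 0 / 200e-6, 0)
})

test_that("local fluid velocity has a Poiseuille profile with leak drift", {
  tw <- tube_with_velocity(0.05)
  seg <- tw$net$segments[1, ]
  on_axis <- local_fluid_velocity(c(5e-4, 0, 0), seg, tw$flow, tw$net)
  expect_equal(on_axis, c(2 * 0.05, 0, 0), tolerance = 1e-9)
  at_wall <- local_fluid_velocity(c(5e-4, 1e-4 - 1e-12, 0), seg, tw$flow,
                                  tw$net)
  expect_equal(at_wall[1], 0, tolerance = 1e-6)
  expect_error(local_fluid_velocity(c(5e-4, 2e-4, 0), seg, tw$flow, tw$net),
               "lumen")

  # cross-section average of the axial profile equals ubar (disc quadrature)
  R <- 1e-4
  rr <- seq(0, R, length.out = 400)
  ux <- vapply(rr, function(r)
    local_fluid_velocity(c(5e-4, r * 0.9999, 0), seg, tw$flow, tw$net)[1],
    numeric(1))
  avg <- sum(ux * rr) * diff(rr)[1] * 2 / R^2  # (1/ pi R^2) int u 2 pi r dr
  expect_equal(avg, 0.05, tolerance = 1e-3)

  # leaky tube: radial component scales linearly to the wall value
  lk <- tube_with_velocity(0.05, alpha = 8.9e-13)
  segl <- lk$net$segments[1, ]
  v_wall <- lk$flow$segments$Q_leak / (pi * segl$diameter * segl$length)
  vmid <- local_fluid_velocity(c(5e-4, 0.5e-4, 0), segl, lk$flow, lk$net)
  expect_equal(vmid[2], 0.5 * v_wall, tolerance = 1e-6)
})

test_that("turbulent segments trigger a laminar-assumption warning", {
  net <- build_tube(1e-2, 1e-3)
  expect_warning(solve_flow(net, boundary_conditions(3e-6, 0), media),
                 "Reynolds")
})

test_that("flow CSV export round-trips", {
  fl <- solve_flow(ref_net, canonical_bc("low"), media)
  stem <- withr::local_tempfile()
  paths <- export_flow_csv(fl, stem)
  segs <- utils::read.csv(paste0(stem, "_segments.csv"))
  expect_equal(segs$Q, fl$segments$Q)
  nodes <- utils::read.csv(paste0(stem, "_nodes.csv"))
  expect_equal(nodes$p, fl$node_pressures$p)
})
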