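media <- media_fluid()
cell <- cell_phenotype()  # 15 um, 1050 kg/m^3

test_that("relaxation time reaches the Stokes limit as Re -> 0", {
  # hand evaluation: 1050 * (1.5e-5)^2 / (18 * 9.4e-4)
  expect_equal(relaxation_time(cell, media, 0), 1.39628e-5,
               tolerance = 1e-5)
  expect_equal(drag_factor(0), 1)
  # corrected drag shortens the relaxation time monotonically
  taus <- relaxation_time(cell, media, c(0, 0.01, 0.1, 1))
  expect_true(all(diff(taus) < 0))
})

test_that("Schiller-Naumann drag factor matches the correlation", {
  expect_equal(drag_factor(1), 1.15)
  Re <- seq(0, 100, by = 0.5)
  expect_true(all(diff(drag_factor(Re)) >= 0))
  expect_equal(drag_factor(5, law = "stokes"), 1)
  expect_error(drag_factor(-1), "Re")
})

test_that("the exponential integrator is exact for uniform flow", {
  u <- c(0.02, 0, 0)
  tau <- relaxation_time(cell, media, 0.02, law = "stokes")
  for (dt in c(1e-7, 1e-5, 1e-3)) {
    st <- particle_state(1, c(0, 0, 0), c(0, 0, 0), 1)
    st2 <- step_particle(st, u, dt, gravity = c(0, 0, 0), cell, media,
                         law = "stokes")
    expect_equal(st2$velocity[1], 0.02 * (1 - exp(-dt / tau)),
                 tolerance = 1e-12)
  }
  # fixed point: particle moving with the fluid stays with the fluid
  st <- particle_state(1, c(0, 0, 0), u, 1)
  st2 <- step_particle(st, u, 1e-4, gravity = c(0, 0, 0), cell, media)
  expect_equal(st2$velocity, u, tolerance = 1e-15)
  # relaxation limit: dt >> tau_r snaps the particle onto the fluid
  st <- particle_state(1, c(0, 0, 0), c(0, 0, 0), 1)
  st2 <- step_particle(st, u, 1, gravity = c(0, 0, 0), cell, media)
  expect_equal(st2$velocity, u, tolerance = 1e-15)
})

test_that("still-fluid settling approaches the closed-form terminal speed", {
  st <- particle_state(1, c(0, 0, 0), c(0, 0, 0), 1)
  for (i in 1:60)
    st <- step_particle(st, c(0, 0, 0), 1e-5, gravity = c(0, 0, -9.81),
                        phenotype = cell, fluid = media)
  v_term <- relaxation_time(cell, media, 0) * 9.81 *
    (cell$density - media$density) / cell$density
  expect_equal(-st$velocity[3], v_term, tolerance = 0.01)
  expect_equal(v_term, 6.52e-6, tolerance = 0.01)
})

test_that("wall impacts are located on the linearized path", {
  net <- build_tube(1e-3, 200e-6)
  seg <- net$segments[1, ]
  R_eff <- 100e-6 - 7.5e-6

  # purely axial on-axis motion: no impact
  a <- particle_state(1, c(1e-4, 0, 0), c(0.05, 0, 0), 1)
  b <- particle_state(1, c(2e-4, 0, 0), c(0.05, 0, 0), 1)
  expect_null(detect_wall_impact(a, b, seg, net))

  # radial crossing: compare against a bisection oracle
  y0 <- 20e-6; y1 <- 97e-6
  a <- particle_state(1, c(1e-4, y0, 0), c(0.05, 1e-3, 0), 1)
  b <- particle_state(1, c(2e-4, y1, 0), c(0.05, 1e-3, 0), 1)
  imp <- detect_wall_impact(a, b, seg, net)
  expect_false(is.null(imp))
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (y0 + mid * (y1 - y0) < R_eff) lo <- mid else hi <- mid
  }
  expect_equal(imp$fraction, lo, tolerance = 1e-9)
  expect_equal(imp$normal, c(0, 1, 0), tolerance = 1e-9)

  # grazing: already at the threshold, moving tangentially
  a <- particle_state(1, c(1e-4, R_eff, 0), c(0.05, 0, 0), 1)
  b <- particle_state(1, c(2e-4, R_eff, 0), c(0.05, 0, 0), 1)
  imp <- detect_wall_impact(a, b, seg, net)
  expect_equal(imp$fraction, 0)
})

test_that("reflection is specular and energy-conserving", {
  n <- c(0, 1, 0)
  st <- particle_state(1, c(0, 1e-4, 0), c(0, 0.02, 0), 1)
  r <- reflect_particle(st, n)
  expect_equal(r$velocity, c(0, -0.02, 0))

  st <- particle_state(1, c(0, 1e-4, 0), c(0.03, 0, 0.01), 1)
  r <- reflect_particle(st, n)
  expect_equal(r$velocity, st$velocity)  # tangential motion unchanged

  st <- particle_state(1, c(0, 1e-4, 0), c(0.03, 0.01, -0.02), 1)
  r <- reflect_particle(st, n)
  expect_equal(sum(r$velocity^2), sum(st$velocity^2), tolerance = 1e-12)
  # inward nudge of 1e-3 d_p
  expect_equal(st$position[2] - r$position[2], 1e-3 * 15e-6)
})

test_that("junction routing follows the flow split", {
  net <- generate_tree(1, 200e-6, "murray", seed = 3)
  fl <- solve_flow(net, canonical_bc("low"), media)
  fork <- net$segments$to[net$segments$region == "artery"]
  st <- particle_state(1, c(0, 0, 0), c(0, 0, 0), 1)

  set.seed(99)
  picks <- replicate(1e4, route_at_junction(st, fork, fl, net))
  tab <- table(picks)
  expect_equal(length(tab), 2)
  # symmetric bifurcation: binomial(1e4, 0.5) within 4 sigma
  expect_lt(abs(tab[1] - 5000), 4 * sqrt(1e4 * 0.25))

  # single continuation is always taken; the outlet exits
  cont <- net$segments$to[net$segments$generation == 1 &
                            net$segments$region == "distal"][1]
  nxt <- route_at_junction(st, cont, fl, net)
  expect_equal(ref <- net$segments$from[net$segments$id == nxt], cont)
  expect_equal(route_at_junction(st, net$outlet, fl, net), "exited")
})

test_that("injection realizes the expected count via remainder carryover", {
  net <- build_tube(1e-3, 200e-6)
  bc <- boundary_conditions(3.81e-6 / 60, 0)
  fl <- solve_flow(net, bc, media)
  conc <- 2.5e11  # 250,000 cells/ml
  set.seed(1)
  total <- 0; carry <- 0; nid <- 1L
  dt <- 1e-3
  for (i in seq_len(1000)) {  # 1 s in total
    out <- inject_particles(net, fl, bc, conc, dt, carry = carry,
                            next_id = nid)
    total <- total + length(out$states)
    carry <- out$carry; nid <- out$next_id
  }
  expect_equal(total, 15875)  # concentration x flow x time
  expect_lt(abs(total + carry - conc * bc$inlet_flow * 1), 1e-6)

  none <- inject_particles(net, fl, bc, 0, 1)
  expect_equal(length(none$states), 0)

  # initial velocity equals the local fluid velocity; positions in-lumen
  set.seed(2)
  out <- inject_particles(net, fl, bc, conc, 0.01)
  st <- out$states[[1]]
  u <- local_fluid_velocity(st$position + c(1e-9, 0, 0), net$segments[1, ],
                            fl, net)
  expect_equal(st$velocity, u, tolerance = 1e-6)
  r <- sqrt(sum(st$position[2:3]^2))
  expect_lt(r, 100e-6 - 7.5e-6)
})
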