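# Shared fixtures built in code. The reference network is constructed once
# per test run; simulation helpers keep runs small enough for routine use.

ref_net <- reference_network()

# straight impermeable tube with prescribed mean velocity
tube_with_velocity <- function(ubar, length = 1e-3, diameter = 200e-6,
                               alpha = 0, ...) {
  net <- build_tube(length, diameter, alpha = alpha, ...)
  bc <- boundary_conditions(ubar * pi * diameter^2 / 4, 0)
  list(net = net, bc = bc, flow = solve_flow(net, bc, media_fluid()))
}

# two parallel tubes of different diameters between shared end segments:
# inlet seg 1 -> (seg 2 | seg 3 in parallel) -> outlet seg 4
parallel_network <- function(d1 = 200e-6, d2 = 150e-6) {
  L <- 1e-3
  nodes <- data.frame(id = 1:4,
                      x = c(0, L, 2 * L, 3 * L),
                      y = 0, z = 0)
  segs <- data.frame(id = 1:4,
                     from = c(1L, 2L, 2L, 3L),
                     to = c(2L, 3L, 3L, 4L),
                     diameter = c(250e-6, d1, d2, 250e-6),
                     alpha = 0, wall_thickness = 50e-6,
                     region = c("artery", "distal", "distal", "vein"))
  line <- function(a, b) rbind(a, b)
  cls <- list(`1` = line(c(0, 0, 0), c(L, 0, 0)),
              `2` = line(c(L, 0, 0), c(2 * L, 0, 0)),
              `3` = line(c(L, 0, 0), c(2 * L, 0, 0)),
              `4` = line(c(2 * L, 0, 0), c(3 * L, 0, 0)))
  vascular_network(nodes, segs, cls, inlet = 1L, outlet = 4L)
}

# small seeding run on the reference network
small_run <- function(model, case = "low", seed = 1, stop_fraction = 5e-4,
                      ...) {
  cfg <- seeding_config(ref_net, canonical_bc(case), model,
                        stop_fraction = stop_fraction, seed = seed, ...)
  run_seeding(cfg)
}
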