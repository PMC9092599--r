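test_that("build_tube constructs a single straight segment", {
  net <- build_tube(1e-3, 200e-6, n_centerline_points = 2)
  expect_equal(nrow(net$segments), 1)
  expect_equal(net$segments$length, 1e-3)

  many <- build_tube(1e-3, 200e-6, n_centerline_points = 11)
  expect_equal(many$segments$length, 1e-3)  # collinear points add no length

  expect_error(build_tube(0, 200e-6), "positive")
  expect_error(build_tube(1e-3, -1e-6), "positive")
})

test_that("Murray and fixed-ratio diameter rules give the expected scaling", {
  net <- generate_tree(1, 200e-6, "murray", seed = 1)
  kids <- net$segments$diameter[net$segments$generation == 1 &
                                  net$segments$region == "distal"]
  expect_equal(unique(kids), 200e-6 * 2^(-1 / 3), tolerance = 1e-12)

  net4 <- generate_tree(4, 300e-6, "fixed_ratio", ratio = 0.75, seed = 1)
  term <- net4$segments$diameter[net4$segments$generation == 4]
  expect_equal(unique(term), 300e-6 * 0.75^4, tolerance = 1e-12)
})

test_that("Murray trees conserve d^3 at every bifurcation", {
  net <- generate_tree(3, 300e-6, "murray", seed = 7,
                       tortuosity_amplitude = 20e-6,
                       n_centerline_points = 5)
  segs <- net$segments
  for (nd in net$nodes$id) {
    parents <- segs$diameter[segs$to == nd]
    children <- segs$diameter[segs$from == nd]
    if (length(parents) == 1 && length(children) == 2) {
      expect_equal(parents^3, sum(children^3), tolerance = 1e-12)
    }
  }
})

test_that("tree generation is deterministic for a fixed seed", {
  a <- generate_tree(3, 300e-6, tortuosity_amplitude = 25e-6,
                     n_centerline_points = 7, seed = 11)
  b <- generate_tree(3, 300e-6, tortuosity_amplitude = 25e-6,
                     n_centerline_points = 7, seed = 11)
  expect_identical(a, b)

  c <- generate_tree(3, 300e-6, tortuosity_amplitude = 25e-6,
                     n_centerline_points = 7, seed = 12)
  expect_false(identical(a$centerlines, c$centerlines))
})

test_that("oversized trees are rejected", {
  expect_error(generate_tree(16, 300e-6), "1e5|segments")
})

test_that("reference network matches its documented contract", {
  net <- ref_net
  expect_equal(max(net$segments$generation), 4)
  expect_true(all(net$segments$diameter >= 100e-6))
  expect_equal(sum(net$segments$region == "artery"), 1)
  expect_equal(sum(net$segments$region == "vein"), 1)
  # single inlet (no segment ends there), single outlet (none starts there)
  expect_false(net$inlet %in% net$segments$to)
  expect_false(net$outlet %in% net$segments$from)
  expect_equal(net$segments$alpha[1], 8.9e-13)
})

test_that("wall discretization partitions the lateral area exactly", {
  tube <- build_tube(1e-3, 200e-6)
  f <- discretize_wall(tube, 0.5e-3, 4)
  expect_equal(nrow(f), 8)
  expect_equal(unique(f$area), pi * 200e-6 * 1e-3 / 8, tolerance = 1e-12)

  f1 <- discretize_wall(tube, 0.25e-3, 1)
  expect_equal(nrow(f1), 4)  # azimuthal = 1: count equals axial bins

  fr <- discretize_wall(ref_net, 2e-4, 8)
  per_seg <- tapply(fr$area, fr$segment_id, sum)
  lateral <- pi * ref_net$segments$diameter * ref_net$segments$length
  expect_equal(as.numeric(per_seg[as.character(ref_net$segments$id)]),
               lateral, tolerance = 1e-9)
})

test_that("networks round-trip through the text format losslessly", {
  path <- withr::local_tempfile(fileext = ".net")
  write_network(ref_net, path)
  back <- read_network(path)
  expect_equal(back$nodes, ref_net$nodes)
  expect_equal(back$segments[, c("from", "to", "diameter", "alpha",
                                 "wall_thickness", "region", "length")],
               ref_net$segments[, c("from", "to", "diameter", "alpha",
                                    "wall_thickness", "region", "length")])
  for (sid in as.character(ref_net$segments$id))
    expect_equal(unname(back$centerlines[[sid]]),
                 unname(ref_net$centerlines[[sid]]))
  expect_equal(back$inlet, ref_net$inlet)
  expect_equal(back$outlet, ref_net$outlet)
  expect_equal(back$p_par, ref_net$p_par)
})

test_that("topology invariants are enforced", {
  nodes <- data.frame(id = 1:4, x = c(0, 1, 2, 5) * 1e-3, y = 0, z = 0)
  line <- function(a, b) rbind(a, b)
  segs <- data.frame(id = 1:2, from = c(1L, 3L), to = c(2L, 4L),
                     diameter = 1e-4, alpha = 0, wall_thickness = 5e-5,
                     region = "distal")
  cls <- list(`1` = line(c(0, 0, 0), c(1e-3, 0, 0)),
              `2` = line(c(2e-3, 0, 0), c(5e-3, 0, 0)))
  expect_error(vascular_network(nodes, segs, cls, 1L, 4L),
               "disconnected|unreachable|fewer than 2")
})

test_that("VTK centerline export writes well-formed legacy polydata", {
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_centerlines(ref_net, path)
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  npts <- sum(vapply(ref_net$centerlines, nrow, integer(1)))
  expect_true(any(grepl(sprintf("^POINTS %d double", npts), lines)))
  expect_true(any(grepl("SCALARS diameter", lines)))
})
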