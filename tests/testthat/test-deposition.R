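cell <- cell_phenotype()
media <- media_fluid()

ctx_200um_5cms <- impact_context(ubar = 0.05, diameter = 200e-6,
                                 tau_w = 1.88, phenotype = cell,
                                 fluid = media)

test_that("Stokes number matches the defining formula", {
  # hand evaluation: 1050 * (1.5e-5)^2 * 0.05 / (18 * 9.4e-4 * 2e-4)
  expect_equal(stokes_number(ctx_200um_5cms), 3.4908e-3, tolerance = 1e-4)
  ctx0 <- impact_context(0, 200e-6, 0)
  expect_equal(stokes_number(ctx0), 0)
  # proportional in ubar, inverse in d
  ctx2 <- impact_context(0.10, 200e-6, 0)
  expect_equal(stokes_number(ctx2), 2 * stokes_number(ctx_200um_5cms),
               tolerance = 1e-12)
  ctx3 <- impact_context(0.05, 400e-6, 0)
  expect_equal(stokes_number(ctx3), stokes_number(ctx_200um_5cms) / 2,
               tolerance = 1e-12)
})

test_that("Stokes probability reproduces the published worked values", {
  Stk <- stokes_number(ctx_200um_5cms)
  expect_equal(100 * stokes_probability(Stk, C = 200), 23.9,
               tolerance = 0.05 / 23.9)
  expect_equal(100 * stokes_probability(Stk, C = 300), 38.5,
               tolerance = 0.05 / 38.5)
  expect_equal(stokes_probability(0, 300), 0)       # limit at Stk = 0
  expect_equal(stokes_probability(1e12, 300), 1, tolerance = 1e-9)
})

test_that("receptor-ligand probability clamps at zero shear and decays", {
  p <- decuzzi_params()  # r0 = 1 um default
  ctx0 <- impact_context(0.05, 200e-6, 0)
  expect_equal(decuzzi_probability(p, ctx0), 1)  # prefactor ~13 clamped
  # independent recomputation of the un-clamped expression
  pref <- 1e14 * 4.15e-2 * pi * (1e-6)^2
  expect_equal(pref, 13.037, tolerance = 1e-4)
  tau <- 1.88
  brack <- 6 * (7.5e-6 + 5e-9) * 1.668 + (1.5e-5)^2 / (2 * 1e-6) * 0.944
  expo <- -(1e-10 * 1.5e-5 * tau) / (2 * 4.14e-21 * (1e-6)^2 * 1e14) * brack
  ctx <- impact_context(0.05, 200e-6, tau)
  expect_equal(decuzzi_probability(p, ctx), min(1, pref * exp(expo)),
               tolerance = 1e-12)
  # vanishing at large shear, monotone non-increasing throughout
  ctx_inf <- impact_context(0.05, 200e-6, 1e4)
  expect_lt(decuzzi_probability(p, ctx_inf), 1e-12)
  taus <- seq(0, 60, by = 0.5)
  Ps <- decuzzi_probability(p, impact_context(0.05, 200e-6, taus))
  expect_true(all(diff(Ps) <= 0))
})

test_that("contact rule always deposits", {
  expect_equal(contact_probability(), 1)
  set.seed(4)
  out <- replicate(50, deposition_trial(contact_probability())$deposited)
  expect_true(all(out))
})

test_that("deposition trial matches its probability empirically", {
  expect_true(deposition_trial(1)$deposited)
  expect_false(deposition_trial(0)$deposited)
  expect_error(deposition_trial(1.2), "\\[0, 1\\]")
  out <- deposition_trial(0.5, draw = 0.3)
  expect_identical(out$deposited, out$probability > out$draw)

  set.seed(7)
  n <- 1e5; P <- 0.385
  se <- sqrt(P * (1 - P) / n)
  hits <- vapply(seq_len(n), function(i) deposition_trial(P)$deposited,
                 logical(1))
  expect_lt(abs(mean(hits) - P), 3 * se)
})

test_that("all rules stay in [0, 1] over random admissible inputs", {
  set.seed(11)
  p <- decuzzi_params()
  for (i in 1:200) {
    ctx <- impact_context(ubar = stats::runif(1, 0, 2),
                          diameter = stats::runif(1, 50e-6, 2e-3),
                          tau_w = stats::runif(1, 0, 100),
                          phenotype = cell_phenotype(
                            stats::runif(1, 5e-6, 30e-6),
                            stats::runif(1, 1000, 1200)),
                          fluid = media)
    for (m in list(deposition_model("contact"),
                   deposition_model("stokes", C = stats::runif(1, 10, 1000)),
                   deposition_model("decuzzi", params = p))) {
      P <- deposition_probability(m, ctx)
      expect_gte(P, 0); expect_lte(P, 1)
    }
  }
})

test_that("Stokes probability is monotone in its drivers", {
  set.seed(13)
  for (i in 1:50) {
    u <- stats::runif(1, 0.005, 1); d <- stats::runif(1, 1e-4, 1e-3)
    C <- stats::runif(1, 50, 600)
    base <- stokes_probability(stokes_number(impact_context(u, d, 0)), C)
    up_u <- stokes_probability(stokes_number(impact_context(u * 1.01, d, 0)), C)
    up_C <- stokes_probability(stokes_number(impact_context(u, d, 0)), C * 1.01)
    up_d <- stokes_probability(stokes_number(impact_context(u, d * 1.01, 0)), C)
    expect_gt(up_u, base); expect_gt(up_C, base); expect_lt(up_d, base)
  }
})

test_that("probability maps carry the worked value and the right monotonicity", {
  m <- deposition_model("stokes", C = 300)
  vel <- c(0.01, 0.05, 0.25)          # m/s
  dia <- c(100e-6, 200e-6, 400e-6)
  P <- probability_map(m, vel, dia)
  expect_equal(100 * P[2, 2], 38.5, tolerance = 0.05 / 38.5)  # (200 um, 5 cm/s)
  for (i in seq_along(dia)) expect_true(all(diff(P[i, ]) >= 0))
  for (j in seq_along(vel)) expect_true(all(diff(P[, j]) <= 0))

  path <- withr::local_tempfile(fileext = ".csv")
  write_probability_map(P, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(unname(as.matrix(back[, -1])), unname(P), tolerance = 1e-12)
})
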