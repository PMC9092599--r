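# Wall-deposition probability models and the uniform-random accept/reflect
# trial. Three rules are provided:
#   contact  - any wall contact deposits (P = 1);
#   decuzzi  - receptor-ligand adhesion probability decreasing with wall
#              shear stress;
#   stokes   - inertial-impaction probability driven by the Stokes number,
#              P = exp(-1/(Stk * C)) with an empirical inertia coefficient C.

#' Impact context
#'
#' The local quantities a deposition rule may consume when a cell touches
#' the wall: the segment's mean velocity and diameter, its Poiseuille wall
#' shear stress, and the cell/fluid properties.
#'
#' @param ubar segment mean velocity, m/s (>= 0).
#' @param diameter vessel diameter, m (> 0).
#' @param tau_w wall shear stress, Pa (>= 0).
#' @param phenotype a [cell_phenotype()].
#' @param fluid a [fluid_properties()].
#' @return An `impact_context` list.
#' @export
impact_context <- function(ubar, diameter, tau_w,
                           phenotype = cell_phenotype(),
                           fluid = media_fluid()) {
  if (any(diameter <= 0)) stop("diameter must be > 0", call. = FALSE)
  if (any(ubar < 0) || any(tau_w < 0))
    stop("ubar and tau_w must be >= 0", call. = FALSE)
  structure(list(ubar = ubar, diameter = diameter, tau_w = tau_w,
                 phenotype = phenotype, fluid = fluid),
            class = "impact_context")
}

#' Stokes number of an impact
#'
#' `Stk = rho_p d_p^2 ubar / (18 mu d)`: the ratio of the particle
#' relaxation time to the flow time scale `d / ubar`, with the vessel
#' diameter as the characteristic length. High-Stk particles cross
#' streamlines and impact walls.
#'
#' @param context an [impact_context()] (fields may be vectors).
#' @return Dimensionless Stokes number (vectorized over the context).
#' @export
stokes_number <- function(context) {
  ph <- context$phenotype; fl <- context$fluid
  ph$density * ph$diameter^2 * context$ubar /
    (18 * fl$viscosity * context$diameter)
}

#' Stokes inertial-impaction deposition probability
#'
#' `P = exp(-1 / (Stk * C))`, defined as the limit 0 at `Stk = 0`. `C` is an
#' empirically adjusted inertia coefficient absorbing the effect of Stokes
#' number on deposition together with biochemical interactions and truncated
#' geometry; `C = 300` is the default (best agreement with ex vivo seeding),
#' with `C = 200` as the common comparison value.
#'
#' @param Stk Stokes number (>= 0); vectorized.
#' @param C inertia coefficient (> 0).
#' @return Probability in [0, 1].
#' @export
stokes_probability <- function(Stk, C = 300) {
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (any(Stk < 0)) stop("Stk must be >= 0", call. = FALSE)
  ifelse(Stk == 0, 0, exp(-1 / (Stk * C)))
}

#' Receptor-ligand model parameters
#'
#' Surface-chemistry parameters of the receptor-ligand adhesion probability.
#' Defaults are the published drug-particle values for pulmonary
#' vasculature: receptor density `m_r = 1e14 /m^2`, ligand-affinity product
#' `m_l Ka0 = 4.15e-2`, bond length `lambda = 1e-10 m`, thermal energy
#' `k_B T = 4.14e-21 J`, equilibrium separation `delta_eq = 5e-9 m`, drag
#' and torque coefficients `F_S = 1.668`, `T_S = 0.944`.
#'
#' `r0`, the interaction-surface radius, is NOT part of that published
#' parameter set: no source value exists for it, so treat the 1 um default
#' as a modeling choice to be reviewed for any serious use, not as data.
#'
#' @param m_r receptor surface density, 1/m^2.
#' @param ml_Ka0 ligand density x affinity constant, dimensionless.
#' @param lambda receptor-ligand bond length, m.
#' @param kBT thermal energy, J.
#' @param delta_eq particle-surface separation, m.
#' @param F_S,T_S drag force and torque coefficients, dimensionless.
#' @param r0 interaction surface radius, m (see above).
#' @return A `decuzzi_params` list.
#' @export
decuzzi_params <- function(m_r = 1e14, ml_Ka0 = 4.15e-2, lambda = 1e-10,
                           kBT = 4.14e-21, delta_eq = 5e-9, F_S = 1.668,
                           T_S = 0.944, r0 = 1e-6) {
  vals <- c(m_r, ml_Ka0, lambda, kBT, delta_eq, F_S, T_S, r0)
  if (any(vals <= 0))
    stop("all receptor-ligand parameters must be strictly positive",
         call. = FALSE)
  structure(list(m_r = m_r, ml_Ka0 = ml_Ka0, lambda = lambda, kBT = kBT,
                 delta_eq = delta_eq, F_S = F_S, T_S = T_S, r0 = r0),
            class = "decuzzi_params")
}

# The algebraic form is isolated here so an alternative reading of the
# published expression is a one-line swap. This parse takes the exponent
# argument as
#   -(lambda d_p muS) / (2 kBT r0^2 m_r) * [6 (d_p/2 + delta_eq) F_S
#                                           + d_p^2/(2 r0) T_S]
# the unique dimensionally consistent grouping (bracket in meters) that
# reduces to the cited receptor-ligand form.
#' @keywords internal
.decuzzi_core <- function(p, d_p, tau_w) {
  pref <- p$m_r * p$ml_Ka0 * pi * p$r0^2
  bracket <- 6 * (d_p / 2 + p$delta_eq) * p$F_S + d_p^2 / (2 * p$r0) * p$T_S
  expo <- -(p$lambda * d_p * tau_w) / (2 * p$kBT * p$r0^2 * p$m_r) * bracket
  pmin(1, pref * exp(expo))
}

#' Receptor-ligand (Decuzzi-type) deposition probability
#'
#' Adhesion probability balancing receptor-ligand binding strength against
#' the shear-driven dislodging force and torque; strictly decreasing in wall
#' shear stress. With the published defaults the zero-shear prefactor
#' `m_r (m_l Ka0) pi r0^2` exceeds 1, so the value is clamped to 1.
#'
#' @param params a [decuzzi_params()].
#' @param context an [impact_context()]; only `tau_w` and the cell diameter
#'   are consumed.
#' @return Probability in [0, 1] (vectorized over `tau_w`).
#' @export
decuzzi_probability <- function(params, context) {
  .decuzzi_core(params, context$phenotype$diameter, context$tau_w)
}

#' Contact deposition probability
#'
#' The deposit-on-contact rule: every wall contact deposits, so the
#' probability is exactly 1 regardless of the impact context.
#'
#' @return 1.
#' @export
contact_probability <- function() 1

#' Deposition model object
#'
#' Bundles a rule name with its parameters; `deposition_probability()`
#' evaluates it on an impact context.
#'
#' @param model `"contact"`, `"stokes"` or `"decuzzi"`.
#' @param C inertia coefficient for the Stokes rule.
#' @param params a [decuzzi_params()] for the receptor-ligand rule.
#' @return A `deposition_model` list.
#' @export
deposition_model <- function(model = c("stokes", "contact", "decuzzi"),
                             C = 300, params = decuzzi_params()) {
  model <- match.arg(model)
  structure(list(model = model, C = C, params = params),
            class = "deposition_model")
}

#' @rdname deposition_model
#' @param context an [impact_context()] (fields may be vectors).
#' @return `deposition_probability()`: probability vector in [0, 1].
#' @export
deposition_probability <- function(model, context) {
  switch(model$model,
         contact = rep(1, length(context$ubar)),
         stokes = stokes_probability(stokes_number(context), model$C),
         decuzzi = decuzzi_probability(model$params, context))
}

#' Uniform-random deposition trial
#'
#' Draws a uniform number in [0, 1] (from the current RNG stream unless a
#' draw is supplied) and deposits the cell iff the probability exceeds the
#' draw; otherwise the cell is reflected off the wall and carried
#' downstream.
#'
#' @param P deposition probability in [0, 1].
#' @param draw optional uniform draw (for reproducing a recorded trial).
#' @return A `deposition_outcome`: list with `probability`, `draw`,
#'   `deposited`.
#' @export
deposition_trial <- function(P, draw = stats::runif(1)) {
  if (P < 0 || P > 1) stop("P must lie in [0, 1]", call. = FALSE)
  structure(list(probability = P, draw = draw, deposited = P > draw),
            class = "deposition_outcome")
}

#' Deposition probability map over a velocity-diameter grid
#'
#' Evaluates a deposition model on every (velocity, diameter) combination,
#' using the Poiseuille shear closure `tau_w = 8 mu u / d` for the
#' receptor-ligand rule. Rows are diameters, columns velocities.
#'
#' @param model a [deposition_model()].
#' @param velocities mean velocities, m/s (> 0).
#' @param diameters vessel diameters, m (> 0).
#' @param phenotype a [cell_phenotype()].
#' @param fluid a [fluid_properties()].
#' @return Numeric matrix `length(diameters) x length(velocities)` with
#'   dimnames giving the grid values.
#' @export
probability_map <- function(model, velocities, diameters,
                            phenotype = cell_phenotype(),
                            fluid = media_fluid()) {
  if (any(velocities <= 0) || any(diameters <= 0))
    stop("velocities and diameters must be positive", call. = FALSE)
  P <- matrix(NA_real_, length(diameters), length(velocities),
              dimnames = list(diameter = format(diameters, digits = 6),
                              velocity = format(velocities, digits = 6)))
  for (i in seq_along(diameters)) {
    ctx <- impact_context(ubar = velocities, diameter = diameters[i],
                          tau_w = 8 * fluid$viscosity * velocities /
                            diameters[i],
                          phenotype = phenotype, fluid = fluid)
    P[i, ] <- deposition_probability(model, ctx)
  }
  P
}

#' Write a probability map as CSV
#'
#' One row per diameter (meters, first column), one column per velocity
#' (m/s, in the header).
#'
#' @param P matrix from [probability_map()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(P, path) {
  df <- data.frame(diameter_m = rownames(P), P, check.names = FALSE)
  names(df)[-1] <- paste0("u_", colnames(P), "_m_s")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
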