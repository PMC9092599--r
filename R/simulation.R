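# Transient seeding orchestration: steady flow solve, plug-flow media-front
# advance, continuous particle injection, vectorized Lagrangian transport,
# wall-impact handling with the configured deposition rule, and ledger /
# event bookkeeping until the target fraction of the media volume has been
# injected.
#
# RNG contract: a single seeded stream drives every stochastic draw, always
# consumed in the same order within a time step -- injection positions
# first, then deposition trials in particle order, then junction routing in
# particle order -- so runs are bit-identical for a fixed seed.
#
# Impact-event definition: a deposition trial fires when a cell crosses the
# wall threshold R - d_p/2 from the bulk. A rejected cell is reflected and
# marked "in contact"; while in contact it is contained at the wall without
# further trials, and the flag clears once the cell retreats a full cell
# diameter back into the lumen. Trials are therefore counted per wall
# encounter (an event set by the trajectory), not per integration step,
# which keeps deposition statistics independent of dt.

#' Simulation configuration
#'
#' @param network a [vascular_network()].
#' @param bc a [boundary_conditions()] (see [canonical_bc()]).
#' @param model a [deposition_model()].
#' @param fluid media properties used for the single steady flow solve.
#' @param buffer buffer (pre-saturation) fluid; recorded but not used by
#'   the flow solve, whose single steady solution uses the media.
#' @param phenotype a [cell_phenotype()].
#' @param concentration cell concentration in cells/m^3 (the canonical
#'   250,000 cells/ml is 2.5e11).
#' @param total_volume total media volume to be injected, m^3 (default
#'   20 ml).
#' @param stop_fraction stop once this fraction of `total_volume` has been
#'   injected, in (0, 1].
#' @param dt time step, s; `NULL` selects
#'   `min(1e-4, 0.1 * L_min / max(ubar))`.
#' @param gravity gravity vector, m/s^2.
#' @param seed integer RNG seed; every stochastic draw of the run flows
#'   from it.
#' @param facet_axial_bin,facet_azimuthal_bins wall discretization passed
#'   to [discretize_wall()].
#' @param drag_law drag closure (see [drag_factor()]).
#' @param n_checkpoints number of evenly spaced volume-fraction checkpoints
#'   in the ledger.
#' @return A `seeding_config` list.
#' @export
seeding_config <- function(network, bc, model = deposition_model("stokes"),
                           fluid = media_fluid(), buffer = buffer_fluid(),
                           phenotype = cell_phenotype(),
                           concentration = 2.5e11,
                           total_volume = 20e-6, stop_fraction = 0.01,
                           dt = NULL, gravity = c(0, 0, -9.81), seed = 1,
                           facet_axial_bin = 2e-4, facet_azimuthal_bins = 8,
                           drag_law = "schiller_naumann",
                           n_checkpoints = 200) {
  if (total_volume <= 0) stop("total_volume must be > 0", call. = FALSE)
  if (stop_fraction <= 0 || stop_fraction > 1)
    stop("stop_fraction must lie in (0, 1]", call. = FALSE)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(list(network = network, bc = bc, model = model, fluid = fluid,
                 buffer = buffer, phenotype = phenotype,
                 concentration = concentration, total_volume = total_volume,
                 stop_fraction = stop_fraction, dt = dt, gravity = gravity,
                 seed = seed, facet_axial_bin = facet_axial_bin,
                 facet_azimuthal_bins = facet_azimuthal_bins,
                 drag_law = drag_law, n_checkpoints = n_checkpoints),
            class = "seeding_config")
}

#' Run a transient seeding simulation
#'
#' Solves the steady flow once, then advances the media front and all
#' suspended cells in lockstep until the configured media volume has been
#' injected. Cells travel with the media (a cell never outruns the plug-flow
#' front); each wall encounter triggers one uniform-random deposition trial
#' under the configured rule, with rejected cells reflected specularly and
#' carried downstream. Cells leave the ledger only by depositing or exiting
#' the vein outlet; cells still suspended at termination count against
#' efficiency.
#'
#' @param config a [seeding_config()].
#' @return A `simulation_result`: list with `counts` (injected / deposited /
#'   exited / suspended), `ledger` (per-checkpoint counts and efficiency),
#'   `events` (one row per deposition: particle id, time, segment, facet,
#'   probability, draw, volume fraction), `facets` (facet table with deposit
#'   counts), `final_efficiency` (percent), `cov` (coefficient of variation
#'   over all facets; `NA` when nothing deposited), `saturation_time`,
#'   `flow` (the steady `flow_solution`) and the `config`.
#' @export
run_seeding <- function(config) {
  stopifnot(inherits(config, "seeding_config"))
  net <- config$network
  if (nrow(net$segments) == 0) stop("empty network", call. = FALSE)
  flow <- solve_flow(net, config$bc, config$fluid)

  if (config$concentration == 0) {
    warning("concentration is 0: no particles injected; efficiency undefined",
            call. = FALSE)
    return(structure(list(counts = list(injected = 0L, deposited = 0L,
                                        exited = 0L, suspended = 0L),
                          ledger = data.frame(), events = .empty_events(),
                          facets = cbind(discretize_wall(
                            net, config$facet_axial_bin,
                            config$facet_azimuthal_bins), count = 0L),
                          final_efficiency = NA_real_, cov = NA_real_,
                          saturation_time = NA_real_, flow = flow,
                          config = config), class = "simulation_result"))
  }

  .with_seed(config$seed, .seeding_engine(config, net, flow))
}

#' @keywords internal
.empty_events <- function() {
  data.frame(particle_id = integer(), time = numeric(),
             segment_id = integer(), facet_id = integer(),
             probability = numeric(), draw = numeric(),
             volume_fraction = numeric())
}

#' @keywords internal
.seeding_engine <- function(config, net, flow) {
  segs <- net$segments
  fs <- flow$segments
  pieces <- .network_pieces(net)
  fmeta <- .facet_meta(net, config$facet_axial_bin,
                       config$facet_azimuthal_bins)
  ftab <- discretize_wall(net, config$facet_axial_bin,
                          config$facet_azimuthal_bins)
  topo <- .front_topology(net)

  # per-segment arrays (row order = segment table order)
  segR <- segs$diameter / 2
  segL <- segs$length
  ubar <- fs$ubar
  vwall <- fs$Q_leak / (pi * segs$diameter * segs$length)
  ph <- config$phenotype; fl <- config$fluid
  Reff <- segR - ph$diameter / 2
  if (any(Reff <= 0))
    stop("cell diameter exceeds a vessel lumen", call. = FALSE)
  ctx <- impact_context(ubar = pmax(0, abs(ubar)), diameter = segs$diameter,
                        tau_w = fs$tau_w, phenotype = ph, fluid = fl)
  P_seg <- deposition_probability(config$model, ctx)

  # per-node routing tables (outgoing segments, cumulative flow weights)
  route <- vector("list", nrow(net$nodes))
  names(route) <- as.character(net$nodes$id)
  for (nd in net$nodes$id) {
    out <- .outgoing_flows(nd, net, flow)
    if (nrow(out))
      route[[as.character(nd)]] <-
        list(rows = out$seg_row, cum = cumsum(out$flow) / sum(out$flow))
  }
  seg_to <- segs$to

  dt <- config$dt
  if (is.null(dt))
    dt <- min(1e-4, 0.1 * min(segL) / max(abs(ubar), 1e-12))
  g_buoy <- config$gravity * (ph$density - fl$density) / ph$density
  tau_stokes <- ph$density * ph$diameter^2 / (18 * fl$viscosity)
  sn_drag <- identical(config$drag_law, "schiller_naumann")

  stop_volume <- config$stop_fraction * config$total_volume
  inj_rate <- config$concentration * config$bc$inlet_flow
  checkpoints <- config$stop_fraction *
    seq_len(config$n_checkpoints) / config$n_checkpoints
  next_cp <- 1L

  front <- media_front(net)

  # active-particle arrays (always in increasing-id order)
  pos <- matrix(numeric(0), 0, 3); vel <- matrix(numeric(0), 0, 3)
  pc <- integer(0); ids <- integer(0); cflag <- logical(0)
  n_inj <- 0L; n_dep <- 0L; n_exit <- 0L
  carry <- 0; t <- 0
  ev <- list(); nev <- 0L
  ledger <- vector("list", config$n_checkpoints)
  facet_counts <- integer(fmeta$n_facets)

  root_row <- which(segs$from == net$inlet)[1]
  root_pc <- pieces$first[root_row]
  root_dir <- pieces$dir[root_pc, ]
  root_e1 <- pieces$e1[root_pc, ]; root_e2 <- pieces$e2[root_pc, ]
  root_R <- segR[root_row]; root_Reff <- Reff[root_row]

  max_steps <- ceiling(stop_volume / config$bc$inlet_flow / dt) + 2L
  for (step in seq_len(max_steps)) {
    if (t * config$bc$inlet_flow >= stop_volume) break
    front <- advance_media_front(net, flow, front, dt, topo)
    t <- t + dt
    vol_frac <- t * config$bc$inlet_flow / config$total_volume

    ## -- injection (draw order 1) ------------------------------------
    expect <- inj_rate * dt + carry
    k <- floor(expect + 1e-9); carry <- max(0, expect - k)
    if (k > 0) {
      r <- .sample_inlet_radius(k, root_R, root_Reff)
      phi <- stats::runif(k, 0, 2 * pi)
      offm <- outer(r * cos(phi), root_e1) + outer(r * sin(phi), root_e2)
      newpos <- matrix(pieces$start[root_pc, ], k, 3, byrow = TRUE) + offm
      u_ax <- 2 * ubar[root_row] * (1 - (r / root_R)^2)
      newvel <- outer(u_ax, root_dir) +
        ((vwall[root_row] * r / root_R) / pmax(r, 1e-300)) * offm
      pos <- rbind(pos, newpos); vel <- rbind(vel, newvel)
      pc <- c(pc, rep.int(root_pc, k))
      ids <- c(ids, n_inj + seq_len(k))
      cflag <- c(cflag, logical(k))
      n_inj <- n_inj + as.integer(k)
    }

    n <- length(ids)
    if (n > 0) {
      sg <- pieces$seg[pc]
      st <- pieces$start[pc, , drop = FALSE]
      dr <- pieces$dir[pc, , drop = FALSE]
      rel <- pos - st
      a0 <- rowSums(rel * dr)
      w0 <- rel - a0 * dr
      r0 <- sqrt(rowSums(w0^2))
      R <- segR[sg]
      u_ax <- 2 * ubar[sg] * (1 - pmin(1, r0 / R)^2)
      u <- u_ax * dr + ((vwall[sg] * r0 / R) / pmax(r0, 1e-300)) * w0
      slip <- sqrt(rowSums((vel - u)^2))
      f <- if (sn_drag)
        1 + 0.15 * (fl$density * slip * ph$diameter / fl$viscosity)^0.687
      else rep(1, n)
      upd <- .exp_update(pos, vel, u, tau_stokes / f, dt, g_buoy)

      rel1 <- upd$pos - st
      a1 <- rowSums(rel1 * dr)
      w1 <- rel1 - a1 * dr
      thit <- .impact_fraction(w0, w1, Reff[sg])
      hit <- which(!is.na(thit))
      drop <- logical(n)

      ## -- deposition trials (draw order 2, particle order) ----------
      if (length(hit)) {
        th <- thit[hit]
        w0h <- w0[hit, , drop = FALSE]
        wi <- w0h + th * (w1[hit, , drop = FALSE] - w0h)
        ri <- sqrt(rowSums(wi^2))
        nhat <- wi / pmax(ri, 1e-300)
        ai <- a0[hit] + th * (a1[hit] - a0[hit])
        trial <- !cflag[hit]           # fresh wall encounters only
        dep <- logical(length(hit))
        if (any(trial)) {
          tr_idx <- which(trial)
          Pi <- P_seg[sg[hit[tr_idx]]]
          draws <- stats::runif(length(tr_idx))
          dep_tr <- Pi > draws
          dep[tr_idx] <- dep_tr
          cflag[hit[tr_idx[!dep_tr]]] <- TRUE   # rejected: now in contact
          if (any(dep_tr)) {
            hd <- hit[tr_idx[dep_tr]]
            s_seg <- pieces$offset[pc[hd]] + ai[tr_idx[dep_tr]]
            wd <- wi[tr_idx[dep_tr], , drop = FALSE]
            ang <- atan2(rowSums(wd * pieces$e2[pc[hd], , drop = FALSE]),
                         rowSums(wd * pieces$e1[pc[hd], , drop = FALSE]))
            fid <- .facet_index(fmeta, sg[hd], s_seg, ang)
            nev <- nev + 1L
            ev[[nev]] <- data.frame(
              particle_id = ids[hd], time = t, segment_id = segs$id[sg[hd]],
              facet_id = fid, probability = Pi[dep_tr],
              draw = draws[dep_tr], volume_fraction = vol_frac)
            for (fi in fid) facet_counts[fi] <- facet_counts[fi] + 1L
            n_dep <- n_dep + as.integer(sum(dep_tr))
            drop[hd] <- TRUE
          }
        }
        # reflect everyone not deposited (fresh rejections and contained
        # wall-riding cells alike); no draws consumed here
        rf <- which(!dep)
        if (length(rf)) {
          hr <- hit[rf]
          nh <- nhat[rf, , drop = FALSE]
          ipos <- st[hr, , drop = FALSE] +
            (a0[hr] + th[rf] * (a1[hr] - a0[hr])) * dr[hr, , drop = FALSE] +
            wi[rf, , drop = FALSE]
          v <- upd$vel[hr, , drop = FALSE]
          v <- v - 2 * rowSums(v * nh) * nh
          upd$pos[hr, ] <- ipos - 1e-3 * ph$diameter * nh
          upd$vel[hr, ] <- v
        }
      }

      pos <- upd$pos; vel <- upd$vel

      ## -- piece transitions and junction routing (draw order 3) -----
      for (pass in 1:6) {
        live <- which(!drop)
        if (!length(live)) break
        stl <- pieces$start[pc[live], , drop = FALSE]
        drl <- pieces$dir[pc[live], , drop = FALSE]
        al <- rowSums((pos[live, , drop = FALSE] - stl) * drl)
        over_l <- which(al > pieces$len[pc[live]])
        if (!length(over_l)) break
        oi <- live[over_l]                    # indices into active arrays
        aover <- al[over_l]
        rem <- aover - pieces$len[pc[oi]]
        wl <- (pos[oi, , drop = FALSE] -
                 pieces$start[pc[oi], , drop = FALSE]) -
          aover * pieces$dir[pc[oi], , drop = FALSE]
        rl <- sqrt(rowSums(wl^2))
        at_end <- pc[oi] == pieces$last[pieces$seg[pc[oi]]]

        # interior piece-to-piece handoff: keep radius, remap the radial
        # offset into the next piece's cross-section
        ii <- oi[!at_end]
        if (length(ii)) {
          newp <- pc[ii] + 1L
          pos[ii, ] <- .reseed_into_piece(pieces, newp, rem[!at_end],
                                          wl[!at_end, , drop = FALSE],
                                          rl[!at_end])
          pc[ii] <- newp
        }

        # junction crossing / outlet exit
        jj <- oi[at_end]
        if (length(jj)) {
          nd <- seg_to[pieces$seg[pc[jj]]]
          is_out <- nd == net$outlet
          if (any(is_out)) {
            n_exit <- n_exit + as.integer(sum(is_out))
            drop[jj[is_out]] <- TRUE
          }
          go <- jj[!is_out]
          if (length(go)) {
            nd_go <- nd[!is_out]
            draws <- stats::runif(length(go))
            newseg <- integer(length(go))
            for (q in seq_along(go)) {
              rt <- route[[as.character(nd_go[q])]]
              if (is.null(rt))
                stop("node ", nd_go[q], " has no outgoing flow",
                     call. = FALSE)
              kq <- findInterval(draws[q], rt$cum,
                                 rightmost.closed = TRUE) + 1L
              newseg[q] <- rt$rows[min(kq, length(rt$rows))]
            }
            # preserve the radial fraction r/R across the junction
            rfrac <- pmin(rl[at_end][!is_out] /
                            pmax(Reff[pieces$seg[pc[go]]], 1e-300), 0.999)
            newp <- pieces$first[newseg]
            pos[go, ] <- .reseed_into_piece(
              pieces, newp, rem[at_end][!is_out],
              wl[at_end, , drop = FALSE][!is_out, , drop = FALSE],
              rl[at_end][!is_out], r_target = rfrac * Reff[newseg])
            pc[go] <- newp
          }
        }
      }

      ## -- media-front gating: cells never outrun the plug front -----
      live <- which(!drop)
      if (length(live)) {
        sgl <- pieces$seg[pc[live]]
        stl <- pieces$start[pc[live], , drop = FALSE]
        drl <- pieces$dir[pc[live], , drop = FALSE]
        al <- rowSums((pos[live, , drop = FALSE] - stl) * drl)
        s_seg <- pieces$offset[pc[live]] + al
        lim <- front$fraction[sgl] * segL[sgl]
        beyond <- which(s_seg > lim)
        if (length(beyond)) {
          excess <- pmin(s_seg[beyond] - lim[beyond],
                         pmax(al[beyond], 0))
          pos[live[beyond], ] <- pos[live[beyond], , drop = FALSE] -
            excess * drl[beyond, , drop = FALSE]
        }
        # clear the contact flag for cells that re-entered the bulk
        rel2 <- pos[live, , drop = FALSE] - stl
        a2 <- rowSums(rel2 * drl)
        r2 <- sqrt(rowSums((rel2 - a2 * drl)^2))
        cflag[live[r2 < Reff[sgl] - ph$diameter]] <- FALSE
      }

      if (any(drop)) {
        keep <- !drop
        pos <- pos[keep, , drop = FALSE]; vel <- vel[keep, , drop = FALSE]
        pc <- pc[keep]; ids <- ids[keep]; cflag <- cflag[keep]
      }
    }

    ## -- ledger checkpoints ------------------------------------------
    while (next_cp <= config$n_checkpoints &&
           vol_frac >= checkpoints[next_cp] - 1e-12) {
      ledger[[next_cp]] <- data.frame(
        volume_fraction = checkpoints[next_cp], time = t,
        injected = n_inj, deposited = n_dep, exited = n_exit,
        suspended = n_inj - n_dep - n_exit)
      next_cp <- next_cp + 1L
    }
  }

  ledger <- do.call(rbind, ledger[!vapply(ledger, is.null, logical(1))])
  if (!is.null(ledger) && nrow(ledger))
    ledger$efficiency <- ifelse(ledger$injected > 0,
                                100 * ledger$deposited / ledger$injected,
                                NA_real_)
  events <- if (nev) do.call(rbind, ev[seq_len(nev)]) else .empty_events()
  ftab$count <- facet_counts
  final_eff <- if (n_inj > 0) 100 * n_dep / n_inj else NA_real_
  cov <- if (n_dep > 0) coefficient_of_variation(facet_counts) else NA_real_

  structure(list(counts = list(injected = n_inj, deposited = n_dep,
                               exited = n_exit,
                               suspended = n_inj - n_dep - n_exit),
                 ledger = ledger, events = events, facets = ftab,
                 final_efficiency = final_eff, cov = cov,
                 saturation_time = front$saturation_time, flow = flow,
                 config = config), class = "simulation_result")
}

# Place particles entering piece `newp` (vector) at axial overshoot `rem`
# with the previous radial offset `w` (matrix) of magnitude `r`, remapped
# into the new piece's cross-section. `r_target` overrides the radius
# (used at junctions to preserve the radial fraction r/R).
#' @keywords internal
.reseed_into_piece <- function(pieces, newp, rem, w, r, r_target = NULL) {
  dn <- pieces$dir[newp, , drop = FALSE]
  wproj <- w - rowSums(w * dn) * dn
  wn <- sqrt(rowSums(wproj^2))
  degen <- wn < 1e-15
  if (any(degen))  # offset parallel to new axis: fall back to the e1 frame
    wproj[degen, ] <- pieces$e1[newp, , drop = FALSE][degen, , drop = FALSE]
  wn <- sqrt(rowSums(wproj^2))
  rr <- if (is.null(r_target)) r else r_target
  pieces$start[newp, , drop = FALSE] + rem * dn + (rr / wn) * wproj
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> model ", x$config$model$model, "\n", sep = "")
  cat(sprintf("  injected %d | deposited %d | exited %d | suspended %d\n",
              x$counts$injected, x$counts$deposited, x$counts$exited,
              x$counts$suspended))
  cat(sprintf("  seeding efficiency %.1f%%, CoV %.3g, saturation %.4g s\n",
              x$final_efficiency, x$cov, x$saturation_time))
  invisible(x)
}

#' Efficiency-versus-volume curve
#'
#' Seeding efficiency `100 * deposited / injected` sampled at the ledger's
#' fixed volume-fraction checkpoints.
#'
#' @param result a `simulation_result` with at least one injected particle.
#' @return data.frame with `volume_fraction` and `efficiency` (percent).
#' @export
efficiency_curve <- function(result) {
  if (is.null(result$ledger) || !nrow(result$ledger) ||
      result$counts$injected < 1)
    stop("no injected particles: efficiency curve undefined", call. = FALSE)
  result$ledger[result$ledger$injected > 0,
                c("volume_fraction", "efficiency")]
}

#' Sweep injection flow rates
#'
#' Runs one simulation per flow rate with a common seed and collects the
#' final efficiency, deposition uniformity (CoV) and front saturation time.
#'
#' @param config a [seeding_config()]; its `bc` supplies the outlet
#'   pressure when plain numeric rates are given.
#' @param rates either a numeric vector of inlet flow rates (m^3/s) or a
#'   list of [boundary_conditions()] (e.g. the canonical low/high pairs,
#'   which tie each rate to its own outlet pressure).
#' @return data.frame with one row per rate: `flow_ml_min`, `efficiency`,
#'   `cov`, `saturation_time`, `injected`, `deposited`.
#' @export
sweep_flow_rates <- function(config, rates) {
  bcs <- if (is.list(rates) && all(vapply(rates, inherits, logical(1),
                                          "boundary_conditions"))) rates
  else lapply(rates, function(q)
    boundary_conditions(q, config$bc$outlet_pressure,
                        config$bc$parenchyma_pressure))
  rows <- lapply(bcs, function(bc) {
    cfg <- config; cfg$bc <- bc
    res <- run_seeding(cfg)
    data.frame(flow_ml_min = bc$inlet_flow * 6e7,
               efficiency = res$final_efficiency, cov = res$cov,
               saturation_time = res$saturation_time,
               injected = res$counts$injected,
               deposited = res$counts$deposited)
  })
  do.call(rbind, rows)
}
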