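# Plug-flow tracking of the cell-media front displacing the pre-saturating
# buffer. Each segment carries a filled arc-length fraction in [0, 1]; the
# front enters a segment only once all of its upstream segments are full.

#' Initialize a media-front state
#'
#' @param network a [vascular_network()].
#' @return A `media_front_state`: list with `fraction` (per segment, all 0),
#'   `time` (0) and `saturation_time` (`NA` until every fraction reaches 1).
#' @export
media_front <- function(network) {
  structure(list(fraction = rep(0, nrow(network$segments)), time = 0,
                 saturation_time = NA_real_),
            class = "media_front_state")
}

# Upstream segment row indices per segment (segments delivering into the
# `from` node), plus which segments hang directly off the inlet.
#' @keywords internal
.front_topology <- function(network) {
  segs <- network$segments
  ups <- lapply(seq_len(nrow(segs)),
                function(i) which(segs$to == segs$from[i]))
  list(upstream = ups, at_inlet = segs$from == network$inlet)
}

#' Advance the media front by one time step
#'
#' Eligible segments (those hanging off the inlet, or whose upstream
#' segments are all full) advance their fill fraction by `ubar * dt / L`,
#' capped at 1. Fractions are monotone non-decreasing; the first time all
#' fractions reach 1 is recorded as the saturation time.
#'
#' @param network a [vascular_network()].
#' @param flow a `flow_solution` from [solve_flow()].
#' @param state a `media_front_state`.
#' @param dt time step, s (> 0).
#' @param topo optional cached result of the internal topology scan (used by
#'   the simulation engine to avoid recomputation).
#' @return Updated `media_front_state`.
#' @export
advance_media_front <- function(network, flow, state, dt, topo = NULL) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (is.null(topo)) topo <- .front_topology(network)
  f <- state$fraction
  full <- f >= 1
  eligible <- topo$at_inlet | vapply(topo$upstream,
                                     function(u) all(full[u]), logical(1))
  adv <- eligible & !full
  f[adv] <- pmin(1, f[adv] + abs(flow$segments$ubar[adv]) * dt /
                   network$segments$length[adv])
  t_new <- state$time + dt
  sat <- state$saturation_time
  if (is.na(sat) && all(f >= 1)) sat <- t_new
  structure(list(fraction = f, time = t_new, saturation_time = sat),
            class = "media_front_state")
}
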