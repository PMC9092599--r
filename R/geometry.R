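# Vascular network data model and synthetic tree generation.
#
# A network is a directed graph of cylindrical vessel segments along
# piecewise-linear centerlines. All geometry is in SI units (meters);
# coordinates are right-handed and gravity points along -z by default.

#' @keywords internal
.unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction vector", call. = FALSE)
  v / n
}

# Run `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
#' @keywords internal
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @keywords internal
.polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Construct a vascular network
#'
#' Low-level constructor assembling nodes, segments and centerlines into a
#' validated `vascular_network` object. Most users will call [build_tube()],
#' [generate_tree()] or [reference_network()] instead.
#'
#' @param nodes data.frame with columns `id, x, y, z` (meters).
#' @param segments data.frame with columns `id, from, to, diameter, alpha,
#'   wall_thickness, region` (`region` one of `"artery"`, `"distal"`,
#'   `"vein"`), plus optionally `generation`.
#' @param centerlines named list (by segment id, as character) of n x 3
#'   matrices of centerline points; endpoints must coincide with the
#'   `from`/`to` node positions.
#' @param inlet,outlet node ids of the single inlet (artery side) and single
#'   outlet (vein side).
#' @param p_par parenchyma reservoir pressure in Pa (default 0).
#' @return A `vascular_network`: list with elements `nodes`, `segments`
#'   (with computed `length` column), `centerlines`, `inlet`, `outlet`,
#'   `p_par`.
#' @export
vascular_network <- function(nodes, segments, centerlines, inlet, outlet,
                             p_par = 0) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)),
            all(c("id", "from", "to", "diameter", "alpha",
                  "wall_thickness") %in% names(segments)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(segments$id)) stop("duplicate segment ids", call. = FALSE)
  if (!"region" %in% names(segments)) segments$region <- "distal"
  if (!"generation" %in% names(segments)) segments$generation <- NA_integer_

  if (any(segments$diameter <= 0)) stop("segment diameter must be > 0", call. = FALSE)
  if (any(segments$alpha < 0)) stop("wall permeability must be >= 0", call. = FALSE)
  if (any(segments$wall_thickness <= 0)) stop("wall thickness must be > 0", call. = FALSE)

  segments$length <- vapply(as.character(segments$id), function(sid) {
    pts <- centerlines[[sid]]
    if (is.null(pts) || nrow(pts) < 2)
      stop("segment ", sid, ": centerline needs >= 2 points", call. = FALSE)
    .polyline_length(pts)
  }, numeric(1))
  if (any(segments$length <= 0)) stop("segment of zero length", call. = FALSE)

  # centerline endpoints must coincide with node positions
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(pos) <- as.character(nodes$id)
  for (i in seq_len(nrow(segments))) {
    pts <- centerlines[[as.character(segments$id[i])]]
    a <- pos[as.character(segments$from[i]), ]
    b <- pos[as.character(segments$to[i]), ]
    tol <- 1e-9 + 1e-9 * segments$length[i]
    if (sqrt(sum((pts[1, ] - a)^2)) > tol || sqrt(sum((pts[nrow(pts), ] - b)^2)) > tol)
      stop("segment ", segments$id[i],
           ": centerline endpoints do not coincide with its nodes", call. = FALSE)
  }

  net <- structure(list(nodes = nodes, segments = segments,
                        centerlines = centerlines,
                        inlet = inlet, outlet = outlet, p_par = p_par),
                   class = "vascular_network")
  .validate_topology(net)
  net
}

#' @keywords internal
.validate_topology <- function(net) {
  ids <- net$nodes$id
  if (!(net$inlet %in% ids) || !(net$outlet %in% ids))
    stop("inlet/outlet node missing from node table", call. = FALSE)
  touch <- table(factor(c(net$segments$from, net$segments$to), levels = ids))
  interior <- setdiff(ids, c(net$inlet, net$outlet))
  if (length(interior) && any(touch[as.character(interior)] < 2))
    stop("interior node(s) touching fewer than 2 segments: ",
         paste(interior[touch[as.character(interior)] < 2], collapse = ", "),
         call. = FALSE)
  # connectivity (undirected reachability from inlet)
  adj <- split(c(net$segments$to, net$segments$from),
               c(net$segments$from, net$segments$to))
  seen <- as.character(net$inlet)
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- as.character(nxt)
  }
  if (length(seen) < length(ids))
    stop("network is disconnected; unreachable node(s): ",
         paste(setdiff(ids, seen), collapse = ", "), call. = FALSE)
  invisible(net)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ", nrow(x$segments),
      " segments\n", sep = "")
  cat("  inlet node ", x$inlet, ", outlet node ", x$outlet,
      ", parenchyma pressure ", x$p_par, " Pa\n", sep = "")
  cat("  diameters [um]: ", paste(round(range(x$segments$diameter) * 1e6, 1),
                                  collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Build a single straight vessel
#'
#' One cylindrical segment from the origin along `axis`, useful as the
#' minimal flow and transport test geometry.
#'
#' @param length,diameter tube dimensions in meters; both must be positive.
#' @param axis direction of the tube axis (any 3-vector, normalized
#'   internally).
#' @param n_centerline_points number of (collinear) centerline points, >= 2.
#' @param alpha wall Darcy permeability in m^2 (0 = impermeable).
#' @param wall_thickness wall leakage path thickness in meters.
#' @param p_par parenchyma pressure, Pa.
#' @return A single-segment [vascular_network()]; node 1 (origin) is the
#'   inlet, node 2 the outlet.
#' @examples
#' tube <- build_tube(1e-3, 200e-6)
#' tube$segments$length   # 1 mm
#' @export
build_tube <- function(length, diameter, axis = c(1, 0, 0),
                       n_centerline_points = 2, alpha = 0,
                       wall_thickness = 50e-6, p_par = 0) {
  if (length <= 0 || diameter <= 0)
    stop("length and diameter must be positive", call. = FALSE)
  if (n_centerline_points < 2) stop("need >= 2 centerline points", call. = FALSE)
  ax <- .unit3(axis)
  tt <- seq(0, length, length.out = n_centerline_points)
  pts <- outer(tt, ax)
  nodes <- data.frame(id = c(1L, 2L),
                      x = c(0, pts[n_centerline_points, 1]),
                      y = c(0, pts[n_centerline_points, 2]),
                      z = c(0, pts[n_centerline_points, 3]))
  segs <- data.frame(id = 1L, from = 1L, to = 2L, diameter = diameter,
                     alpha = alpha, wall_thickness = wall_thickness,
                     region = "artery", generation = 0L)
  vascular_network(nodes, segs, list(`1` = pts), inlet = 1L, outlet = 2L,
                   p_par = p_par)
}

# Orthonormal vector pair spanning the plane normal to `d`.
#' @keywords internal
.transverse_frame <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit3(ref - sum(ref * d) * d)
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Sinusoidally perturbed centerline between two points: a half-wave of
# amplitude `amp` along a transverse direction drawn from the current RNG.
#' @keywords internal
.tortuous_centerline <- function(a, b, n_pts, amp) {
  if (n_pts < 2) n_pts <- 2
  tt <- seq(0, 1, length.out = n_pts)
  pts <- outer(1 - tt, a) + outer(tt, b)
  if (amp > 0 && n_pts > 2) {
    d <- .unit3(b - a)
    fr <- .transverse_frame(d)
    phi <- stats::runif(1, 0, 2 * pi)
    tv <- cos(phi) * fr$e1 + sin(phi) * fr$e2
    pts <- pts + outer(amp * sin(pi * tt), tv)
  }
  pts
}

#' Generate a symmetric bifurcating arterio-venous tree
#'
#' Grows a binary arterial tree from a single inlet artery through
#' `generations` bifurcation levels, then mirrors the tree across the plane
#' of the terminal tips so the terminal branches re-merge into a single
#' outlet vein (an arterio-venous loop). Daughter diameters follow either
#' Murray's law (`d_parent^3 = sum d_child^3`, symmetric split:
#' `d_child = d_parent * 2^(-1/3)`) or a fixed ratio. Segment length is
#' `length_to_diameter_ratio * diameter`. Branches advance axially by
#' `L*cos(angle)` and offset transversely by `L*sin(angle)`, alternating the
#' transverse axis between y and z at successive generations so the tree
#' spreads in 3D. Optional tortuosity displaces interior centerline points
#' by a transverse half-sine of the stated amplitude.
#'
#' @param generations number of bifurcation levels (>= 1) between artery and
#'   vein.
#' @param root_diameter inlet artery diameter, meters.
#' @param diameter_rule `"murray"` or `"fixed_ratio"`.
#' @param ratio daughter/parent diameter ratio when `diameter_rule =
#'   "fixed_ratio"`.
#' @param length_to_diameter_ratio segment length as a multiple of its
#'   diameter.
#' @param branch_angle bifurcation half-angle, degrees.
#' @param tortuosity_amplitude transverse half-sine amplitude in meters
#'   (0 = straight segments).
#' @param n_centerline_points centerline points per segment (the bends that
#'   drive inertial impaction need >= 3 when tortuosity is nonzero).
#' @param seed integer seed; the tree is deterministic for a fixed seed.
#' @param alpha,wall_thickness,p_par wall-leakage parameters applied to
#'   every segment (see [wall_permeance()]).
#' @return A [vascular_network()]; segments carry `region` labels
#'   (`artery` = root arterial segment, `vein` = final venous segment,
#'   `distal` otherwise) and a `generation` column.
#' @examples
#' net <- generate_tree(2, 300e-6, seed = 1)
#' table(net$segments$region)
#' @export
generate_tree <- function(generations, root_diameter,
                          diameter_rule = c("murray", "fixed_ratio"),
                          ratio = 0.75, length_to_diameter_ratio = 6,
                          branch_angle = 35, tortuosity_amplitude = 0,
                          n_centerline_points = 2, seed = 1,
                          alpha = 0, wall_thickness = 50e-6, p_par = 0) {
  diameter_rule <- match.arg(diameter_rule)
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  if (root_diameter <= 0) stop("root_diameter must be > 0", call. = FALSE)
  n_seg_total <- 2 * (2^(generations + 1) - 1)
  if (n_seg_total > 1e5)
    stop("tree would contain ", n_seg_total, " segments (> 1e5)", call. = FALSE)

  shrink <- if (diameter_rule == "murray") 2^(-1 / 3) else ratio
  theta <- branch_angle * pi / 180

  .with_seed(seed, {
    # --- arterial half -------------------------------------------------
    # node bookkeeping: positions accumulated in a list, ids sequential
    npos <- list(c(0, 0, 0))
    new_node <- function(p) { npos[[length(npos) + 1]] <<- p; length(npos) }

    segs <- list()
    cls <- list()
    add_seg <- function(from, to, d, gen, region) {
      id <- length(segs) + 1L
      segs[[id]] <<- data.frame(id = id, from = from, to = to, diameter = d,
                                alpha = alpha, wall_thickness = wall_thickness,
                                region = region, generation = gen)
      cls[[id]] <<- .tortuous_centerline(npos[[from]], npos[[to]],
                                         n_centerline_points,
                                         tortuosity_amplitude)
      id
    }

    # root artery along +x
    d0 <- root_diameter
    L0 <- length_to_diameter_ratio * d0
    root_tip <- new_node(c(L0, 0, 0))
    add_seg(1L, root_tip, d0, 0L, "artery")

    # frontier: list of (node id, transverse-axis index 1=y 2=z)
    frontier <- list(list(node = root_tip))
    d <- d0
    for (g in seq_len(generations)) {
      d <- d * shrink
      L <- length_to_diameter_ratio * d
      axis_t <- if (g %% 2 == 1) c(0, 1, 0) else c(0, 0, 1)
      nxt <- list()
      for (br in frontier) {
        p <- npos[[br$node]]
        for (sgn in c(-1, 1)) {
          tip <- p + c(L * cos(theta), 0, 0) + sgn * L * sin(theta) * axis_t
          nid <- new_node(tip)
          add_seg(br$node, nid, d, g, "distal")
          nxt[[length(nxt) + 1]] <- list(node = nid)
        }
      }
      frontier <- nxt
    }

    # --- venous half: mirror across the plane of the terminal tips -----
    x_tip <- npos[[frontier[[1]]$node]][1]
    # all tips share x by construction
    n_art_nodes <- length(npos)
    n_art_segs <- length(segs)
    tip_ids <- vapply(frontier, function(b) b$node, integer(1))
    mirror_id <- integer(n_art_nodes)  # arterial node -> venous image node
    for (i in seq_len(n_art_nodes)) {
      if (i %in% tip_ids) { mirror_id[i] <- i; next }
      p <- npos[[i]]
      mirror_id[i] <- new_node(c(2 * x_tip - p[1], p[2], p[3]))
    }
    # venous counterpart of arterial segment (from -> to) runs
    # mirror(to) -> mirror(from): flow continues tipward -> vein root.
    for (i in seq_len(n_art_segs)) {
      s <- segs[[i]]
      region <- if (s$region == "artery") "vein" else "distal"
      add_seg(mirror_id[s$to], mirror_id[s$from], s$diameter, s$generation,
              region)
    }

    nodes <- data.frame(id = seq_along(npos),
                        x = vapply(npos, `[`, numeric(1), 1),
                        y = vapply(npos, `[`, numeric(1), 2),
                        z = vapply(npos, `[`, numeric(1), 3))
    segments <- do.call(rbind, segs)
    names(cls) <- as.character(seq_along(cls))
    outlet <- mirror_id[1]
    vascular_network(nodes, segments, cls, inlet = 1L, outlet = outlet,
                     p_par = p_par)
  })
}

#' Canned four-generation arterio-venous reference network
#'
#' A version-pinned desk-scale network emulating the topology of a truncated
#' lung vascular domain: a single inlet artery, four generations of distal
#' vessels, and a single outlet vein. Root diameter 300 um with Murray
#' scaling (terminal diameter ~119 um, all diameters >= 100 um), gentle
#' bends between generations, and porous walls with Darcy permeability
#' 8.9e-9 cm^2. The wall leakage path thickness (1.2 mm) is the effective
#' parenchymal path to the constant-pressure reservoir -- not a literal
#' membrane thickness -- chosen so the vein outlet carries about a third of
#' the inflow at the canonical low rate, the flow-split regime of perfused
#' whole-organ scaffolds; see the package vignette.
#'
#' The construction (generator arguments and seed) is pinned so simulation
#' results on this network are stable across sessions.
#'
#' @return A [vascular_network()] with 62 segments.
#' @examples
#' net <- reference_network()
#' range(net$segments$diameter) * 1e6   # um
#' @export
reference_network <- function() {
  generate_tree(generations = 4, root_diameter = 300e-6,
                diameter_rule = "murray", length_to_diameter_ratio = 6,
                branch_angle = 35, tortuosity_amplitude = 30e-6,
                n_centerline_points = 5, seed = 42,
                alpha = 8.9e-13,       # 8.9e-9 cm^2
                wall_thickness = 1.2e-3, # effective parenchymal path length
                p_par = 0)
}
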