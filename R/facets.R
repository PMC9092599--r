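# Discretization of vessel walls into facets for deposition mapping.
#
# Each segment's lateral surface (pi*d*L) is split into n_axial equal-length
# axial bins times n_azimuthal equal angular sectors; every wall point maps
# to exactly one facet and facet areas partition the lateral area exactly.

#' Discretize vessel walls into facets
#'
#' @param network a [vascular_network()].
#' @param axial_bin_length target axial bin length in meters; each segment
#'   uses `ceiling(L / axial_bin_length)` equal bins so bins never exceed the
#'   target length.
#' @param n_azimuthal_bins number of angular sectors per axial bin (>= 1).
#' @return data.frame with columns `facet_id`, `segment_id`, `axial_bin`,
#'   `azimuthal_bin`, `area` (m^2). Facet ids are consecutive integers; per
#'   segment, the facet areas sum to `pi * d * L`.
#' @examples
#' f <- discretize_wall(build_tube(1e-3, 200e-6), 0.5e-3, 4)
#' nrow(f)        # 8 facets
#' sum(f$area)    # pi * d * L
#' @export
discretize_wall <- function(network, axial_bin_length, n_azimuthal_bins) {
  if (axial_bin_length <= 0) stop("axial_bin_length must be > 0", call. = FALSE)
  if (n_azimuthal_bins < 1) stop("n_azimuthal_bins must be >= 1", call. = FALSE)
  segs <- network$segments
  out <- vector("list", nrow(segs))
  offset <- 0L
  for (i in seq_len(nrow(segs))) {
    L <- segs$length[i]
    n_ax <- max(1L, as.integer(ceiling(L / axial_bin_length)))
    area <- pi * segs$diameter[i] * L / (n_ax * n_azimuthal_bins)
    grid <- expand.grid(azimuthal_bin = seq_len(n_azimuthal_bins),
                        axial_bin = seq_len(n_ax))
    out[[i]] <- data.frame(facet_id = offset + seq_len(nrow(grid)),
                           segment_id = segs$id[i],
                           axial_bin = grid$axial_bin,
                           azimuthal_bin = grid$azimuthal_bin,
                           area = area)
    offset <- offset + nrow(grid)
  }
  do.call(rbind, out)
}

# Per-segment facet indexing metadata used by the simulation engine to map
# an impact (segment, arc position, azimuth) to a facet id in O(1).
#' @keywords internal
.facet_meta <- function(network, axial_bin_length, n_azimuthal_bins) {
  segs <- network$segments
  n_ax <- pmax(1L, as.integer(ceiling(segs$length / axial_bin_length)))
  base <- cumsum(c(0L, head(n_ax * n_azimuthal_bins, -1L)))
  list(n_ax = n_ax, n_az = n_azimuthal_bins, base = base,
       seg_len = segs$length, n_facets = sum(n_ax) * n_azimuthal_bins)
}

# Vectorized facet lookup. `seg_idx` is the row index of the segment (not its
# id), `s` the arc position along the segment, `angle` the azimuth in
# radians (any real).
#' @keywords internal
.facet_index <- function(meta, seg_idx, s, angle) {
  nax <- meta$n_ax[seg_idx]
  L <- meta$seg_len[seg_idx]
  ax <- pmin(nax, pmax(1L, as.integer(floor(s / (L / nax))) + 1L))
  a <- angle %% (2 * pi)
  az <- pmin(meta$n_az, as.integer(floor(a / (2 * pi / meta$n_az))) + 1L)
  meta$base[seg_idx] + (ax - 1L) * meta$n_az + az
}
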