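# Internal flattening of piecewise-linear centerlines into straight pieces.
#
# The transport engine works in the local frame of one straight centerline
# piece at a time: radial coordinates are measured to the piece axis, and a
# fixed orthonormal cross-section frame (e1, e2) per piece gives a
# well-defined azimuth for facet mapping.

#' @keywords internal
.network_pieces <- function(network) {
  segs <- network$segments
  rows <- list()
  first <- integer(nrow(segs)); last <- integer(nrow(segs))
  k <- 0L
  for (i in seq_len(nrow(segs))) {
    pts <- network$centerlines[[as.character(segs$id[i])]]
    np <- nrow(pts)
    first[i] <- k + 1L
    off <- 0
    for (j in seq_len(np - 1L)) {
      a <- pts[j, ]; b <- pts[j + 1L, ]
      v <- b - a
      len <- sqrt(sum(v^2))
      if (len == 0) next
      d <- v / len
      fr <- .transverse_frame(d)
      k <- k + 1L
      rows[[k]] <- c(a, d, fr$e1, fr$e2, len, off, i)
      off <- off + len
    }
    last[i] <- k
  }
  M <- do.call(rbind, rows)
  list(start = M[, 1:3, drop = FALSE],
       dir = M[, 4:6, drop = FALSE],
       e1 = M[, 7:9, drop = FALSE],
       e2 = M[, 10:12, drop = FALSE],
       len = M[, 13],
       offset = M[, 14],          # arc offset of piece start within segment
       seg = as.integer(M[, 15]), # segment row index
       first = first, last = last)
}
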