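# Plain-text network serialization and VTK centerline export.
#
# Format (whitespace-delimited UTF-8):
#   vasonet 1
#   inlet <id> outlet <id> p_par <Pa>
#   nodes <n>
#   <id> <x> <y> <z>                      (n lines)
#   segments <m>
#   <id> <from> <to> <d> <alpha> <t_w> <region> <npts>
#   <x> <y> <z>                           (npts centerline lines)
# Numbers are written with full double precision so networks round-trip
# losslessly.

#' Write a network to the plain-text format
#'
#' @param network a [vascular_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(network, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines("vasonet 1", con)
  writeLines(sprintf("inlet %d outlet %d p_par %s",
                     as.integer(network$inlet), as.integer(network$outlet),
                     num(network$p_par)), con)
  writeLines(sprintf("nodes %d", nrow(network$nodes)), con)
  with(network$nodes,
       writeLines(sprintf("%d %s %s %s", as.integer(id), num(x), num(y),
                          num(z)), con))
  writeLines(sprintf("segments %d", nrow(network$segments)), con)
  for (i in seq_len(nrow(network$segments))) {
    s <- network$segments[i, ]
    pts <- network$centerlines[[as.character(s$id)]]
    writeLines(sprintf("%d %d %d %s %s %s %s %d", as.integer(s$id),
                       as.integer(s$from), as.integer(s$to), num(s$diameter),
                       num(s$alpha), num(s$wall_thickness), s$region,
                       nrow(pts)), con)
    writeLines(apply(pts, 1, function(p) paste(num(p), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a network from the plain-text format
#'
#' @param path file written by [write_network()].
#' @return A [vascular_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "\\s+")
  if (!identical(tok[[1]], c("vasonet", "1")))
    stop("not a vasonet v1 file: ", path, call. = FALSE)
  hdr <- tok[[2]]
  inlet <- as.integer(hdr[2]); outlet <- as.integer(hdr[4])
  p_par <- as.numeric(hdr[6])
  i <- 3
  stopifnot(tok[[i]][1] == "nodes")
  n <- as.integer(tok[[i]][2]); i <- i + 1
  nd <- do.call(rbind, lapply(tok[i:(i + n - 1)], as.numeric))
  nodes <- data.frame(id = as.integer(nd[, 1]), x = nd[, 2], y = nd[, 3],
                      z = nd[, 4])
  i <- i + n
  stopifnot(tok[[i]][1] == "segments")
  m <- as.integer(tok[[i]][2]); i <- i + 1
  segs <- vector("list", m); cls <- vector("list", m)
  keys <- character(m)
  for (k in seq_len(m)) {
    h <- tok[[i]]; i <- i + 1
    npts <- as.integer(h[8])
    pts <- do.call(rbind, lapply(tok[i:(i + npts - 1)], as.numeric))
    i <- i + npts
    segs[[k]] <- data.frame(id = as.integer(h[1]), from = as.integer(h[2]),
                            to = as.integer(h[3]), diameter = as.numeric(h[4]),
                            alpha = as.numeric(h[5]),
                            wall_thickness = as.numeric(h[6]), region = h[7])
    keys[k] <- h[1]
    cls[[k]] <- pts
  }
  names(cls) <- keys
  vascular_network(nodes, do.call(rbind, segs), cls, inlet = inlet,
                   outlet = outlet, p_par = p_par)
}

#' Export centerlines as VTK legacy polydata
#'
#' Writes segment centerlines as polylines with vessel diameter attached as
#' point data, for visualization in ParaView and friends. Visualization
#' only; the file is not read back by this package.
#'
#' @param network a [vascular_network()].
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_centerlines <- function(network, path) {
  pts_list <- lapply(as.character(network$segments$id),
                     function(sid) network$centerlines[[sid]])
  npts <- vapply(pts_list, nrow, integer(1))
  all_pts <- do.call(rbind, pts_list)
  diam <- rep(network$segments$diameter, npts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vasoseed vessel centerlines", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(all_pts))), con)
  writeLines(apply(all_pts, 1, function(p)
    paste(format(p, digits = 10), collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", length(npts), sum(npts + 1L)), con)
  off <- cumsum(c(0L, npts[-length(npts)]))
  for (k in seq_along(npts))
    writeLines(paste(c(npts[k], off[k] + seq_len(npts[k]) - 1L),
                     collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(all_pts)),
               "SCALARS diameter double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(diam, digits = 10), con)
  invisible(path)
}
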