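# Seeding outcome statistics: efficiency, per-facet deposition uniformity
# (coefficient of variation), regional distributions, and the cell surface
# coverage percentage used for histology sections.

#' Seeding efficiency
#'
#' Percentage of injected cells that deposited: `100 * deposited/injected`.
#'
#' @param deposited,injected non-negative counts, `deposited <= injected`,
#'   `injected > 0`.
#' @return Efficiency in percent.
#' @export
seeding_efficiency <- function(deposited, injected) {
  if (injected <= 0) stop("injected must be > 0", call. = FALSE)
  if (deposited < 0 || deposited > injected)
    stop("need 0 <= deposited <= injected", call. = FALSE)
  100 * deposited / injected
}

#' Coefficient of variation of per-facet deposition
#'
#' `CoV = sigma / mu` over the per-facet deposit counts, with the population
#' standard deviation (divide by n, not n - 1). Facets with zero deposits
#' are part of n: the statistic is taken over every wall facet, which
#' materially lowers the mean and raises the CoV relative to a
#' deposited-facets-only convention.
#'
#' @param counts integer vector of deposit counts, one entry per facet
#'   (zeros included).
#' @return Dimensionless CoV; 0 for a perfectly uniform distribution.
#' @export
coefficient_of_variation <- function(counts) {
  if (length(counts) < 1) stop("need at least one facet", call. = FALSE)
  mu <- mean(counts)
  if (mu == 0) stop("no deposition: CoV undefined (mean = 0)", call. = FALSE)
  sqrt(mean((counts - mu)^2)) / mu
}

#' Cell surface coverage percentage
#'
#' `CSC% = 100 * cell_area / (cell_area + uncovered_area)`; a pure formula
#' utility for histology-style area measurements (any consistent unit).
#'
#' @param cell_area,uncovered_area non-negative areas, not both zero.
#' @return Coverage in percent.
#' @export
cell_surface_coverage <- function(cell_area, uncovered_area) {
  if (cell_area < 0 || uncovered_area < 0)
    stop("areas must be >= 0", call. = FALSE)
  if (cell_area + uncovered_area == 0)
    stop("both areas are zero", call. = FALSE)
  100 * cell_area / (cell_area + uncovered_area)
}

#' Regional deposition distribution
#'
#' Counts deposition events per anatomical region (`artery`, `distal`,
#' `vein`) at each volume-fraction checkpoint.
#'
#' @param events deposition-event data.frame with columns `segment_id` and
#'   `volume_fraction` (as produced by [run_seeding()]).
#' @param region_labels named character vector mapping segment id (as
#'   character) to region; every segment appearing in `events` must be
#'   labeled.
#' @param checkpoints increasing volume fractions at which cumulative
#'   counts are reported (default: the final total only, `Inf`).
#' @return data.frame with one row per checkpoint and one column per region
#'   (cumulative counts), plus a `volume_fraction` column.
#' @export
regional_distribution <- function(events, region_labels,
                                  checkpoints = Inf) {
  regions <- c("artery", "distal", "vein")
  miss <- setdiff(as.character(unique(events$segment_id)),
                  names(region_labels))
  if (length(miss))
    stop("unlabeled segment(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lab <- region_labels[as.character(events$segment_id)]
  if (!all(lab %in% regions))
    stop("region labels must be one of: ", paste(regions, collapse = ", "),
         call. = FALSE)
  out <- lapply(checkpoints, function(v) {
    sel <- events$volume_fraction <= v
    tab <- table(factor(lab[sel], levels = regions))
    as.data.frame(as.list(tab))
  })
  cbind(volume_fraction = checkpoints, do.call(rbind, out))
}

#' Region labels of a network
#'
#' Named character vector (by segment id) of the `region` column, suitable
#' for [regional_distribution()].
#'
#' @param network a [vascular_network()].
#' @return Named character vector.
#' @export
network_regions <- function(network) {
  stats::setNames(network$segments$region,
                  as.character(network$segments$id))
}
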