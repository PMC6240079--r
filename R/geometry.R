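# Shoreline geometry: re-express lateral aquatic-to-terrestrial flows from
# donor-area or shoreline-length units into areal units of the recipient
# terrestrial band. All functions are vectorised and linear in the flow, so
# carbon is conserved exactly: per-band flow * perimeter * band width equals
# per-donor-m2 flow * donor area.

#' Approximate a lake perimeter from its area and shoreline development
#'
#' Uses the limnological shoreline-development approximation
#' `perimeter = 2 * D_L * sqrt(area * pi)`, where the development factor
#' `D_L` is the ratio of the true perimeter to that of a circle of equal
#' area (`D_L = 1` for a circular lake, 2 for a lake of the same area with a
#' two-fold longer shoreline). A measured perimeter, when available, should
#' be used instead of this approximation.
#'
#' @param area Lake area in m2 (> 0).
#' @param d_l Shoreline development factor (>= 1).
#' @return Perimeter in m.
#' @examples
#' lake_perimeter(pi, 1)    # circle of radius 1: 2*pi
#' lake_perimeter(1e4, 1)   # ~354.49 m
#' @export
lake_perimeter <- function(area, d_l = 1) {
  check_positive(area, "area")
  if (any(!is.finite(d_l) | d_l < 1)) {
    abort("shoreline development factor must be >= 1 (1 = circular)",
          class = "crossflux_domain_error")
  }
  2 * d_l * sqrt(area * pi)
}

#' Convert a per-donor-area lake flow to a per-shoreline flow
#'
#' Emergence-type fluxes measured per m2 of lake surface are converted to a
#' flow per metre of shoreline by multiplying by the total lake area and
#' dividing by the perimeter.
#'
#' @param flow Flow in gC per m2 of lake per year (>= 0).
#' @param area Lake area in m2 (> 0).
#' @param perimeter Lake perimeter in m (> 0); see [lake_perimeter()].
#' @return Flow in gC per m of shoreline per year.
#' @examples
#' flow_per_shoreline_lake(1, 1e4, lake_perimeter(1e4, 1))
#' @export
flow_per_shoreline_lake <- function(flow, area, perimeter) {
  check_positive(area, "area")
  check_positive(perimeter, "perimeter")
  flow * area / perimeter
}

#' Convert a per-donor-area stream flow to a per-shoreline flow
#'
#' Stream fluxes per m2 of stream surface are multiplied by the stream width
#' and divided by two (one bank on each side) to obtain the flow per metre
#' of shoreline.
#'
#' @param flow Flow in gC per m2 of stream per year.
#' @param width Stream width in m (> 0).
#' @return Flow in gC per m of shoreline per year.
#' @examples
#' flow_per_shoreline_stream(1, 4)  # 2
#' @export
flow_per_shoreline_stream <- function(flow, width) {
  if (any(!is.finite(width) | width <= 0)) {
    abort("stream width must be positive", class = "crossflux_contract_error")
  }
  flow * width / 2
}

#' Spread a shoreline flow over the recipient terrestrial band
#'
#' Assumes the flow deposits uniformly over the first `band_width` metres
#' inland from the shore (default 10 m, the distance within which most
#' aquatic insect deposition and carcass transport falls; 100 m is the
#' conservative sensitivity setting and scales every result by exactly
#' one tenth).
#'
#' @param flow Flow in gC per m of shoreline per year.
#' @param band_width Width of the recipient band in m (> 0).
#' @return Flow in gC per m2 of recipient ecosystem per year.
#' @examples
#' distribute_on_band(28.21, 10)
#' @export
distribute_on_band <- function(flow, band_width = 10) {
  check_positive(band_width, "band_width")
  flow / band_width
}

check_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(paste0(what, " must be positive"), class = "crossflux_domain_error")
  }
  invisible(x)
}
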