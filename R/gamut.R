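# Mapping the attainable quasi-color gamut over pigment grids.
#
# The network defines the only quasi-colors a leaf can attain for a given
# pigment combination; evaluating it on a dense (SR-S, Lb-A) grid yields
# per-coordinate surfaces, attainable ranges at fixed pigment levels, and
# the sum/difference views used to read off how combined or relative pigment
# content shapes the quasi-color.

#' Evaluate the quasi-color gamut over a pigment grid
#'
#' Predicts CMQ coordinates at every point of a regular (SR-S, Lb-A) grid.
#' The default ranges cover the full span observed across all tested plant
#' species (SR-S up to 9.7, Lb-A up to 8.0) at step 0.1.
#'
#' @param net A `"tanh_network"`.
#' @param srs_range,lba_range Grid ranges, `c(min, max)`.
#' @param step Grid step (same for both axes).
#' @return A data frame of class `"gamut_table"` with one row per grid point
#'   and columns `srs`, `lba`, `qL`, `qa`, `qb`, `qC`, `qh` (0–360 scale),
#'   `qh_wrapped`, `srs_plus_lba`, `srs_minus_lba`.
#' @examples
#' g <- compute_gamut(published_cmq_network(), step = 0.5)
#' attainable_range(g, "qb", "srs", 5.0)
#' @export
compute_gamut <- function(net, srs_range = c(0, 9.7), lba_range = c(0, 8.0),
                          step = 0.1) {
  stopifnot(inherits(net, "tanh_network"), step > 0,
            srs_range[1] <= srs_range[2], lba_range[1] <= lba_range[2])
  grid <- expand.grid(srs = seq(srs_range[1], srs_range[2], by = step),
                      lba = seq(lba_range[1], lba_range[2], by = step))
  pred <- predict(net, grid, check_range = FALSE)
  out <- cbind(grid, pred,
               srs_plus_lba = grid$srs + grid$lba,
               srs_minus_lba = grid$srs - grid$lba)
  class(out) <- c("gamut_table", class(out))
  out
}

#' Attainable range of a coordinate at a fixed pigment level
#'
#' The min and max of one quasi-color coordinate over all grid rows where
#' the other pigment varies freely — e.g. the attainable qb* span when
#' SR-S is held at 5.0.
#'
#' @param table A `"gamut_table"` from [compute_gamut()].
#' @param coordinate One of `"qL"`, `"qa"`, `"qb"`, `"qC"`, `"qh"`.
#' @param fixed_input `"srs"` or `"lba"` — the axis to hold fixed.
#' @param fixed_value Value on that axis (matched to grid points within
#'   half a step).
#' @return Named numeric `c(min, max)`.
#' @export
attainable_range <- function(table, coordinate = c("qL", "qa", "qb", "qC", "qh"),
                             fixed_input = c("srs", "lba"), fixed_value) {
  coordinate <- match.arg(coordinate)
  fixed_input <- match.arg(fixed_input)
  axis <- table[[fixed_input]]
  tol <- if (length(unique(axis)) > 1) min(diff(sort(unique(axis)))) / 2 else Inf
  rows <- abs(axis - fixed_value) < tol
  if (!any(rows)) {
    stop(sprintf("no grid rows with %s near %g", fixed_input, fixed_value))
  }
  v <- table[[coordinate]][rows]
  c(min = min(v), max = max(v))
}

#' Hue in the single-pigment corners of the gamut
#'
#' Mean predicted hue angle where essentially only one pigment is present:
#' the anthocyanin-only corner (top `corner_fraction` of the Lb-A axis,
#' bottom fraction of SR-S) and the chlorophyll-only corner (the reverse).
#' Hues are averaged on the wrapped (-180, 180] scale — the purple–red
#' corner straddles 360° — and reported on the 0–360 scale.
#'
#' @param table A `"gamut_table"`.
#' @param corner_fraction Fraction of each axis range defining a corner.
#' @return Named numeric with `anthocyanin_corner` and `chlorophyll_corner`
#'   mean hues in degrees on the 0–360 scale.
#' @export
hue_extremes <- function(table, corner_fraction = 0.1) {
  stopifnot(corner_fraction > 0, corner_fraction < 0.5)
  lo <- function(v) min(v) + corner_fraction * diff(range(v))
  hi <- function(v) max(v) - corner_fraction * diff(range(v))
  antho <- table$srs <= lo(table$srs) & table$lba >= hi(table$lba)
  chlor <- table$srs >= hi(table$srs) & table$lba <= lo(table$lba)
  if (!any(antho) || !any(chlor)) stop("grid does not cover the corner regions")
  corner_mean <- function(rows) {
    unwrap_hue(mean(table$qh_wrapped[rows], na.rm = TRUE))
  }
  c(anthocyanin_corner = corner_mean(antho),
    chlorophyll_corner = corner_mean(chlor))
}
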