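# Inferring the color of an unobserved leaf surface.
#
# Because the CMQ is the mean of the two surface colors, knowing one surface
# and the (pigment-predicted) CMQ determines the other surface exactly:
# hidden = 2 * CMQ - known, per coordinate. The relation is symmetric in the
# two surfaces, so either one may play the role of "known".

#' Estimate the color of the unobserved leaf surface
#'
#' Given the measured CIELab color of one surface (typically adaxial, the
#' one an overhead sensor sees) and the leaf's pigment levels, predicts the
#' CMQ from the network and solves the midpoint relation for the other
#' surface: each coordinate is twice the predicted CMQ coordinate minus the
#' known one. Estimates whose lightness leaves [0, 100] are never clipped
#' silently — they are flagged in the `L_in_range` column.
#'
#' @param known The observed surface color: a (L, a, b) triple or an
#'   n x 3 table.
#' @param pigments Pigment levels: `c(srs, lba)`, or a data frame / matrix
#'   with `srs`, `lba` columns (rows paired with `known`).
#' @param net A `"tanh_network"`; defaults to the published model.
#' @return A data frame with the estimated surface (`L`, `a`, `b`), its
#'   chroma `C` and hue `h` (0–360 scale; `NA` at zero chroma), and the
#'   logical flag `L_in_range`.
#' @examples
#' # a leaf with strongly different surfaces: known dark-red adaxial side
#' estimate_hidden_surface(c(23.1, 8.1, 5.2), c(srs = 5.4, lba = 3.9))
#' @export
estimate_hidden_surface <- function(known, pigments,
                                    net = published_cmq_network()) {
  stopifnot(inherits(net, "tanh_network"))
  km <- as_lab_matrix(known, "known")
  X <- as_pigment_matrix(pigments)
  if (nrow(X) == 1 && nrow(km) > 1) X <- X[rep(1, nrow(km)), , drop = FALSE]
  if (nrow(km) != nrow(X)) stop("'known' and 'pigments' must have matching rows")
  cmq <- predict(net, X)
  est <- 2 * as.matrix(cmq[, c("qL", "qa", "qb")]) - km
  C <- chroma(est[, 2], est[, 3])
  h <- ifelse(C == 0, NA_real_, (atan2(est[, 3], est[, 2]) * 180 / pi) %% 360)
  out <- data.frame(L = est[, 1], a = est[, 2], b = est[, 3],
                    C = C, h = h,
                    L_in_range = est[, 1] >= 0 & est[, 1] <= 100,
                    row.names = NULL)
  if (any(!out$L_in_range)) {
    warning(sum(!out$L_in_range),
            " estimated surface(s) have lightness outside [0, 100]")
  }
  out
}
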