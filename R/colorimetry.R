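# CIELab arithmetic for leaf surfaces and quasi-colors.
#
# Colors are plain numeric triples (L, a, b) or n x 3 matrices / data frames
# with those columns; quasi-colors (qL, qa, qb) are treated identically.
# Angles are always degrees; the hue scale ("0-360" vs "wrapped") is explicit
# in every interface that touches hue.

#' CIELab chroma
#'
#' Chroma C* = sqrt(a*^2 + b*^2) measures the vividness of a color; low
#' chroma means a dull, gray-ish color.
#'
#' @param a Red–green coordinate(s).
#' @param b Yellow–blue coordinate(s).
#' @return Non-negative chroma, vectorized over `a` and `b`.
#' @examples
#' chroma(8, -9.9)  # 12.7 at one decimal
#' @export
chroma <- function(a, b) {
  sqrt(a^2 + b^2)
}

#' CIELab hue angle
#'
#' The hue angle is the direction of (a*, b*) computed with the
#' quadrant-aware two-argument arctangent, in degrees. Red–purple sits near
#' 0°, yellow near 90°, green near 125°, purple–red near 340°. On the
#' `"wrapped"` scale, angles above 180° have 360° subtracted so that
#' leaf hues — which never fall in the cyan/teal/blue band around 180–360°
#' boundary crossing — form a contiguous interval suitable for averaging
#' (the mean of 350° and 16° is 3°, not 183°).
#'
#' @param a Red–green coordinate(s).
#' @param b Yellow–blue coordinate(s).
#' @param scale `"0-360"` for the usual [0, 360) scale, `"wrapped"` for
#'   (-180, 180].
#' @return Hue angle(s) in degrees on the requested scale.
#' @examples
#' hue_angle(8, -9.9)            # 309 degrees (nearest degree)
#' hue_angle(-12, 28)            # 113 degrees
#' hue_angle(8, -9.9, "wrapped") # -51 degrees
#' @export
hue_angle <- function(a, b, scale = c("0-360", "wrapped")) {
  scale <- match.arg(scale)
  if (any(a == 0 & b == 0)) {
    stop("hue angle is undefined at a = b = 0")
  }
  h <- (atan2(b, a) * 180 / pi) %% 360
  if (scale == "wrapped") wrap_hue(h) else h
}

#' Wrap hue angles onto the (-180, 180] scale
#'
#' Angles strictly above 180° have 360° subtracted; 180° itself is kept
#' (half-open convention — no leaf hues occur there, the cyan/teal band).
#' `unwrap_hue()` is the exact inverse.
#'
#' @param h Hue angle(s) in degrees in [0, 360).
#' @return Angle(s) in (-180, 180].
#' @examples
#' wrap_hue(345) # -15: a purple hue enters analyses as a small negative angle
#' @export
wrap_hue <- function(h) {
  if (any(h < 0 | h >= 360)) {
    stop("wrap_hue() expects angles in [0, 360)")
  }
  ifelse(h > 180, h - 360, h)
}

#' @rdname wrap_hue
#' @param hw Hue angle(s) in degrees in (-180, 180].
#' @export
unwrap_hue <- function(hw) {
  if (any(hw <= -180 | hw > 180)) {
    stop("unwrap_hue() expects angles in (-180, 180]")
  }
  ifelse(hw < 0, hw + 360, hw)
}

# Coerce a color triple (vector with or without names, list, 1-row data
# frame) or an n x 3 matrix / data frame to an n x 3 numeric matrix.
as_lab_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(dim(x))) {
    if (length(x) != 3) {
      stop(sprintf("'%s' must be a (L, a, b) triple or an n x 3 table", arg))
    }
    x <- matrix(as.numeric(x), nrow = 1)
  }
  if (ncol(x) != 3) {
    stop(sprintf("'%s' must have exactly 3 columns (L, a, b)", arg))
  }
  x <- matrix(as.numeric(x), nrow = nrow(x))
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", arg))
  x
}

#' CIELab color difference
#'
#' The Euclidean distance between two CIELab triples,
#' \eqn{\Delta E = \sqrt{\Delta L^2 + \Delta a^2 + \Delta b^2}}. Also applied
#' to quasi-color triples (qL, qa, qb), where it is written \eqn{\Delta qE};
#' quasi-colors live in the same coordinate space, so the formula is
#' identical, but the result compares notional rather than visible colors.
#'
#' @param c1,c2 Color triples (L, a, b) or n x 3 tables compared row-wise.
#' @return Non-negative difference(s); zero iff the triples are identical.
#' @examples
#' delta_e(c(26.2, 8, -9.9), c(44, -12, 28)) # 46.4: dark-red vs green surface
#' @export
delta_e <- function(c1, c2) {
  m1 <- as_lab_matrix(c1, "c1")
  m2 <- as_lab_matrix(c2, "c2")
  if (nrow(m1) != nrow(m2)) {
    if (nrow(m1) == 1) m1 <- m1[rep(1, nrow(m2)), , drop = FALSE]
    else if (nrow(m2) == 1) m2 <- m2[rep(1, nrow(m1)), , drop = FALSE]
    else stop("'c1' and 'c2' must have the same number of rows")
  }
  sqrt(rowSums((m1 - m2)^2))
}

# Attach derived chroma and hue columns to a (qL, qa, qb) matrix.
cmq_frame <- function(m) {
  qC <- chroma(m[, 2], m[, 3])
  qh <- ifelse(qC == 0, NA_real_, (atan2(m[, 3], m[, 2]) * 180 / pi) %% 360)
  data.frame(qL = m[, 1], qa = m[, 2], qb = m[, 3],
             qC = qC, qh = qh,
             qh_wrapped = ifelse(is.na(qh), NA_real_, wrap_hue(qh)))
}

#' Conceptual midpoint quasi-color of a two-surface measurement
#'
#' The CMQ coordinates are the per-axis arithmetic means of the CIELab
#' coordinates measured at antipodal points on the adaxial and abaxial
#' surfaces: qL* = (L_D + L_B)/2, qa* = (a_D + a_B)/2, qb* = (b_D + b_B)/2.
#' The CMQ is not a visible color — it is the conceptual midpoint between the
#' two surface colors, and it is what the pigment-based models predict. When
#' both surfaces have identical color, the CMQ equals that color.
#'
#' @param adaxial,abaxial Surface colors, each a (L, a, b) triple or an
#'   n x 3 table (rows are paired).
#' @return A data frame with columns `qL`, `qa`, `qb`, derived chroma `qC`,
#'   and the hue on both scales (`qh` in [0, 360), `qh_wrapped` in
#'   (-180, 180]; `NA` when qC = 0).
#' @examples
#' compute_cmq(c(26.2, 8, -9.9), c(44, -12, 28))
#' @export
compute_cmq <- function(adaxial, abaxial) {
  m1 <- as_lab_matrix(adaxial, "adaxial")
  m2 <- as_lab_matrix(abaxial, "abaxial")
  if (nrow(m1) != nrow(m2)) stop("surface tables must have the same number of rows")
  if (any(m1[, 1] < 0 | m1[, 1] > 100 | m2[, 1] < 0 | m2[, 1] > 100)) {
    stop("lightness L must lie in [0, 100]")
  }
  cmq_frame((m1 + m2) / 2)
}
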