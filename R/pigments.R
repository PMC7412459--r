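# Transformations between raw meter readings and the modeling units.
#
# Chlorophyll content is measured in SPAD units (transmittance meter) and
# modeled as SR-S = sqrt(SPAD); anthocyanin content is measured in ACI units
# and modeled as Lb-A = log2(ACI). Both transforms were chosen to improve
# normality and put the two pigments on comparable numeric ranges.

# Calibrated ranges of the transformed units over all tested plant species.
SRS_MAX <- 9.7
LBA_MIN <- 0
LBA_MAX <- 8.0

#' Convert SPAD chlorophyll readings to SR-S units
#'
#' SR-S is the square root of a SPAD reading. `srs_to_spad()` is the exact
#' inverse.
#'
#' @param spad SPAD reading(s), non-negative.
#' @return SR-S value(s).
#' @examples
#' spad_to_srs(36) # 6
#' @export
spad_to_srs <- function(spad) {
  if (any(spad < 0)) stop("SPAD readings must be non-negative")
  sqrt(spad)
}

#' @rdname spad_to_srs
#' @param srs SR-S value(s), non-negative.
#' @export
srs_to_spad <- function(srs) {
  if (any(srs < 0)) stop("SR-S values must be non-negative")
  srs^2
}

#' Convert ACI anthocyanin readings to Lb-A units
#'
#' Lb-A is the binary logarithm of an ACI reading. `lba_to_aci()` is the
#' exact inverse. ACI readings below 1 give negative Lb-A, outside the range
#' observed on real leaves (0.1–7.8 in lettuce); they are accepted with a
#' warning rather than rejected, since the models are deliberately applied
#' beyond the calibration range.
#'
#' @param aci ACI reading(s), strictly positive.
#' @return Lb-A value(s).
#' @examples
#' aci_to_lba(16) # 4
#' @export
aci_to_lba <- function(aci) {
  if (any(aci <= 0)) stop("ACI readings must be strictly positive")
  lba <- log2(aci)
  if (any(lba < LBA_MIN)) {
    warning("Lb-A below 0: outside the calibrated range, prediction is extrapolation")
  }
  lba
}

#' @rdname aci_to_lba
#' @param lba Lb-A value(s).
#' @export
lba_to_aci <- function(lba) {
  2^lba
}

#' Flag pigment levels outside the calibrated range
#'
#' The models were calibrated on SR-S in [0, 9.7] and Lb-A in [0, 8.0]
#' (the full range over all tested plant species). Values outside are legal
#' inputs — predictions there are extrapolations.
#'
#' @param srs,lba Pigment levels in transformed units.
#' @return Logical vector, `TRUE` where the pair is outside the range.
#' @export
pigment_out_of_range <- function(srs, lba) {
  srs < 0 | srs > SRS_MAX | lba < LBA_MIN | lba > LBA_MAX
}

warn_if_extrapolating <- function(srs, lba) {
  n_out <- sum(pigment_out_of_range(srs, lba))
  if (n_out > 0) {
    warning(sprintf(
      "%d pigment input(s) outside the calibrated range (SR-S in [0, %.1f], Lb-A in [%.0f, %.1f]); predictions are extrapolations",
      n_out, SRS_MAX, LBA_MIN, LBA_MAX))
  }
  invisible(n_out)
}

#' Average pigment levels measured at antipodal points
#'
#' Meter readings are taken at antipodal points on the adaxial and abaxial
#' surfaces and averaged per pigment. Averaging is done in the transformed
#' units (SR-S, Lb-A) — the scale on which all downstream modeling operates.
#'
#' @param adaxial,abaxial Pigment levels: numeric pairs `c(srs, lba)` or
#'   data frames / matrices with columns `srs`, `lba` (rows paired).
#' @return The per-component mean, in the same shape as the inputs.
#' @examples
#' average_antipodal(c(6, 4), c(4, 2)) # c(5, 3)
#' @export
average_antipodal <- function(adaxial, abaxial) {
  as_pair <- function(x, arg) {
    if (is.data.frame(x) || is.matrix(x)) {
      x <- as.matrix(as.data.frame(x)[, c("srs", "lba")])
    } else if (length(x) == 2) {
      x <- matrix(as.numeric(x), nrow = 1, dimnames = list(NULL, c("srs", "lba")))
    } else {
      stop(sprintf("'%s' must be a (srs, lba) pair or a table with those columns", arg))
    }
    if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", arg))
    x
  }
  m1 <- as_pair(adaxial, "adaxial")
  m2 <- as_pair(abaxial, "abaxial")
  if (nrow(m1) != nrow(m2)) stop("inputs must have the same number of rows")
  out <- (m1 + m2) / 2
  if (nrow(out) == 1 && is.null(dim(adaxial))) {
    c(srs = unname(out[1, 1]), lba = unname(out[1, 2]))
  } else {
    as.data.frame(out)
  }
}
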