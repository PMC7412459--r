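# Polynomial baselines for CMQ prediction, fitted by ordinary least squares
# (one lm per response). The three families are nested subsets of the full
# second-order response surface in (SR-S, Lb-A):
#
#   full_factorial       1, S, A, S:A
#   quadratic_polynomial 1, S, A, S^2, A^2
#   response_surface     1, S, A, S:A, S^2, A^2

parametric_formulas <- list(
  full_factorial       = ~ srs + lba + srs:lba,
  quadratic_polynomial = ~ srs + lba + I(srs^2) + I(lba^2),
  response_surface     = ~ srs + lba + srs:lba + I(srs^2) + I(lba^2))

#' Fit a polynomial baseline model for CMQ prediction
#'
#' Ordinary least squares of each CMQ coordinate on polynomial terms in the
#' two pigment levels. The term sets are nested (`full_factorial` and
#' `quadratic_polynomial` are both subsets of `response_surface`), so the
#' response-surface training error can never exceed either of the other two.
#'
#' @param data Data frame with columns `srs`, `lba`, `qL`, `qa`, `qb`.
#' @param family One of `"full_factorial"`, `"quadratic_polynomial"`,
#'   `"response_surface"`.
#' @return An object of class `"cmq_parametric"` holding one `lm` fit per
#'   coordinate.
#' @examples
#' d <- simulate_leaf_data(100, seed = 1)
#' fit <- fit_cmq_parametric(d, "response_surface")
#' predict(fit, data.frame(srs = 5, lba = 3))
#' @export
fit_cmq_parametric <- function(data,
                               family = c("response_surface", "full_factorial",
                                          "quadratic_polynomial")) {
  d <- as_training_frame(data)
  family <- match.arg(family)
  rhs <- parametric_formulas[[family]]
  nterms <- ncol(stats::model.matrix(rhs, d[1:2, ]))
  if (nrow(d) <= nterms) {
    stop(sprintf("need more than %d samples to fit %s", nterms, family))
  }
  fits <- lapply(c("qL", "qa", "qb"), function(resp) {
    f <- stats::as.formula(paste(resp, paste(deparse(rhs), collapse = "")))
    fit <- lm(f, data = d)
    if (fit$rank < nterms) {
      stop(sprintf("rank-deficient design for %s (%s): rank %d < %d terms",
                   resp, family, fit$rank, nterms))
    }
    fit
  })
  names(fits) <- c("qL", "qa", "qb")
  structure(list(family = family, fits = fits, data = d, call = match.call()),
            class = "cmq_parametric")
}

#' Predict CMQ coordinates from a polynomial baseline
#'
#' @param object A `"cmq_parametric"` fit.
#' @param newdata Pigment inputs: data frame with `srs`/`lba` columns, an
#'   n x 2 matrix, or a single `c(srs, lba)` pair.
#' @param ... Unused.
#' @return A data frame with `qL`, `qa`, `qb`, `qC`, `qh`, `qh_wrapped`,
#'   as for [predict.tanh_network()].
#' @export
predict.cmq_parametric <- function(object, newdata, ...) {
  X <- as_pigment_matrix(newdata)
  nd <- data.frame(srs = X[, 1], lba = X[, 2])
  out <- vapply(object$fits, function(f) unname(predict(f, nd)),
                numeric(nrow(nd)))
  cmq_frame(matrix(out, ncol = 3))
}

#' @export
print.cmq_parametric <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric quasi-color model: %s (n = %d)\n", x$family, nrow(x$data)))
  for (resp in names(x$fits)) {
    co <- coef(x$fits[[resp]])
    cat(sprintf("  %s: %s\n", resp,
                paste(sprintf("%s = %s", names(co), formatC(co, digits = digits, format = "g")),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.cmq_parametric <- function(object, ...) {
  lapply(object$fits, coef)
}

#' @export
residuals.cmq_parametric <- function(object, ...) {
  as.data.frame(lapply(object$fits, residuals))
}
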