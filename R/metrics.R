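# Agreement and error metrics between observed and predicted coordinates,
# the side-by-side model comparison harness, and an approximate
# variable-importance (total-effect sensitivity) analysis.

check_paired <- function(observed, predicted, min_n = 1) {
  if (length(observed) != length(predicted)) {
    stop("'observed' and 'predicted' must have equal length")
  }
  if (length(observed) < min_n) stop("need at least ", min_n, " paired values")
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("paired series must be finite")
  }
  invisible(TRUE)
}

#' Coefficient of determination
#'
#' `1 - SS_residual / SS_total` with residual = observed - predicted. Can be
#' negative when the predictions fit worse than the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return R-squared (at most 1).
#' @export
r_squared <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed series has zero variance; R-squared undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Root mean square error
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Non-negative RMSE.
#' @export
rmse <- function(observed, predicted) {
  check_paired(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the paired-series validation used
#' throughout the package.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 2)
  if (sd(observed) == 0 || sd(predicted) == 0) {
    stop("correlation undefined for a zero-variance series")
  }
  cor(observed, predicted)
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line:
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' using population (divide-by-n) moments, Lin's original estimator. It
#' combines Pearson correlation (closeness to the best-fit line) with a
#' penalty for location/scale shift away from identity, so
#' \eqn{|\rho_c| \le |r|}, with equality when means and variances match.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Concordance in [-1, 1].
#' @examples
#' lins_concordance(c(1, 2, 3), c(2, 3, 4)) # 4/7: perfect r, shifted location
#' @export
lins_concordance <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 2)
  n <- length(observed)
  mx <- mean(observed); my <- mean(predicted)
  vx <- mean((observed - mx)^2); vy <- mean((predicted - my)^2)
  if (vx == 0 || vy == 0) stop("concordance undefined for a zero-variance series")
  sxy <- mean((observed - mx) * (predicted - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Split records into training and testing sets
#'
#' Seeded uniform split without replacement. By default the training set has
#' `floor(n * fraction)` rows; `sizes = c(n_train, n_test)` overrides the
#' counts exactly (e.g. `c(480, 124)` to mirror the original 604-leaf split).
#'
#' @param data A data frame.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param sizes Optional exact `c(training, testing)` sizes summing to
#'   `nrow(data)`.
#' @return A list with elements `training` and `testing`.
#' @export
train_test_split <- function(data, fraction = 0.8, seed = 1, sizes = NULL) {
  n <- nrow(data)
  if (n < 2) stop("need at least 2 rows to split")
  if (is.null(sizes)) {
    stopifnot(fraction > 0, fraction < 1)
    ntr <- floor(n * fraction)
  } else {
    stopifnot(length(sizes) == 2, sum(sizes) == n, all(sizes >= 1))
    ntr <- sizes[1]
  }
  set.seed(seed)
  idx <- sample.int(n, ntr)
  list(training = data[idx, , drop = FALSE],
       testing = data[-idx, , drop = FALSE])
}

#' Compare network and polynomial models on a train/test split
#'
#' Fits the three polynomial baselines and a tanh network on the training
#' set and tabulates R-squared and RMSE per CMQ coordinate on both the
#' training and testing sets — the standard side-by-side layout for judging
#' whether the network's extra flexibility pays off.
#'
#' @param training,testing Data frames with columns `srs`, `lba`, `qL`,
#'   `qa`, `qb`.
#' @param hidden Hidden-node count for the network.
#' @param families Polynomial families to include.
#' @param ... Passed to [fit_cmq_network()] (`penalty`, `restarts`, `seed`, ...).
#' @return An object of class `"cmq_comparison"`: a data frame with columns
#'   `model`, `set`, `metric`, `qL`, `qa`, `qb`, plus the fitted models in
#'   attribute `"models"`.
#' @export
model_comparison <- function(training, testing, hidden = 3,
                             families = c("full_factorial",
                                          "quadratic_polynomial",
                                          "response_surface"), ...) {
  training <- as_training_frame(training)
  testing <- as_training_frame(testing)
  models <- lapply(families, function(fam) fit_cmq_parametric(training, fam))
  names(models) <- families
  models$neural_network <- fit_cmq_network(training, hidden = hidden, ...)

  rows <- list()
  for (nm in names(models)) {
    for (set_nm in c("training", "testing")) {
      d <- if (set_nm == "training") training else testing
      pred <- predict(models[[nm]], d[, c("srs", "lba")],
                      check_range = FALSE)
      r2 <- vapply(c("qL", "qa", "qb"),
                   function(k) r_squared(d[[k]], pred[[k]]), numeric(1))
      rm <- vapply(c("qL", "qa", "qb"),
                   function(k) rmse(d[[k]], pred[[k]]), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(model = nm, set = set_nm,
                                             metric = "r_squared",
                                             qL = r2[1], qa = r2[2], qb = r2[3])
      rows[[length(rows) + 1]] <- data.frame(model = nm, set = set_nm,
                                             metric = "rmse",
                                             qL = rm[1], qa = rm[2], qb = rm[3])
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "models") <- models
  class(tab) <- c("cmq_comparison", class(tab))
  tab
}

#' @export
print.cmq_comparison <- function(x, digits = 3, ...) {
  tab <- as.data.frame(x)
  tab[c("qL", "qa", "qb")] <- round(tab[c("qL", "qa", "qb")], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Approximate variable importance of the network inputs
#'
#' The relative impact of SR-S and Lb-A on each CMQ coordinate, estimated as
#' Monte-Carlo total-effect (Sobol-style) sensitivity indices over
#' independent uniform inputs on the given ranges, using the Jansen
#' estimator. Reported as percentages of each response's output variance;
#' an input's total effect includes its interactions, so the two columns
#' need not sum to exactly 100.
#'
#' @param net A `"tanh_network"`.
#' @param srs_range,lba_range Input ranges (default: the span observed in
#'   the lettuce dataset).
#' @param n Monte-Carlo sample size per matrix.
#' @param seed Integer seed.
#' @return A 3 x 2 matrix of percentages (rows `qL`, `qa`, `qb`; columns
#'   `srs`, `lba`).
#' @export
variable_importance <- function(net, srs_range = c(0, 8.6),
                                lba_range = c(0.1, 7.8),
                                n = 10000, seed = 1) {
  stopifnot(inherits(net, "tanh_network"))
  if (diff(srs_range) <= 0 || diff(lba_range) <= 0) {
    stop("input ranges must have positive width")
  }
  set.seed(seed)
  draw <- function() cbind(runif(n, srs_range[1], srs_range[2]),
                           runif(n, lba_range[1], lba_range[2]))
  A <- draw()
  B <- draw()
  fA <- as.matrix(predict(net, A, check_range = FALSE)[, c("qL", "qa", "qb")])
  vy <- apply(fA, 2, function(y) mean((y - mean(y))^2))
  out <- matrix(NA_real_, 3, 2,
                dimnames = list(c("qL", "qa", "qb"), c("srs", "lba")))
  for (i in 1:2) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- as.matrix(predict(net, ABi, check_range = FALSE)[, c("qL", "qa", "qb")])
    # Jansen total-effect estimator: E[(f(A) - f(AB_i))^2] / (2 V[Y])
    out[, i] <- 100 * colMeans((fA - fABi)^2) / (2 * vy)
  }
  out
}
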