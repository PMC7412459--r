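# The 2-H-3 hyperbolic-tangent network family.
#
# A network maps the two pigment inputs (SR-S, Lb-A) through H hidden tanh
# units to the three CMQ responses (qL, qa, qb):
#
#   H_j  = tanh( s * (bh_j + W[j,1]*SR-S + W[j,2]*Lb-A) )
#   qL*  = bo_1 + sum_j Wo[1,j] * H_j     (and likewise qa*, qb*)
#
# The pre-activation scale s (0.5 in the published model) is stored as an
# explicit field rather than folded into the weights, so the published
# coefficients are represented bit-for-bit as printed.

#' Construct a tanh quasi-color network
#'
#' @param hidden_weights `H x 2` matrix of hidden-layer coefficients on
#'   (SR-S, Lb-A).
#' @param hidden_biases Length-`H` hidden-layer intercepts.
#' @param output_weights `3 x H` matrix of output coefficients
#'   (rows: qL, qa, qb).
#' @param output_biases Length-3 output intercepts (qL, qa, qb).
#' @param scale Pre-activation scale factor applied inside tanh.
#' @return An object of class `"tanh_network"`.
#' @seealso [published_cmq_network()], [fit_cmq_network()],
#'   [predict.tanh_network()]
#' @export
tanh_network <- function(hidden_weights, hidden_biases,
                         output_weights, output_biases, scale = 0.5) {
  hidden_weights <- as.matrix(hidden_weights)
  output_weights <- as.matrix(output_weights)
  h <- nrow(hidden_weights)
  stopifnot(ncol(hidden_weights) == 2,
            length(hidden_biases) == h,
            nrow(output_weights) == 3, ncol(output_weights) == h,
            length(output_biases) == 3,
            length(scale) == 1)
  vals <- c(hidden_weights, hidden_biases, output_weights, output_biases, scale)
  if (any(!is.finite(vals))) stop("all network coefficients must be finite")
  structure(list(
    hidden_count   = h,
    hidden_weights = unname(hidden_weights),
    hidden_biases  = unname(as.numeric(hidden_biases)),
    output_weights = unname(output_weights),
    output_biases  = unname(as.numeric(output_biases)),
    scale          = as.numeric(scale)
  ), class = "tanh_network")
}

#' The published CMQ network
#'
#' The three-hidden-node tanh network fitted to 480 lettuce leaves, with the
#' coefficients exactly as published (four decimals):
#' \deqn{qL^* = 76.8278 - 23.3637 H_1 + 0.6636 H_2 - 24.9085 H_3}
#' \deqn{qa^* = -13.0326 + 24.3295 H_1 + 34.7418 H_2 + 22.0398 H_3}
#' \deqn{qb^* = 28.5284 - 34.0210 H_1 - 5.4716 H_2 + 0.7791 H_3}
#' with hidden activations
#' \deqn{H_1 = \tanh[0.5 (-1.0617 + 0.0311\,\mathrm{SRS} + 0.6420\,\mathrm{LbA})]}
#' \deqn{H_2 = \tanh[0.5 (1.4045 - 0.5334\,\mathrm{SRS} - 0.0241\,\mathrm{LbA})]}
#' \deqn{H_3 = \tanh[0.5 (-0.1777 + 0.3507\,\mathrm{SRS} + 0.9401\,\mathrm{LbA})]}
#' Inputs are raw SR-S / Lb-A values (no internal standardization).
#'
#' @return A `"tanh_network"` object with `hidden_count = 3`.
#' @examples
#' net <- published_cmq_network()
#' predict(net, data.frame(srs = 9.7, lba = 7.5)) # the darkest quasi-color
#' @export
published_cmq_network <- function() {
  tanh_network(
    hidden_weights = matrix(c(
       0.0311,  0.6420,
      -0.5334, -0.0241,
       0.3507,  0.9401), nrow = 3, byrow = TRUE),
    hidden_biases = c(-1.0617, 1.4045, -0.1777),
    output_weights = matrix(c(
      -23.3637,   0.6636, -24.9085,
       24.3295,  34.7418,  22.0398,
      -34.0210,  -5.4716,   0.7791), nrow = 3, byrow = TRUE),
    output_biases = c(76.8278, -13.0326, 28.5284),
    scale = 0.5)
}

# Coerce pigment inputs (data frame with srs/lba columns, matrix, or a
# single c(srs, lba) pair) to an n x 2 matrix.
as_pigment_matrix <- function(newdata) {
  if (is.data.frame(newdata)) {
    if (!all(c("srs", "lba") %in% names(newdata))) {
      stop("'newdata' must contain columns 'srs' and 'lba'")
    }
    m <- cbind(newdata$srs, newdata$lba)
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) != 2) stop("pigment matrix must have 2 columns (srs, lba)")
    m <- newdata
  } else if (is.numeric(newdata) && length(newdata) == 2) {
    m <- matrix(newdata, nrow = 1)
  } else {
    stop("'newdata' must be a data frame with srs/lba columns, an n x 2 matrix, or a (srs, lba) pair")
  }
  m <- matrix(as.numeric(m), nrow = nrow(m))
  if (any(!is.finite(m))) stop("pigment inputs must be finite")
  m
}

#' Hidden-layer activations of a tanh network
#'
#' Evaluates `tanh(scale * (bias + W %*% (srs, lba)))` for each hidden unit.
#' All activations lie strictly inside (-1, 1).
#'
#' @param net A `"tanh_network"`.
#' @param newdata Pigment inputs: data frame with `srs`/`lba` columns, an
#'   n x 2 matrix, or a single `c(srs, lba)` pair.
#' @return An `n x hidden_count` matrix of activations.
#' @export
hidden_activations <- function(net, newdata) {
  stopifnot(inherits(net, "tanh_network"))
  X <- as_pigment_matrix(newdata)
  Z <- sweep(X %*% t(net$hidden_weights), 2, net$hidden_biases, "+")
  tanh(net$scale * Z)
}

#' Predict CMQ coordinates from pigment levels
#'
#' Forward evaluation of the network at the given SR-S / Lb-A inputs. Inputs
#' outside the calibrated range (SR-S in [0, 9.7], Lb-A in [0, 8.0]) are
#' allowed with a warning — the quasi-color surface is defined everywhere,
#' but only the calibrated region is supported by data.
#'
#' @param object A `"tanh_network"`.
#' @param newdata Pigment inputs: data frame with `srs`/`lba` columns, an
#'   n x 2 matrix, or a single `c(srs, lba)` pair.
#' @param check_range Warn on out-of-calibration inputs (default `TRUE`).
#' @param ... Unused.
#' @return A data frame with columns `qL`, `qa`, `qb`, chroma `qC`, and hue
#'   on both scales (`qh` in degrees [0, 360), `qh_wrapped` in (-180, 180]).
#' @examples
#' predict(published_cmq_network(), data.frame(srs = 5.4, lba = 3.9))
#' @export
predict.tanh_network <- function(object, newdata, check_range = TRUE, ...) {
  X <- as_pigment_matrix(newdata)
  if (check_range) warn_if_extrapolating(X[, 1], X[, 2])
  H <- hidden_activations(object, X)
  out <- sweep(H %*% t(object$output_weights), 2, object$output_biases, "+")
  cmq_frame(out)
}

#' Attainable output intervals of a tanh network
#'
#' Because every hidden activation is bounded by |tanh| <= 1, each response
#' is confined to bias +/- sum(|output weights|) regardless of the inputs.
#'
#' @param net A `"tanh_network"`.
#' @return A 3 x 2 matrix (rows qL, qa, qb; columns min, max).
#' @export
output_bounds <- function(net) {
  stopifnot(inherits(net, "tanh_network"))
  span <- rowSums(abs(net$output_weights))
  cbind(min = net$output_biases - span, max = net$output_biases + span)
}

#' @export
print.tanh_network <- function(x, digits = 4, ...) {
  resp <- c("qL*", "qa*", "qb*")
  cat(sprintf("Tanh quasi-color network: 2 inputs (SR-S, Lb-A) -> %d hidden -> 3 responses\n",
              x$hidden_count))
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  for (k in 1:3) {
    terms <- paste(sprintf("%s * H%d", fmt(x$output_weights[k, ]), seq_len(x$hidden_count)),
                   collapse = " + ")
    cat(sprintf("  %s = %s + %s\n", resp[k], fmt(x$output_biases[k]), terms))
  }
  for (j in seq_len(x$hidden_count)) {
    cat(sprintf("  H%d  = tanh[%s * (%s + %s * SR-S + %s * Lb-A)]\n",
                j, fmt(x$scale), fmt(x$hidden_biases[j]),
                fmt(x$hidden_weights[j, 1]), fmt(x$hidden_weights[j, 2])))
  }
  invisible(x)
}

#' @export
coef.tanh_network <- function(object, ...) {
  list(hidden_weights = object$hidden_weights,
       hidden_biases  = object$hidden_biases,
       output_weights = object$output_weights,
       output_biases  = object$output_biases,
       scale          = object$scale)
}

#' Read and write tanh networks as plain-text JSON
#'
#' Networks serialize to a small JSON object whose fields match the
#' coefficient layout of the printed equations (hidden weights on
#' (SR-S, Lb-A) per unit, hidden biases, output weights per response,
#' output biases, pre-activation scale). The published model ships with the
#' package: `system.file("extdata", "published_cmq_network.json",
#' package = "leafcmq")`.
#'
#' @param net A `"tanh_network"`.
#' @param path File path.
#' @return `read_cmq_network()` returns a `"tanh_network"`;
#'   `write_cmq_network()` returns `path` invisibly.
#' @export
write_cmq_network <- function(net, path) {
  stopifnot(inherits(net, "tanh_network"))
  obj <- list(
    family = "tanh_network",
    hidden_count = net$hidden_count,
    scale = net$scale,
    hidden_weights = net$hidden_weights,
    hidden_biases = net$hidden_biases,
    output_weights = net$output_weights,
    output_biases = net$output_biases,
    responses = c("qL", "qa", "qb"),
    inputs = c("srs", "lba"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cmq_network
#' @export
read_cmq_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$family, "tanh_network")) {
    stop("not a tanh_network file: ", path)
  }
  tanh_network(
    hidden_weights = matrix(unlist(obj$hidden_weights), ncol = 2),
    hidden_biases = obj$hidden_biases,
    output_weights = matrix(unlist(obj$output_weights), ncol = obj$hidden_count),
    output_biases = obj$output_biases,
    scale = obj$scale)
}
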