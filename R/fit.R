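# Fitting tanh quasi-color networks and selecting the hidden-layer size.
#
# The loss is penalized squared error summed over the three responses, with
# each response standardized to unit variance during fitting (so qL, whose
# spread is several times that of qa, does not dominate) and the fitted
# coefficients back-transformed to the raw scale afterwards. Optimization is
# quasi-Newton (BFGS) with an analytic gradient and multiple seeded random
# restarts; tanh networks have permutation/sign symmetric optima and local
# minima, so restarts matter more than optimizer sophistication here.

# --- internal: parameter vector layout --------------------------------------
# [ hidden_weights (h x 2, column-major) | hidden_biases (h) |
#   output_weights (3 x h, column-major) | output_biases (3) ]
n_network_params <- function(h) 6 * h + 3

unpack_params <- function(p, h) {
  list(W  = matrix(p[seq_len(2 * h)], h, 2),
       bh = p[2 * h + seq_len(h)],
       Wo = matrix(p[3 * h + seq_len(3 * h)], 3, h),
       bo = p[6 * h + 1:3])
}

# Loss and gradient on standardized responses. X: n x 2, Ys: n x 3.
network_loss <- function(p, h, X, Ys, lambda, s) {
  q <- unpack_params(p, h)
  n <- nrow(X)
  H <- tanh(s * sweep(X %*% t(q$W), 2, q$bh, "+"))
  R <- sweep(H %*% t(q$Wo), 2, q$bo, "+") - Ys
  sum(R^2) / n + lambda * (sum(q$W^2) + sum(q$Wo^2))
}

network_grad <- function(p, h, X, Ys, lambda, s) {
  q <- unpack_params(p, h)
  n <- nrow(X)
  H <- tanh(s * sweep(X %*% t(q$W), 2, q$bh, "+"))
  R <- sweep(H %*% t(q$Wo), 2, q$bo, "+") - Ys
  dWo <- 2 * crossprod(R, H) / n + 2 * lambda * q$Wo
  dbo <- 2 * colSums(R) / n
  dH  <- (R %*% q$Wo) * (1 - H^2) * s
  dW  <- 2 * crossprod(dH, X) / n + 2 * lambda * q$W
  dbh <- 2 * colSums(dH) / n
  c(dW, dbh, dWo, dbo)
}

as_training_frame <- function(data) {
  req <- c("srs", "lba", "qL", "qa", "qb")
  if (!all(req %in% names(data))) {
    stop("training data must contain columns ", paste(req, collapse = ", "))
  }
  d <- as.data.frame(data)[, req]
  if (nrow(d) == 0) stop("training data must be nonempty")
  if (any(!complete.cases(d)) || any(!is.finite(as.matrix(d)))) {
    stop("training data contain missing or non-finite values")
  }
  if (any(d$qL < 0 | d$qL > 100)) stop("observed qL must lie in [0, 100]")
  d
}

#' Fit a tanh quasi-color network
#'
#' Fits a 2-`hidden`-3 tanh network mapping pigment levels (SR-S, Lb-A) to
#' the CMQ coordinates (qL, qa, qb) by penalized least squares. The three
#' responses are standardized to unit variance during optimization and the
#' coefficients are back-transformed, so the returned network predicts on
#' the raw CIELab scale. The best of `restarts` seeded random
#' initializations is returned; the whole fit is deterministic given `seed`.
#'
#' @param data Data frame with columns `srs`, `lba`, `qL`, `qa`, `qb`.
#' @param hidden Number of hidden tanh units.
#' @param penalty Ridge penalty on hidden and output weights (not biases),
#'   or `"auto"` to choose from `c(0, 1e-4, 1e-3, 1e-2, 1e-1)` by validation
#'   likelihood on an internal 80/20 split.
#' @param restarts Number of random initializations (>= 1).
#' @param maxit Maximum BFGS iterations per restart.
#' @param tol Relative convergence tolerance on the loss.
#' @param seed Integer master seed; all restarts and the internal penalty
#'   split derive from it.
#' @return An object of classes `"cmq_fit"` and `"tanh_network"`: a network
#'   usable with [predict.tanh_network()] plus fitting metadata (`fitted`,
#'   `residuals`, `loss`, `penalty`, `convergence`, the training data and
#'   the call).
#' @examples
#' d <- simulate_leaf_data(120, seed = 1)
#' fit <- fit_cmq_network(d, hidden = 2, restarts = 3, seed = 1)
#' summary(fit)
#' @export
fit_cmq_network <- function(data, hidden = 3, penalty = 1e-4, restarts = 10,
                            maxit = 500, tol = 1e-8, seed = 1) {
  d <- as_training_frame(data)
  h <- as.integer(hidden)
  stopifnot(h >= 1, restarts >= 1, maxit >= 1, tol > 0)
  npar <- n_network_params(h)
  if (nrow(d) <= npar) {
    stop(sprintf(
      "under-determined fit: %d samples for %d free parameters (hidden = %d); need more samples or fewer hidden units",
      nrow(d), npar, h))
  }

  if (identical(penalty, "auto")) {
    penalty <- choose_penalty(d, h, restarts, maxit, tol, seed)
  }
  stopifnot(is.numeric(penalty), penalty >= 0)

  X <- as.matrix(d[, c("srs", "lba")])
  Y <- as.matrix(d[, c("qL", "qa", "qb")])
  ym <- colMeans(Y)
  ys <- apply(Y, 2, sd)
  ys[ys == 0] <- 1 # constant response: leave unscaled
  Ys <- sweep(sweep(Y, 2, ym), 2, ys, "/")
  s <- 0.5

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + 1000L * r)
    p0 <- c(rnorm(3 * h, 0, 0.5), rnorm(3 * h, 0, 0.5), numeric(3))
    opt <- optim(p0, network_loss, network_grad, method = "BFGS",
                 h = h, X = X, Ys = Ys, lambda = penalty, s = s,
                 control = list(maxit = maxit, reltol = tol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$convergence != 0 && best$convergence != 1) {
    warning("optimizer reported convergence code ", best$convergence,
            if (!is.null(best$message)) paste0(": ", best$message) else "")
  }

  q <- unpack_params(best$par, h)
  # back-transform outputs from standardized to raw response scale
  net <- tanh_network(hidden_weights = q$W, hidden_biases = q$bh,
                      output_weights = q$Wo * ys, output_biases = q$bo * ys + ym,
                      scale = s)
  H <- hidden_activations(net, X)
  fitted <- sweep(H %*% t(net$output_weights), 2, net$output_biases, "+")
  colnames(fitted) <- c("qL", "qa", "qb")
  net$fitted <- as.data.frame(fitted)
  net$residuals <- d[, c("qL", "qa", "qb")] - net$fitted
  net$loss <- best$value
  net$penalty <- penalty
  net$convergence <- best$convergence
  net$data <- d
  net$seed <- seed
  net$call <- match.call()
  class(net) <- c("cmq_fit", "tanh_network")
  net
}

# Internal 80/20 split choice of the ridge penalty by validation NLL.
choose_penalty <- function(d, h, restarts, maxit, tol, seed,
                           grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1)) {
  set.seed(seed + 77L)
  n <- nrow(d)
  idx <- sample.int(n)
  ntr <- floor(0.8 * n)
  tr <- d[idx[seq_len(ntr)], ]
  va <- d[idx[(ntr + 1):n], ]
  nlls <- vapply(grid, function(lam) {
    f <- fit_cmq_network(tr, hidden = h, penalty = lam,
                         restarts = max(1L, restarts %/% 2L),
                         maxit = maxit, tol = tol, seed = seed + 31L)
    cmq_nll(f, va)
  }, numeric(1))
  grid[which.min(nlls)]
}

#' Summed Gaussian negative log-likelihood of a network on a dataset
#'
#' For each response the residual variance is estimated by the mean squared
#' residual on the same data (plug-in Gaussian likelihood, with a floor of
#' `var_floor` to keep perfect fits finite); the three per-response negative
#' log-likelihoods are summed. This is the statistic minimized during
#' hidden-node selection.
#'
#' @param net A `"tanh_network"`.
#' @param data Data frame with columns `srs`, `lba`, `qL`, `qa`, `qb`.
#' @param var_floor Lower bound on the plug-in residual variance.
#' @return The summed negative log-likelihood (smaller is better).
#' @export
cmq_nll <- function(net, data, var_floor = 1e-8) {
  d <- as_training_frame(data)
  n <- nrow(d)
  pred <- predict(net, d[, c("srs", "lba")], check_range = FALSE)
  R <- as.matrix(d[, c("qL", "qa", "qb")]) - as.matrix(pred[, c("qL", "qa", "qb")])
  sig2 <- pmax(colMeans(R^2), var_floor)
  sum(n / 2 * log(2 * pi * sig2) + colSums(R^2) / (2 * sig2))
}

#' Select the hidden-layer size by repeated cross-validation
#'
#' For each repeat the data are split at random into a 9:1
#' training:validation pair (mirroring a K = 10 fold size); a network is
#' fitted per candidate hidden-node count on the training part and its
#' summed negative log-likelihood ([cmq_nll()]) evaluated on the validation
#' part. Validation NLLs are averaged over repeats, and the selected count
#' is the smallest one whose mean NLL lies within one standard error of the
#' minimum (a parsimony tie-break; the SE is that of the minimizing count's
#' mean across repeats). `method = "kfold"` instead rotates through all K
#' folds per repeat and averages the K validation NLLs.
#'
#' @param data Data frame with columns `srs`, `lba`, `qL`, `qa`, `qb`.
#' @param nodes Candidate hidden-node counts.
#' @param k Fold count: validation size is `n/k` per split.
#' @param repeats Number of repeated splits.
#' @param method `"split"` (one random 9:1 split per repeat, default) or
#'   `"kfold"` (full rotation per repeat).
#' @param penalty,restarts,maxit,tol Passed to [fit_cmq_network()].
#' @param var_floor Residual-variance floor passed to [cmq_nll()]; raise it
#'   to the measurement resolution when comparing near-perfect fits, so that
#'   models below the floor tie and parsimony decides.
#' @param seed Integer master seed; split r and node j use seeds derived
#'   from it.
#' @return An object of class `"cmq_cv"`: data frame `results`
#'   (node, repeat, validation NLL), `mean_nll` and `se_nll` per node,
#'   and `selected`.
#' @examples
#' \donttest{
#' d <- simulate_leaf_data(200, seed = 1)
#' cv <- select_hidden_nodes(d, nodes = 1:4, repeats = 3, restarts = 2, seed = 1)
#' cv$selected
#' }
#' @export
select_hidden_nodes <- function(data, nodes = 1:25, k = 10, repeats = 20,
                                method = c("split", "kfold"),
                                penalty = 1e-4, restarts = 3,
                                maxit = 400, tol = 1e-8, seed = 1,
                                var_floor = 1e-8) {
  d <- as_training_frame(data)
  method <- match.arg(method)
  n <- nrow(d)
  if (n < k) stop("fewer samples than folds")
  nodes <- sort(unique(as.integer(nodes)))

  rows <- vector("list", repeats * length(nodes))
  ri <- 0L
  for (r in seq_len(repeats)) {
    set.seed(seed * 1009L + r)
    fold_of <- sample(rep_len(seq_len(k), n)) # balanced random fold per row
    val_folds <- if (method == "split") 1L else seq_len(k)
    for (j in seq_along(nodes)) {
      nll_vals <- vapply(val_folds, function(f) {
        va <- which(fold_of == f)
        fit <- fit_cmq_network(d[-va, ], hidden = nodes[j], penalty = penalty,
                               restarts = restarts, maxit = maxit, tol = tol,
                               seed = seed * 211L + r * 37L + nodes[j] * 7L + f)
        cmq_nll(fit, d[va, ], var_floor = var_floor)
      }, numeric(1))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(nodes = nodes[j], rep = r,
                               validation_nll = mean(nll_vals))
    }
  }
  results <- do.call(rbind, rows)
  mean_nll <- tapply(results$validation_nll, results$nodes, mean)
  se_nll <- tapply(results$validation_nll, results$nodes, sd) / sqrt(repeats)
  se_nll[is.na(se_nll)] <- 0 # single repeat: no spread estimate
  best <- which.min(mean_nll)
  threshold <- mean_nll[best] + se_nll[best]
  selected <- nodes[min(which(mean_nll <= threshold))]
  structure(list(results = results,
                 nodes = nodes,
                 mean_nll = as.numeric(mean_nll),
                 se_nll = as.numeric(se_nll),
                 selected = selected,
                 k = k, repeats = repeats, method = method, seed = seed),
            class = "cmq_cv")
}

#' @export
print.cmq_cv <- function(x, ...) {
  cat(sprintf("Hidden-node selection: %d repeats of %s validation (k = %d)\n",
              x$repeats, if (x$method == "split") "a single 9:1 split" else "full k-fold rotation",
              x$k))
  tab <- data.frame(nodes = x$nodes,
                    mean_validation_nll = round(x$mean_nll, 2),
                    se = round(x$se_nll, 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Selected hidden nodes (one-SE rule): %d\n", x$selected))
  invisible(x)
}

# --- methods for fitted networks --------------------------------------------

#' @export
print.cmq_fit <- function(x, ...) {
  cat("Fitted quasi-color network\n")
  cat(sprintf("  n = %d samples, penalty = %g, final loss = %.6g\n",
              nrow(x$data), x$penalty, x$loss))
  NextMethod()
}

#' @export
summary.cmq_fit <- function(object, ...) {
  obs <- object$data[, c("qL", "qa", "qb")]
  prd <- object$fitted
  tab <- data.frame(
    coordinate = c("qL", "qa", "qb"),
    r_squared = vapply(1:3, function(k) r_squared(obs[[k]], prd[[k]]), numeric(1)),
    rmse = vapply(1:3, function(k) rmse(obs[[k]], prd[[k]]), numeric(1)))
  out <- list(call = object$call, n = nrow(object$data),
              hidden = object$hidden_count, penalty = object$penalty,
              training = tab)
  class(out) <- "summary.cmq_fit"
  out
}

#' @export
print.summary.cmq_fit <- function(x, ...) {
  cat("Fitted quasi-color network\n")
  cat(sprintf("  hidden nodes: %d, penalty: %g, n: %d\n", x$hidden, x$penalty, x$n))
  cat("Training fit per coordinate:\n")
  tab <- x$training
  tab$r_squared <- round(tab$r_squared, 4)
  tab$rmse <- round(tab$rmse, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
residuals.cmq_fit <- function(object, ...) object$residuals

#' @export
fitted.cmq_fit <- function(object, ...) object$fitted

#' Observed-versus-predicted plot of a fitted network
#'
#' One panel per CMQ coordinate with the identity line.
#'
#' @param x A `"cmq_fit"`.
#' @param ... Passed to [plot.default()].
#' @export
plot.cmq_fit <- function(x, ...) {
  obs <- x$data[, c("qL", "qa", "qb")]
  prd <- x$fitted
  labs <- c("qL*", "qa*", "qb*")
  old <- par(mfrow = c(1, 3))
  on.exit(par(old))
  for (k in 1:3) {
    plot.default(obs[[k]], prd[[k]], xlab = paste("observed", labs[k]),
                 ylab = paste("predicted", labs[k]), ...)
    abline(0, 1, col = "grey40")
  }
  invisible(x)
}
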