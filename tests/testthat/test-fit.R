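# Network fitting, the likelihood statistic, hidden-node selection, and the
# polynomial baselines.

test_that("fitting recovers the generating prediction surface", {
  # noiseless samples from the published network on a 20 x 20 grid; the
  # generating network itself is the oracle for the fitted surface
  net <- published_cmq_network()
  grid <- expand.grid(srs = seq(0, 9.7, length.out = 20),
                      lba = seq(0, 8, length.out = 20))
  truth <- predict(net, grid, check_range = FALSE)
  d <- cbind(grid, truth[, c("qL", "qa", "qb")])
  fit <- fit_cmq_network(d, hidden = 3, penalty = 0, restarts = 5, seed = 2)
  pred <- predict(fit, grid, check_range = FALSE)
  for (k in c("qL", "qa", "qb")) {
    expect_lt(max(abs(pred[[k]] - truth[[k]])), 0.5)
  }
})

test_that("fits are deterministic given the seed and refuse too few samples", {
  d <- simulate_leaf_data(60, seed = 4)
  f1 <- fit_cmq_network(d, hidden = 2, restarts = 2, seed = 9)
  f2 <- fit_cmq_network(d, hidden = 2, restarts = 2, seed = 9)
  expect_identical(coef(f1), coef(f2))
  # 5 samples cannot determine the 21 parameters of a 3-node network
  expect_error(fit_cmq_network(d[1:5, ], hidden = 3), "under-determined")
})

test_that("an equivalent single-hidden-layer fit from nnet agrees on fit quality", {
  skip_if_not_installed("nnet")
  # independent route: nnet's logistic-hidden/linear-output family spans the
  # same functions as a tanh hidden layer up to reparametrization, so both
  # routes should reach comparable training RMSE on the same data
  d <- simulate_leaf_data(250, seed = 21)
  fit <- fit_cmq_network(d, hidden = 3, restarts = 5, seed = 21)
  Y <- as.matrix(d[, c("qL", "qa", "qb")])
  Ys <- scale(Y)
  set.seed(21)
  nn <- nnet::nnet(as.matrix(d[, c("srs", "lba")]), Ys, size = 3,
                   linout = TRUE, decay = 1e-4, maxit = 500, trace = FALSE)
  rmse_nnet <- sqrt(colMeans((nn$fitted.values %*% diag(attr(Ys, "scaled:scale")) +
                              rep(1, nrow(Y)) %o% attr(Ys, "scaled:center") - Y)^2))
  rmse_ours <- sqrt(colMeans(as.matrix(residuals(fit))^2))
  expect_equal(rmse_ours, rmse_nnet, tolerance = 0.15)
})

test_that("the likelihood statistic matches its closed form", {
  net <- published_cmq_network()
  d <- simulate_leaf_data(40, seed = 8, noise_sd = c(0, 0, 0))
  n <- nrow(d)
  # perfect predictions: every response sits at the variance floor
  expect_equal(cmq_nll(net, d, var_floor = 1e-8),
               3 * n / 2 * log(2 * pi * 1e-8))
  # independent hand computation of the plug-in Gaussian form
  d2 <- simulate_leaf_data(40, seed = 8)
  pred <- predict(net, d2[, c("srs", "lba")], check_range = FALSE)
  expected <- 0
  for (k in c("qL", "qa", "qb")) {
    r <- d2[[k]] - pred[[k]]
    s2 <- mean(r^2)
    expected <- expected + sum(-log(stats::dnorm(r, 0, sqrt(s2))))
  }
  expect_equal(cmq_nll(net, d2), expected)
  # doubling the residuals increases the statistic
  d3 <- d2
  for (k in c("qL", "qa", "qb")) d3[[k]] <- pred[[k]] + 2 * (d2[[k]] - pred[[k]])
  expect_gt(cmq_nll(net, d3), cmq_nll(net, d2))
  expect_error(cmq_nll(net, d2[0, ]), "nonempty")
})

test_that("node selection is reproducible and parsimonious on linear data", {
  # linear responses along one pigment index plus unit observation noise:
  # one hidden unit captures the whole signal, so extra nodes buy nothing
  # and the one-SE rule must return the smallest candidate
  grid <- expand.grid(srs = seq(0, 9, length.out = 10),
                      lba = seq(0, 8, length.out = 10))
  idx <- 2 * grid$srs + grid$lba
  set.seed(105)
  d <- cbind(grid, qL = 60 - idx + rnorm(100),
             qa = 1 + 0.5 * idx + rnorm(100),
             qb = 3 + 0.2 * idx + rnorm(100))
  cv <- select_hidden_nodes(d, nodes = 1:3, repeats = 5, restarts = 3, seed = 5)
  expect_equal(cv$selected, 1L)
  # determinism of the full CV result under a fixed seed
  d2 <- simulate_leaf_data(80, seed = 6)
  cv1 <- select_hidden_nodes(d2, nodes = 1:2, repeats = 1, restarts = 2, seed = 3)
  cv2 <- select_hidden_nodes(d2, nodes = 1:2, repeats = 1, restarts = 2, seed = 3)
  expect_identical(cv1$results, cv2$results)
  expect_identical(cv1$selected, cv2$selected)
  # selection is invariant to sample order given fixed seeds
  cv3 <- select_hidden_nodes(d2[sample.int(nrow(d2)), ], nodes = 1:2,
                             repeats = 1, restarts = 2, seed = 3)
  expect_identical(cv3$selected, cv1$selected)
  expect_error(select_hidden_nodes(d2[1:5, ], k = 10), "fewer samples")
})

test_that("full k-fold rotation averages over every fold", {
  d <- simulate_leaf_data(60, seed = 19)
  cv <- select_hidden_nodes(d, nodes = 1, k = 5, repeats = 1, restarts = 1,
                            maxit = 150, method = "kfold", seed = 2)
  expect_equal(nrow(cv$results), 1)
  expect_true(is.finite(cv$mean_nll))
  expect_identical(cv$selected, 1L)
  # a second identical call reproduces the rotation exactly
  cv2 <- select_hidden_nodes(d, nodes = 1, k = 5, repeats = 1, restarts = 1,
                             maxit = 150, method = "kfold", seed = 2)
  expect_identical(cv$results, cv2$results)
})

test_that("polynomial baselines recover generating coefficients exactly", {
  set.seed(13)
  grid <- data.frame(srs = runif(60, 0, 6), lba = runif(60, 0, 6))
  # full factorial: y = 1 + 2 S + 3 A + 1.5 S A (kept inside the qL range)
  d <- cbind(grid, qL = 1 + 2 * grid$srs + 3 * grid$lba + 1.5 * grid$srs * grid$lba)
  d$qa <- d$qL; d$qb <- d$qL
  ff <- fit_cmq_parametric(d, "full_factorial")
  expect_equal(unname(coef(ff)$qL), c(1, 2, 3, 1.5), tolerance = 1e-8)
  # response surface: full quadratic
  d2 <- cbind(grid,
              qL = 40 + 1 * grid$srs - 2 * grid$lba + 0.5 * grid$srs * grid$lba +
                   0.3 * grid$srs^2 - 0.4 * grid$lba^2)
  d2$qa <- d2$qL; d2$qb <- d2$qL
  rs <- fit_cmq_parametric(d2, "response_surface")
  co <- coef(rs)$qL
  expect_equal(unname(co[c("(Intercept)", "srs", "lba", "srs:lba",
                           "I(srs^2)", "I(lba^2)")]),
               c(40, 1, -2, 0.5, 0.3, -0.4), tolerance = 1e-8)
  # constant response: intercept only
  d3 <- cbind(grid, qL = rep(7, 60), qa = rep(7, 60), qb = rep(7, 60))
  qp <- fit_cmq_parametric(d3, "quadratic_polynomial")
  expect_equal(unname(coef(qp)$qL), c(7, 0, 0, 0, 0), tolerance = 1e-10)
})

test_that("parametric prediction equals term-by-term evaluation", {
  d <- simulate_leaf_data(50, seed = 14)
  rs <- fit_cmq_parametric(d, "response_surface")
  newd <- data.frame(srs = c(2.5, 7.1), lba = c(1.2, 6.3))
  pred <- predict(rs, newd)
  co <- coef(rs)
  for (k in c("qL", "qa", "qb")) {
    manual <- co[[k]]["(Intercept)"] + co[[k]]["srs"] * newd$srs +
      co[[k]]["lba"] * newd$lba + co[[k]]["srs:lba"] * newd$srs * newd$lba +
      co[[k]]["I(srs^2)"] * newd$srs^2 + co[[k]]["I(lba^2)"] * newd$lba^2
    expect_equal(pred[[k]], unname(manual), tolerance = 1e-12)
  }
})

test_that("nested families obey the training-error ordering", {
  d <- simulate_leaf_data(150, seed = 15)
  sse <- function(fit) sum(as.matrix(residuals(fit))^2)
  ff <- fit_cmq_parametric(d, "full_factorial")
  qp <- fit_cmq_parametric(d, "quadratic_polynomial")
  rs <- fit_cmq_parametric(d, "response_surface")
  expect_lte(sse(rs), sse(ff) + 1e-8)
  expect_lte(sse(rs), sse(qp) + 1e-8)
})

test_that("automatic penalty choice returns a grid value and a usable fit", {
  d <- simulate_leaf_data(120, seed = 16)
  fit <- fit_cmq_network(d, hidden = 2, penalty = "auto", restarts = 2, seed = 7)
  expect_true(fit$penalty %in% c(0, 1e-4, 1e-3, 1e-2, 1e-1))
  expect_true(all(is.finite(as.matrix(fit$fitted))))
})
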