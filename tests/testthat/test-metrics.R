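# Agreement metrics, splitting, the comparison harness, and sensitivity.

test_that("R-squared, RMSE and Pearson r match hand computations", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5) # 1 - 1/2
  expect_error(r_squared(rep(1, 3), c(1, 2, 3)), "zero variance")
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1) # constant offset
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.98198, tolerance = 1e-5)
})

test_that("Lin's concordance uses population moments and penalizes shift", {
  expect_equal(lins_concordance(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lins_concordance(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(30); y <- 0.7 * x + rnorm(30, sd = 0.5) + runif(1, -1, 1)
    expect_lte(abs(lins_concordance(x, y)), abs(pearson_r(x, y)) + 1e-12)
  }
  # equality when means and variances match exactly
  x <- rnorm(50)
  y <- rev(x) # same moments, different pairing
  expect_equal(lins_concordance(x, y), pearson_r(x, y), tolerance = 1e-12)
})

test_that("R2, RMSE and total variance satisfy their identity", {
  set.seed(17)
  for (i in 1:10) {
    obs <- rnorm(25, 40, 8); pred <- obs + rnorm(25, 0, 2)
    ss_tot <- sum((obs - mean(obs))^2)
    expect_equal(r_squared(obs, pred),
                 1 - rmse(obs, pred)^2 * length(obs) / ss_tot,
                 tolerance = 1e-12)
  }
})

test_that("train/test splits have the right sizes and are seeded", {
  d <- simulate_leaf_data(604, seed = 2, asymmetry_mean = 0)
  sp <- train_test_split(d, fraction = 0.8, seed = 10)
  expect_equal(nrow(sp$training), 483) # floor(604 * 0.8)
  expect_equal(nrow(sp$testing), 121)
  # exact override mirroring the original 480/124 split
  sp2 <- train_test_split(d, seed = 10, sizes = c(480, 124))
  expect_equal(nrow(sp2$training), 480)
  expect_equal(nrow(sp2$testing), 124)
  sp3 <- train_test_split(d, seed = 10, sizes = c(480, 124))
  expect_identical(sp2$training$sample_id, sp3$training$sample_id)
  # disjoint union of the input
  expect_setequal(c(sp$training$sample_id, sp$testing$sample_id), d$sample_id)
  expect_length(intersect(sp$training$sample_id, sp$testing$sample_id), 0)
  expect_error(train_test_split(d[1, , drop = FALSE]), "at least 2")
})

test_that("the comparison table has the side-by-side layout and ordering", {
  d <- simulate_leaf_data(220, seed = 18)
  sp <- train_test_split(d, seed = 3)
  tab <- model_comparison(sp$training, sp$testing, hidden = 2,
                          restarts = 3, seed = 3)
  expect_setequal(unique(tab$model),
                  c("full_factorial", "quadratic_polynomial",
                    "response_surface", "neural_network"))
  expect_setequal(unique(tab$set), c("training", "testing"))
  expect_setequal(unique(tab$metric), c("r_squared", "rmse"))
  expect_equal(nrow(tab), 4 * 2 * 2)
  # nesting: response surface never beaten on training error by full factorial
  tr_rmse <- function(m) {
    r <- tab[tab$model == m & tab$set == "training" & tab$metric == "rmse", ]
    sum(unlist(r[, c("qL", "qa", "qb")])^2)
  }
  expect_lte(tr_rmse("response_surface"), tr_rmse("full_factorial") + 1e-10)
  expect_lte(tr_rmse("response_surface"), tr_rmse("quadratic_polynomial") + 1e-10)
})

test_that("network beats polynomials on noiseless network-generated data", {
  net <- published_cmq_network()
  grid <- expand.grid(srs = seq(0.5, 9, length.out = 15),
                      lba = seq(0.5, 7.5, length.out = 15))
  d <- cbind(grid, predict(net, grid, check_range = FALSE)[, c("qL", "qa", "qb")])
  sp <- train_test_split(d, seed = 4)
  tab <- model_comparison(sp$training, sp$testing, hidden = 3, penalty = 0,
                          restarts = 5, seed = 4)
  ann <- tab[tab$model == "neural_network" & tab$set == "testing" &
             tab$metric == "rmse", c("qL", "qa", "qb")]
  rs <- tab[tab$model == "response_surface" & tab$set == "testing" &
            tab$metric == "rmse", c("qL", "qa", "qb")]
  expect_true(all(ann < 0.2))      # the surface is in the network family
  expect_true(all(rs > unlist(ann))) # but is not a quadratic polynomial
})

test_that("total-effect sensitivity behaves on analytically known functions", {
  # response depending on one input only
  one_input <- tanh_network(matrix(c(1, 0), 1, 2), hidden_biases = 0,
                            output_weights = matrix(10, 3, 1),
                            output_biases = rep(0, 3), scale = 0.1)
  vi <- variable_importance(one_input, c(0, 8.6), c(0.1, 7.8),
                            n = 4000, seed = 2)
  expect_true(all(vi[, "srs"] > 95))
  expect_true(all(vi[, "lba"] < 2))
  # near-linear additive function: importance ratio tracks slope^2 * range variance
  lin <- tanh_network(matrix(c(2, 1), 1, 2), hidden_biases = 0,
                      output_weights = matrix(1, 3, 1),
                      output_biases = rep(0, 3), scale = 1e-3)
  vi2 <- variable_importance(lin, c(0, 1), c(0, 1), n = 60000, seed = 3)
  # var contributions 4/12 vs 1/12 -> 80% vs 20%
  expect_equal(unname(vi2[1, ]), c(80, 20), tolerance = 0.05)
  # the published model: anthocyanins dominate quasi-lightness
  vi3 <- variable_importance(published_cmq_network(), n = 5000, seed = 4)
  expect_gt(vi3["qL", "lba"], vi3["qL", "srs"])
  expect_error(variable_importance(published_cmq_network(),
                                   srs_range = c(5, 5)), "positive width")
})
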