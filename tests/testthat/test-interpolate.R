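test_that("nearest-neighbour matches an exhaustive scan with index tie-breaking", {
  sites <- make_layout(50, seed = 41)
  targets <- make_layout(40, seed = 42)
  got <- nn_predict(targets, sites, sites$value)
  for (i in seq_len(nrow(targets))) {
    d <- sqrt((sites$x - targets$x[i])^2 + (sites$y - targets$y[i])^2)
    expect_identical(got$prediction[i], sites$value[which.min(d)])
  }
  # coincident target returns the site's own value; single site serves all
  one <- data.frame(x = 5, y = 5)
  expect_equal(nn_predict(sites[3, ], sites, sites$value)$prediction,
               sites$value[3])
  expect_equal(nn_predict(targets, one, 9.9)$prediction, rep(9.9, 40))
  expect_error(nn_predict(targets, sites[0, ], numeric(0)))
})

test_that("IDW weights follow d^-idp with exact behaviour at coincident points", {
  sites <- data.frame(x = c(-1, 1), y = c(0, 0))
  # equidistant neighbours average regardless of power
  for (idp in c(0.5, 1, 2.2)) {
    expect_equal(idw_predict(data.frame(x = 0, y = 0), sites, c(2, 4),
                             nmax = 2, idp = idp)$prediction, 3)
  }
  # hand computation: d = {1, 2}, values {0, 3}, idp 1 -> weights {2/3, 1/3}
  s2 <- data.frame(x = c(0, 0), y = c(1, 2))
  expect_equal(idw_predict(data.frame(x = 0, y = 0), s2, c(0, 3),
                           nmax = 2, idp = 1)$prediction, 1)
  # idp = 0 is the unweighted neighbour mean
  expect_equal(idw_predict(data.frame(x = 0, y = 0), s2, c(0, 3),
                           nmax = 2, idp = 0)$prediction, 1.5)
  # coincident with a site
  expect_equal(idw_predict(s2[1, ], s2, c(7, 3), nmax = 2,
                           idp = 2)$prediction, 7)
})

test_that("IDW with nmax = 1 reproduces NN, and converges to NN as idp grows", {
  sites <- make_layout(60, seed = 43)
  targets <- make_layout(50, seed = 44)
  nn <- nn_predict(targets, sites, sites$value)$prediction
  idw1 <- idw_predict(targets, sites, sites$value, nmax = 1,
                      idp = 2)$prediction
  expect_identical(idw1, nn)
  idw_hi <- idw_predict(targets, sites, sites$value, nmax = 10,
                        idp = 50)$prediction
  # the NN limit holds where the nearest site is well separated from the
  # runner-up; near-equidistant pairs converge only as idp -> infinity
  sep <- vapply(seq_len(nrow(targets)), function(i) {
    d <- sort(sqrt((sites$x - targets$x[i])^2 + (sites$y - targets$y[i])^2))
    d[2] / d[1]
  }, numeric(1))
  expect_gt(sum(sep > 1.2), 25)  # the comparison is not vacuous
  expect_equal(idw_hi[sep > 1.2], nn[sep > 1.2], tolerance = 1e-3)
})

test_that("predictions of NN/IDW stay within the neighbour value range", {
  sites <- make_layout(40, seed = 45)
  targets <- make_layout(30, seed = 46)
  preds <- list(nn_predict(targets, sites, sites$value),
                idw_predict(targets, sites, sites$value, nmax = 8,
                            idp = 1.3))
  for (p in preds) {
    expect_true(all(p$prediction >= min(sites$value) - 1e-12))
    expect_true(all(p$prediction <= max(sites$value) + 1e-12))
  }
})

test_that("zero-nugget kriging interpolates exactly with zero variance at data sites", {
  sites <- make_layout(30, seed = 47)
  model <- variogram_model(0, 4, 3e4, kappa = 0.5)
  at_sites <- ok_predict(sites, sites, sites$value, model,
                         nmax = 20, nmin = 2)
  expect_equal(at_sites$prediction, sites$value, tolerance = 1e-8)
  expect_true(all(abs(at_sites$variance) < 1e-8 * 4))
})

test_that("local kriging with nmax >= n matches a dense global oracle", {
  sites <- make_layout(30, seed = 48)
  targets <- make_layout(25, seed = 49)
  model <- variogram_model(0.5, 2, 4e4, kappa = 0.5)
  gamma_fun <- function(h) exp_gamma(h, 0.5, 2, 4e4)
  oracle <- global_ok_oracle(targets$x, targets$y, sites$x, sites$y,
                             sites$value, gamma_fun)
  got <- ok_predict(targets, sites, sites$value, model, nmax = 30, nmin = 2)
  expect_equal(got$prediction, unname(oracle[, "pred"]), tolerance = 1e-8)
  expect_equal(got$variance, unname(oracle[, "var"]), tolerance = 1e-8)
})

test_that("pure-nugget kriging gives equal weights and variance c(1 + 1/n)", {
  sites <- make_layout(12, seed = 50)
  c0 <- 3.7
  model <- variogram_model(c0, 0, 1e4)
  far <- data.frame(x = 1e6, y = 1e6)  # distinct from every site
  got <- ok_predict(far, sites, sites$value, model, nmax = 12, nmin = 2)
  expect_equal(got$prediction, mean(sites$value), tolerance = 1e-10)
  expect_equal(got$variance, c0 * (1 + 1 / 12), tolerance = 1e-10)
})

test_that("kriging weights sum to one and variance grows with distance from data", {
  sites <- data.frame(x = seq(0, 9000, by = 1000), y = rep(0, 10))
  sites$value <- rnorm(10)
  model <- variogram_model(0.1, 1, 5e3, kappa = 0.5)
  targets <- data.frame(x = seq(10000, 60000, by = 5000), y = 0)
  got <- ok_predict(targets, sites, sites$value, model, nmax = 10, nmin = 2)
  expect_true(all(diff(got$variance) > 0))
  # weight-sum identity checked through the exactness of the constant field
  const <- ok_predict(targets, sites, rep(5, 10), model, nmax = 10, nmin = 2)
  expect_equal(const$prediction, rep(5, length(targets$x)),
               tolerance = 1e-8)
})

test_that("nmin gates predictions and duplicate sites are rejected", {
  sites <- make_layout(5, seed = 51)
  model <- variogram_model(0, 1, 1e4)
  res <- ok_predict(data.frame(x = 0, y = 0), sites, sites$value, model,
                    nmax = 20, nmin = 10)
  expect_true(is.na(res$prediction) && is.na(res$variance))
  dup <- rbind(sites, sites[1, ])
  expect_error(ok_predict(data.frame(x = 0, y = 0), dup, dup$value, model),
               "duplicate")
})

test_that("grid interpolation fills rasters and kriging beats NN on a smooth field", {
  # joint GRF at sites AND grid centres, built independently of the package
  # simulator, so the true surface at every cell is known
  set.seed(52)
  g <- grid_spec(xlim = c(0, 1e6), ylim = c(0, 1e6), cell_size = 1e5)
  centres <- build_grid(g)
  n_s <- 200
  sx <- runif(n_s, 0, 1e6); sy <- runif(n_s, 0, 1e6)
  D <- as.matrix(dist(cbind(c(sx, centres$x), c(sy, centres$y))))
  C <- exp(-sqrt(2) * D / 2e5)  # Matern kappa 0.5, psill 1, range 2e5
  z <- as.vector(t(chol(C + diag(1e-8, nrow(C)))) %*% rnorm(nrow(C)))
  s <- data.frame(x = sx, y = sy)
  z_sites <- z[seq_len(n_s)]
  z_grid <- z[-seq_len(n_s)]

  model <- fit_variogram(empirical_variogram(s$x, s$y, z_sites), TRUE)
  f_ok <- interpolate_grid(s, z_sites, list(method = "okzn", model = model,
                                            nmax = 50, nmin = 2), g)
  f_nn <- interpolate_grid(s, z_sites, list(method = "nn"), g)
  expect_equal(dim(f_ok$values), c(g$n_rows, g$n_cols))
  expect_false(is.null(f_ok$variance))
  expect_true(is.null(f_nn$variance))

  # constant field in, constant raster out
  f_const <- interpolate_grid(s, rep(2, n_s), list(method = "nn"), g)
  expect_true(all(f_const$values == 2))

  # grid RMSE against the true surface: kriging under NN
  rmse <- function(f) sqrt(mean((as.vector(t(f$values)) - z_grid)^2))
  expect_lt(rmse(f_ok), rmse(f_nn))

  # variance raster minima lie at cells holding data
  v <- as.vector(t(f_ok$variance))
  near_dist <- vapply(seq_len(nrow(centres)), function(i)
    min(sqrt((s$x - centres$x[i])^2 + (s$y - centres$y[i])^2)), numeric(1))
  near_cells <- near_dist < g$cell_size / 2
  expect_lt(mean(v[near_cells]), mean(v[!near_cells]))
})
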