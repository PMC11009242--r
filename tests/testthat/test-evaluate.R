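test_that("error metrics match their defining formulas on hand-computed cases", {
  perfect <- error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mbe, 0)
  expect_equal(perfect$msa, 0)

  m <- error_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$mbe, 0)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$msa, 0.5)   # exp(median(|ln(Z/Z')|)) - 1 = exp(ln 1.5) - 1

  sym <- error_metrics(c(10, 20), c(20, 10))  # symmetric 2x errors
  expect_equal(sym$msa, 1)

  # zero-variance prediction: r undefined, others still computed
  flat <- error_metrics(c(1, 2, 3, 4), rep(2.5, 4))
  expect_true(is.na(flat$r))
  expect_equal(flat$mae, 1)
})

test_that("metrics agree with a naive one-pass loop oracle to 1e-12", {
  set.seed(61)
  for (rep in 1:5) {
    z <- runif(200, 1, 100)
    zp <- z * exp(rnorm(200, 0, 0.3))
    m <- error_metrics(z, zp)
    n <- length(z)
    sae <- 0; sse <- 0; se <- 0; logs <- numeric(n)
    for (i in seq_len(n)) {
      e <- zp[i] - z[i]
      sae <- sae + abs(e); sse <- sse + e^2; se <- se + e
      logs[i] <- abs(log(z[i] / zp[i]))
    }
    expect_equal(m$mae, sae / n, tolerance = 1e-12)
    expect_equal(m$rmse, sqrt(sse / n), tolerance = 1e-12)
    expect_equal(m$mbe, se / n, tolerance = 1e-12)
    expect_equal(m$msa, exp(median(logs)) - 1, tolerance = 1e-12)
    expect_equal(m$r, cor(z, zp), tolerance = 1e-12)
  }
})

test_that("MSA is invariant under exchanging observed and predicted", {
  set.seed(62)
  z <- runif(50, 1, 10)
  zp <- runif(50, 1, 10)
  expect_equal(error_metrics(z, zp)$msa, error_metrics(zp, z)$msa)
})

test_that("LOOCV on three collinear sites matches a hand trace and never leaks", {
  sites <- data.frame(site_id = c("a", "b", "c"),
                      x = c(0, 1000, 2000), y = 0,
                      region = "R", stringsAsFactors = FALSE)
  vals <- c(1, 5, 9)
  cv <- loocv(sites, vals, list(method = "nn"))
  # a's nearest other site is b; b ties a/c broken by index (a); c's is b
  expect_equal(cv$predicted, c(5, 1, 5))
  m <- summary(cv)
  expect_equal(m$mae, mean(abs(c(5 - 1, 1 - 5, 5 - 9))))

  # leakage: perturbing site i's value never changes its held-out prediction
  vals2 <- vals; vals2[2] <- 100
  cv2 <- loocv(sites, vals2, list(method = "nn"))
  expect_equal(cv2$predicted[2], cv$predicted[2])

  # translation equivariance of residuals
  cv3 <- loocv(sites, vals + 42, list(method = "nn"))
  expect_equal(cv3$predicted - (vals + 42), cv$predicted - vals)
})

test_that("k-fold partitions are seeded, exhaustive, and reduce to LOOCV at k = n", {
  sites <- make_layout(40, seed = 63)
  spec <- list(method = "idw", nmax = 5, idp = 2)
  cv_a <- kfold_cv(sites, sites$value, spec, k = 5, seed = 9)
  cv_b <- kfold_cv(sites, sites$value, spec, k = 5, seed = 9)
  expect_identical(cv_a, cv_b)
  expect_setequal(cv_a$site_id, sites$site_id)
  expect_equal(nrow(cv_a), 40L)

  cv_n <- kfold_cv(sites, sites$value, spec, k = 40, seed = 9)
  cv_loo <- loocv(sites, sites$value, spec)
  expect_equal(sort(cv_n$predicted), sort(cv_loo$predicted))

  # residual multiset identity: pooled per-fold residuals = global residuals
  pooled <- unlist(lapply(split(cv_a, cv_a$fold), function(f)
    f$predicted - f$observed))
  expect_equal(sort(unname(pooled)), sort(cv_a$predicted - cv_a$observed))
})

test_that("kriging LOOCV is no worse than NN on a spatially structured field", {
  truth <- simulate_gaussian_field(variogram_model(0, 1, 2e5, 0.5), 120,
                                   seed = 64)
  s <- truth$sites
  model <- fit_variogram(empirical_variogram(s$x, s$y, s$z), TRUE)
  rmse_nn <- summary(loocv(s, s$z, list(method = "nn")))$rmse
  rmse_ok <- summary(loocv(s, s$z, list(method = "okzn", model = model,
                                        nmax = 40, nmin = 2)))$rmse
  expect_lt(rmse_ok, rmse_nn)
})

test_that("IDW optimization recovers a known power and responds to the objective", {
  # data generated by an IDW surface with idp* = 2, plus small noise
  gen <- make_layout(120, seed = 65, extent = 1e5)
  anchors <- make_layout(15, seed = 66, extent = 1e5)
  surf <- idw_predict(gen, anchors, anchors$value, nmax = 15, idp = 2)
  set.seed(67)
  vals <- surf$prediction + rnorm(120, 0, 0.05)
  opt <- optimize_idw(gen, vals, "rmse", k = 5, seed = 5,
                      nmax_grid = c(5, 10, 15, 20))
  expect_true(abs(opt$idp - 2) <= 0.75)
  expect_true(opt$value <= min(opt$profile$value) + 1e-12)

  # outlier-spiked data: RMSE- and MAE-optimal powers differ
  spiked <- vals
  spiked[1:4] <- spiked[1:4] + 40
  o_rmse <- optimize_idw(gen, spiked, "rmse", k = 5, seed = 5,
                         nmax_grid = c(3, 8, 15))
  o_mae <- optimize_idw(gen, spiked, "mae", k = 5, seed = 5,
                        nmax_grid = c(3, 8, 15))
  expect_false(isTRUE(all.equal(c(o_rmse$nmax, o_rmse$idp),
                                c(o_mae$nmax, o_mae$idp),
                                tolerance = 1e-3)))

  # degenerate single-candidate grid returns that candidate
  single <- optimize_idw(gen, vals, "rmse", k = 5, seed = 5, nmax_grid = 7)
  expect_equal(single$nmax, 7L)
})

test_that("regional metrics equal global metrics computed on each region subset", {
  sites <- make_layout(90, seed = 68)
  cv <- loocv(sites, sites$value, list(method = "idw", nmax = 4, idp = 1))
  reg <- regional_metrics(cv)
  expect_setequal(reg$region, c("A", "B", "C"))
  for (rg in reg$region) {
    sub <- cv[cv$region == rg, ]
    direct <- error_metrics(sub$observed, sub$predicted)
    expect_equal(reg$rmse[reg$region == rg], direct$rmse)
    expect_equal(reg$r[reg$region == rg], direct$r)
    expect_equal(reg$n[reg$region == rg], direct$n)
  }
  # single-region data reproduce the global metrics
  one <- cv; one$region <- "Z"
  r1 <- regional_metrics(one)
  g <- summary(cv)
  expect_equal(r1$mae, g$mae)
})

test_that("method selection counts per-metric wins and reports ties as joint-best", {
  mk <- function(r, rmse, mae, mbe, msa) {
    structure(list(r = r, rmse = rmse, mae = mae, mbe = mbe, msa = msa,
                   n = 100L, n_missing = 0L, n_msa = 100L),
              class = "metric_report")
  }
  dominant <- list(good = mk(0.9, 1, 1, 0.01, 0.1),
                   bad = mk(0.5, 2, 2, 0.5, 0.3))
  expect_equal(select_method(dominant)$best, "good")

  tied <- list(m1 = mk(0.8, 1, 1, 0.1, 0.2), m2 = mk(0.8, 1, 1, 0.1, 0.2))
  expect_equal(select_method(tied)$best, c("m1", "m2"))

  # split winners: hand tally — a wins r+mae, b wins rmse+mbe -> joint-best
  split <- list(a = mk(0.9, 2.0, 1.0, 0.5, 0.2),
                b = mk(0.7, 1.5, 1.5, 0.1, 0.2))
  sel <- select_method(split)
  expect_setequal(sel$best, c("a", "b"))
  expect_equal(sel$winners$r, "a")
  expect_equal(sel$winners$rmse, "b")
  # MBE ranked by magnitude, sign ignored
  mag <- list(a = mk(0.8, 1, 1, -0.05, 0.2), b = mk(0.8, 1, 1, 0.2, 0.2))
  expect_equal(select_method(mag)$winners$mbe, "a")
})
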