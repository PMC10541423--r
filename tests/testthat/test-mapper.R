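test_that("regrid aggregates by block mean and upsamples by replication", {
  expect_equal(regrid(matrix(1, 4, 4), 2, "down"), matrix(1, 2, 2))
  expect_equal(regrid(matrix(c(1, 5, 3, 7), 2, 2), 2, "down"),
               matrix(4, 1, 1))
  expect_equal(regrid(matrix(9, 1, 1), 3, "up"), matrix(9, 3, 3))
  expect_error(regrid(matrix(0, 5, 4), 2, "down"), "divisible")
  g <- matrix(1:15, 5, 3)
  padded <- regrid(g, 2, "down", pad = TRUE)
  expect_equal(dim(padded), c(3, 2))
  expect_equal(padded[3, 2], mean(g[5, 3]))   # 1x1 edge block
  expect_equal(padded[1, 1], mean(g[1:2, 1:2]))
  # down-then-up preserves block means exactly
  set.seed(1)
  G <- matrix(rnorm(64), 8, 8)
  rt <- regrid(regrid(G, 2, "down"), 2, "up")
  expect_equal(regrid(rt, 2, "down"), regrid(G, 2, "down"), tolerance = 1e-12)
})

test_that("feature extraction matches covariates at sites and transforms RQs", {
  fx <- std_fixture()
  rec <- fx$rq[fx$rq$compound == "ofloxacin", ][1:40, ]
  out <- extract_features(rec, fx$covariates,
                          predictors = c("clay", "elevation"),
                          year_matching = FALSE)
  raw <- sweep(sweep(out$features, 2, out$scale, "*"), 2, out$center, "+")
  cells <- (rec$x - 1) * 32 + rec$y
  expect_equal(unname(raw[, "clay"]), fx$covariates$clay[cells])
  expect_equal(unname(colMeans(out$features)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(out$features, 2, sd)), c(1, 1), tolerance = 1e-8)
  # positive RQs: delta is 0 and RQ 1 maps to target 0
  rec$rq <- rep(1, nrow(rec))
  out1 <- extract_features(rec, fx$covariates, predictors = "clay")
  expect_equal(out1$delta, 0)
  expect_equal(out1$targets, rep(0, nrow(rec)))
  # zero RQs get the documented floor: half the smallest nonzero RQ
  rec$rq <- c(0, 0.4, rep(2, nrow(rec) - 2))
  out2 <- extract_features(rec, fx$covariates, predictors = "clay")
  expect_equal(out2$delta, 0.2)
  expect_equal(out2$targets[1], log10(0.2))
  # out-of-bounds sites are named
  bad <- rec; bad$x[3] <- 99
  expect_error(extract_features(bad, fx$covariates, predictors = "clay"),
               "outside grid")
})

test_that("year matching shifts time-varying covariates by the stored trend", {
  fx <- std_fixture()
  rec <- fx$rq[fx$rq$compound == "ofloxacin", ][1:30, ]
  rec$year <- 2020
  out <- extract_features(rec, fx$covariates, predictors = "temperature")
  cells <- (rec$x - 1) * 32 + rec$y
  trend <- attr(fx$covariates, "meta")$time_varying[["temperature"]]
  raw <- out$features * out$scale[1] + out$center[1]
  expect_equal(unname(raw[, 1]),
               fx$covariates$temperature[cells] + trend * 10)
})

test_that("accuracy metrics match closed forms", {
  obs <- c(1, 2, 3, 4)
  m <- cv_metrics(obs, obs)
  expect_equal(m$rmse, 0)
  expect_equal(m$pearson_r, 1)
  m2 <- cv_metrics(obs, obs + 2.5)
  expect_equal(m2$rmse, 2.5)
  expect_equal(m2$pearson_r, 1)
  m3 <- cv_metrics(c(1, 2), c(2, 1))
  expect_equal(m3$pearson_r, -1)
})

test_that("ensembles resample distinctly and are seed-reproducible", {
  set.seed(1)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(30, 0, 0.1)
  ens <- fit_ensemble(X, y, n_members = 3, max_trees = 50, seed = 11)
  expect_equal(length(ens$members), 3)
  expect_false(identical(sort(ens$samples[[1]]), sort(ens$samples[[2]])))
  ens2 <- fit_ensemble(X, y, n_members = 3, max_trees = 50, seed = 11)
  expect_identical(predict_members(ens, X), predict_members(ens2, X))
  expect_error(fit_ensemble(X[1:10, ], y[1:10], 2), ">= 20")
  expect_warning(fit_ensemble(X, rep(1, 30), n_members = 2, max_trees = 10),
                 "constant")
})

test_that("hold-out validation recovers a planted low-noise surface", {
  fx <- std_fixture()
  tr <- toy_truth(list(ofloxacin = c(manure_rate = 0.01, arable_prop = 10)),
                  intercept = 1, noise_sd = 0.05)
  mec <- generate_mec_samples(fx$landscape, fx$covariates, tr, 250,
                              detection_limit = 0, seed = 6)
  mec$rq <- mec$concentration / 25
  out <- extract_features(mec, fx$covariates,
                          predictors = setdiff(names(fx$covariates),
                                               "human_footprint"))
  cvm <- cross_validate(out$features, out$targets, n_members = 10,
                        max_trees = 200, seed = 3)
  expect_gt(cvm$pearson_r, 0.95)
  expect_equal(cvm$n_train + cvm$n_validation, 250)
  expect_error(cross_validate(out$features[1:9, ], out$targets[1:9]),
               "too few|>= 10")
})

test_that("predicted maps honor the mask and compose cumulatively", {
  fx <- std_fixture()
  preds <- c("manure_rate", "arable_prop", "irrigated_prop", "clay")
  maps <- list()
  for (cmp in c("ofloxacin", "tetracycline")) {
    rec <- fx$rq[fx$rq$compound == cmp, ]
    out <- extract_features(rec, fx$covariates, predictors = preds)
    ens <- fit_ensemble(out$features, out$targets, n_members = 8,
                        max_trees = 100, seed = 2)
    maps[[cmp]] <- predict_maps(ens, fx$covariates, fx$landscape$soil_mask,
                                out$center, out$scale, out$delta)
  }
  m <- maps[[1]]
  masked <- !fx$landscape$soil_mask
  expect_true(all(is.na(m$mean[masked])))
  expect_true(all(is.na(m$sd[masked])))
  expect_true(all(m$mean[!masked] >= 0))
  cum <- cumulative_risk_maps(maps)
  soil <- fx$landscape$soil_mask
  expect_true(all(cum$mean[soil] >= maps[[1]]$mean[soil] - 1e-12))
  expect_true(all(cum$mean[soil] >= maps[[2]]$mean[soil] - 1e-12))
  expect_equal(cum$mean[soil],
               maps[[1]]$mean[soil] + maps[[2]]$mean[soil],
               tolerance = 1e-10)
  bad_cov <- fx$covariates[setdiff(names(fx$covariates), "clay")]
  attr(bad_cov, "meta") <- attr(fx$covariates, "meta")
  ens <- fit_ensemble(extract_features(fx$rq[fx$rq$compound == "ofloxacin", ],
                                       fx$covariates, preds)$features,
                      rnorm(120), n_members = 2, max_trees = 10, seed = 1)
  expect_error(predict_maps(ens, bad_cov, soil, 0, 1, 0), "clay")
})

test_that("a noise-free planted surface yields a tight ensemble", {
  fx <- std_fixture()
  tr <- toy_truth(list(ofloxacin = c(manure_rate = 0.01, arable_prop = 10)),
                  intercept = 1, noise_sd = 0)
  mec <- generate_mec_samples(fx$landscape, fx$covariates, tr, 500,
                              detection_limit = 0, seed = 8)
  mec$rq <- mec$concentration / 25
  preds <- c("manure_rate", "arable_prop", "irrigated_prop", "livestock_density")
  out <- extract_features(mec, fx$covariates, predictors = preds)
  ens <- fit_ensemble(out$features, out$targets, n_members = 20,
                      max_trees = 400, mtry = 3, seed = 5)
  maps <- predict_maps(ens, fx$covariates, fx$landscape$soil_mask,
                       out$center, out$scale, out$delta)
  soil <- fx$landscape$soil_mask
  expect_lt(max(maps$sd[soil]), 0.05 * mean(maps$mean[soil]))
})

test_that("doubling the ensemble barely moves the mean map", {
  fx <- std_fixture()
  rec <- fx$rq[fx$rq$compound == "ofloxacin", ]
  preds <- c("manure_rate", "arable_prop", "irrigated_prop")
  out <- extract_features(rec, fx$covariates, predictors = preds)
  soil <- fx$landscape$soil_mask
  m1 <- predict_maps(fit_ensemble(out$features, out$targets, 10, 100, seed = 1),
                     fx$covariates, soil, out$center, out$scale, out$delta)
  m2 <- predict_maps(fit_ensemble(out$features, out$targets, 20, 100, seed = 1),
                     fx$covariates, soil, out$center, out$scale, out$delta)
  drift <- mean(abs(m2$mean[soil] - m1$mean[soil]))
  expect_lt(drift, mean(m1$sd[soil]) / sqrt(10))
})
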