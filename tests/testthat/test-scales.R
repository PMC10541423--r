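test_that("watershed summaries average cell values correctly", {
  fx <- std_fixture()
  uniform <- matrix(3.5, 32, 32)
  s <- summarize_watersheds(uniform, fx$covariates, fx$landscape, 1)
  expect_true(all(abs(s$cum_rq - 3.5) < 1e-12))
  s4 <- summarize_watersheds(uniform, fx$covariates, fx$landscape, 4)
  expect_gte(nrow(s4), nrow(s))
  # hand-built two-watershed check on a small landscape
  ls <- generate_landscape(8, 8, 2, 2, seed = 3, mask_frac = 0)
  vals <- matrix(seq_len(64), 8, 8)
  cv_stub <- fx$covariates
  cv_stub <- lapply(fx$covariates, function(g) g[1:8, 1:8])
  attr(cv_stub, "meta") <- attr(fx$covariates, "meta")
  class(cv_stub) <- "agro_covariates"
  s2 <- summarize_watersheds(vals, cv_stub, ls, 1)
  lab <- as.vector(ls$watershed_ids[[1]])
  expect_equal(s2$cum_rq, as.vector(tapply(as.vector(vals), lab, mean)))
})

test_that("intensification scores are summed min-max components", {
  base <- data.frame(watershed_id = 1:3, level = 1)
  base$arable_prop <- c(0, 1, 0.5)
  base$manure_rate <- c(0, 400, 100)
  base$irrigated_prop <- c(0, 0.8, 0.6)
  sc <- intensification_score(base)
  expect_equal(as.vector(sc), c(0, 3, 0.5 + 0.25 + 0.75))
  const <- base; const$manure_rate <- 5
  expect_warning(sc2 <- intensification_score(const), "constant")
  expect_equal(as.vector(sc2)[2], 2)      # max watershed loses one component
  expect_error(intensification_score(base[1, ]), ">= 2")
})

test_that("omission builds exactly 20 nested subdatasets", {
  s <- std_summaries(4)
  subs <- make_subdatasets(s)
  expect_length(subs, 20)
  sides <- vapply(subs, `[[`, "", "omission_side")
  expect_equal(sum(sides == "upper"), 10)
  full <- sort(s$watershed_id)
  for (side in c("upper", "lower")) {
    members <- lapply(subs[sides == side], `[[`, "watershed_ids")
    fracs <- vapply(subs[sides == side], `[[`, 0, "omission_fraction")
    expect_equal(sort(members[[which(fracs == 0)]]), full)
    ord <- order(fracs)
    for (i in seq_len(9))
      expect_true(all(members[[ord[i + 1]]] %in% members[[ord[i]]]))
    expect_equal(vapply(members[ord], length, 0L),
                 nrow(s) - ceiling(seq(0, 0.9, 0.1) * nrow(s)))
  }
})

test_that("omission removes from the correct end of the footprint ranking", {
  s10 <- std_summaries(4)[1:10, ]
  subs <- make_subdatasets(s10)
  top <- s10$watershed_id[which.max(s10$human_footprint)]
  up1 <- Filter(function(x) x$omission_side == "upper" &&
                  x$omission_fraction == 0.1, subs)[[1]]
  expect_false(top %in% up1$watershed_ids)
  expect_length(up1$watershed_ids, 9)
  low9 <- Filter(function(x) x$omission_side == "lower" &&
                   abs(x$omission_fraction - 0.9) < 1e-9, subs)[[1]]
  expect_equal(low9$watershed_ids, top)
  expect_error(make_subdatasets(s10[1:9, ]), "10")
})

test_that("AICc matches the small-sample correction formula", {
  set.seed(2)
  d <- data.frame(y = rnorm(20), x1 = rnorm(20), x2 = rnorm(20))
  m <- lm(y ~ x1 + x2, data = d)       # k = 4: intercept, 2 slopes, sigma
  expect_equal(aicc(m), AIC(m) + 40 / 15)
  rss <- sum(residuals(m)^2)
  expect_equal(aicc(m), aicc_from_rss(rss, 20, 2), tolerance = 1e-10)
})

test_that("model averaging matches an exhaustive enumeration oracle", {
  set.seed(4)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$cum_rq <- 1.5 * d$x1 - 0.8 * d$x2 + rnorm(n, 0, 0.6)
  ma <- fit_model_average(d, predictors = c("x1", "x2", "x3"), delta = 2)
  # oracle: enumerate the 8 subsets independently via RSS-based AICc
  zs <- function(v) (v - mean(v)) / sd(v)
  dz <- as.data.frame(lapply(d, zs))
  combos <- expand.grid(x1 = c(FALSE, TRUE), x2 = c(FALSE, TRUE),
                        x3 = c(FALSE, TRUE))
  oracle <- lapply(seq_len(8), function(i) {
    inc <- names(combos)[unlist(combos[i, ])]
    X <- cbind(`(Intercept)` = 1, as.matrix(dz[inc]))
    fit <- lm.fit(X, dz$cum_rq)
    list(inc = inc, coef = fit$coefficients,
         aicc = aicc_from_rss(sum(fit$residuals^2), n, length(inc)),
         rss = sum(fit$residuals^2), rank = fit$rank)
  })
  av <- vapply(oracle, `[[`, 0, "aicc")
  expect_equal(sort(ma$models$aicc), sort(av), tolerance = 1e-8)
  best <- which(av - min(av) < 2)
  w <- exp(-0.5 * (av[best] - min(av))); w <- w / sum(w)
  for (p in c("x1", "x2", "x3")) {
    b <- vapply(seq_along(best), function(k) {
      cf <- oracle[[best[k]]]$coef
      if (p %in% names(cf)) unname(cf[p]) else 0
    }, 0)
    expect_equal(ma$coefficients$beta[ma$coefficients$predictor == p],
                 sum(w * b), tolerance = 1e-8)
  }
  expect_equal(length(ma$best), length(best))
})

test_that("a strong single predictor is ranked first and recovered", {
  set.seed(11)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$cum_rq <- 2 * d$x1 + rnorm(n, 0, 1e-6)
  ma <- fit_model_average(d, predictors = c("x1", "x2", "x3"))
  ranked <- ma$models[order(ma$models$aicc), ]
  top <- ranked$model[1]
  # AICc-best model is {x1} alone: model index 2 in truth-table order
  expect_equal(top, 2)
  ols <- coef(lm(scale(cum_rq) ~ scale(x1), d))[2]
  expect_equal(ma$coefficients$beta[1], unname(ols), tolerance = 1e-3)
  expect_true(ma$coefficients$significant[1])
  expect_gt(ma$r_squared, 0.999)
})

test_that("a null response favors the intercept-only model most of the time", {
  set.seed(21)
  wins <- 0
  for (r in 1:100) {
    n <- 100
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$cum_rq <- rnorm(n)
    ma <- fit_model_average(d, predictors = c("x1", "x2", "x3"))
    if (which.min(ma$models$aicc) == 1) wins <- wins + 1
  }
  expect_gt(wins, 50)
})

test_that("collinear predictors are dropped with natural_prop first", {
  s <- std_summaries(4)
  s$natural_prop <- 1 - s$arable_prop - s$built_prop   # exact collinearity
  ma <- fit_model_average(s, predictors = c("arable_prop", "built_prop",
                                            "natural_prop", "manure_rate"))
  expect_equal(ma$dropped, "natural_prop")
  expect_false("natural_prop" %in% ma$coefficients$predictor)
})

test_that("contribution percentages are normalized absolute-coefficient shares", {
  ctb <- contribution_percentages(c(arable_prop = 0.5, built_prop = -0.25,
                                    natural_prop = 0.25))
  expect_equal(ctb$by_predictor$contribution, c(50, 25, 25))
  expect_equal(sum(ctb$by_predictor$contribution), 100, tolerance = 1e-9)
  one <- contribution_percentages(c(manure_rate = -2))
  expect_equal(one$by_predictor$contribution, 100)
  grp <- contribution_percentages(c(arable_prop = 0.3, built_prop = 0.1,
                                    manure_rate = 0.6))
  expect_equal(unname(grp$by_group[c("land_use", "management")]), c(40, 60))
  expect_error(contribution_percentages(c(a = 0, b = 0)), "zero")
})

test_that("the scale battery recovers the planted manure effect at level 4", {
  s <- std_summaries(4, noise_sd = 0.02, hinge_strength = 0.03)
  bat <- run_scale_battery(list(s))
  expect_equal(nrow(bat$counts), 7)
  manure <- bat$counts[bat$counts$predictor == "manure_rate", ]
  expect_gte(manure$sig_positive, 16)     # of 20 omission analyses
  expect_equal(manure$sig_negative, 0)
  per_level <- bat$contributions[bat$contributions$level == 4, ]
  expect_equal(sum(per_level$mean), 100, tolerance = 1e-9)
  # management (the planted driver) dominates the explained variance
  expect_gt(per_level$mean[per_level$group == "management"],
            per_level$mean[per_level$group == "land_use"])
  # the 80/90% omissions leave fewer rows than predictors + 5: logged
  expect_equal(bat$failures$failed, 4)
})
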