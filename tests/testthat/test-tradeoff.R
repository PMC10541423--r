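test_that("improvement scores follow the min-max identity cases", {
  expect_equal(improvement(c(2, 4, 6)), c(0, 0.5, 1))
  A <- c(3, 9, 5, 7)
  P <- improvement(A)
  expect_equal(P[which.min(A)], 0)
  expect_equal(P[which.max(A)], 1)
  expect_true(all(P >= 0 & P <= 1))
  # affine invariance
  expect_equal(improvement(10 + 3 * A), P)
  expect_error(improvement(rep(2, 5)), "constant")
})

test_that("tradeoff is the signed distance from the 1:1 line", {
  expect_equal(tradeoff_value(1, 0), 1)
  expect_equal(tradeoff_value(0.5, 0.5), 0)
  expect_equal(tradeoff_value(0.3, 0.8), -0.5)
  py <- c(0.2, 0.9, 0.5); pr <- c(0.4, 0.1, 0.5)
  expect_equal(tradeoff_value(py, pr), -tradeoff_value(pr, py))
  expect_error(tradeoff_value(c(0.1, 0.2), 0.3), "mismatch")
  expect_error(tradeoff_value(1.4, 0.3), "\\[0, 1\\]")
})

test_that("constraint lines take per-bin quantile boundaries", {
  x <- c(rep(0.2, 100), rep(0.7, 5))
  y <- c(1:100, 2, 4, 6, 8, 10)
  cl <- constraint_line(x, y, n_bins = 2, side = "upper")
  expect_equal(cl$boundary[1], 99.01)     # interpolated 99% quantile
  expect_equal(cl$boundary[2], unname(quantile(c(2, 4, 6, 8, 10), 0.99)))
  low <- constraint_line(x, y, n_bins = 2, side = "lower")
  expect_equal(low$boundary[1], unname(quantile(1:100, 0.01)))
  # all-equal responses collapse both boundaries onto the constant
  ye <- rep(7, length(x))
  expect_equal(constraint_line(x, ye, n_bins = 2, side = "upper")$boundary,
               c(7, 7))
  expect_equal(constraint_line(x, ye, n_bins = 2, side = "lower")$boundary,
               c(7, 7))
})

test_that("constraint lines have 50 point columns, 10 at level 1", {
  set.seed(5)
  x <- runif(400); y <- rnorm(400)
  cl4 <- constraint_line(x, y, level = 4)
  expect_equal(nrow(cl4), 50)
  cl1 <- constraint_line(x, y, level = 1)
  expect_equal(nrow(cl1), 10)
  expect_error(constraint_line(rep(1, 10), rnorm(10)), "degenerate")
  # sparse clouds leave empty point columns, reported not fabricated
  sparse <- constraint_line(c(rep(0, 5), 1), c(1:5, 9), n_bins = 50)
  expect_equal(sum(sparse$n > 0), 2)
  expect_length(attr(sparse, "skipped"), 48)
  expect_true(all(is.na(sparse$boundary[sparse$n == 0])))
})

test_that("boundaries match a sort-based quantile oracle and stay in range", {
  set.seed(6)
  x <- runif(600); y <- rnorm(600)
  cl <- constraint_line(x, y, level = 4, side = "upper")
  edges <- seq(min(x), max(x), length.out = 51)
  bins <- findInterval(x, edges, rightmost.closed = TRUE)
  for (b in which(cl$n > 0)) {
    yb <- sort(y[bins == b])
    nb <- length(yb)
    h <- (nb - 1) * 0.99 + 1              # type-7 interpolation by hand
    lo <- floor(h)
    oracle <- yb[lo] + (h - lo) * (yb[min(lo + 1, nb)] - yb[lo])
    expect_equal(cl$boundary[b], oracle, tolerance = 1e-12)
    expect_lte(cl$boundary[b], max(yb))
    expect_gte(cl$boundary[b], median(yb))
  }
})

test_that("moving-window size selection follows the relative-range rule", {
  s <- data.frame(watershed_id = 1:100, cum_rq = as.numeric(1:100),
                  manure_rate = 1:100)
  mw <- fix_window_size(s, "manure_rate", candidate_sizes = c(1, 50, 100))
  expect_equal(mw$table$relative_range[1], 1)          # w = 1 is maximal
  expect_equal(mw$table$relative_range[3], 0)          # single window
  expect_equal(mw$chosen_w, 1)
  mw2 <- fix_window_size(s, "manure_rate", candidate_sizes = c(5, 50, 95))
  expect_equal(mw2$chosen_w, 5)
  expect_equal(mw2$table$relative_range,
               c(95, 50, 5) / 99, tolerance = 1e-12)
  expect_equal(nrow(mw2$windows), 96)
  expect_equal(mw2$windows$cum_rq[1], mean(1:5))
  expect_error(fix_window_size(s, "manure_rate", candidate_sizes = c(95, 100)),
               "threshold")
  expect_error(fix_window_size(s[1:10, ], "manure_rate"), ">= 20")
})

test_that("exact parabolas are interpolated with zero residual", {
  x <- 0:4
  fit <- fit_inverted_u(x, -x^2 + 4 * x + 1)
  expect_equal(c(fit$a, fit$b, fit$c), c(-1, 4, 1), tolerance = 1e-10)
  expect_true(fit$inverted_u)
  up <- fit_inverted_u(x, 2 * x^2 - 3 * x)
  expect_gt(up$a, 0)
  expect_false(up$inverted_u)
  expect_error(fit_inverted_u(c(1, 1, 2, 2), c(1, 2, 3, 4)), "distinct")
  expect_error(fit_inverted_u(1:3, 1:3), ">= 4")
})

test_that("thresholds are the vertex with delta-method uncertainty", {
  f <- list(a = -1, b = 4, c = 1,
            vcov = matrix(0, 3, 3, dimnames = list(c("a", "b", "c"),
                                                   c("a", "b", "c"))),
            inverted_u = TRUE)
  class(f) <- "parabola_fit"
  th <- threshold_from_fit(f)
  expect_equal(th$threshold, 2)
  expect_equal(th$se, 0)
  f$a <- -2; f$b <- 8
  expect_equal(threshold_from_fit(f)$threshold, 2)
  f$a <- 0.5
  nores <- threshold_from_fit(f)
  expect_false(nores$defined)
  expect_true(is.na(nores$threshold))
  # exact generating vertex recovered to numerical precision
  x <- seq(0, 4, length.out = 41)
  fit <- fit_inverted_u(x, -0.7 * x^2 + 2.8 * x + 0.3)
  expect_equal(threshold_from_fit(fit)$threshold, 2, tolerance = 1e-9)
})

test_that("delta-method SE agrees with a parametric bootstrap", {
  set.seed(12)
  x <- runif(200, 0, 4)
  y <- -(x - 2)^2 + 3 + rnorm(200, 0, 0.1)
  fit <- fit_inverted_u(x, y)
  th <- threshold_from_fit(fit)
  boot <- replicate(400, {
    yb <- fit$a * x^2 + fit$b * x + fit$c +
      rnorm(200, 0, 0.1)
    threshold_from_fit(fit_inverted_u(x, yb))$threshold
  })
  expect_lt(abs(th$se - sd(boot)) / sd(boot), 0.15)
})

test_that("hinge breakpoints are recovered and absent on linear data", {
  set.seed(14)
  rq <- runif(500, 0, 20)
  signal <- 100 - 2 * pmax(rq - 9, 0)
  y <- signal + rnorm(500, 0, 0.05 * sd(signal))
  bp <- fit_yield_breakpoint(rq, y)
  expect_true(bp$has_breakpoint)
  expect_lt(abs(bp$breakpoint - 9), 0.5)
  expect_lt(bp$slope_change, 0)
  expect_gt(bp$adj_r_squared, 0.8)
  # strictly linear: no significant slope change
  lin <- fit_yield_breakpoint(rq, 5 + 0.3 * rq)
  expect_false(lin$has_breakpoint)
  expect_true(is.na(lin$breakpoint))
  # symmetric tent peaking at the median
  tent <- 10 - abs(rq - median(rq))
  bt <- fit_yield_breakpoint(rq, tent, n_grid = 200)
  expect_true(bt$has_breakpoint)
  expect_lt(abs(bt$breakpoint - median(rq)), diff(range(rq)) * 0.9 / 200 * 2)
  expect_error(fit_yield_breakpoint(rq[1:10], y[1:10]), ">= 30")
})

test_that("the threshold battery spans levels x crops x variables", {
  s4 <- std_summaries(4, noise_sd = 0.02, hinge_strength = 0.03)
  s3 <- std_summaries(3, noise_sd = 0.02, hinge_strength = 0.03)
  bat <- threshold_battery(list(s3, s4))
  expect_equal(nrow(bat), 2 * 4 * 3)
  expect_setequal(unique(bat$level), c(3, 4))
  ok <- bat[bat$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$a < 0))
  expect_true(all(is.finite(ok$se)))
})

test_that("noise-free battery thresholds match planted vertices and ordering", {
  s <- std_summaries(4, noise_sd = 0, hinge_strength = 0)
  fx <- std_fixture()
  # vertex recovery on the intensification axis itself
  I01 <- minmax(s$intensification)
  verts <- vapply(c("maize", "rice", "wheat", "vegetables"), function(crop) {
    tf <- tradeoff_value(improvement(s[[paste0("yield_", crop)]]),
                         improvement(s$cum_rq))
    threshold_from_fit(fit_inverted_u(I01, tf))$threshold
  }, 0)
  planted <- fx$truth$tradeoff_vertex[names(verts)]
  expect_lt(max(abs(verts - planted)), 0.06)
  # battery on the land-system variables preserves the planted crop ordering
  bat <- threshold_battery(list(s))
  for (v in unique(bat$variable)) {
    th <- bat$threshold[bat$variable == v]
    names(th) <- bat$crop[bat$variable == v]
    expect_equal(names(sort(th)),
                 c("maize", "rice", "wheat", "vegetables"), info = v)
  }
})
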