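# Risk-yield tradeoff analysis: smoother-based yield-risk breakpoints,
# min-max improvement scores and their tradeoff, quantile constraint lines,
# the moving-window summarization, inverted-U (development Kuznets curve)
# fits, and vertex thresholds with delta-method uncertainties.

#' Yield response to cumulative risk: smoother fit and breakpoint
#'
#' Fits a generalized additive model of yield on cumulative RQ with a
#' thin-plate smoother of basis dimension 5, and estimates the risk
#' threshold for yield reduction by a two-segment (hinge) least-squares
#' search: candidate breakpoints on a grid over the interior of the RQ
#' range, continuous piecewise-linear fit at each, best SSE refined by
#' local optimization. The slope change is retained only when the hinge
#' term significantly improves on a straight line (F test, p < 0.05);
#' otherwise the data are reported as breakpoint-free.
#'
#' @param rq cumulative RQ values (>= 30, nondegenerate range).
#' @param yields matching crop yields.
#' @param crop crop label carried into the result.
#' @param n_grid number of candidate breakpoints (default 100).
#' @return object of class `breakpoint_fit`: list with `crop`, `breakpoint`
#'   (NA when no slope change), `has_breakpoint`, `slope_change`,
#'   `p_breakpoint` (hinge F test), `adj_r_squared` and `p_smooth` (GAM),
#'   `gam` (the mgcv fit).
#' @export
fit_yield_breakpoint <- function(rq, yields, crop = NA_character_,
                                 n_grid = 100) {
  stopifnot(length(rq) == length(yields))
  if (length(rq) < 30) stop("need >= 30 paired observations")
  if (diff(range(rq)) == 0) stop("degenerate RQ range")
  g <- mgcv::gam(yields ~ s(rq, k = 5))
  sg <- summary(g)
  lin <- stats::lm(yields ~ rq)
  hinge_sse <- function(t) {
    h <- pmax(rq - t, 0)
    sum(stats::lm.fit(cbind(1, rq, h), yields)$residuals^2)
  }
  qs <- stats::quantile(rq, c(0.05, 0.95))
  cand <- seq(qs[1], qs[2], length.out = n_grid)
  sse <- vapply(cand, hinge_sse, 0)
  best <- which.min(sse)
  lo <- cand[max(1, best - 1)]; hi <- cand[min(n_grid, best + 1)]
  opt <- stats::optimize(hinge_sse, c(lo, hi))
  t_hat <- opt$minimum
  h <- pmax(rq - t_hat, 0)
  seg <- stats::lm(yields ~ rq + h)
  sse_lin <- sum(stats::residuals(lin)^2)
  sse_seg <- sum(stats::residuals(seg)^2)
  n <- length(rq)
  # F test for the hinge improvement (2 extra parameters: breakpoint, slope)
  df2 <- n - 4
  if (sse_seg <= .Machine$double.eps * sse_lin || sse_lin == 0) {
    f <- if (sse_lin > sse_seg * (1 + 1e-8)) Inf else 0
  } else {
    f <- ((sse_lin - sse_seg) / 2) / (sse_seg / df2)
  }
  p_bp <- stats::pf(f, 2, df2, lower.tail = FALSE)
  has <- is.finite(t_hat) && !is.na(p_bp) && p_bp < 0.05
  structure(list(
    crop = crop,
    breakpoint = if (has) t_hat else NA_real_,
    has_breakpoint = has,
    slope_change = unname(stats::coef(seg)["h"]),
    p_breakpoint = p_bp,
    adj_r_squared = sg$r.sq,
    p_smooth = unname(sg$s.table[1, "p-value"]),
    gam = g
  ), class = "breakpoint_fit")
}

#' Improvement score of an objective across watersheds
#'
#' P = (A_i - A_min) / (A_max - A_min): the min-max standardized level of
#' one objective (a crop yield, or the antibiotic pollution risk treated as
#' a disservice) relative to all watersheds. P is 0 at the minimum and 1 at
#' the maximum; constant input is an error (the scaling is undefined).
#'
#' @param values objective values A_i over watersheds.
#' @return numeric vector of P scores in \[0, 1\].
#' @export
improvement <- function(values) {
  if (diff(range(values)) == 0)
    stop("improvement undefined: constant objective values")
  minmax(values)
}

#' Risk-yield tradeoff value
#'
#' The improvement score for crop yield minus the improvement score for
#' antibiotic pollution risk, i.e. the signed distance from the 1:1 line.
#' Positive values mean yield benefits exceed risks.
#'
#' @param p_yield,p_risk improvement scores in \[0, 1\], same watersheds in
#'   the same order.
#' @return numeric vector in \[-1, 1\].
#' @export
tradeoff_value <- function(p_yield, p_risk) {
  if (length(p_yield) != length(p_risk))
    stop("mismatched watershed sets")
  if (any(p_yield < 0 | p_yield > 1 | p_risk < 0 | p_risk > 1))
    stop("improvement scores must lie in [0, 1]")
  p_yield - p_risk
}

#' Quantile constraint line of a scattered point cloud
#'
#' Splits the constraint-variable axis into equal-width bins (50, or 10 for
#' the level-1 watershed), and returns per bin the y-quantile boundary
#' point (99% upper boundary for yields and tradeoffs, 1% lower boundary
#' for risk). Quantiles use linear interpolation. Empty bins are reported
#' with NA boundaries and listed in the `skipped` attribute.
#'
#' @param x constraint variable.
#' @param y response variable.
#' @param level watershed level; level 1 uses 10 bins, others 50 (can be
#'   overridden with `n_bins`).
#' @param side "upper" (default quantile 0.99) or "lower" (0.01).
#' @param quantile boundary quantile; defaults by `side`.
#' @param n_bins explicit number of point columns.
#' @return data.frame of class `constraint_line` with one row per point
#'   column: `bin`, `x_mid` (bin midpoint), `boundary` (y quantile),
#'   `n` (points in bin); attributes `side`, `quantile`, `skipped`.
#' @export
constraint_line <- function(x, y, level = 4, side = c("upper", "lower"),
                            quantile = NULL, n_bins = NULL) {
  side <- match.arg(side)
  stopifnot(length(x) == length(y))
  if (is.null(quantile)) quantile <- if (side == "upper") 0.99 else 0.01
  if (is.null(n_bins)) n_bins <- if (level == 1) 10L else 50L
  if (diff(range(x)) == 0) stop("degenerate constraint-variable range")
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  out <- data.frame(bin = seq_len(n_bins),
                    x_mid = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                    boundary = NA_real_, n = 0L)
  for (b in seq_len(n_bins)) {
    yb <- y[bin == b]
    out$n[b] <- length(yb)
    if (length(yb))
      out$boundary[b] <- unname(stats::quantile(yb, quantile, type = 7))
  }
  if (sum(out$n > 0) < 2) stop("fewer than 2 nonempty point columns")
  attr(out, "side") <- side
  attr(out, "quantile") <- quantile
  attr(out, "skipped") <- out$bin[out$n == 0]
  class(out) <- c("constraint_line", "data.frame")
  out
}

#' Fix the moving-window size by the relative range of risk
#'
#' Watersheds are ordered by the constraint variable; for each candidate
#' window size w, contiguous sliding windows (step 1) of w watersheds are
#' formed and the range of their mean RQs is computed. The relative range
#' is that range divided by the maximum range over all window sizes (the
#' raw, size-1 range, since windowed-mean ranges shrink as windows grow);
#' the chosen w is the smallest whose relative range exceeds 0.6 (maximal
#' resolution under the stability constraint). Per-window means of every
#' numeric column are returned for the chosen size.
#'
#' @param summaries watershed summary table (with `cum_rq`), >= 20 rows.
#' @param order_by constraint variable column used for ordering.
#' @param candidate_sizes ascending window sizes; default
#'   {2, 3, 5, 8, 12, 20, 0.05n, 0.1n} (capped at n).
#' @param threshold relative-range cutoff (default 0.6).
#' @return list with `chosen_w`, `table` (w, range, relative_range),
#'   `windows` (data.frame of per-window means for the chosen w).
#' @export
fix_window_size <- function(summaries, order_by, candidate_sizes = NULL,
                            threshold = 0.6) {
  n <- nrow(summaries)
  if (n < 20) stop("need >= 20 watersheds for the moving-window analysis")
  stopifnot(order_by %in% names(summaries), "cum_rq" %in% names(summaries))
  if (is.null(candidate_sizes))
    candidate_sizes <- sort(unique(pmin(
      c(2, 3, 5, 8, 12, 20, ceiling(0.05 * n), ceiling(0.1 * n)), n)))
  if (is.unsorted(candidate_sizes)) stop("candidate sizes must be ascending")
  ord <- order(summaries[[order_by]], summaries$watershed_id)
  s <- summaries[ord, , drop = FALSE]
  win_means <- function(v, w) {
    cs <- cumsum(c(0, v))
    (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  }
  rng <- vapply(candidate_sizes, function(w)
    diff(range(win_means(s$cum_rq, w))), 0)
  max_rng <- diff(range(s$cum_rq))          # window size 1
  if (max_rng == 0) stop("constant risk: relative range undefined")
  rel <- rng / max_rng
  ok <- which(rel > threshold)
  if (!length(ok))
    stop("no candidate window size reaches the relative-range threshold; ",
         "supply smaller candidate sizes")
  w <- candidate_sizes[ok[1]]
  num <- names(s)[vapply(s, is.numeric, TRUE)]
  windows <- as.data.frame(lapply(s[num], win_means, w = w))
  list(chosen_w = w,
       table = data.frame(w = candidate_sizes, range = rng,
                          relative_range = rel),
       windows = windows)
}

#' Ordinary least-squares inverted-U (quadratic) fit
#'
#' Fits y = a x^2 + b x + c by OLS and returns the coefficients with their
#' covariance (from the residual variance). The fit is flagged as an
#' inverted U when a < 0.
#'
#' @param x,y numeric vectors (>= 4 points, >= 3 distinct x).
#' @return object of class `parabola_fit`: list with `a`, `b`, `c`, `vcov`
#'   (3 x 3, order a, b, c), `r_squared`, `n`, `inverted_u`.
#' @export
fit_inverted_u <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need >= 4 points")
  if (length(unique(x)) < 3) stop("collinear design: need >= 3 distinct x")
  fit <- stats::lm(y ~ I(x^2) + x)
  cf <- stats::coef(fit)
  rss0 <- sum(stats::residuals(fit)^2)
  sigma2 <- rss0 / stats::df.residual(fit)
  R <- qr.R(fit$qr)
  vc <- chol2inv(R) * sigma2
  dimnames(vc) <- list(names(cf), names(cf))
  ord <- c("I(x^2)", "x", "(Intercept)")
  vc <- vc[ord, ord]
  dimnames(vc) <- list(c("a", "b", "c"), c("a", "b", "c"))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(a = unname(cf["I(x^2)"]), b = unname(cf["x"]),
                 c = unname(cf["(Intercept)"]), vcov = vc,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(x),
                 inverted_u = unname(cf["I(x^2)"]) < 0),
            class = "parabola_fit")
}

#' Intensification threshold from an inverted-U fit
#'
#' The threshold is the vertex -b / (2a) of the fitted parabola, defined
#' only for a < 0 (a genuine inverted U). Its standard error follows from
#' the delta method on (a, b): dt/da = b / (2 a^2), dt/db = -1 / (2 a).
#' An upright or flat fit returns an explicit no-threshold result.
#'
#' @param fit a `parabola_fit`.
#' @return object of class `threshold_estimate`: list with `threshold`,
#'   `se`, `defined`, `a`, `b`.
#' @export
threshold_from_fit <- function(fit) {
  if (!inherits(fit, "parabola_fit")) stop("expected a parabola_fit")
  if (fit$a >= 0)
    return(structure(list(threshold = NA_real_, se = NA_real_,
                          defined = FALSE, a = fit$a, b = fit$b),
                     class = "threshold_estimate"))
  t <- -fit$b / (2 * fit$a)
  g <- c(fit$b / (2 * fit$a^2), -1 / (2 * fit$a))
  v <- fit$vcov[c("a", "b"), c("a", "b")]
  se <- sqrt(max(0, as.numeric(t(g) %*% v %*% g)))
  structure(list(threshold = t, se = se, defined = TRUE,
                 a = fit$a, b = fit$b),
            class = "threshold_estimate")
}

#' Threshold battery over levels, crops and land-system variables
#'
#' For every combination of watershed level, crop and constraint variable
#' (manure application rate, irrigated-area proportion, arable-land
#' proportion): fix the moving-window size on the risk series, compute
#' windowed improvement scores and their tradeoff, fit the inverted U of
#' the tradeoff against the windowed constraint variable, and return the
#' vertex threshold with its delta-method standard error. Combinations
#' whose quadratic term is nonnegative are reported as no-threshold;
#' failures (e.g. too few watersheds at coarse levels) are recorded, not
#' fatal.
#'
#' @param summaries_by_level list of watershed summary tables including
#'   `yield_<crop>` columns.
#' @param crops crop names (default maize, rice, wheat, vegetables).
#' @param variables constraint variables (default manure_rate,
#'   irrigated_prop, arable_prop).
#' @param candidate_sizes passed to [fix_window_size()].
#' @return data.frame: `level`, `crop`, `variable`, `threshold`, `se`,
#'   `a`, `r_squared`, `n_windows`, `chosen_w`, `status`
#'   ("ok", "no_threshold", or the error message).
#' @export
threshold_battery <- function(summaries_by_level,
                              crops = c("maize", "rice", "wheat", "vegetables"),
                              variables = c("manure_rate", "irrigated_prop",
                                            "arable_prop"),
                              candidate_sizes = NULL) {
  rows <- list()
  for (summ in summaries_by_level) {
    lev <- summ$level[1]
    for (crop in crops) {
      ycol <- paste0("yield_", crop)
      for (v in variables) {
        res <- tryCatch({
          if (!ycol %in% names(summ)) stop("missing ", ycol)
          mw <- fix_window_size(summ, order_by = v,
                                candidate_sizes = candidate_sizes)
          wd <- mw$windows
          tf <- tradeoff_value(improvement(wd[[ycol]]),
                               improvement(wd$cum_rq))
          fit <- fit_inverted_u(wd[[v]], tf)
          th <- threshold_from_fit(fit)
          data.frame(level = lev, crop = crop, variable = v,
                     threshold = th$threshold, se = th$se, a = fit$a,
                     r_squared = fit$r_squared, n_windows = nrow(wd),
                     chosen_w = mw$chosen_w,
                     status = if (th$defined) "ok" else "no_threshold")
        }, error = function(e) {
          data.frame(level = lev, crop = crop, variable = v,
                     threshold = NA_real_, se = NA_real_, a = NA_real_,
                     r_squared = NA_real_, n_windows = NA_integer_,
                     chosen_w = NA_integer_,
                     status = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
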