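# Scale-dependent watershed analysis: aggregate risk and land-system
# indicators to the four nested watershed levels, build the 20
# human-footprint omission subdatasets, run AICc-based all-subsets model
# averaging, and attribute explained variance to land use vs management.

LAND_SYSTEM_PREDICTORS <- c("arable_prop", "built_prop", "natural_prop",
                            "manure_rate", "irrigated_prop",
                            "population_density", "gdp")
LAND_USE_GROUP <- c("arable_prop", "built_prop", "natural_prop")
MANAGEMENT_GROUP <- c("manure_rate", "irrigated_prop")

#' Summarize risk and land-system indicators per watershed
#'
#' Means over the non-masked cells of each watershed at one nesting level:
#' cumulative RQ, land-use proportions (natural = grassland + forest
#' reclassification, generated directly here), management intensity,
#' socioeconomic pressure and the human-footprint ranking index. Watersheds
#' with no soil cells are excluded (their IDs are recorded in the
#' `excluded` attribute).
#'
#' @param risk_map cumulative RQ matrix (e.g. `risk_maps$mean`).
#' @param covariates an `agro_covariates`.
#' @param landscape an `agro_landscape`.
#' @param level watershed level, 1-4.
#' @param yields optional yield table from [generate_yields()] at the same
#'   level; spread into `yield_<crop>` columns.
#' @return data.frame, one row per watershed.
#' @export
summarize_watersheds <- function(risk_map, covariates, landscape, level,
                                 yields = NULL) {
  if (!level %in% seq_along(landscape$watershed_ids))
    stop("level must be in 1..", length(landscape$watershed_ids))
  labels <- landscape$watershed_ids[[level]]
  mask <- landscape$soil_mask
  all_ids <- sort(unique(as.vector(labels)))
  vars <- c("arable_prop", "built_prop", "natural_prop", "manure_rate",
            "irrigated_prop", "population_density", "gdp", "human_footprint")
  agg <- lapply(covariates[vars], aggregate_by_label, labels = labels,
                mask = mask)
  rq <- aggregate_by_label(risk_map, labels, mask)
  ids <- as.integer(names(rq))
  out <- data.frame(watershed_id = ids, level = level, cum_rq = as.vector(rq))
  for (v in vars) out[[v]] <- as.vector(agg[[v]][as.character(ids)])
  excluded <- setdiff(all_ids, ids)
  if (!is.null(yields)) {
    for (crop in unique(yields$crop)) {
      yc <- yields[yields$crop == crop, c("watershed_id", "yield")]
      out[[paste0("yield_", crop)]] <-
        yc$yield[match(out$watershed_id, yc$watershed_id)]
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' Land system intensification score per watershed
#'
#' Sum of the min-max standardized arable proportion, manure application
#' rate and irrigated-area proportion; each component lies in \[0, 1\] and
#' the score in \[0, 3\]. A constant component carries no information and
#' contributes 0, with a warning.
#'
#' @param summaries watershed summary table (see [summarize_watersheds()]).
#' @return numeric score vector aligned with `summaries` rows; the
#'   standardized components are attached as the `components` attribute.
#' @export
intensification_score <- function(summaries) {
  if (nrow(summaries) < 2) stop("need >= 2 watersheds for min-max scaling")
  comp <- sapply(c("arable_prop", "manure_rate", "irrigated_prop"),
                 function(v) {
    x <- summaries[[v]]
    if (diff(range(x)) == 0) {
      warning(sprintf("constant component '%s': contribution set to 0", v))
      rep(0, length(x))
    } else minmax(x)
  })
  score <- rowSums(comp)
  attr(score, "components") <- comp
  score
}

#' Build the 20 human-footprint omission subdatasets
#'
#' Watersheds are ranked by human footprint (ties broken by watershed ID).
#' For omission fractions f = 0.0, 0.1, ..., 0.9, the upper-omission
#' subdataset removes the ceiling(f * n) highest-footprint watersheds and
#' the lower-omission subdataset removes the lowest; f = 0 keeps the full
#' set on both sides, giving exactly 20 subdatasets.
#'
#' @param summaries watershed summary table with a `human_footprint` column
#'   and >= 10 rows.
#' @return list of 20 elements, each a list with `omission_side`,
#'   `omission_fraction`, `watershed_ids`, `level`.
#' @export
make_subdatasets <- function(summaries) {
  n <- nrow(summaries)
  if (n < 10) stop("omission granularity undefined for < 10 watersheds")
  ord <- order(summaries$human_footprint, summaries$watershed_id)
  ranked <- summaries$watershed_id[ord]           # ascending footprint
  out <- list()
  for (side in c("upper", "lower")) {
    for (f in seq(0, 0.9, by = 0.1)) {
      k <- ceiling(f * n)
      ids <- if (k == 0) ranked
      else if (side == "upper") ranked[seq_len(n - k)]
      else ranked[(k + 1):n]
      out[[length(out) + 1L]] <- list(
        omission_side = side, omission_fraction = f,
        watershed_ids = ids, level = summaries$level[1])
    }
  }
  out
}

# ---------------------------------------------------------------------------
# AICc all-subsets model averaging

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k+1)/(n - k - 1), with k the number of estimated
#' parameters (intercept, slopes and residual variance).
#'
#' @param model a fitted `lm`.
#' @return AICc value.
#' @export
aicc <- function(model) {
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  n <- stats::nobs(model)
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  stats::AIC(model) + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets AICc model averaging of standardized regressions
#'
#' Fits OLS models for every subset of the candidate predictors (response
#' and predictors Z-scored first), ranks them by AICc, retains the best-
#' model set with delta AICc below `delta` (2 by default, extendable to 5),
#' and averages coefficients with Akaike weights. Full averaging is the
#' default: a predictor absent from a model contributes a 0 coefficient;
#' conditional averaging (average only over models containing the
#' predictor) is available. Significance uses a two-sided z test on the
#' model-averaged coefficient and its unconditional standard error.
#'
#' Collinear predictors are dropped before enumeration (the redundant land
#' proportion `natural_prop` first), with a log entry in the result.
#'
#' @param data data.frame holding response and predictors.
#' @param response response column name (default `"cum_rq"`).
#' @param predictors candidate predictor names (default the land-system
#'   set: three land-use proportions, two management intensities,
#'   population and GDP).
#' @param delta AICc window for the best-model set (default 2).
#' @param averaging "full" (default) or "conditional".
#' @return object of class `agro_model_average`: list with `coefficients`
#'   (data.frame: predictor, beta, se, z, p, significant), `models`
#'   (AICc table of every subset), `best` (indices of the best set),
#'   `r_squared` (global model), `n`, `delta`, `dropped`.
#' @export
fit_model_average <- function(data, response = "cum_rq",
                              predictors = LAND_SYSTEM_PREDICTORS,
                              delta = 2, averaging = c("full", "conditional")) {
  averaging <- match.arg(averaging)
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  n <- nrow(data)
  if (n < length(predictors) + 5)
    stop("need at least predictors + 5 rows, got ", n)
  zs <- function(x) if (stats::sd(x) == 0) x - mean(x) else
    (x - mean(x)) / stats::sd(x)
  d <- as.data.frame(lapply(data[c(response, predictors)], zs))
  names(d) <- c(".y", predictors)
  # collinearity guard: drop rank-deficient predictors, natural_prop first
  dropped <- character(0)
  ordered_preds <- c(setdiff(predictors, "natural_prop"),
                     intersect("natural_prop", predictors))
  while (length(ordered_preds) > 1 &&
         qr(cbind(1, as.matrix(d[ordered_preds])))$rank <
           length(ordered_preds) + 1) {
    drop_cand <- ordered_preds[length(ordered_preds)]
    dropped <- c(dropped, drop_cand)
    ordered_preds <- ordered_preds[-length(ordered_preds)]
  }
  predictors <- intersect(predictors, ordered_preds)
  p <- length(predictors)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  colnames(subsets) <- predictors
  Xall <- cbind(`(Intercept)` = 1, as.matrix(d[predictors]))
  yv <- d$.y
  n_models <- nrow(subsets)
  tab <- data.frame(model = seq_len(n_models), k = NA_real_,
                    aicc = NA_real_)
  betas <- ses <- matrix(0, n_models, p, dimnames = list(NULL, predictors))
  rss_all <- numeric(n_models)
  for (i in seq_len(n_models)) {
    cols <- c(TRUE, subsets[i, ])
    fit <- stats::lm.fit(Xall[, cols, drop = FALSE], yv)
    rss <- sum(fit$residuals^2)
    rss_all[i] <- rss
    k <- fit$rank + 1                    # slopes + intercept + sigma
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    tab$k[i] <- k
    tab$aicc[i] <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    inc <- predictors[subsets[i, ]]
    if (length(inc)) {
      sigma2 <- rss / (n - fit$rank)
      R <- qr.R(fit$qr)
      cov <- chol2inv(R) * sigma2
      cn <- colnames(Xall)[cols]
      se_i <- sqrt(diag(cov))
      betas[i, inc] <- fit$coefficients[match(inc, cn)]
      ses[i, inc] <- se_i[match(inc, cn)]
    }
  }
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  best <- which(tab$delta_aicc < delta)
  w <- exp(-0.5 * tab$delta_aicc[best])
  w <- w / sum(w)
  coefs <- data.frame(predictor = predictors, beta = 0, se = 0)
  for (j in seq_len(p)) {
    present <- subsets[best, j]
    bj <- betas[best, j]; sej <- ses[best, j]
    if (averaging == "full") {
      wj <- w
    } else {
      if (!any(present)) { coefs$beta[j] <- NA; coefs$se[j] <- NA; next }
      wj <- ifelse(present, w, 0); wj <- wj / sum(wj)
    }
    bbar <- sum(wj * bj)
    # unconditional SE: within-model variance plus between-model spread
    coefs$beta[j] <- bbar
    coefs$se[j] <- sqrt(sum(wj * (sej^2 + (bj - bbar)^2)))
  }
  coefs$z <- ifelse(coefs$se > 0, coefs$beta / coefs$se, 0)
  coefs$p <- 2 * stats::pnorm(-abs(coefs$z))
  coefs$significant <- !is.na(coefs$p) & coefs$p < 0.05
  r2 <- 1 - rss_all[n_models] / rss_all[1]    # global vs intercept-only
  structure(list(coefficients = coefs, models = tab, best = best,
                 weights = w, r_squared = r2,
                 n = n, delta = delta, averaging = averaging,
                 dropped = dropped),
            class = "agro_model_average")
}

#' Contribution percentages from standardized coefficients
#'
#' Each predictor's contribution to explained variance is |beta_i| divided
#' by the sum of |beta_j| over all predictors, times 100, so contributions
#' are nonnegative and sum to 100. Grouped totals are returned for land use
#' (arable, built, natural) and management (manure rate, irrigated
#' proportion); predictors outside both groups (population, GDP) form an
#' "other" group.
#'
#' @param coefficients data.frame with `predictor` and `beta` columns (as in
#'   `agro_model_average$coefficients`) or a named beta vector.
#' @return list with `by_predictor` (data.frame predictor/contribution) and
#'   `by_group` (named vector: land_use, management, other).
#' @export
contribution_percentages <- function(coefficients) {
  if (is.numeric(coefficients))
    coefficients <- data.frame(predictor = names(coefficients),
                               beta = unname(coefficients))
  b <- coefficients$beta
  tot <- sum(abs(b), na.rm = TRUE)
  if (tot == 0) stop("contributions undefined: all coefficients are zero")
  contrib <- 100 * abs(b) / tot
  by_pred <- data.frame(predictor = coefficients$predictor,
                        contribution = contrib)
  grp <- ifelse(coefficients$predictor %in% LAND_USE_GROUP, "land_use",
                ifelse(coefficients$predictor %in% MANAGEMENT_GROUP,
                       "management", "other"))
  bg <- tapply(contrib, factor(grp, c("land_use", "management", "other")),
               sum, default = 0)
  list(by_predictor = by_pred,
       by_group = stats::setNames(as.vector(bg), names(bg)))
}

#' Run the full scale battery: 4 levels x 20 omission subdatasets
#'
#' For every watershed level, builds the 20 human-footprint omission
#' subdatasets and fits the AICc model average on each. Returns per level
#' and predictor the counts of significantly positive / significantly
#' negative / nonsignificant relationships across the 20 analyses, the mean
#' and SD of the grouped contribution percentages, and the mean global-model
#' R-squared.
#'
#' @param summaries_by_level list of watershed summary tables, one per
#'   level (names/order = levels).
#' @param predictors candidate predictors (default land-system set).
#' @param delta AICc window (default 2).
#' @param response response column (default `"cum_rq"`).
#' @return list with `counts` (data.frame level x predictor), `contributions`
#'   (data.frame level x group, mean and sd over analyses), `r_squared`
#'   (per-level mean), `failures` (per-level count of failed fits).
#' @export
run_scale_battery <- function(summaries_by_level,
                              predictors = LAND_SYSTEM_PREDICTORS,
                              delta = 2, response = "cum_rq") {
  counts <- list(); contribs <- list(); r2 <- list(); failures <- list()
  for (li in seq_along(summaries_by_level)) {
    summ <- summaries_by_level[[li]]
    lev <- summ$level[1]
    subs <- make_subdatasets(summ)
    sig_pos <- sig_neg <- nonsig <- stats::setNames(rep(0, length(predictors)),
                                                    predictors)
    grp <- list(); r2s <- c(); fail <- 0
    for (sd_ in subs) {
      rows <- summ[summ$watershed_id %in% sd_$watershed_ids, , drop = FALSE]
      ma <- tryCatch(fit_model_average(rows, response = response,
                                       predictors = predictors,
                                       delta = delta),
                     error = function(e) NULL)
      if (is.null(ma)) { fail <- fail + 1; next }
      cf <- ma$coefficients
      for (j in seq_len(nrow(cf))) {
        nm <- cf$predictor[j]
        if (isTRUE(cf$significant[j])) {
          if (cf$beta[j] > 0) sig_pos[nm] <- sig_pos[nm] + 1
          else sig_neg[nm] <- sig_neg[nm] + 1
        } else nonsig[nm] <- nonsig[nm] + 1
      }
      ctb <- tryCatch(contribution_percentages(cf), error = function(e) NULL)
      if (!is.null(ctb)) grp[[length(grp) + 1L]] <- ctb$by_group
      r2s <- c(r2s, ma$r_squared)
    }
    counts[[li]] <- data.frame(level = lev, predictor = predictors,
                               sig_positive = unname(sig_pos),
                               sig_negative = unname(sig_neg),
                               nonsignificant = unname(nonsig))
    gm <- do.call(rbind, grp)
    contribs[[li]] <- data.frame(
      level = lev, group = colnames(gm),
      mean = colMeans(gm), sd = apply(gm, 2, stats::sd),
      n_analyses = nrow(gm), row.names = NULL)
    r2[[li]] <- data.frame(level = lev, mean_r_squared = mean(r2s))
    failures[[li]] <- data.frame(level = lev, failed = fail)
  }
  list(counts = do.call(rbind, counts),
       contributions = do.call(rbind, contribs),
       r_squared = do.call(rbind, r2),
       failures = do.call(rbind, failures))
}
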