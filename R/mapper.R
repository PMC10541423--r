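# Spatial upscaling of site risk quotients with an ensemble of random
# forests: harmonize grids, extract year-matched features at sampling sites,
# train a Monte-Carlo ensemble on log10 RQs, and predict per-cell mean, SD
# and relative-uncertainty maps with a soil mask.

#' Resample a grid by an integer factor
#'
#' Downsampling uses block means (mean aggregation); upsampling replicates
#' each value into a factor x factor block (simple upsampling, no
#' interpolation). Downsampling a grid whose shape is not divisible by the
#' factor is an error unless `pad = TRUE`, in which case edge blocks are
#' averaged over the available cells.
#'
#' @param grid numeric matrix.
#' @param factor positive integer resampling factor.
#' @param direction "down" (aggregate) or "up" (replicate).
#' @param pad allow non-divisible shapes when downsampling.
#' @return resampled matrix.
#' @export
regrid <- function(grid, factor, direction = c("down", "up"), pad = FALSE) {
  direction <- match.arg(direction)
  if (factor != round(factor) || factor < 1) stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  if (direction == "up") {
    grid[rep(seq_len(nrow(grid)), each = factor),
         rep(seq_len(ncol(grid)), each = factor), drop = FALSE]
  } else {
    if (!pad && (nrow(grid) %% factor || ncol(grid) %% factor))
      stop(sprintf(
        "grid shape %dx%d not divisible by factor %d (set pad = TRUE to average partial edge blocks)",
        nrow(grid), ncol(grid), factor))
    ri <- (seq_len(nrow(grid)) - 1L) %/% factor
    ci <- (seq_len(ncol(grid)) - 1L) %/% factor
    out <- rowsum(t(rowsum(grid, ri, reorder = TRUE)), ci, reorder = TRUE)
    cnt <- tcrossprod(tabulate(ci + 1L), tabulate(ri + 1L))
    out <- t(out) / t(cnt)
    dimnames(out) <- NULL
    out
  }
}

#' Extract a standardized feature matrix and log-RQ targets at sites
#'
#' One row per record: the covariate values at the record's grid cell, with
#' time-varying covariates matched to the sampling year. Features are
#' Z-score standardized using the mean/SD of the extracted rows; the
#' parameters are stored so cell-level prediction uses the same scaling.
#' Targets are log10(RQ + delta): delta is 0 when every RQ is positive and
#' otherwise half the smallest nonzero RQ (recorded in the output), so zero
#' RQs stay finite and ordering is preserved.
#'
#' @param records data.frame with `x`, `y`, `year` and an `rq` column (see
#'   [rq_table()]).
#' @param covariates an `agro_covariates`.
#' @param predictors covariate names to use (default all).
#' @param year_matching match time-varying covariates to sampling year.
#' @return list with `features` (standardized matrix), `targets`
#'   (log10-transformed RQs), `center`, `scale`, `delta`, `predictors`.
#' @export
extract_features <- function(records, covariates,
                             predictors = names(covariates),
                             year_matching = TRUE) {
  shp <- dim(covariates[[1]])
  bad <- records$y < 1 | records$y > shp[1] | records$x < 1 | records$x > shp[2]
  if (any(bad))
    stop("records outside grid bounds at rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  n <- nrow(records)
  cells <- (records$x - 1L) * shp[1] + records$y
  feats <- matrix(0, n, length(predictors),
                  dimnames = list(NULL, predictors))
  tv <- names(attr(covariates, "meta")$time_varying)
  for (nm in predictors) {
    if (year_matching && nm %in% tv) {
      for (yr in unique(records$year)) {
        idx <- records$year == yr
        feats[idx, nm] <- covariate_at(covariates, nm, yr)[cells[idx]]
      }
    } else {
      feats[, nm] <- covariates[[nm]][cells]
    }
  }
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, stats::sd)
  scl[scl == 0] <- 1
  feats <- sweep(sweep(feats, 2, ctr), 2, scl, "/")
  rq <- records$rq
  nz <- rq[rq > 0]
  delta <- if (!any(rq == 0)) 0 else if (length(nz)) min(nz) * 0.5 else 1e-6
  list(features = feats, targets = log10(rq + delta),
       center = ctr, scale = scl, delta = delta, predictors = predictors)
}

#' Fit a Monte-Carlo ensemble of random forests
#'
#' Trains `n_members` random forests, each on an independent bootstrap
#' resample of the training rows (optionally a random 70% subset instead),
#' so the spread of member predictions measures model uncertainty.
#'
#' @param features standardized feature matrix.
#' @param targets numeric response (log10 RQ).
#' @param n_members ensemble size (default 500).
#' @param max_trees trees per member forest (default 1000).
#' @param resampling "bootstrap" (default) or "subset" (random 70% of rows).
#' @param mtry predictors tried per split; default max(1, p/3) as is
#'   conventional for regression forests.
#' @param seed integer seed; members get derived sub-seeds.
#' @return object of class `agro_ensemble`.
#' @export
fit_ensemble <- function(features, targets, n_members = 500, max_trees = 1000,
                         resampling = c("bootstrap", "subset"),
                         mtry = NULL, seed = 1) {
  resampling <- match.arg(resampling)
  if (nrow(features) < 20) stop("need >= 20 training rows")
  if (stats::sd(targets) == 0)
    warning("constant targets: ensemble will predict a constant")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(features) / 3))
  members <- vector("list", n_members)
  samples <- vector("list", n_members)
  df <- data.frame(.y = targets, features, check.names = FALSE)
  for (m in seq_len(n_members)) {
    s <- derive_seed(seed, paste0("member", m))
    idx <- with_seed(s, {
      if (resampling == "bootstrap")
        sample(nrow(df), replace = TRUE)
      else sample(nrow(df), max(2L, floor(0.7 * nrow(df))))
    })
    members[[m]] <- ranger::ranger(
      dependent.variable.name = ".y", data = df[idx, , drop = FALSE],
      num.trees = max_trees, mtry = min(mtry, ncol(features)),
      seed = s, num.threads = 1, verbose = FALSE)
    samples[[m]] <- idx
  }
  structure(list(members = members, samples = samples,
                 n_members = n_members, max_trees = max_trees,
                 resampling = resampling, mtry = mtry, seed = seed,
                 predictors = colnames(features)),
            class = "agro_ensemble")
}

#' Predict with every ensemble member
#' @param ensemble an `agro_ensemble`.
#' @param features standardized feature matrix (training scaling).
#' @return matrix: rows = feature rows, columns = members.
#' @export
predict_members <- function(ensemble, features) {
  df <- as.data.frame(features, check.names = FALSE)
  vapply(ensemble$members, function(m)
    stats::predict(m, data = df, num.threads = 1)$predictions,
    numeric(nrow(df)))
}

#' Accuracy of observed vs predicted values
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return list with `rmse` and `pearson_r`.
#' @export
cv_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  list(rmse = sqrt(mean((observed - predicted)^2)),
       pearson_r = if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
         NA_real_ else stats::cor(observed, predicted))
}

#' Hold-out validation of the ensemble mapper
#'
#' Randomly splits rows into training (70% by default) and validation sets,
#' fits an ensemble on the training rows only, and reports RMSE and
#' Pearson's r between observed and ensemble-mean predicted targets on the
#' validation set.
#'
#' @param features standardized feature matrix.
#' @param targets numeric response.
#' @param train_frac training fraction (default 0.7).
#' @param n_members,max_trees ensemble parameters for the validation fit.
#' @param seed integer seed controlling the split and the fit.
#' @return list with `rmse`, `pearson_r`, `n_train`, `n_validation`,
#'   `train_frac`, `seed`.
#' @export
cross_validate <- function(features, targets, train_frac = 0.7,
                           n_members = 25, max_trees = 500, seed = 1) {
  n <- nrow(features)
  if (n < 10) stop("need >= 10 rows for hold-out validation")
  idx <- with_seed(derive_seed(seed, "split"),
                   sample(n, floor(train_frac * n)))
  if (length(idx) >= n || length(idx) < 20)
    stop("too few rows for a 70/30 hold-out with >= 20 training rows")
  ens <- fit_ensemble(features[idx, , drop = FALSE], targets[idx],
                      n_members = n_members, max_trees = max_trees,
                      seed = seed)
  pred <- rowMeans(predict_members(ens, features[-idx, , drop = FALSE]))
  m <- cv_metrics(targets[-idx], pred)
  c(m, list(n_train = length(idx), n_validation = n - length(idx),
            train_frac = train_frac, seed = seed))
}

#' Predict risk maps with ensemble uncertainty
#'
#' Applies the ensemble to every grid cell: features are built from the
#' covariate grids, standardized with the training parameters, predicted by
#' every member, back-transformed member-wise to the RQ scale
#' (10^pred - delta, clipped at 0), and summarized as the per-cell mean, SD
#' and relative uncertainty (SD/mean). Non-soil cells are NA everywhere;
#' relative uncertainty is also NA where the mean is 0.
#'
#' @param ensemble an `agro_ensemble`.
#' @param covariates an `agro_covariates` containing every predictor.
#' @param soil_mask logical matrix (TRUE = soil).
#' @param center,scale,delta training standardization parameters (from
#'   [extract_features()]).
#' @param log_scale if TRUE, average in log space instead of back-
#'   transforming per member (default FALSE).
#' @return object of class `risk_maps`: list with `mean`, `sd`,
#'   `relative_uncertainty` matrices and `member_matrix` (soil cells x
#'   members, on the RQ scale) for downstream cumulative summaries.
#' @export
predict_maps <- function(ensemble, covariates, soil_mask, center, scale,
                         delta, log_scale = FALSE) {
  missing <- setdiff(ensemble$predictors, names(covariates))
  if (length(missing))
    stop("missing covariate grids: ", paste(missing, collapse = ", "))
  shp <- dim(covariates[[1]])
  cells <- which(soil_mask)
  feats <- vapply(ensemble$predictors,
                  function(nm) covariates[[nm]][cells], numeric(length(cells)))
  feats <- sweep(sweep(feats, 2, center[ensemble$predictors]), 2,
                 scale[ensemble$predictors], "/")
  pm <- predict_members(ensemble, feats)
  if (log_scale) {
    mu_log <- rowMeans(pm)
    sd_log <- apply(pm, 1, stats::sd)
    mu <- pmax(10^mu_log - delta, 0)
    sdv <- mu * log(10) * sd_log      # delta-method SD on the RQ scale
    member_rq <- pmax(10^pm - delta, 0)
  } else {
    member_rq <- pmax(10^pm - delta, 0)
    mu <- rowMeans(member_rq)
    sdv <- apply(member_rq, 1, stats::sd)
  }
  blank <- matrix(NA_real_, shp[1], shp[2])
  mean_g <- blank; mean_g[cells] <- mu
  sd_g <- blank; sd_g[cells] <- sdv
  rel <- blank; rel[cells] <- ifelse(mu > 0, sdv / mu, NA_real_)
  structure(list(mean = mean_g, sd = sd_g, relative_uncertainty = rel,
                 member_matrix = member_rq, cells = cells, delta = delta),
            class = "risk_maps")
}

#' Combine per-compound risk maps into a cumulative map
#'
#' Concentration addition at the map level: the cumulative mean map is the
#' sum of the per-compound ensemble mean maps; the cumulative SD is taken
#' over member-wise cumulative sums (members are aligned by index).
#'
#' @param maps list of `risk_maps`, one per compound (same grid and mask).
#' @return a `risk_maps` for the cumulative RQ.
#' @export
cumulative_risk_maps <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  cells <- maps[[1]]$cells
  member_sum <- Reduce(`+`, lapply(maps, function(m) m$member_matrix))
  mu <- rowMeans(member_sum)
  sdv <- apply(member_sum, 1, stats::sd)
  shp <- dim(maps[[1]]$mean)
  blank <- matrix(NA_real_, shp[1], shp[2])
  mean_g <- blank; mean_g[cells] <- mu
  sd_g <- blank; sd_g[cells] <- sdv
  rel <- blank; rel[cells] <- ifelse(mu > 0, sdv / mu, NA_real_)
  structure(list(mean = mean_g, sd = sd_g, relative_uncertainty = rel,
                 member_matrix = member_sum, cells = cells, delta = NA),
            class = "risk_maps")
}
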