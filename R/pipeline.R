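# End-to-end orchestration: synthetic landscape -> risk assessment ->
# ensemble upscaling -> scale battery -> tradeoff thresholds, with a
# serialized configuration, per-stage logs, file digests and a provenance
# record, so a run is reproducible from its output directory alone.

#' Default pipeline configuration
#'
#' Desk-scale demonstration settings: a 32 x 32 landscape with 2 level-1
#' watersheds branching 3-fold per level, 120 sampling sites, a 25-member
#' forest ensemble, the standard AICc window of 2 and the 99%/1% constraint
#' quantiles.
#'
#' @param seed root seed; per-stage seeds are derived from it.
#' @param ... overrides for any config entry.
#' @return named list of class `agro_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    rows = 32, cols = 32, n_level1 = 2, branching = 3,
    autocorr_range = 4, mask_frac = 0.05,
    n_sites = 120, detection_limit = 0.01,
    n_members = 25, max_trees = 300, train_frac = 0.7,
    delta_aicc = 2,
    upper_quantile = 0.99, lower_quantile = 0.01,
    window_candidates = NULL,
    yield_level = 4, yield_noise_sd = 0.02,
    stages = c("synth", "risk", "mapper", "scales", "tradeoff")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "agro_config")
}

validate_config <- function(config) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  miss <- setdiff(names(ref), names(config))
  if (length(miss)) stop("missing config keys: ", paste(miss, collapse = ", "))
  stopifnot(all(config$stages %in% ref$stages))
  invisible(config)
}

stage_file <- function(dir, ...) file.path(dir, paste0(...))

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order (synth, risk, mapper, scales,
#' tradeoff), writing every intermediate table as CSV, every grid as a
#' plain-text TSV matrix, the planted truth and the configuration as YAML,
#' and a provenance record (config snapshot, package version, per-stage
#' wall-clock and output-file digests). A disabled stage whose outputs are
#' required downstream raises a dependency error naming the stage.
#'
#' @param config an `agro_config` (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return the provenance record, invisibly; all outputs on disk.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  prov <- list(config = unclass(config),
               package_version = as.character(utils::packageVersion("agrorisk")),
               stages = list())
  state <- new.env(parent = emptyenv())

  need <- function(what, from_stage) {
    if (!exists(what, envir = state)) {
      loaded <- try(suppressWarnings(load_state(state, what, out_dir)),
                    silent = TRUE)
      if (inherits(loaded, "try-error"))
        stop(sprintf(
          "stage dependency error: '%s' requires outputs of stage '%s' (missing '%s')",
          stage_current, from_stage, what), call. = FALSE)
    }
    get(what, envir = state)
  }
  stage_current <- NA_character_
  run_stage <- function(name, fn) {
    stage_current <<- name
    t0 <- Sys.time()
    files <- fn()
    prov$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      files = as.list(tools::md5sum(files)))
  }

  if ("synth" %in% stages) run_stage("synth", function() {
    ls <- generate_landscape(config$rows, config$cols, config$n_level1,
                             config$branching, seed = config$seed,
                             mask_frac = config$mask_frac)
    cv <- generate_covariates(ls, config$autocorr_range, seed = config$seed)
    tr <- planted_truth(seed = config$seed)
    mec <- generate_mec_samples(ls, cv, tr, config$n_sites,
                                config$detection_limit, seed = config$seed)
    assign("landscape", ls, state); assign("covariates", cv, state)
    assign("truth", tr, state); assign("mec", mec, state)
    files <- c()
    for (k in seq_along(ls$watershed_ids))
      files <- c(files, write_grid(ls$watershed_ids[[k]],
                                   stage_file(out_dir, "watershed_level", k, ".tsv")))
    files <- c(files, write_grid(ls$soil_mask * 1,
                                 stage_file(out_dir, "soil_mask.tsv")))
    for (nm in names(cv))
      files <- c(files, write_grid(cv[[nm]],
                                   stage_file(out_dir, "cov_", nm, ".tsv")))
    yaml::write_yaml(attr(cv, "meta"), stage_file(out_dir, "covariates_meta.yaml"))
    write_truth(tr, stage_file(out_dir, "truth.yaml"))
    utils::write.csv(mec, stage_file(out_dir, "mec_records.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(grid_shape = as.list(ls$grid_shape),
                          params = ls$params),
                     stage_file(out_dir, "landscape_meta.yaml"))
    c(files, stage_file(out_dir, c("covariates_meta.yaml", "truth.yaml",
                                   "mec_records.csv", "landscape_meta.yaml")))
  })

  if ("risk" %in% stages) run_stage("risk", function() {
    mec <- need("mec", "synth")
    tox <- load_toxicity_table()
    fl <- filter_records(mec)
    rq <- rq_table(fl$kept, tox)
    cum <- cumulative_rq(rq)
    site_xy <- unique(rq[c("site_id", "x", "y")])
    cum <- merge(cum, site_xy, by = "site_id", sort = TRUE)
    mi <- morans_i(cum$cum_rq, spatial_weights(cum$x, cum$y, "idw"))
    assign("rq", rq, state); assign("cum", cum, state)
    utils::write.csv(rq, stage_file(out_dir, "site_rq.csv"), row.names = FALSE)
    utils::write.csv(cum, stage_file(out_dir, "site_cumulative_rq.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(rejections = as.list(fl$log),
                          morans_i = mi[c("I", "z_score", "p_value")]),
                     stage_file(out_dir, "risk_log.yaml"))
    stage_file(out_dir, c("site_rq.csv", "site_cumulative_rq.csv",
                          "risk_log.yaml"))
  })

  if ("mapper" %in% stages) run_stage("mapper", function() {
    rq <- need("rq", "risk")
    cv <- need("covariates", "synth")
    ls <- need("landscape", "synth")
    cvm <- list(); maps <- list()
    preds <- setdiff(names(cv), "human_footprint")
    for (cmp in unique(rq$compound)) {
      rc <- rq[rq$compound == cmp, , drop = FALSE]
      fx <- extract_features(rc, cv, predictors = preds)
      m <- cross_validate(fx$features, fx$targets,
                          train_frac = config$train_frac,
                          n_members = config$n_members,
                          max_trees = config$max_trees,
                          seed = derive_seed(config$seed, paste0("cv", cmp)))
      cvm[[cmp]] <- data.frame(compound = cmp, rmse = m$rmse,
                               pearson_r = m$pearson_r,
                               n_train = m$n_train,
                               n_validation = m$n_validation)
      ens <- fit_ensemble(fx$features, fx$targets,
                          n_members = config$n_members,
                          max_trees = config$max_trees,
                          seed = derive_seed(config$seed, paste0("ens", cmp)))
      maps[[cmp]] <- predict_maps(ens, cv, ls$soil_mask, fx$center,
                                  fx$scale, fx$delta)
    }
    cum_map <- cumulative_risk_maps(maps)
    assign("cum_map", cum_map, state)
    files <- c(
      write_grid(cum_map$mean, stage_file(out_dir, "map_cum_rq_mean.tsv")),
      write_grid(cum_map$sd, stage_file(out_dir, "map_cum_rq_sd.tsv")),
      write_grid(cum_map$relative_uncertainty,
                 stage_file(out_dir, "map_cum_rq_reluncert.tsv")))
    cvt <- do.call(rbind, cvm)
    utils::write.csv(cvt, stage_file(out_dir, "cv_metrics.csv"),
                     row.names = FALSE)
    c(files, stage_file(out_dir, "cv_metrics.csv"))
  })

  if ("scales" %in% stages) run_stage("scales", function() {
    cum_map <- need("cum_map", "mapper")
    cv <- need("covariates", "synth")
    ls <- need("landscape", "synth")
    tr <- need("truth", "synth")
    ig <- intensification_grid(cv)
    summ <- list()
    for (lev in seq_along(ls$watershed_ids)) {
      yl <- generate_yields(ls, ig, cum_map$mean, tr, level = lev,
                            noise_sd = config$yield_noise_sd,
                            seed = config$seed)
      summ[[lev]] <- summarize_watersheds(cum_map$mean, cv, ls, lev,
                                          yields = yl)
      summ[[lev]]$intensification <- tryCatch(
        as.vector(intensification_score(summ[[lev]])),
        error = function(e) NA_real_)
    }
    assign("summaries", summ, state)
    files <- c()
    for (lev in seq_along(summ)) {
      f <- stage_file(out_dir, "watershed_summary_level", lev, ".csv")
      utils::write.csv(summ[[lev]], f, row.names = FALSE)
      files <- c(files, f)
    }
    # the omission battery needs >= 10 watersheds per level
    usable <- Filter(function(s) nrow(s) >= 10, summ)
    if (length(usable)) {
      bat <- run_scale_battery(usable, delta = config$delta_aicc)
      utils::write.csv(bat$counts, stage_file(out_dir, "battery_counts.csv"),
                       row.names = FALSE)
      utils::write.csv(bat$contributions,
                       stage_file(out_dir, "battery_contributions.csv"),
                       row.names = FALSE)
      utils::write.csv(bat$r_squared, stage_file(out_dir, "battery_r2.csv"),
                       row.names = FALSE)
      files <- c(files, stage_file(out_dir, c("battery_counts.csv",
                                              "battery_contributions.csv",
                                              "battery_r2.csv")))
    }
    files
  })

  if ("tradeoff" %in% stages) run_stage("tradeoff", function() {
    summ <- need("summaries", "scales")
    files <- c()
    # yield-risk breakpoints at the finest level with enough watersheds
    fine <- summ[[length(summ)]]
    bps <- list()
    for (crop in c("maize", "rice", "wheat", "vegetables")) {
      ycol <- paste0("yield_", crop)
      bp <- tryCatch(fit_yield_breakpoint(fine$cum_rq, fine[[ycol]], crop),
                     error = function(e) NULL)
      if (!is.null(bp))
        bps[[crop]] <- data.frame(crop = crop, breakpoint = bp$breakpoint,
                                  has_breakpoint = bp$has_breakpoint,
                                  adj_r_squared = bp$adj_r_squared,
                                  p_smooth = bp$p_smooth)
    }
    if (length(bps)) {
      utils::write.csv(do.call(rbind, bps),
                       stage_file(out_dir, "yield_breakpoints.csv"),
                       row.names = FALSE)
      files <- c(files, stage_file(out_dir, "yield_breakpoints.csv"))
    }
    # constraint lines of scaled yield / scaled risk vs intensification
    cls <- list()
    for (lev in seq_along(summ)) {
      s <- summ[[lev]]
      if (nrow(s) < 10 || !is.finite(s$intensification[1])) next
      for (resp in c("yield_vegetables", "cum_rq")) {
        side <- if (resp == "cum_rq") "lower" else "upper"
        cl <- tryCatch(
          constraint_line(s$intensification, improvement(s[[resp]]),
                          level = lev, side = side),
          error = function(e) NULL)
        if (!is.null(cl))
          cls[[length(cls) + 1L]] <- cbind(level = lev, response = resp, cl)
      }
    }
    if (length(cls)) {
      utils::write.csv(do.call(rbind, cls),
                       stage_file(out_dir, "constraint_lines.csv"),
                       row.names = FALSE)
      files <- c(files, stage_file(out_dir, "constraint_lines.csv"))
    }
    bat <- threshold_battery(summ, candidate_sizes = config$window_candidates)
    utils::write.csv(bat, stage_file(out_dir, "threshold_table.csv"),
                     row.names = FALSE)
    c(files, stage_file(out_dir, "threshold_table.csv"))
  })

  yaml::write_yaml(unclass(config), stage_file(out_dir, "config.yaml"))
  yaml::write_yaml(prov, stage_file(out_dir, "provenance.yaml"))
  invisible(prov)
}

# Reload objects a disabled upstream stage would have produced.
load_state <- function(state, what, dir) {
  if (what == "landscape") {
    meta <- yaml::read_yaml(file.path(dir, "landscape_meta.yaml"))
    n_levels <- meta$params$n_levels
    ws <- lapply(seq_len(n_levels), function(k) {
      m <- read_grid(file.path(dir, paste0("watershed_level", k, ".tsv")))
      storage.mode(m) <- "integer"; m
    })
    ls <- structure(list(
      grid_shape = c(rows = meta$grid_shape$rows, cols = meta$grid_shape$cols),
      watershed_ids = ws,
      soil_mask = read_grid(file.path(dir, "soil_mask.tsv")) > 0,
      params = meta$params), class = "agro_landscape")
    assign("landscape", ls, state)
  } else if (what == "covariates") {
    meta <- yaml::read_yaml(file.path(dir, "covariates_meta.yaml"))
    grids <- lapply(COVARIATE_NAMES, function(nm)
      read_grid(file.path(dir, paste0("cov_", nm, ".tsv"))))
    names(grids) <- COVARIATE_NAMES
    meta$time_varying <- unlist(meta$time_varying)
    cv <- structure(grids, class = "agro_covariates", meta = meta)
    assign("covariates", cv, state)
  } else if (what == "truth") {
    tr <- yaml::read_yaml(file.path(dir, "truth.yaml"))
    tr$mec_coefficients <- lapply(tr$mec_coefficients, unlist)
    tr$mec_intercept <- unlist(tr$mec_intercept)
    tr$noise_sd <- unlist(tr$noise_sd)
    tr$tradeoff_vertex <- unlist(tr$tradeoff_vertex)
    class(tr) <- "agro_truth"
    assign("truth", tr, state)
  } else if (what == "mec") {
    mec <- utils::read.csv(file.path(dir, "mec_records.csv"),
                           stringsAsFactors = FALSE)
    if (!file.exists(file.path(dir, "mec_records.csv"))) stop("missing")
    assign("mec", mec, state)
  } else if (what == "rq") {
    assign("rq", utils::read.csv(file.path(dir, "site_rq.csv"),
                                 stringsAsFactors = FALSE), state)
  } else if (what == "cum_map") {
    m <- read_grid(file.path(dir, "map_cum_rq_mean.tsv"))
    assign("cum_map", list(mean = m), state)
  } else if (what == "summaries") {
    files <- list.files(dir, "^watershed_summary_level[0-9]+\\.csv$")
    if (!length(files)) stop("missing summaries")
    ord <- order(as.integer(gsub("\\D", "", files)))
    assign("summaries", lapply(files[ord], function(f)
      utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)), state)
  } else stop("unknown state object: ", what)
  invisible(TRUE)
}

#' Validate a pipeline run directory
#'
#' Re-checks output schemas and invariants: required files present, land
#' proportions and improvement scores within \[0, 1\], grouped contribution
#' percentages summing to 100, the threshold table covering levels x crops
#' x variables, and file digests matching the provenance record.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return data.frame of violations (zero rows when the run is intact),
#'   columns `check`, `file`, `detail`.
#' @export
validate_run <- function(run_dir) {
  v <- list()
  note <- function(check, file, detail)
    v[[length(v) + 1L]] <<- data.frame(check = check, file = file,
                                       detail = detail)
  prov_path <- file.path(run_dir, "provenance.yaml")
  if (!file.exists(prov_path)) {
    note("missing_file", "provenance.yaml", "no provenance record")
    return(do.call(rbind, v))
  }
  prov <- yaml::read_yaml(prov_path)
  for (stage in names(prov$stages)) {
    for (f in names(prov$stages[[stage]]$files)) {
      digest <- prov$stages[[stage]]$files[[f]]
      if (!file.exists(f)) {
        note("integrity", basename(f), sprintf("stage '%s' output deleted", stage))
      } else if (!identical(unname(tools::md5sum(f)), digest)) {
        note("integrity", basename(f), sprintf("digest mismatch (stage '%s')", stage))
      }
    }
  }
  for (f in list.files(run_dir, "^watershed_summary_level[0-9]+\\.csv$",
                       full.names = TRUE)) {
    s <- utils::read.csv(f)
    for (col in c("arable_prop", "built_prop", "natural_prop",
                  "irrigated_prop")) {
      bad <- which(s[[col]] < 0 | s[[col]] > 1)
      for (b in bad)
        note("proportion_range", basename(f),
             sprintf("row %d: %s = %g outside [0, 1]", b, col, s[[col]][b]))
    }
  }
  cf <- file.path(run_dir, "battery_contributions.csv")
  if (file.exists(cf)) {
    ct <- utils::read.csv(cf)
    for (lev in unique(ct$level)) {
      tot <- sum(ct$mean[ct$level == lev])
      if (abs(tot - 100) > 1e-6)
        note("contribution_sum", basename(cf),
             sprintf("level %d group means sum to %g, not 100", lev, tot))
    }
  }
  tf <- file.path(run_dir, "threshold_table.csv")
  if (file.exists(tf)) {
    tt <- utils::read.csv(tf)
    expected <- length(unique(tt$level)) * length(unique(tt$crop)) *
      length(unique(tt$variable))
    if (nrow(tt) != expected)
      note("threshold_shape", basename(tf),
           sprintf("%d rows, expected %d (levels x crops x variables)",
                   nrow(tt), expected))
  }
  if (!length(v))
    return(data.frame(check = character(), file = character(),
                      detail = character()))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
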