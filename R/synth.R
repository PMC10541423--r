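# Synthetic landscapes with planted ground truth.
#
# The generators here stand in for the geodata a national-scale risk
# assessment would assemble (nested hydrological watersheds, gridded climate,
# soil, land-use and socioeconomic covariates, point measurements of
# antibiotic concentrations, and watershed crop yields). Everything is seeded
# and the generating parameters are recorded, so downstream estimators can be
# tested by parameter recovery.

#' Target antibiotic compounds
#'
#' The nine frequently detected soil antibiotics used throughout the package:
#' four tetracyclines and five fluoroquinolones.
#' @export
TARGET_ANTIBIOTICS <- c(
  "tetracycline", "chlortetracycline", "oxytetracycline", "doxycycline",
  "ofloxacin", "norfloxacin", "ciprofloxacin", "enrofloxacin", "lomefloxacin"
)

#' Covariate names produced by [generate_covariates()]
#' @export
COVARIATE_NAMES <- c(
  "temperature", "precipitation", "arable_prop", "built_prop", "natural_prop",
  "livestock_density", "population_density", "gdp", "chemical_fertilization",
  "pesticide_use", "clay", "organic_carbon", "bulk_density", "soil_thickness",
  "saturated_conductivity", "groundwater_depth", "ndvi", "elevation",
  "manure_rate", "irrigated_prop", "human_footprint"
)

# ---------------------------------------------------------------------------
# Spatially autocorrelated fields

# Standardized Gaussian random field: white noise convolved with a separable
# Gaussian kernel of standard deviation `range` (in cells), reflected at the
# edges, then re-standardized. range <= 0.3 cells returns plain white noise.
gaussian_field <- function(rows, cols, range) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (range <= 0.3) return(z)
  r <- min(ceiling(3 * range), rows - 1L, cols - 1L)
  k <- stats::dnorm(seq(-r, r), sd = range)
  k <- k / sum(k)
  z <- conv_sep(z, k)
  (z - mean(z)) / stats::sd(z)
}

# Separable 2-D convolution with reflection padding.
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  pad_idx <- function(n) c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
  smooth1 <- function(mm) {       # smooth down columns
    p <- mm[pad_idx(nrow(mm)), , drop = FALSE]
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(k))
      out <- out + k[i] * p[seq_len(nrow(mm)) + i - 1L, , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(m))))
}

# ---------------------------------------------------------------------------
# Landscape: nested watershed hierarchy + soil mask

#' Generate a synthetic landscape with nested watersheds
#'
#' Partitions a `rows` by `cols` grid into a 4-level nested watershed
#' hierarchy by recursive k-means on cell coordinates: level 1 has
#' `n_level1` watersheds and each watershed at level k is split into
#' `branching` children at level k + 1, so level k holds
#' `n_level1 * branching^(k-1)` watersheds. A soil mask flags a small
#' fraction of cells (bare land / water) for exclusion downstream.
#'
#' Recursive spatial partition is used instead of flow routing because only
#' the nesting/aggregation structure matters to the analyses built on top.
#'
#' @param rows,cols grid dimensions (each >= 8).
#' @param n_level1 number of level-1 (largest) watersheds.
#' @param branching children per watershed at each refinement (>= 2).
#' @param seed integer seed; output is deterministic given the seed.
#' @param n_levels number of nesting levels (default 4).
#' @param mask_frac fraction of cells masked as non-soil (default 0.05).
#' @return an object of class `agro_landscape`: list with `grid_shape`,
#'   `watershed_ids` (list of integer label matrices, one per level),
#'   `soil_mask` (logical matrix, TRUE = soil), `params`.
#' @export
generate_landscape <- function(rows, cols, n_level1 = 2, branching = 3,
                               seed = 1, n_levels = 4, mask_frac = 0.05) {
  if (rows < 8 || cols < 8) stop("rows and cols must be >= 8")
  if (branching < 2) stop("branching must be >= 2")
  n_leaf <- n_level1 * branching^(n_levels - 1)
  if (rows * cols < 4 * n_leaf)
    stop(sprintf(
      "grid too small: %d cells cannot host %d leaf watersheds (need >= %d)",
      rows * cols, n_leaf, 4 * n_leaf))
  with_seed(derive_seed(seed, "landscape"), {
    coords <- cbind(
      row = rep(seq_len(rows), times = cols),
      col = rep(seq_len(cols), each = rows)
    )
    labels <- matrix(1L, rows * cols, n_levels)
    # level 1
    labels[, 1] <- cluster_cells(coords, n_level1)
    for (lev in seq_len(n_levels - 1L)) {
      parent <- labels[, lev]
      child <- integer(length(parent))
      nxt <- 0L
      for (p in sort(unique(parent))) {
        idx <- which(parent == p)
        cl <- cluster_cells(coords[idx, , drop = FALSE], branching)
        child[idx] <- nxt + cl
        nxt <- nxt + max(cl)
      }
      labels[, lev + 1L] <- child
    }
    mask <- gaussian_field(rows, cols, max(2, min(rows, cols) / 8))
    soil <- if (mask_frac <= 0) matrix(TRUE, rows, cols) else
      mask > stats::quantile(mask, mask_frac)
    structure(list(
      grid_shape = c(rows = rows, cols = cols),
      watershed_ids = lapply(seq_len(n_levels), function(k)
        matrix(labels[, k], rows, cols)),
      soil_mask = soil,
      params = list(n_level1 = n_level1, branching = branching,
                    n_levels = n_levels, mask_frac = mask_frac, seed = seed)
    ), class = "agro_landscape")
  })
}

# k-means on coordinates; deterministic under the caller's RNG state.
cluster_cells <- function(coords, k) {
  if (k == 1L) return(rep(1L, nrow(coords)))
  if (nrow(coords) < k) stop("too few cells to split watershed")
  km <- stats::kmeans(coords, centers = k, nstart = 5, iter.max = 100)
  # relabel clusters in a deterministic spatial order (by centroid)
  ord <- order(km$centers[, 1], km$centers[, 2])
  match(km$cluster, ord)
}

#' @export
print.agro_landscape <- function(x, ...) {
  cat(sprintf("agro_landscape: %d x %d grid, %d watershed levels (%s), %d%% masked\n",
              x$grid_shape[1], x$grid_shape[2], length(x$watershed_ids),
              paste(vapply(x$watershed_ids, function(w) length(unique(as.vector(w))),
                           1L), collapse = "/"),
              round(100 * mean(!x$soil_mask))))
  invisible(x)
}

#' Count watersheds per level
#' @param landscape an `agro_landscape`.
#' @return integer vector, one count per level.
#' @export
watershed_counts <- function(landscape) {
  vapply(landscape$watershed_ids, function(w) length(unique(as.vector(w))), 1L)
}

# ---------------------------------------------------------------------------
# Covariates

#' Generate spatially autocorrelated covariate grids
#'
#' Produces the predictor stack used by the upscaling model: climate, soil
#' properties, land-use proportions, socioeconomic pressure and land
#' management intensity. Each layer is a transformed Gaussian random field
#' (Gaussian-filtered white noise) with autocorrelation range
#' `autocorr_range` cells. Land proportions (arable/built/natural) come from
#' a softmax with a slack class so they each lie in \[0, 1\] and sum to < 1.
#' Manure rate and irrigated proportion are positively coupled to arable
#' land and livestock so that land-system signal exists for the watershed
#' regressions to find. Temperature and precipitation carry a small linear
#' annual trend (stored in metadata) to exercise year-matched extraction.
#'
#' @param landscape an `agro_landscape`.
#' @param autocorr_range autocorrelation range in cells (> 0).
#' @param seed integer seed.
#' @return an object of class `agro_covariates`: named list of matrices with
#'   a `meta` attribute recording the generation parameters.
#' @export
generate_covariates <- function(landscape, autocorr_range = 4, seed = 1) {
  if (autocorr_range <= 0) stop("autocorr_range must be > 0")
  rows <- landscape$grid_shape[1]; cols <- landscape$grid_shape[2]
  with_seed(derive_seed(seed, "covariates"), {
    g <- function() gaussian_field(rows, cols, autocorr_range)
    f_ar <- g(); f_bu <- g(); f_na <- g(); f_sl <- g()
    sm <- exp(f_ar) + exp(f_bu - 1.2) + exp(f_na + 0.5) + exp(f_sl - 0.5)
    arable  <- exp(f_ar) / sm
    built   <- exp(f_bu - 1.2) / sm
    natural <- exp(f_na + 0.5) / sm
    f_li <- 0.6 * f_ar + 0.8 * g()
    livestock <- 50 * exp(0.8 * f_li)
    pop  <- 300 * exp(0.9 * (0.7 * f_bu + 0.7 * g()))
    gdp  <- 5  * exp(0.8 * (0.8 * f_bu + 0.6 * g()))
    manure <- 900 * exp(0.45 * f_ar + 0.45 * f_li + 0.3 * g())
    irrig  <- stats::plogis(0.9 * f_ar + 0.7 * g() - 0.2)
    cov <- list(
      temperature = 12 + 6 * g(),
      precipitation = 800 * exp(0.35 * g()),
      arable_prop = arable,
      built_prop = built,
      natural_prop = natural,
      livestock_density = livestock,
      population_density = pop,
      gdp = gdp,
      chemical_fertilization = 120 * exp(0.4 * (0.5 * f_ar + 0.8 * g())),
      pesticide_use = 8 * exp(0.5 * (0.4 * f_ar + 0.9 * g())),
      clay = pmin(pmax(25 + 10 * g(), 1), 80),
      organic_carbon = 15 * exp(0.4 * g()),
      bulk_density = pmin(pmax(1.35 + 0.12 * g(), 0.8), 1.9),
      soil_thickness = 20 * exp(0.5 * g()),
      saturated_conductivity = 10 * exp(0.8 * g()),
      groundwater_depth = 8 * exp(0.6 * g()),
      ndvi = stats::plogis(0.8 * f_na + 0.5 * g()),
      elevation = 500 * exp(0.7 * g()),
      manure_rate = manure,
      irrigated_prop = irrig
    )
    # cumulative human pressure index used to rank watersheds
    cov$human_footprint <-
      minmax(as.vector(log(pop))) + minmax(as.vector(log(gdp))) +
      minmax(as.vector(built)) + minmax(as.vector(arable)) +
      0.1 * stats::rnorm(rows * cols)
    cov$human_footprint <- matrix(cov$human_footprint, rows, cols)
    structure(cov, class = "agro_covariates",
              meta = list(autocorr_range = autocorr_range, seed = seed,
                          time_varying = c(temperature = 0.03,
                                           precipitation = 2.0),
                          reference_year = 2010))
  })
}

#' Covariate grid matched to a sampling year
#'
#' Time-varying layers (temperature, precipitation) are shifted by their
#' recorded linear annual trend relative to the reference year; all other
#' layers are treated as static.
#'
#' @param covariates an `agro_covariates`.
#' @param name covariate name.
#' @param year sampling year (default: reference year).
#' @return matrix.
#' @export
covariate_at <- function(covariates, name, year = NULL) {
  if (!name %in% names(covariates)) stop("unknown covariate: ", name)
  g <- covariates[[name]]
  meta <- attr(covariates, "meta")
  tv <- meta$time_varying
  if (!is.null(year) && name %in% names(tv))
    g <- g + tv[[name]] * (year - meta$reference_year)
  g
}

# ---------------------------------------------------------------------------
# Planted truth

#' Construct the planted ground truth for a synthetic study
#'
#' Fixes the generating parameters that downstream estimators are asked to
#' recover: per-compound linear weights of measured concentration on the
#' covariates (plus noise SD), per-crop tradeoff vertices on the unit-scaled
#' intensification axis, and the cumulative-risk breakpoint beyond which
#' yields decline.
#'
#' @param seed integer seed recorded in the truth object.
#' @param compounds compound names (default the nine target antibiotics).
#' @param noise_sd measurement noise SD (ug/kg) shared by compounds.
#' @param yield_breakpoint cumulative RQ at which yields start to decline.
#' @param tradeoff_vertex named per-crop vertex on unit-scaled
#'   intensification.
#' @return object of class `agro_truth`.
#' @export
planted_truth <- function(seed = 1, compounds = TARGET_ANTIBIOTICS,
                          noise_sd = 2,
                          yield_breakpoint = 9,
                          tradeoff_vertex = c(maize = 0.35, rice = 0.42,
                                              wheat = 0.55, vegetables = 0.68)) {
  # Concentrations load on the land-system and soil covariates that the
  # mapping model is later asked to exploit; weights vary by compound class.
  base <- c(manure_rate = 0.0075, irrigated_prop = 9, arable_prop = 11,
            livestock_density = 0.06, organic_carbon = 0.22)
  coef <- lapply(seq_along(compounds), function(i) {
    scale <- 0.5 + 1.5 * ((i - 1) %% 3) / 2          # compound potency spread
    w <- base * scale
    if (i %% 2 == 0) w["irrigated_prop"] <- w["irrigated_prop"] * 1.6
    w
  })
  names(coef) <- compounds
  structure(list(
    mec_coefficients = coef,
    mec_intercept = stats::setNames(rep(0.8, length(compounds)), compounds),
    noise_sd = stats::setNames(rep(noise_sd, length(compounds)), compounds),
    yield_breakpoint = yield_breakpoint,
    tradeoff_vertex = tradeoff_vertex,
    seed = seed
  ), class = "agro_truth")
}

#' Expected (noise-free) concentration grid for one compound
#'
#' Evaluates the planted linear concentration model of `truth` on the
#' covariate grids, clipped at zero.
#'
#' @param covariates an `agro_covariates`.
#' @param truth an `agro_truth`.
#' @param compound compound name.
#' @param year optional sampling year for time-varying covariates.
#' @return concentration matrix (ug/kg).
#' @export
true_mec_grid <- function(covariates, truth, compound, year = NULL) {
  w <- truth$mec_coefficients[[compound]]
  if (is.null(w)) stop("compound not in truth: ", compound)
  g <- truth$mec_intercept[[compound]]
  acc <- matrix(g, nrow(covariates[[1]]), ncol(covariates[[1]]))
  for (nm in names(w))
    acc <- acc + w[[nm]] * covariate_at(covariates, nm, year)
  pmax(acc, 0)
}

#' Expected cumulative risk-quotient grid under the planted truth
#'
#' Sums the per-compound expected concentration grids divided by the
#' compound's worst-case PNEC (concentration addition).
#'
#' @param covariates an `agro_covariates`.
#' @param truth an `agro_truth`.
#' @param pnecs named vector of worst-case PNECs (ug/kg) per compound.
#' @return cumulative RQ matrix.
#' @export
true_cumulative_rq_grid <- function(covariates, truth, pnecs) {
  compounds <- names(truth$mec_coefficients)
  missing <- setdiff(compounds, names(pnecs))
  if (length(missing)) stop("missing PNECs for: ", paste(missing, collapse = ", "))
  acc <- 0
  for (cmp in compounds)
    acc <- acc + true_mec_grid(covariates, truth, cmp) / pnecs[[cmp]]
  acc
}

# ---------------------------------------------------------------------------
# Measured environmental concentrations

#' Sample synthetic measured environmental concentration (MEC) records
#'
#' Draws `n_sites` soil (non-masked) cells without replacement, assigns each
#' a uniform sampling year in 2000-2020, and emits one record per site and
#' compound: concentration = planted linear model of the (year-matched)
#' covariates + Gaussian noise, truncated at zero. Values below
#' `detection_limit` are reported as exactly 0, mirroring the convention of
#' treating non-detects as zero (not half the detection limit).
#'
#' @param landscape an `agro_landscape`.
#' @param covariates an `agro_covariates`.
#' @param truth an `agro_truth`.
#' @param n_sites number of sampling locations (>= 10).
#' @param detection_limit concentrations below this are reported as 0.
#' @param seed integer seed.
#' @return data.frame of class `mec_records` with columns `site_id`, `x`
#'   (column), `y` (row), `year`, `compound`, `concentration` (ug/kg),
#'   `land_use_context`, `treated_flag`, `polluted_site_flag`.
#' @export
generate_mec_samples <- function(landscape, covariates, truth, n_sites,
                                 detection_limit = 0.01, seed = 1) {
  if (n_sites < 10) stop("n_sites must be >= 10")
  soil_cells <- which(landscape$soil_mask)
  if (n_sites > length(soil_cells))
    stop(sprintf("n_sites (%d) exceeds available soil cells (%d)",
                 n_sites, length(soil_cells)))
  rows <- landscape$grid_shape[1]
  with_seed(derive_seed(seed, "mec"), {
    cells <- sample(soil_cells, n_sites)
    ri <- (cells - 1L) %% rows + 1L
    ci <- (cells - 1L) %/% rows + 1L
    years <- sample(2000:2020, n_sites, replace = TRUE)
    compounds <- names(truth$mec_coefficients)
    recs <- vector("list", length(compounds))
    arable <- covariates$arable_prop; built <- covariates$built_prop
    ctx <- ifelse(arable[cells] > 0.4, "cropland",
                  ifelse(built[cells] > 0.3, "urban_green_space",
                         ifelse(covariates$ndvi[cells] > 0.6, "forestland",
                                "grassland")))
    for (k in seq_along(compounds)) {
      cmp <- compounds[k]
      w <- truth$mec_coefficients[[cmp]]
      mu <- rep(truth$mec_intercept[[cmp]], n_sites)
      for (nm in names(w)) {
        tv <- names(attr(covariates, "meta")$time_varying)
        if (nm %in% tv) {
          vals <- vapply(seq_len(n_sites), function(i)
            covariate_at(covariates, nm, years[i])[ri[i], ci[i]], 0)
        } else {
          vals <- covariates[[nm]][cells]
        }
        mu <- mu + w[[nm]] * vals
      }
      conc <- pmax(mu + stats::rnorm(n_sites, 0, truth$noise_sd[[cmp]]), 0)
      conc[conc < detection_limit] <- 0
      recs[[k]] <- data.frame(
        site_id = seq_len(n_sites), x = ci, y = ri, year = years,
        compound = cmp, concentration = conc,
        land_use_context = ctx,
        treated_flag = FALSE, polluted_site_flag = FALSE,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    class(out) <- c("mec_records", "data.frame")
    out
  })
}

# ---------------------------------------------------------------------------
# Yields

#' Per-cell land system intensification grid
#'
#' Cell-level analogue of the watershed intensification score: the sum of
#' min-max standardized arable proportion, manure application rate and
#' irrigated-area proportion (each component in \[0, 1\], score in \[0, 3\]).
#'
#' @param covariates an `agro_covariates`.
#' @return matrix of intensification scores.
#' @export
intensification_grid <- function(covariates) {
  m <- minmax(as.vector(covariates$arable_prop)) +
    minmax(as.vector(covariates$manure_rate)) +
    minmax(as.vector(covariates$irrigated_prop))
  matrix(m, nrow(covariates$arable_prop), ncol(covariates$arable_prop))
}

# Crop-specific scaled yield over unit intensification: the isotonic
# estimate m(I) of E[scaled risk | intensification] plus a concave
# parabola q(I) = x0*I - I^2/2 whose vertex sits exactly at the planted
# x0. The parabola amplitude is solved so that the combined curve spans
# exactly [0, 1] over the realized watersheds; min-max rescaling of the
# yields then returns the curve unchanged, and subtracting scaled risk
# downstream leaves (in expectation) exactly the planted parabola.
plant_yield_curve <- function(I01, P_risk, x0) {
  ord <- order(I01)
  iso <- stats::isoreg(I01[ord], P_risk[ord])
  m <- numeric(length(I01))
  m[ord] <- iso$yf
  q <- x0 * I01 - I01^2 / 2
  G <- function(b) diff(range(m + b * q)) - 1
  if (G(0) >= 0) {
    # the risk trend alone already spans the scale (e.g. risk is a pure
    # function of intensification): add the parabola at a fixed amplitude
    # and clip the overflow at 1; clipped watersheds sit above the vertex
    # in risk, so the vertex stays the tradeoff's argmax
    f <- m + 0.6 * q
    return(pmin(f - min(f), 1))
  }
  bmax <- 4 / max(diff(range(q)), 1e-9)
  while (G(bmax) < 0) bmax <- bmax * 2
  beta <- stats::uniroot(G, c(0, bmax), tol = 1e-10)$root
  f <- m + beta * q
  f - min(f)
}

#' Generate synthetic watershed crop yields with a planted risk-yield vertex
#'
#' Builds per-watershed yields for maize, rice, wheat and vegetables such
#' that the scaled-yield-minus-scaled-risk tradeoff, plotted against
#' unit-scaled intensification, has an interior maximum at the planted
#' per-crop vertex, and such that yields decline once watershed cumulative
#' risk exceeds the planted breakpoint. With a constant (e.g. all-zero) risk
#' grid the yields are simply monotone nondecreasing in intensification.
#'
#' Scaled yield is built as the isotonic trend of scaled risk on
#' intensification plus a concave parabola centred on the planted vertex,
#' with amplitude solved so the curve spans exactly \[0, 1\] across
#' watersheds; a curve with that span passes through min-max rescaling
#' unchanged, so subtracting scaled risk downstream leaves, in
#' expectation, exactly the planted concave tradeoff.
#'
#' @param landscape an `agro_landscape`.
#' @param intensification_grid cell-level intensification (see
#'   [intensification_grid()]).
#' @param risk_grid cell-level cumulative RQ grid (same shape).
#' @param truth an `agro_truth` carrying `tradeoff_vertex` and
#'   `yield_breakpoint`.
#' @param level watershed level at which yields are reported (default 4).
#' @param noise_sd lognormal yield noise SD (default 0.02).
#' @param hinge_strength fractional yield loss per unit RQ above the
#'   breakpoint (default 0.03).
#' @param seed integer seed.
#' @return data.frame with columns `watershed_id`, `level`, `crop`, `yield`
#'   (t/ha), plus a `planted` attribute recording the construction.
#' @export
generate_yields <- function(landscape, intensification_grid, risk_grid, truth,
                            level = 4, noise_sd = 0.02,
                            hinge_strength = 0.03, seed = 1) {
  shp <- landscape$grid_shape
  if (!all(dim(intensification_grid) == shp) || !all(dim(risk_grid) == shp))
    stop("intensification_grid / risk_grid not aligned with landscape")
  labels <- landscape$watershed_ids[[level]]
  I_w <- aggregate_by_label(intensification_grid, labels, landscape$soil_mask)
  R_w <- aggregate_by_label(risk_grid, labels, landscape$soil_mask)
  ids <- as.integer(names(I_w))
  I01 <- minmax(I_w)
  risk_constant <- diff(range(R_w)) < .Machine$double.eps^0.5
  P_risk <- if (risk_constant) rep(0, length(R_w)) else minmax(R_w)
  base_yield <- c(maize = 6, rice = 6.5, wheat = 4.5, vegetables = 30)
  crops <- names(truth$tradeoff_vertex)
  with_seed(derive_seed(seed, "yields"), {
    out <- lapply(crops, function(crop) {
      if (risk_constant) {
        f <- I01
      } else {
        f <- plant_yield_curve(I01, P_risk, truth$tradeoff_vertex[[crop]])
      }
      hinge <- 1 - hinge_strength * pmax(0, R_w - truth$yield_breakpoint)
      y <- base_yield[[crop]] * (0.25 + 0.75 * f) * pmax(hinge, 0.1) *
        exp(stats::rnorm(length(f), 0, noise_sd))
      data.frame(watershed_id = ids, level = level, crop = crop, yield = y,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    attr(out, "planted") <- list(vertex = truth$tradeoff_vertex,
                                 breakpoint = truth$yield_breakpoint,
                                 noise_sd = noise_sd,
                                 hinge_strength = hinge_strength, seed = seed)
    out
  })
}

# ---------------------------------------------------------------------------
# Serialization

#' Write the planted truth as YAML
#' @param truth an `agro_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    mec_coefficients = lapply(truth$mec_coefficients, as.list),
    mec_intercept = as.list(truth$mec_intercept),
    noise_sd = as.list(truth$noise_sd),
    yield_breakpoint = truth$yield_breakpoint,
    tradeoff_vertex = as.list(truth$tradeoff_vertex),
    seed = truth$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Write a grid as a plain-text TSV matrix
#'
#' Grids travel as headerless tab-separated matrices (one row per grid row;
#' masked cells as NA), a portable text stand-in for single-band rasters.
#'
#' @param grid numeric matrix.
#' @param path output file.
#' @param mask optional logical matrix; FALSE cells are written as NA.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, mask = NULL) {
  if (!is.null(mask)) grid[!mask] <- NA
  utils::write.table(format(grid, digits = 10, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#' @param path TSV matrix file.
#' @return numeric matrix.
#' @export
read_grid <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}
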