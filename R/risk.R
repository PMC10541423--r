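# Ecotoxicological risk assessment: PNEC derivation with assessment factors,
# per-compound risk quotients (RQ = MEC / PNEC), concentration-addition
# cumulative risk under the worst-case (lowest PNEC, highest RQ) rules, and
# the global Moran's I diagnostic for sampling-network autocorrelation.

#' Filter MEC records by the study selection criteria
#'
#' Removes (i) experimentally treated samples (antibiotics added on purpose)
#' and (ii) samples from seriously polluted sites such as hospitals or
#' livestock farms. Records for compounds outside `target_compounds` are
#' dropped with a warning rather than an error.
#'
#' @param records data.frame with at least `compound`, `treated_flag`,
#'   `polluted_site_flag`.
#' @param target_compounds compounds to retain (default the nine targets).
#' @return list with `kept` (filtered data.frame) and `log` (named counts of
#'   rejections per rule: `treated`, `polluted_site`, `non_target`).
#' @export
filter_records <- function(records, target_compounds = TARGET_ANTIBIOTICS) {
  stopifnot(all(c("compound", "treated_flag", "polluted_site_flag") %in%
                  names(records)))
  non_target <- !(records$compound %in% target_compounds)
  if (any(non_target))
    warning(sprintf("dropping %d records for non-target compounds",
                    sum(non_target)))
  treated <- records$treated_flag & !non_target
  polluted <- records$polluted_site_flag & !treated & !non_target
  keep <- !(non_target | records$treated_flag | records$polluted_site_flag)
  list(
    kept = records[keep, , drop = FALSE],
    log = c(treated = sum(treated), polluted_site = sum(polluted),
            non_target = sum(non_target))
  )
}

#' Convert a water PNEC to a soil PNEC by equilibrium partitioning
#'
#' PNEC_soil = PNEC_water x Kd, with Kd the soil-water partition
#' coefficient (L/kg).
#'
#' @param pnec_water PNEC in water (ug/L), > 0.
#' @param kd partition coefficient (L/kg), > 0.
#' @return soil PNEC (ug/kg).
#' @export
pnec_soil_from_water <- function(pnec_water, kd) {
  check_positive(pnec_water, "pnec_water")
  check_positive(kd, "kd")
  pnec_water * kd
}

# Assessment factors: acute endpoints (EC50/LC50) get 1000, the chronic
# NOEC gets 100.
ASSESSMENT_FACTORS <- c(EC50 = 1000, LC50 = 1000, NOEC = 100)

#' Derive PNECs for one compound by the assessment-factor approach
#'
#' Each toxicity endpoint is divided by its assessment factor (1000 for
#' EC50/LC50, 100 for NOEC). Endpoints reported in water are first divided
#' by the factor and then converted to soil via the compound's Kd
#' (equilibrium partitioning). The minimum across endpoints/species is
#' retained as the worst-case PNEC.
#'
#' @param tox data.frame with columns `compound`, `endpoint_type`
#'   (EC50/LC50/NOEC), `value` (> 0; ug/kg for soil, ug/L for water),
#'   `medium` ("soil" or "water"), `kd` (L/kg; required for water records),
#'   and optionally `species`.
#' @return object of class `pnec_set`: list with `compound`, `pnecs`
#'   (per-record soil PNECs, ug/kg), `worst_case_pnec`, `assessment_factors`.
#' @export
derive_pnec <- function(tox) {
  if (nrow(tox) == 0) stop("no toxicity records supplied")
  cmp <- unique(tox$compound)
  if (length(cmp) != 1) stop("derive_pnec expects records for one compound")
  if (!all(tox$endpoint_type %in% names(ASSESSMENT_FACTORS)))
    stop("endpoint_type must be one of EC50, LC50, NOEC")
  check_positive(tox$value, "toxicity value")
  af <- ASSESSMENT_FACTORS[tox$endpoint_type]
  pnec <- tox$value / af
  water <- tox$medium == "water"
  if (any(water)) {
    if (any(is.na(tox$kd[water]))) stop("water-medium records require kd")
    check_positive(tox$kd[water], "kd")
    pnec[water] <- pnec_soil_from_water(pnec[water], tox$kd[water])
  }
  structure(list(compound = cmp, pnecs = unname(pnec),
                 worst_case_pnec = min(pnec),
                 assessment_factors = unname(af)),
            class = "pnec_set")
}

#' Derive worst-case PNECs for every compound in a toxicity table
#' @param tox toxicity table (see [derive_pnec()]) covering >= 1 compound.
#' @return named numeric vector of worst-case soil PNECs (ug/kg).
#' @export
derive_pnec_table <- function(tox) {
  sets <- lapply(split(tox, tox$compound), derive_pnec)
  vapply(sets, function(s) s$worst_case_pnec, 0)
}

#' Risk quotient of one record against a compound's PNEC set
#'
#' RQ = MEC / worst-case PNEC (the lowest PNEC governs).
#'
#' @param record one-row MEC record (fields `compound`, `concentration`).
#' @param pnec a `pnec_set` for the same compound.
#' @return list with `compound`, `site_id` (if present), `rq`.
#' @export
compute_rq <- function(record, pnec) {
  if (record$compound != pnec$compound)
    stop(sprintf("compound mismatch: record '%s' vs PNEC set '%s'",
                 record$compound, pnec$compound))
  if (pnec$worst_case_pnec <= 0) stop("worst_case_pnec must be > 0")
  list(compound = record$compound,
       site_id = if ("site_id" %in% names(record)) record$site_id else NA,
       rq = record$concentration / pnec$worst_case_pnec)
}

#' Per-site cumulative risk quotient by concentration addition
#'
#' For each site, the highest RQ of each compound is retained (worst-case
#' rule for duplicate measurements) and these per-compound maxima are
#' summed. Compounds not reported at a site are treated as absent (RQ 0).
#'
#' @param rq_table data.frame with columns `site_id`, `compound`, `rq`.
#' @return data.frame with `site_id`, `cum_rq`, `n_compounds_above_1`.
#' @export
cumulative_rq <- function(rq_table) {
  stopifnot(all(c("site_id", "compound", "rq") %in% names(rq_table)))
  if (nrow(rq_table) == 0) stop("at least one RQ required")
  sp <- split(rq_table, rq_table$site_id)
  out <- lapply(sp, function(d) {
    mx <- tapply(d$rq, d$compound, max)
    data.frame(site_id = d$site_id[1], cum_rq = sum(mx),
               n_compounds_above_1 = sum(mx > 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$site_id), , drop = FALSE]
}

#' Per-site RQ table from MEC records and a toxicity table
#'
#' Convenience wrapper: derives worst-case PNECs per compound and divides
#' each record's concentration by them.
#'
#' @param records MEC records (`site_id`, `compound`, `concentration`, and
#'   coordinates carried through).
#' @param tox toxicity table covering every compound in `records`.
#' @return data.frame of records with an added `rq` column.
#' @export
rq_table <- function(records, tox) {
  pnecs <- derive_pnec_table(tox)
  missing <- setdiff(unique(records$compound), names(pnecs))
  if (length(missing))
    stop("no toxicity data for: ", paste(missing, collapse = ", "))
  records$rq <- records$concentration / unname(pnecs[records$compound])
  records
}

# ---------------------------------------------------------------------------
# Moran's I

#' Spatial weight matrix from site coordinates
#'
#' Builds binary contiguity weights (sites within `threshold` distance, the
#' default covering rook adjacency on a unit grid) or inverse-distance
#' weights, optionally row-standardized.
#'
#' @param x,y site coordinates.
#' @param style "binary" distance-threshold weights or "idw" inverse
#'   distance.
#' @param threshold neighbour distance for binary weights (default 1 = rook
#'   neighbours on a unit grid).
#' @param row_standardize divide each row by its sum (default TRUE).
#' @return n x n weight matrix with zero diagonal.
#' @export
spatial_weights <- function(x, y, style = c("binary", "idw"), threshold = 1,
                            row_standardize = TRUE) {
  style <- match.arg(style)
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- if (style == "binary") (d <= threshold + 1e-9) * 1 else {
    dd <- d; dd[dd == 0] <- Inf; 1 / dd
  }
  diag(w) <- 0
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  w
}

#' Global Moran's I with normal-approximation inference
#'
#' I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centred
#' values. The expectation under the null is -1/(n-1); the z-score and
#' two-sided p-value use the variance under the normality assumption.
#' A permutation test is available as an alternative.
#'
#' @param values numeric vector at n >= 4 sites; must not be constant.
#' @param weights n x n spatial weight matrix (zero diagonal).
#' @param method "normal" (default) or "permutation".
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed seed for the permutation test.
#' @return list with `I`, `expected`, `sd`, `z_score`, `p_value`, `method`.
#' @export
morans_i <- function(values, weights, method = c("normal", "permutation"),
                     n_perm = 999, seed = 1) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 4) stop("Moran's I requires >= 4 sites")
  if (!all(dim(weights) == c(n, n))) stop("weights must be n x n")
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("Moran's I undefined for constant values")
  S0 <- sum(weights)
  I <- (n / S0) * as.numeric(crossprod(z, weights %*% z)) / m2
  EI <- -1 / (n - 1)
  if (method == "normal") {
    S1 <- 0.5 * sum((weights + t(weights))^2)
    S2 <- sum((rowSums(weights) + colSums(weights))^2)
    b2 <- n * sum(z^4) / m2^2
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    sdI <- sqrt(VI)
    zsc <- (I - EI) / sdI
    p <- 2 * stats::pnorm(-abs(zsc))
  } else {
    perm <- with_seed(seed, replicate(n_perm, {
      zp <- sample(z)
      (n / S0) * as.numeric(crossprod(zp, weights %*% zp)) / m2
    }))
    sdI <- stats::sd(perm)
    zsc <- (I - mean(perm)) / sdI
    p <- (1 + sum(abs(perm - EI) >= abs(I - EI))) / (n_perm + 1)
  }
  list(I = I, expected = EI, sd = sdI, z_score = zsc, p_value = p,
       method = method)
}

#' Load the bundled synthetic toxicity table
#'
#' A small, clearly synthetic endpoint table (EC50/LC50/NOEC values with Kd
#' for water-medium records) shipped so the risk pipeline runs without any
#' literature compilation. The values are schema-compatible illustrations,
#' not curated ecotoxicology.
#'
#' @return toxicity data.frame (see [derive_pnec()]).
#' @export
load_toxicity_table <- function() {
  path <- system.file("extdata", "toxicity_synthetic.csv", package = "agrorisk")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
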