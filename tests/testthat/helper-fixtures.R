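# Shared fixtures, built once per test run. The standard study landscape is
# the 32 x 32 grid with 2 level-1 watersheds branching 3-fold (54 leaf
# watersheds), 120 sampling sites and the bundled synthetic toxicity table.

fixture_env <- new.env()

std_fixture <- function() {
  if (!exists("std", fixture_env, inherits = FALSE)) {
    ls <- generate_landscape(32, 32, 2, 3, seed = 1)
    cv <- generate_covariates(ls, 4, seed = 1)
    tr <- planted_truth(seed = 1)
    tox <- load_toxicity_table()
    pnecs <- derive_pnec_table(tox)
    mec <- generate_mec_samples(ls, cv, tr, 120, seed = 1)
    rq <- rq_table(filter_records(mec)$kept, tox)
    risk_grid <- true_cumulative_rq_grid(cv, tr, pnecs)
    igrid <- intensification_grid(cv)
    assign("std", list(landscape = ls, covariates = cv, truth = tr,
                       tox = tox, pnecs = pnecs, mec = mec, rq = rq,
                       risk_grid = risk_grid, igrid = igrid), fixture_env)
  }
  get("std", fixture_env, inherits = FALSE)
}

# Level-4 watershed summaries with noise-free planted yields.
std_summaries <- function(level = 4, noise_sd = 0, hinge_strength = 0) {
  key <- paste0("summ", level, "_", noise_sd, "_", hinge_strength)
  if (!exists(key, fixture_env, inherits = FALSE)) {
    fx <- std_fixture()
    yl <- generate_yields(fx$landscape, fx$igrid, fx$risk_grid, fx$truth,
                          level = level, noise_sd = noise_sd,
                          hinge_strength = hinge_strength, seed = 1)
    s <- summarize_watersheds(fx$risk_grid, fx$covariates, fx$landscape,
                              level, yields = yl)
    s$intensification <- as.vector(intensification_score(s))
    assign(key, s, fixture_env)
  }
  get(key, fixture_env, inherits = FALSE)
}

# Brute-force O(n^2) Moran's I oracle: plain double sum, no linear algebra.
morans_i_bruteforce <- function(values, weights) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + weights[i, j] * z[i] * z[j]
  (n / sum(weights)) * num / sum(z^2)
}

# Independent AICc computed from the residual sum of squares.
aicc_from_rss <- function(rss, n, n_slopes) {
  k <- n_slopes + 2                       # intercept + slopes + sigma
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# A tiny truth object with full control over the concentration model.
toy_truth <- function(coefficients, intercept = 0, noise_sd = 0,
                      vertex = c(maize = 0.5)) {
  structure(list(
    mec_coefficients = coefficients,
    mec_intercept = stats::setNames(rep(intercept, length(coefficients)),
                                    names(coefficients)),
    noise_sd = stats::setNames(rep(noise_sd, length(coefficients)),
                               names(coefficients)),
    yield_breakpoint = 9,
    tradeoff_vertex = vertex,
    seed = 1
  ), class = "agro_truth")
}
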