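#' @keywords internal
#' @importFrom mgcv gam s
"_PACKAGE"

#' Derive a named sub-seed from a root seed
#'
#' Deterministically maps (root seed, stage tag) to an integer seed below
#' 2^31 - 1, so that one root seed controls every stage of a run while
#' toggling a stage never perturbs the random streams of the others.
#'
#' @param seed integer root seed.
#' @param tag character stage label.
#' @return integer seed in \[0, 2^31 - 1).
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  s <- as.double(seed) %% 2147483647
  s <- (s * 48271) %% 2147483647
  as.integer((s + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Min-max rescaling to the unit interval
#'
#' Rescales a numeric vector to \[0, 1\] as (x - min) / (max - min).
#' Degenerate (constant) input is handled according to `constant`.
#'
#' @param x numeric vector.
#' @param constant value returned for every element when max == min
#'   (`NA` raises an error instead).
#' @return numeric vector in \[0, 1\].
#' @export
minmax <- function(x, constant = 0) {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r))) stop("minmax: non-finite range")
  if (r[1] == r[2]) {
    if (is.na(constant)) stop("minmax undefined for constant input")
    return(rep(constant, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

# Validation helper used across modules.
check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("%s must be positive and finite", name), call. = FALSE)
  invisible(x)
}

# Aggregate a grid by an integer label grid: mean of `grid` over the cells of
# each label, restricted to non-masked cells. Returns a named numeric vector.
aggregate_by_label <- function(grid, labels, mask = NULL) {
  stopifnot(all(dim(grid) == dim(labels)))
  keep <- if (is.null(mask)) rep(TRUE, length(labels)) else as.vector(mask)
  v <- as.vector(grid)[keep]
  l <- as.vector(labels)[keep]
  tapply(v, l, mean)
}
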