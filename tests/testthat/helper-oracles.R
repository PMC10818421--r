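# Independent oracles and shared fixtures, kept free of the package's own
# code paths wherever they serve as cross-checks.

# NIPALS PLS1 regression oracle: a-component partial least squares on
# column-centered X and centered y, fitted values on the original y scale.
nipalsPls <- function(X, y, a) {
  X <- as.matrix(X)
  ybar <- mean(y)
  E <- scale(X, scale = FALSE)
  f <- y - ybar
  fitted <- rep(ybar, nrow(X))
  for (k in seq_len(a)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    p <- drop(crossprod(E, t)) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    fitted <- fitted + q * t
    E <- E - tcrossprod(t, p)
    f <- f - q * t
  }
  fitted
}

# Small test grid (fast): full band territory, 301 points.
testGrid <- function() buildGrid(3700, 700, 10)

# Tiny 3-row SpectraSet for IO / structural tests.
tinyCollection <- function(grid = buildGrid(1800, 900, 100)) {
  set.seed(42)
  a <- matrix(round(runif(3 * length(grid)), 6), nrow = 3)
  a[2, 1] <- 1 / 3  # exercise full-precision round-trip
  md <- data.frame(
    sample_id = c("S1", "S1", "S2"),
    cohort = c("UC", "UC", "HC"),
    remission_wk8 = c("RM", "RM", NA),
    remission_wk56 = c("NRM", "NRM", NA),
    site_id = c("site1", "site1", "site2"),
    replicate_index = c(1L, 2L, 1L))
  SpectraSet(a, grid, md)
}

# Reduced cohort config: defaults except a coarse grid (and optional
# overrides); bands outside the grid range, and their effect entries, are
# dropped so narrow test grids remain valid configs.
smallCohortConfig <- function(seed = 1, grid = testGrid(), ...) {
  args <- list(grid = grid, seed = seed, ...)
  bands <- args$bands %||% defaultBands()
  keep <- bands$center >= min(grid) & bands$center <= max(grid)
  args$bands <- bands[keep, , drop = FALSE]
  effects <- args$effects %||% defaultEffects()
  args$effects <- lapply(effects, function(e) {
    e[as.numeric(names(e)) %in% args$bands$center]
  })
  do.call(cohortConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

smallCohort <- function(seed = 1, grid = testGrid(), ...) {
  generateCohort(smallCohortConfig(seed = seed, grid = grid, ...))
}

# Effects map with every fold set to 1 (null cohort).
nullEffects <- function() {
  lapply(defaultEffects(), function(e) { e[] <- 1; e })
}

# Separable two-band toy data for classifier checks.
separableData <- function(n = 40, p = 10, gap = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  y <- rep(c("NRM", "RM"), length.out = n)
  X[y == "RM", 1:2] <- X[y == "RM", 1:2] + gap
  list(X = X, y = y)
}
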