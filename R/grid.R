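#' Build a uniform wavenumber grid
#'
#' Constructs the inclusive, uniformly spaced wavenumber axis used throughout
#' the package. Mid-infrared acquisition runs high-to-low (4000 to 400
#' cm\eqn{^{-1}}), so grids are stored in descending order whenever
#' \code{start_cm1 > end_cm1}. The default acquisition grid,
#' \code{buildGrid(4000, 400, 0.5)}, has 7201 points.
#'
#' @param start_cm1 First wavenumber (cm\eqn{^{-1}}).
#' @param end_cm1 Last wavenumber (cm\eqn{^{-1}}); included in the grid.
#' @param spacing_cm1 Absolute spacing between adjacent points (> 0).
#' @return Numeric vector of wavenumbers from \code{start_cm1} to
#'   \code{end_cm1} inclusive.
#' @examples
#' g <- buildGrid(4000, 400, 0.5)
#' length(g) # 7201
#' @export
buildGrid <- function(start_cm1, end_cm1, spacing_cm1) {
  if (!is.numeric(spacing_cm1) || length(spacing_cm1) != 1L ||
      !is.finite(spacing_cm1) || spacing_cm1 <= 0) {
    stop("'spacing_cm1' must be a single positive finite number")
  }
  if (start_cm1 == end_cm1) stop("'start_cm1' and 'end_cm1' must differ")
  span <- abs(start_cm1 - end_cm1)
  n_steps <- span / spacing_cm1
  resid <- abs(n_steps - round(n_steps))
  if (resid > 1e-9 * max(1, n_steps)) {
    stop(sprintf(
      "grid span %g is not an integer multiple of spacing %g (residual %g steps)",
      span, spacing_cm1, resid))
  }
  n <- as.integer(round(n_steps)) + 1L
  step <- if (start_cm1 > end_cm1) -spacing_cm1 else spacing_cm1
  g <- start_cm1 + step * (0:(n - 1L))
  g[n] <- end_cm1  # exact endpoint
  assertWavenumberGrid(g)
  g
}

# Grid invariants: length >= 2, positive finite, strictly monotonic, uniform.
assertWavenumberGrid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2L) {
    stop("wavenumber grid must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(grid)) || any(grid <= 0)) {
    stop("all wavenumbers must be finite and > 0")
  }
  d <- diff(grid)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotonic")
  }
  sp <- abs(mean(d))
  if (max(abs(abs(d) - sp)) > 1e-9 * sp) {
    stop("wavenumber grid must be uniformly spaced")
  }
  invisible(grid)
}

# Absolute spacing of a validated grid.
gridSpacing <- function(grid) abs(grid[2L] - grid[1L])

#' Index of the grid point nearest to a query wavenumber
#'
#' Ties between two equidistant grid points resolve to the lower wavenumber.
#'
#' @param grid Uniform wavenumber grid (see [buildGrid()]).
#' @param wavenumber Query position (cm\eqn{^{-1}}); must lie inside the grid
#'   range.
#' @return Integer index into \code{grid}.
#' @examples
#' g <- buildGrid(4000, 400, 0.5)
#' g[nearestIndex(g, 1625.2)] # 1625
#' @export
nearestIndex <- function(grid, wavenumber) {
  assertWavenumberGrid(grid)
  if (length(wavenumber) != 1L || !is.finite(wavenumber)) {
    stop("'wavenumber' must be a single finite number")
  }
  if (wavenumber < min(grid) || wavenumber > max(grid)) {
    stop(sprintf("wavenumber %g outside grid range [%g, %g]",
                 wavenumber, min(grid), max(grid)))
  }
  d <- abs(grid - wavenumber)
  cand <- which(d == min(d))
  if (length(cand) > 1L) cand <- cand[which.min(grid[cand])]
  cand
}
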