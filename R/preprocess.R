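# Spectral preprocessing: replicate averaging, evanescent-wave ATR
# correction, Savitzky-Golay derivatives, per-spectrum normalization and
# per-wavelength scaling.

#' Preprocessing configuration
#'
#' One cell of the preprocessing grid. Stages run in the order: replicate
#' averaging, ATR correction, derivative, row normalization, column scaling.
#'
#' @param averaging_group_size Replicates averaged per output spectrum
#'   (default 3, turning 9 acquisitions into 3 averaged spectra).
#' @param atr_correction Apply the multiplicative evanescent-wave depth
#'   correction (default \code{FALSE}).
#' @param derivative_order \code{"none"}, \code{"first"} or \code{"second"}.
#' @param sg_window,sg_polyorder Savitzky-Golay window (odd) and polynomial
#'   order; defaults 7 and 3.
#' @param normalization \code{"none"}, \code{"area"}, \code{"minmax"},
#'   \code{"amide"} or \code{"vector"}. Vector normalization requires a
#'   derivative (it is defined on derivative spectra).
#' @param scaling \code{"none"}, \code{"mean_center"}, \code{"pareto"} or
#'   \code{"unit_variance"}.
#' @param amide_window High/low bounds (cm\eqn{^{-1}}) of the amide I region
#'   used by amide normalization; default \code{c(1650, 1600)}.
#' @return A validated list of class \code{"preprocessConfig"}.
#' @export
preprocessConfig <- function(averaging_group_size = 3L,
                             atr_correction = FALSE,
                             derivative_order = c("none", "first", "second"),
                             sg_window = 7L, sg_polyorder = 3L,
                             normalization = c("none", "area", "minmax",
                                               "amide", "vector"),
                             scaling = c("none", "mean_center", "pareto",
                                         "unit_variance"),
                             amide_window = c(1650, 1600)) {
  cfg <- list(averaging_group_size = as.integer(averaging_group_size),
              atr_correction = isTRUE(atr_correction),
              derivative_order = match.arg(derivative_order),
              sg_window = as.integer(sg_window),
              sg_polyorder = as.integer(sg_polyorder),
              normalization = match.arg(normalization),
              scaling = match.arg(scaling),
              amide_window = as.numeric(amide_window))
  class(cfg) <- "preprocessConfig"
  if (cfg$averaging_group_size < 1L) stop("averaging_group_size must be >= 1")
  if (cfg$sg_window %% 2L == 0L || cfg$sg_window <= cfg$sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder")
  }
  if (cfg$normalization == "vector" && cfg$derivative_order == "none") {
    stop("vector normalization is defined on derivative spectra; ",
         "set derivative_order to 'first' or 'second'")
  }
  if (length(cfg$amide_window) != 2L) stop("amide_window must have length 2")
  cfg
}

#' Average consecutive replicate spectra
#'
#' Replicates of each sample are ordered by \code{replicate_index},
#' partitioned into consecutive groups of \code{group_size}, and each group
#' is replaced by its pointwise mean (9 acquisitions with the default group
#' size 3 yield 3 averaged spectra per sample). Output replicate indices are
#' renumbered 1..k.
#'
#' @param collection A \linkS4class{SpectraSet}.
#' @param group_size Replicates per averaged spectrum.
#' @return A \linkS4class{SpectraSet} with \code{1/group_size} as many
#'   spectra.
#' @export
averageReplicates <- function(collection, group_size = 3L) {
  stopifnot(methods::is(collection, "SpectraSet"), group_size >= 1L)
  if (group_size == 1L) return(collection)
  meta <- sampleMeta(collection)
  a <- SummarizedExperiment::assay(collection, "absorbance")
  out_cols <- list(); out_meta <- list()
  for (sid in unique(meta$sample_id)) {
    idx <- which(meta$sample_id == sid)
    idx <- idx[order(meta$replicate_index[idx])]
    if (length(idx) %% group_size != 0L) {
      stop(sprintf("sample '%s' has %d replicates, not divisible by %d",
                   sid, length(idx), group_size))
    }
    k <- length(idx) %/% group_size
    for (g in seq_len(k)) {
      grp <- idx[((g - 1L) * group_size + 1L):(g * group_size)]
      out_cols[[length(out_cols) + 1L]] <- rowMeans(a[, grp, drop = FALSE])
      m <- meta[grp[1L], , drop = FALSE]
      m$replicate_index <- g
      out_meta[[length(out_meta) + 1L]] <- m
    }
  }
  SpectraSet(do.call(cbind, out_cols), wavenumbers(collection),
             do.call(rbind, out_meta),
             metadata = S4Vectors::metadata(collection))
}

#' Evanescent-wave ATR depth correction
#'
#' In attenuated total reflection the evanescent-wave penetration depth
#' scales as \eqn{1/\nu}, so low-wavenumber bands are over-weighted relative
#' to transmission spectra. This correction multiplies the absorbance at
#' \eqn{\nu} by \eqn{\nu / \nu_{ref}}, boosting high-wavenumber bands and
#' leaving the reference wavenumber unchanged. It is a first-order, openly
#' documented approximation of the proprietary "advanced ATR correction"
#' found in instrument vendor software.
#'
#' @param absorbance Numeric vector or spectra-in-rows matrix.
#' @param grid Wavenumber grid aligned to \code{absorbance}.
#' @param reference_wavenumber Fixed point of the correction (default 1000).
#' @return Corrected absorbance, same shape as the input.
#' @export
atrCorrection <- function(absorbance, grid, reference_wavenumber = 1000) {
  assertWavenumberGrid(grid)
  if (reference_wavenumber < min(grid) || reference_wavenumber > max(grid)) {
    stop("reference_wavenumber outside grid range")
  }
  factor <- grid / reference_wavenumber
  if (is.matrix(absorbance)) {
    stopifnot(ncol(absorbance) == length(grid))
    sweep(absorbance, 2L, factor, `*`)
  } else {
    stopifnot(length(absorbance) == length(grid))
    absorbance * factor
  }
}

#' Savitzky-Golay derivative with respect to wavenumber
#'
#' Least-squares polynomial convolution (default 7 points, polynomial order
#' 3). The filter runs in index space; coefficients are rescaled by the grid
#' spacing (and sign-corrected for descending storage) so the result is the
#' derivative with respect to increasing wavenumber in physical units
#' (absorbance per cm\eqn{^{-1}}, per cm\eqn{^{-2}} for the second order).
#' Edge points use the one-sided polynomial fits of the filter matrix, so
#' polynomials up to the filter order are reproduced exactly everywhere.
#'
#' @param absorbance Numeric vector or spectra-in-rows matrix.
#' @param grid Wavenumber grid aligned to \code{absorbance}.
#' @param order Derivative order, 1 or 2.
#' @param window,polyorder Filter window (odd, > polyorder) and polynomial
#'   order.
#' @return Derivative spectrum, same shape as the input.
#' @export
savgolDerivative <- function(absorbance, grid, order = 1L,
                             window = 7L, polyorder = 3L) {
  assertWavenumberGrid(grid)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  if (window >= length(grid)) stop("window must be smaller than the grid")
  step <- grid[2L] - grid[1L]  # signed; negative for descending storage
  scale <- (1 / step)^order
  f <- function(v) signal::sgolayfilt(v, p = polyorder, n = window,
                                      m = order) * scale
  if (is.matrix(absorbance)) {
    stopifnot(ncol(absorbance) == length(grid))
    t(apply(absorbance, 1L, f))
  } else {
    stopifnot(length(absorbance) == length(grid))
    f(absorbance)
  }
}

#' Row normalizations
#'
#' Per-spectrum normalizations applied before any column scaling:
#' \describe{
#'   \item{\code{normalizeArea}}{divide by the sum over all wavenumbers;
#'     non-negative spectra then sum to 1. Invariant to positive rescaling,
#'     which is what cancels multiplicative pathlength variation.}
#'   \item{\code{normalizeMinmax}}{subtract the minimum, divide by the
#'     range; output spans exactly [0, 1].}
#'   \item{\code{normalizeAmide}}{subtract the global minimum, divide by
#'     (max absorbance in the amide I window - global minimum); the amide I
#'     maximum maps to exactly 1 and values above it may exceed 1.}
#'   \item{\code{normalizeVector}}{divide by the Euclidean norm (defined on
#'     derivative spectra); output has unit L2 norm.}
#' }
#'
#' @param x Numeric vector (one spectrum).
#' @return Normalized vector.
#' @name row-normalization
NULL

#' @rdname row-normalization
#' @export
normalizeArea <- function(x) {
  s <- sum(x)
  if (s == 0) stop("cannot area-normalize: absorbance sums to zero")
  x / s
}

#' @rdname row-normalization
#' @export
normalizeMinmax <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("cannot min-max normalize a constant spectrum")
  (x - lo) / (hi - lo)
}

#' @rdname row-normalization
#' @param grid Wavenumber grid aligned to \code{x}.
#' @param window High/low bounds (cm\eqn{^{-1}}) of the amide I region.
#' @export
normalizeAmide <- function(x, grid, window = c(1650, 1600)) {
  assertWavenumberGrid(grid)
  stopifnot(length(x) == length(grid))
  hi <- max(window); lo <- min(window)
  in_win <- grid <= hi & grid >= lo
  if (!any(in_win)) stop("amide window does not intersect the grid")
  gmin <- min(x)
  amax <- max(x[in_win])
  if (amax <= gmin) {
    stop("amide window maximum does not exceed the global minimum")
  }
  (x - gmin) / (amax - gmin)
}

#' @rdname row-normalization
#' @export
normalizeVector <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum")
  x / nrm
}

applyRowNormalization <- function(mat, grid, normalization, amide_window) {
  f <- switch(normalization,
              none = return(mat),
              area = normalizeArea,
              minmax = normalizeMinmax,
              amide = function(v) normalizeAmide(v, grid, amide_window),
              vector = normalizeVector)
  t(apply(mat, 1L, f))
}

#' Column-wise scaling of a feature matrix
#'
#' Scales each wavelength (column) across samples: \code{mean_center}
#' subtracts the column mean; \code{pareto} additionally divides by the
#' square root of the column SD; \code{unit_variance} divides by the column
#' SD. SDs use the n-1 denominator. Constant columns are centered and left
#' at zero (0/0 -> 0). When \code{center}/\code{scale} vectors are supplied
#' (e.g. statistics frozen from a development set), they are applied as-is
#' instead of being recomputed -- the leakage guard for external validation.
#'
#' @param mat Spectra-in-rows numeric matrix (>= 2 rows unless frozen
#'   statistics are supplied).
#' @param method Scaling method.
#' @param center,scale Optional frozen statistics.
#' @return Scaled matrix with attributes \code{"center"} and \code{"scale"}
#'   recording the statistics applied.
#' @export
scaleColumns <- function(mat, method = c("none", "mean_center", "pareto",
                                         "unit_variance"),
                         center = NULL, scale = NULL) {
  method <- match.arg(method)
  if (method == "none") {
    attr(mat, "center") <- rep(0, ncol(mat))
    attr(mat, "scale") <- rep(1, ncol(mat))
    return(mat)
  }
  frozen <- !is.null(center)
  if (!frozen && nrow(mat) < 2L) {
    stop("column scaling needs at least 2 rows")
  }
  if (!frozen) {
    center <- colMeans(mat)
    sds <- colSds(mat)
    scale <- switch(method,
                    mean_center = rep(1, ncol(mat)),
                    pareto = sqrt(sds),
                    unit_variance = sds)
    scale[scale == 0] <- Inf  # 0/0 -> 0 rule for constant columns
  }
  out <- sweep(sweep(mat, 2L, center, `-`), 2L, scale, `/`)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Run the full preprocessing pipeline
#'
#' Stages in order: replicate averaging, ATR correction, Savitzky-Golay
#' derivative, row normalization, column scaling. The returned SpectraSet
#' records the configuration and the column-scaling statistics in its
#' metadata (\code{metadata(x)$preprocess}, \code{metadata(x)$scaling_stats}),
#' and keeps the normalized pre-scaling matrix in
#' \code{metadata(x)$prescale} for fold-change/t-test use.
#'
#' @param collection A \linkS4class{SpectraSet}.
#' @param config A [preprocessConfig()].
#' @param frozen_stats Optional list with \code{center} and \code{scale}
#'   components (from a previous run's \code{scaling_stats}) applied instead
#'   of statistics computed on \code{collection}.
#' @return A preprocessed \linkS4class{SpectraSet}.
#' @export
applyPreprocess <- function(collection, config = preprocessConfig(),
                            frozen_stats = NULL) {
  stopifnot(methods::is(collection, "SpectraSet"),
            inherits(config, "preprocessConfig"))
  avg <- averageReplicates(collection, config$averaging_group_size)
  grid <- wavenumbers(avg)
  mat <- spectraMatrix(avg)
  if (config$atr_correction) mat <- atrCorrection(mat, grid)
  if (config$derivative_order != "none") {
    mat <- savgolDerivative(
      mat, grid,
      order = if (config$derivative_order == "first") 1L else 2L,
      window = config$sg_window, polyorder = config$sg_polyorder)
  }
  mat <- applyRowNormalization(mat, grid, config$normalization,
                               config$amide_window)
  prescale <- mat
  mat <- scaleColumns(mat, config$scaling,
                      center = frozen_stats$center,
                      scale = frozen_stats$scale)
  stats <- list(center = attr(mat, "center"), scale = attr(mat, "scale"))
  attr(mat, "center") <- NULL
  attr(mat, "scale") <- NULL
  md <- S4Vectors::metadata(avg)
  md$preprocess <- config
  md$scaling_stats <- stats
  md$prescale <- prescale
  SpectraSet(t(mat), grid, sampleMeta(avg), metadata = md)
}
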