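# Univariate spectral-marker selection: per-wavenumber Student's t-test,
# fold change, and the VIP >= 1.0 & p < 0.05 selection rule.

#' Two-sample pooled-variance Student's t-test
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) variant instead.
#' @return Named list with \code{t} and two-sided \code{p}. A zero pooled
#'   variance with equal means gives t = 0, p = 1.
#' @export
studentsT <- function(group_a, group_b, welch = FALSE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  dm <- mean(group_a) - mean(group_b)
  if (va == 0 && vb == 0) {
    if (dm == 0) return(list(t = 0, p = 1))
    return(list(t = sign(dm) * Inf, p = 0))
  }
  if (welch) {
    se2 <- va / na + vb / nb
    t <- dm / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Fold change between group means
#'
#' @param group_a,group_b Numeric vectors; the ratio is mean(a)/mean(b)
#'   (first-named group over comparator).
#' @return Single number.
#' @export
foldChange <- function(group_a, group_b) {
  mb <- mean(group_b)
  if (mb == 0) stop("fold change undefined: comparator group mean is zero")
  mean(group_a) / mb
}

#' Build the spectral marker table
#'
#' Per-wavenumber VIP, pooled t statistic, two-sided p-value and fold
#' change (first-named group over comparator), with the selection rule
#' VIP >= 1.0 (inclusive) and p < 0.05 (exclusive). Statistics should be
#' computed on normalized but unscaled intensities (column scaling would
#' distort the fold-change interpretation); pass the pre-scaling matrix
#' kept by [applyPreprocess()]. No multiple-testing correction is applied
#' by default (\code{adjust = "BH"} enables Benjamini-Hochberg on the
#' p-values entering the rule).
#'
#' @param features Spectra-in-rows matrix of normalized intensities.
#' @param labels Binary label per row; the \code{positive} group is the
#'   fold-change numerator.
#' @param vip_scores VIP vector aligned to the wavenumber grid.
#' @param grid Wavenumber grid (one entry per feature column).
#' @param positive First-named group.
#' @param vip_cut VIP cutoff (inclusive), default 1.0.
#' @param alpha p-value cutoff (exclusive), default 0.05.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @param bands Optional band template \code{data.frame}; wavenumbers
#'   within one sigma of a template center inherit its assignment label.
#' @return \code{data.frame} with columns wavenumber, assignment, vip, t,
#'   p, fold_change, selected.
#' @export
buildMarkerTable <- function(features, labels, vip_scores, grid,
                             positive = "UC", vip_cut = 1.0, alpha = 0.05,
                             adjust = c("none", "BH"), bands = NULL) {
  adjust <- match.arg(adjust)
  X <- as.matrix(features)
  stopifnot(length(vip_scores) == ncol(X), length(grid) == ncol(X),
            length(labels) == nrow(X))
  is_a <- labels == positive
  if (sum(is_a) < 2L || sum(!is_a) < 2L) {
    stop("each group needs at least 2 rows")
  }
  tt <- apply(X, 2L, function(col) {
    r <- studentsT(col[is_a], col[!is_a])
    c(r$t, r$p)
  })
  fc <- apply(X, 2L, function(col) {
    mb <- mean(col[!is_a])
    if (mb == 0) NA_real_ else mean(col[is_a]) / mb
  })
  p <- tt[2L, ]
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  assignment <- rep(NA_character_, ncol(X))
  if (!is.null(bands)) {
    for (i in seq_len(nrow(bands))) {
      hit <- abs(grid - bands$center[i]) <= bands$sigma[i]
      assignment[hit] <- bands$assignment[i]
    }
  }
  data.frame(wavenumber = grid, assignment = assignment,
             vip = vip_scores, t = tt[1L, ], p = p, fold_change = fc,
             selected = vip_scores >= vip_cut & p < alpha,
             stringsAsFactors = FALSE)
}
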