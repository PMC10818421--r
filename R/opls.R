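# From-scratch OPLS-DA for a binary class label: orthogonal-signal-
# correction fit, prediction, cross-validated Q2Y, autofit of the number of
# orthogonal components, permutation-test validation with intercept rules,
# CV-ANOVA, and VIP scores.

#' OplsModel: a fitted binary OPLS-DA model
#'
#' Slots hold the quantities of the orthogonal projections to latent
#' structures decomposition with a single predictive component:
#' \describe{
#'   \item{xCenter, xScale}{column statistics applied to X before fitting.}
#'   \item{yMean}{mean of the 0/1-coded response.}
#'   \item{w, p, t}{predictive weight (unit norm), loading and score
#'     (the score plot's t[1]).}
#'   \item{Wo, Po, To}{orthogonal weights, loadings and scores, one column
#'     per orthogonal component (to[1] is \code{To[, 1]}).}
#'   \item{coef}{regression coefficient of centered y on t.}
#'   \item{R2Y, Q2Y}{training-fit explained variance and cross-validated
#'     predictive ability.}
#'   \item{levels, positive}{class labels; \code{positive} is coded 1.}
#' }
#' @exportClass OplsModel
setClass("OplsModel", representation(
  xCenter = "numeric", xScale = "numeric", yMean = "numeric",
  w = "numeric", p = "numeric", t = "numeric",
  Wo = "matrix", Po = "matrix", To = "matrix",
  nOrtho = "integer", coef = "numeric",
  R2Y = "numeric", Q2Y = "numeric",
  levels = "character", positive = "character"))

setValidity("OplsModel", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@w^2)) - 1) > 1e-8) {
    msg <- c(msg, "predictive weight w must have unit norm")
  }
  for (j in seq_len(object@nOrtho)) {
    ip <- abs(sum(object@t * object@To[, j]))
    lim <- 1e-8 * sqrt(sum(object@t^2)) * sqrt(sum(object@To[, j]^2))
    if (ip > max(lim, 1e-12)) {
      msg <- c(msg, sprintf("t not orthogonal to To[, %d]", j))
    }
  }
  if (object@R2Y < -1e-12 || object@R2Y > 1 + 1e-12) {
    msg <- c(msg, "R2Y must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "OplsModel", function(object) {
  cat(sprintf("OplsModel: 1 predictive + %d orthogonal component(s)\n",
              object@nOrtho))
  cat(sprintf("  n = %d, p = %d, positive class = '%s'\n",
              length(object@t), length(object@w), object@positive))
  cat(sprintf("  R2Y = %.3f  Q2Y = %s\n", object@R2Y,
              if (length(object@Q2Y)) sprintf("%.3f", object@Q2Y) else "NA"))
})

# 0/1 encoding: positive class -> 1. Default positive class is the
# lexicographically larger label (UC over HC, RM over NRM).
encodeLabels <- function(y, positive = NULL) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1))) stop("numeric y must be coded 0/1")
    return(list(y01 = as.numeric(y), levels = c("0", "1"), positive = "1"))
  }
  y <- as.character(y)
  if (anyNA(y)) stop("labels contain missing values")
  lev <- sort(unique(y))
  if (length(lev) != 2L) {
    stop(sprintf("need exactly 2 classes, found %d", length(lev)))
  }
  if (is.null(positive)) positive <- lev[2L]
  if (!positive %in% lev) stop("positive class not present in labels")
  list(y01 = as.numeric(y == positive), levels = lev, positive = positive)
}

# Core OSC-PLS decomposition on a centered/scaled matrix and centered y.
oplsCore <- function(Xc, yc, n_ortho) {
  n <- nrow(Xc); p <- ncol(Xc)
  Wo <- matrix(0, p, 0); Po <- matrix(0, p, 0); To <- matrix(0, n, 0)
  for (j in seq_len(n_ortho)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("no y-correlated variation left in X")
    w <- w / nw
    t <- drop(Xc %*% w)
    pl <- drop(crossprod(Xc, t)) / sum(t^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10 * sqrt(sum(pl^2))) {
      stop(sprintf(
        "no orthogonal variation left after %d component(s); reduce n_ortho",
        j - 1L))
    }
    wo <- wo / nwo
    to <- drop(Xc %*% wo)
    po <- drop(crossprod(Xc, to)) / sum(to^2)
    Xc <- Xc - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  w <- drop(crossprod(Xc, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("X carries no y-correlated variation")
  w <- w / nw
  t <- drop(Xc %*% w)
  pl <- drop(crossprod(Xc, t)) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  list(w = w, p = pl, t = t, Wo = Wo, Po = Po, To = To, coef = cc)
}

#' Fit a binary OPLS-DA model
#'
#' The class label is coded 0/1 and mean-centered; X columns are centered
#' (and optionally unit-scaled -- normally scaling is done upstream by
#' [scaleColumns()] as part of preprocessing). For each orthogonal
#' component, variation in X uncorrelated with y is split off by
#' orthogonalizing the loading of the current predictive score against the
#' predictive weight and deflating X; the final predictive component is
#' extracted from the filtered matrix. R2Y is the training-fit explained
#' variance of y; Q2Y comes from k-fold cross-validation refitting the
#' whole procedure in each fold.
#'
#' @param X Spectra-in-rows numeric matrix (or a preprocessed
#'   \linkS4class{SpectraSet}).
#' @param y Binary labels (factor/character, or numeric 0/1).
#' @param n_ortho Number of orthogonal components (>= 0).
#' @param cv_folds Folds for the fit-time Q2Y; \code{0} skips Q2Y.
#' @param seed Seed for the CV fold assignment.
#' @param positive Label coded as 1 (default: lexicographically larger).
#' @param scale Also unit-variance scale X columns inside the fit.
#' @return An \linkS4class{OplsModel}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 12), 40)
#' y <- rep(c("A", "B"), each = 20)
#' X[y == "B", 1:3] <- X[y == "B", 1:3] + 2
#' m <- fitOpls(X, y, n_ortho = 1, seed = 1)
#' @export
fitOpls <- function(X, y, n_ortho = 0L, cv_folds = 10L, seed = 1L,
                    positive = NULL, scale = FALSE) {
  if (methods::is(X, "SpectraSet")) X <- spectraMatrix(X)
  X <- as.matrix(X)
  if (nrow(X) < 4L) stop("need at least 4 rows to fit OPLS-DA")
  enc <- encodeLabels(y, positive)
  if (length(unique(enc$y01)) < 2L) stop("y contains a single class")
  n_ortho <- as.integer(n_ortho)
  if (n_ortho >= min(nrow(X) - 1L, ncol(X))) {
    stop("n_ortho must be smaller than the rank bound min(n - 1, p)")
  }
  ctr <- colMeans(X)
  scl <- if (scale) { s <- colSds(X); s[s == 0] <- Inf; s } else
    rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2L, ctr, `-`), 2L, scl, `/`)
  ym <- mean(enc$y01)
  yc <- enc$y01 - ym
  core <- oplsCore(Xc, yc, n_ortho)
  fitted <- ym + core$coef * core$t
  ss_tot <- sum(yc^2)
  r2y <- 1 - sum((enc$y01 - fitted)^2) / ss_tot
  q2 <- if (cv_folds >= 2L) {
    q2Details(X, enc$y01, n_ortho, folds = cv_folds, seed = seed,
              scale = scale)$q2
  } else numeric(0)
  methods::new("OplsModel", xCenter = ctr, xScale = scl, yMean = ym,
               w = core$w, p = core$p, t = core$t,
               Wo = core$Wo, Po = core$Po, To = core$To,
               nOrtho = n_ortho, coef = core$coef,
               R2Y = max(0, min(1, r2y)), Q2Y = q2,
               levels = enc$levels, positive = enc$positive)
}

#' Predict from a fitted OPLS-DA model
#'
#' Applies the stored centering/scaling, removes the orthogonal variation
#' with the stored orthogonal weights/loadings, projects on the predictive
#' weight and regresses to a continuous prediction (ypred) on the 0/1
#' scale. The class call is the positive class when ypred >= 0.5.
#'
#' @param object An \linkS4class{OplsModel}.
#' @param newdata Spectra-in-rows matrix (or preprocessed SpectraSet) with
#'   the training column count.
#' @return \code{data.frame} with columns \code{ypred}, \code{t} (predictive
#'   score), and \code{class}.
#' @export
setMethod("predict", "OplsModel", function(object, newdata) {
  if (methods::is(newdata, "SpectraSet")) newdata <- spectraMatrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@w)) {
    stop(sprintf("newdata has %d columns; model was trained on %d",
                 ncol(newdata), length(object@w)))
  }
  Xc <- sweep(sweep(newdata, 2L, object@xCenter, `-`), 2L, object@xScale, `/`)
  for (j in seq_len(object@nOrtho)) {
    to <- drop(Xc %*% object@Wo[, j])
    Xc <- Xc - tcrossprod(to, object@Po[, j])
  }
  t_new <- drop(Xc %*% object@w)
  ypred <- object@yMean + object@coef * t_new
  cls <- ifelse(ypred >= 0.5, object@positive,
                setdiff(object@levels, object@positive))
  data.frame(ypred = ypred, t = t_new, class = cls,
             stringsAsFactors = FALSE)
})

# Stratified k-fold assignment used by Q2Y CV (also re-exported through the
# benchmark module's kfoldSplit).
stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (lev in unique(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    # shuffle fold labels within class blocks already random; rotate so fold
    # sizes stay balanced across classes
    fold
  })
}

q2Details <- function(X, y01, n_ortho, folds = 10L, seed = 1L,
                      scale = FALSE) {
  n <- length(y01)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > n) stop("folds must not exceed the number of rows")
  fold <- stratifiedFolds(y01, folds, subSeed(seed, 17L))
  resid <- numeric(n)
  for (f in sort(unique(fold))) {
    test <- fold == f
    ytr <- y01[!test]
    if (length(unique(ytr)) < 2L) {
      stop("degenerate fold: training part contains a single class")
    }
    m <- fitOpls(X[!test, , drop = FALSE], ytr, n_ortho,
                 cv_folds = 0L, scale = scale)
    pr <- predict(m, X[test, , drop = FALSE])
    resid[test] <- y01[test] - pr$ypred
  }
  press <- sum(resid^2)
  ss <- sum((y01 - mean(y01))^2)
  list(q2 = 1 - press / ss, press = press, ss = ss, residuals = resid,
       n_components = n_ortho + 1L, folds = fold)
}

#' Cross-validated Q2Y
#'
#' \eqn{Q^2 = 1 - \sum (y - \hat y_{oof})^2 / \sum (y - \bar y)^2} with
#' out-of-fold predictions from refitting the full OPLS procedure per
#' stratified fold.
#'
#' @inheritParams fitOpls
#' @param folds Number of CV folds (>= 2).
#' @return Q2Y as a single number.
#' @export
q2y <- function(X, y, n_ortho = 0L, folds = 10L, seed = 1L,
                positive = NULL, scale = FALSE) {
  if (methods::is(X, "SpectraSet")) X <- spectraMatrix(X)
  enc <- encodeLabels(y, positive)
  q2Details(as.matrix(X), enc$y01, as.integer(n_ortho), folds = folds,
            seed = seed, scale = scale)$q2
}

#' Choose the number of orthogonal components
#'
#' Emulates an automatic component fit: orthogonal components are added
#' greedily while the cross-validated Q2Y improves by more than
#' \code{q2_gain_threshold}; the last accepted count is returned.
#'
#' @inheritParams fitOpls
#' @param max_ortho Upper bound on orthogonal components.
#' @param q2_gain_threshold Minimum Q2Y improvement to accept a component.
#' @return Integer number of orthogonal components (possibly 0).
#' @export
autofitOpls <- function(X, y, max_ortho = 5L, q2_gain_threshold = 0.01,
                        cv_folds = 10L, seed = 1L, positive = NULL,
                        scale = FALSE) {
  if (methods::is(X, "SpectraSet")) X <- spectraMatrix(X)
  X <- as.matrix(X)
  enc <- encodeLabels(y, positive)
  best_k <- 0L
  best_q2 <- q2Details(X, enc$y01, 0L, folds = cv_folds, seed = seed,
                       scale = scale)$q2
  k <- 0L
  while (k < max_ortho) {
    k <- k + 1L
    q2k <- tryCatch(
      q2Details(X, enc$y01, k, folds = cv_folds, seed = seed,
                scale = scale)$q2,
      error = function(e) NA_real_)
    if (is.na(q2k) || q2k <= best_q2 + q2_gain_threshold) break
    best_q2 <- q2k
    best_k <- k
  }
  best_k
}

#' Permutation-test validation of an OPLS-DA model
#'
#' Refits the model \code{n_permutations} times with randomly permuted
#' labels, recording for each permutation the absolute Pearson correlation
#' of the permuted with the original labels, R2Y and Q2Y. Straight lines
#' are fitted through the (correlation, metric) points -- including the
#' observed model at correlation 1 -- and their values at correlation 0 are
#' the R2Y and Q2Y intercepts. The model is flagged valid when the R2Y
#' intercept is below 0.4 and the Q2Y intercept below 0.05. Empirical
#' p-values use the add-one rule (permutations at least as good as
#' observed + 1) / (n + 1).
#'
#' @inheritParams fitOpls
#' @param n_permutations Number of label permutations (>= 1).
#' @return List of class \code{"permutationReport"}: \code{observed} (R2Y,
#'   Q2Y), \code{permuted} (data.frame correlation/R2Y/Q2Y),
#'   \code{intercepts}, \code{valid}, \code{p_values}.
#' @export
permutationTest <- function(X, y, n_ortho = 0L, n_permutations = 100L,
                            cv_folds = 10L, seed = 1L, positive = NULL,
                            scale = FALSE) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (methods::is(X, "SpectraSet")) X <- spectraMatrix(X)
  X <- as.matrix(X)
  enc <- encodeLabels(y, positive)
  y01 <- enc$y01
  obs_fit <- fitOpls(X, y01, n_ortho, cv_folds = cv_folds, seed = seed,
                     scale = scale)
  obs <- c(R2Y = obs_fit@R2Y, Q2Y = obs_fit@Q2Y)
  perm <- matrix(NA_real_, n_permutations, 3,
                 dimnames = list(NULL, c("correlation", "R2Y", "Q2Y")))
  for (i in seq_len(n_permutations)) {
    yp <- withSeed(subSeed(seed, 23L, i), sample(y01))
    r <- abs(stats::cor(yp, y01))
    if (is.na(r)) r <- 0
    fi <- fitOpls(X, yp, n_ortho, cv_folds = cv_folds,
                  seed = subSeed(seed, 29L, i), scale = scale)
    perm[i, ] <- c(r, fi@R2Y, fi@Q2Y)
  }
  perm <- as.data.frame(perm)
  fit_int <- function(metric) {
    xx <- c(perm$correlation, 1)
    yy <- c(perm[[metric]], obs[[metric]])
    unname(stats::coef(stats::lm(yy ~ xx))[1L])
  }
  intercepts <- c(R2Y = fit_int("R2Y"), Q2Y = fit_int("Q2Y"))
  p_values <- c(
    R2Y = (1 + sum(perm$R2Y >= obs[["R2Y"]])) / (1 + n_permutations),
    Q2Y = (1 + sum(perm$Q2Y >= obs[["Q2Y"]])) / (1 + n_permutations))
  structure(list(
    observed = obs, permuted = perm, intercepts = intercepts,
    valid = unname(intercepts[["R2Y"]] < 0.4 & intercepts[["Q2Y"]] < 0.05),
    p_values = p_values, n_permutations = n_permutations),
    class = "permutationReport")
}

#' @export
print.permutationReport <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations)\n", x$n_permutations))
  cat(sprintf("  observed  R2Y = %.3f  Q2Y = %.3f\n",
              x$observed[["R2Y"]], x$observed[["Q2Y"]]))
  cat(sprintf("  intercepts R2Y = %.3f  Q2Y = %.3f  (valid: %s)\n",
              x$intercepts[["R2Y"]], x$intercepts[["Q2Y"]], x$valid))
  cat(sprintf("  empirical p: R2Y %.3f, Q2Y %.3f\n",
              x$p_values[["R2Y"]], x$p_values[["Q2Y"]]))
  invisible(x)
}

#' CV-ANOVA significance test for Q2Y
#'
#' F-test of the cross-validated predictive residuals against total label
#' variation: \eqn{F = [(SS_y - PRESS)/d_1] / [PRESS/d_2]} with
#' \eqn{d_1} the number of model components consumed and
#' \eqn{d_2 = n - 1 - d_1}. When PRESS >= SS (no predictive ability) the
#' p-value is 1 by convention.
#'
#' @param press_residuals Out-of-fold residuals (from the Q2Y CV).
#' @param y Binary labels or 0/1 vector.
#' @param n_components Components consumed (orthogonal + 1 predictive).
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
cvAnova <- function(press_residuals, y, n_components = 1L) {
  enc <- encodeLabels(y)
  press <- sum(press_residuals^2)
  ss <- sum((enc$y01 - mean(enc$y01))^2)
  d1 <- as.integer(n_components)
  d2 <- length(enc$y01) - 1L - d1
  if (d2 < 1L) stop("too few observations for CV-ANOVA")
  if (press >= ss) {
    return(list(F = ((ss - press) / d1) / (press / d2),
                df1 = d1, df2 = d2, p = 1))
  }
  f <- ((ss - press) / d1) / (press / d2)
  list(F = f, df1 = d1, df2 = d2,
       p = stats::pf(f, d1, d2, lower.tail = FALSE))
}

#' VIP scores (variable influence on projection)
#'
#' Computed over the predictive component: with a single predictive
#' component and unit-norm weight w,
#' \eqn{VIP_j = \sqrt{p}\,|w_j|} (p = number of variables), so the squared
#' VIPs average exactly 1 and VIP >= 1 marks above-average contributors.
#'
#' @param model A fitted \linkS4class{OplsModel}.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vipScores <- function(model) {
  stopifnot(methods::is(model, "OplsModel"))
  sqrt(length(model@w)) * abs(model@w)
}
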