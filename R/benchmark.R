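# Classifier benchmark: logistic regression, KNN, decision tree, random
# forest, linear/rbf SVM and OPLS-DA, with exhaustive hyperparameter grid
# search, stratified sample-grouped 10-fold CV, manual metric formulas with
# 95% CIs, and site-based external validation.

#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive Positive class (default \code{"RM"}).
#' @return Named list with \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusionCounts <- function(y_true, y_pred, positive = "RM") {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fn <- sum(y_true == positive & y_pred != positive)
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' accuracy = (TP+TN)/total; precision = TP/(TP+FP); recall = TP/(TP+FN);
#' F1 = 2 (precision x recall)/(precision + recall). Zero-denominator cases
#' return 0 with a warning.
#'
#' @param counts List with TP/FP/TN/FN (see [confusionCounts()]).
#' @return Named numeric vector (accuracy, precision, recall, f1).
#' @export
metricsFromConfusion <- function(counts) {
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0L) stop("empty confusion table")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what))
      0
    } else num / den
  }
  acc <- (counts$TP + counts$TN) / total
  prec <- safe(counts$TP, counts$TP + counts$FP, "precision")
  rec <- safe(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (prec + rec == 0) {
    warning("F1 undefined (precision + recall = 0); returning 0")
    0
  } else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Rank-based ROC-AUC
#'
#' Mann-Whitney AUC with mid-rank tie handling: the probability that a
#' random positive scores above a random negative (ties count 1/2).
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param y_true Label vector containing both classes.
#' @param positive Positive class.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, y_true, positive = "RM") {
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present for AUC")
  r <- rank(scores)  # mid-ranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified (optionally sample-grouped) k-fold assignment
#'
#' Partitions n cases into k folds of sizes differing by at most one,
#' stratified by label. With \code{groups} supplied, whole groups (e.g. the
#' averaged spectra of one sample) are assigned to folds as units so no
#' group straddles a fold boundary.
#'
#' @param n Number of cases.
#' @param k Number of folds.
#' @param labels Stratification labels (length n).
#' @param groups Optional grouping vector (length n).
#' @param seed Seed for the assignment.
#' @return Integer fold vector of length n with values in 1..k.
#' @export
kfoldSplit <- function(n, k = 10L, labels = rep(1L, n), groups = NULL,
                       seed = 1L) {
  if (k > n) stop("k must not exceed n")
  if (k < 2L) stop("k must be >= 2")
  if (is.null(groups)) groups <- seq_len(n)
  stopifnot(length(labels) == n, length(groups) == n)
  glab <- tapply(as.character(labels), groups, function(v) v[1L])
  gids <- names(glab)
  gfold <- integer(length(gids)); names(gfold) <- gids
  withSeed(seed, {
    offset <- sample.int(k, 1L) - 1L
    pos <- 0L
    for (lev in sample(unique(glab))) {
      ids <- sample(gids[glab == lev])
      for (g in ids) {
        gfold[g] <- ((pos + offset) %% k) + 1L
        pos <- pos + 1L
      }
    }
  })
  unname(gfold[as.character(groups)])
}

#' Algorithm specification for the benchmark
#'
#' Default hyperparameter grids contain the winners reported for this kind
#' of task (LR C = 1; rbf SVM gamma = 1e-4 with C = 100 or 1000):
#' LR C in \{0.01, 0.1, 1, 10, 100\}; SVM C in \{0.1, 1, 10, 100, 1000\},
#' gamma in \{1e-5 .. 1e-1\}; KNN k in \{3, 5, 7, 9, 11\}; decision tree
#' max depth 2..10; random forest 100/500 trees x depth \{unlimited, 5,
#' 10\}; OPLS-DA orthogonal components 0..2.
#'
#' @param name One of \code{"LR"}, \code{"KNN"}, \code{"DT"}, \code{"RF"},
#'   \code{"SVM_linear"}, \code{"SVM_rbf"}, \code{"OPLSDA"}.
#' @param grid Optional named list of candidate hyperparameter values
#'   overriding the default grid.
#' @return List of class \code{"algorithmSpec"}.
#' @export
algorithmSpec <- function(name = c("LR", "KNN", "DT", "RF", "SVM_linear",
                                   "SVM_rbf", "OPLSDA"),
                          grid = NULL) {
  name <- match.arg(name)
  if (is.null(grid)) {
    grid <- switch(name,
      LR = list(C = c(0.01, 0.1, 1, 10, 100)),
      KNN = list(k = c(3, 5, 7, 9, 11)),
      DT = list(maxdepth = 2:10),
      RF = list(ntree = c(100, 500), maxdepth = c(Inf, 5, 10)),
      SVM_linear = list(C = c(0.1, 1, 10, 100, 1000)),
      SVM_rbf = list(C = c(0.1, 1, 10, 100, 1000),
                     gamma = c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)),
      OPLSDA = list(n_ortho = 0:2))
  }
  if (!length(grid) || any(!lengths(grid))) stop("grid must be non-empty")
  structure(list(name = name, grid = grid), class = "algorithmSpec")
}

# Tie-break ordering: candidates sorted "simplest first" per algorithm, so
# the first argmax of inner-CV accuracy is the simplest winner.
orderCandidates <- function(name, cand) {
  ord <- switch(name,
    LR = order(cand$C),
    SVM_linear = order(cand$C),
    SVM_rbf = order(cand$C, cand$gamma),
    KNN = order(cand$k),
    DT = order(cand$maxdepth),
    RF = order(cand$ntree, -is.infinite(cand$maxdepth), cand$maxdepth),
    OPLSDA = order(cand$n_ortho))
  cand[ord, , drop = FALSE]
}

# Fit one algorithm with fixed hyperparameters; returns an object with a
# score() closure mapping a new X to a continuous positive-class score.
fitClassifier <- function(name, params, X, y, positive, seed = 1L) {
  y <- as.character(y)
  neg <- setdiff(sort(unique(y)), positive)
  yf <- factor(y, levels = c(neg, positive))
  withSeed(subSeed(seed, 37L), switch(name,
    LR = {
      # ridge-penalized logistic regression; lambda = 1/(C n) matches the
      # C convention of penalized LR implementations
      lam <- 1 / (params$C * nrow(X))
      fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                            lambda = lam, standardize = FALSE)
      list(score = function(Z) drop(stats::predict(fit, Z,
                                                   type = "response")))
    },
    KNN = {
      k <- params$k
      list(score = function(Z) {
        pr <- class::knn(X, Z, yf, k = k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == positive, p, 1 - p)
      })
    },
    DT = {
      df <- as.data.frame(X)
      colnames(df) <- paste0("V", seq_len(ncol(X)))
      df$.y <- yf
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = params$maxdepth, cp = 0.001,
                            minsplit = 5, xval = 0))
      list(score = function(Z) {
        zd <- as.data.frame(Z)
        colnames(zd) <- paste0("V", seq_len(ncol(Z)))
        stats::predict(fit, zd)[, positive]
      })
    },
    RF = {
      args <- list(x = X, y = yf, ntree = params$ntree)
      if (is.finite(params$maxdepth)) args$maxnodes <- 2^params$maxdepth
      fit <- do.call(randomForest::randomForest, args)
      list(score = function(Z) {
        stats::predict(fit, Z, type = "prob")[, positive]
      })
    },
    SVM_linear = ,
    SVM_rbf = {
      fit <- e1071::svm(X, yf, kernel = if (name == "SVM_rbf") "radial"
                                        else "linear",
                        cost = params$C,
                        gamma = if (name == "SVM_rbf") params$gamma
                                else 1 / ncol(X),
                        scale = FALSE)
      list(score = function(Z) {
        dv <- attr(stats::predict(fit, Z, decision.values = TRUE),
                   "decision.values")
        # decision values are positive for the class named first in the
        # "A/B" column label; orient toward the positive class
        first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1]][1]
        if (first == positive) drop(dv) else -drop(dv)
      })
    },
    OPLSDA = {
      fit <- fitOpls(X, yf, n_ortho = params$n_ortho, cv_folds = 0L,
                     positive = positive)
      list(score = function(Z) predict(fit, Z)$ypred)
    }))
}

scoreToClass <- function(name, scores, positive, negative) {
  thr <- 0.5  # probability-like scores; SVM decision values cut at 0
  if (name %in% c("SVM_linear", "SVM_rbf")) thr <- 0
  ifelse(scores >= thr, positive, negative)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every grid point by stratified inner cross-validation and
#' returns the hyperparameters maximizing mean inner-CV accuracy. Ties
#' break toward the simplest model (smaller C, smaller gamma, fewer
#' neighbors, shallower tree, fewer trees, fewer components).
#'
#' @param spec An [algorithmSpec()].
#' @param X Spectra-in-rows feature matrix.
#' @param y Binary labels.
#' @param inner_folds Inner CV folds (default 5).
#' @param positive Positive class.
#' @param groups Optional grouping vector for leakage-free inner folds.
#' @param seed Seed.
#' @return List with \code{params} (named list) and \code{cv_accuracy}.
#' @export
gridSearch <- function(spec, X, y, inner_folds = 5L, positive = "RM",
                       groups = NULL, seed = 1L) {
  stopifnot(inherits(spec, "algorithmSpec"))
  X <- as.matrix(X); y <- as.character(y)
  cand <- orderCandidates(spec$name,
                          expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE))
  fold <- kfoldSplit(length(y), k = inner_folds, labels = y,
                     groups = groups, seed = subSeed(seed, 41L))
  neg <- setdiff(sort(unique(y)), positive)
  acc <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    params <- as.list(cand[ci, , drop = FALSE])
    correct <- 0L
    for (f in sort(unique(fold))) {
      test <- fold == f
      fit <- tryCatch(
        fitClassifier(spec$name, params, X[!test, , drop = FALSE],
                      y[!test], positive, seed = subSeed(seed, 43L, f)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sc <- fit$score(X[test, , drop = FALSE])
      correct <- correct +
        sum(scoreToClass(spec$name, sc, positive, neg) == y[test])
    }
    acc[ci] <- correct / length(y)
  }
  best <- which.max(acc)
  list(params = as.list(cand[best, , drop = FALSE]),
       cv_accuracy = acc[best])
}

foldMetrics <- function(name, scores, y_true, positive, negative) {
  pred <- scoreToClass(name, scores, positive, negative)
  m <- suppressWarnings(
    metricsFromConfusion(confusionCounts(y_true, pred, positive)))
  auc <- if (length(unique(y_true)) < 2L) NA_real_ else
    rocAuc(scores, y_true, positive)
  c(m, roc_auc = auc)
}

ciSummary <- function(vals, k) {
  vals <- vals[!is.na(vals)]
  m <- mean(vals)
  half <- 1.96 * stats::sd(vals) / sqrt(length(vals))
  c(mean = m, lo = m - half, hi = m + half)
}

#' Benchmark classification algorithms with k-fold cross-validation
#'
#' For each algorithm: hyperparameters are chosen once by inner-CV grid
#' search, then train/test accuracy, precision, recall, F1 and ROC-AUC are
#' computed per outer fold and summarized as mean with a normal-
#' approximation 95\% CI (mean +/- 1.96 SD/sqrt(k); bounds may exceed
#' [0, 1]). Outer folds are stratified and grouped by sample, so the
#' averaged spectra of one sample never straddle a fold boundary
#' (\code{cv_unit = "spectrum"} disables the grouping).
#'
#' @param features Preprocessed \linkS4class{SpectraSet} or spectra-in-rows
#'   matrix.
#' @param labels Binary labels, one per row of \code{features}.
#' @param algorithms List of [algorithmSpec()]s.
#' @param k Outer folds (default 10).
#' @param positive Positive class.
#' @param sample_ids Grouping ids (taken from the SpectraSet when omitted).
#' @param cv_unit \code{"sample"} (grouped, default) or \code{"spectrum"}.
#' @param seed Seed.
#' @return \code{data.frame} of class \code{"benchmarkReport"}: one row per
#'   algorithm x metric x split with mean and CI bounds, plus chosen
#'   hyperparameters in \code{attr(x, "params")}.
#' @export
runBenchmark <- function(features, labels,
                         algorithms = lapply(c("LR", "KNN", "DT", "RF",
                                               "SVM_linear", "SVM_rbf",
                                               "OPLSDA"), algorithmSpec),
                         k = 10L, positive = "RM", sample_ids = NULL,
                         cv_unit = c("sample", "spectrum"), seed = 1L) {
  cv_unit <- match.arg(cv_unit)
  if (methods::is(features, "SpectraSet")) {
    if (is.null(sample_ids)) sample_ids <- sampleMeta(features)$sample_id
    features <- spectraMatrix(features)
  }
  X <- as.matrix(features)
  y <- as.character(labels)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) != 2L) stop("labels must contain exactly 2 classes")
  groups <- if (cv_unit == "sample" && !is.null(sample_ids)) sample_ids
            else seq_len(nrow(X))
  neg <- setdiff(sort(unique(y)), positive)
  fold <- kfoldSplit(nrow(X), k = k, labels = y, groups = groups,
                     seed = subSeed(seed, 47L))
  # leakage guard: no group may straddle folds
  stopifnot(all(tapply(fold, groups, function(f) length(unique(f))) == 1L))
  rows <- list(); chosen <- list()
  for (spec in algorithms) {
    gs <- gridSearch(spec, X, y, positive = positive, groups = groups,
                     seed = subSeed(seed, 53L))
    chosen[[spec$name]] <- gs$params
    per_fold <- list(train = list(), test = list())
    na_metrics <- c(accuracy = NA_real_, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, roc_auc = NA_real_)
    for (f in sort(unique(fold))) {
      test <- fold == f
      fit <- tryCatch(
        fitClassifier(spec$name, gs$params, X[!test, , drop = FALSE],
                      y[!test], positive, seed = subSeed(seed, 59L, f)),
        error = function(e) {
          warning(sprintf("%s: fold %d dropped (%s)", spec$name, f,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) {
        per_fold$train[[f]] <- na_metrics
        per_fold$test[[f]] <- na_metrics
        next
      }
      per_fold$train[[f]] <- foldMetrics(spec$name,
                                         fit$score(X[!test, , drop = FALSE]),
                                         y[!test], positive, neg)
      per_fold$test[[f]] <- foldMetrics(spec$name,
                                        fit$score(X[test, , drop = FALSE]),
                                        y[test], positive, neg)
    }
    for (split in c("train", "test")) {
      mm <- do.call(rbind, per_fold[[split]])
      for (metric in colnames(mm)) {
        s <- ciSummary(mm[, metric], k)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = spec$name, split = split, metric = metric,
          mean = s[["mean"]], ci_lo = s[["lo"]], ci_hi = s[["hi"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- chosen
  attr(out, "cv_unit") <- cv_unit
  class(out) <- c("benchmarkReport", "data.frame")
  out
}

#' Split a collection by collection site
#'
#' @param collection A \linkS4class{SpectraSet}.
#' @param validation_site Site id held out for external validation.
#' @return List with \code{development} and \code{validation} SpectraSets.
#' @export
siteSplit <- function(collection, validation_site) {
  meta <- sampleMeta(collection)
  if (!validation_site %in% meta$site_id) {
    stop(sprintf("unknown site '%s'", validation_site))
  }
  val <- meta$site_id == validation_site
  if (all(val)) stop("development split would be empty")
  list(development = collection[, !val], validation = collection[, val])
}

#' External validation against a held-out site
#'
#' Preprocessing column statistics are learned on the development samples
#' only and applied frozen to the validation samples; the model is refit on
#' the full development set with grid-searched hyperparameters. Reports
#' development 10-fold CV metrics plus single-shot metrics on the
#' validation set. With a single-class validation set the AUC is reported
#' as NA and the other metrics are still computed.
#'
#' @param spec An [algorithmSpec()].
#' @param development,validation Raw \linkS4class{SpectraSet}s (per-site
#'   halves of [siteSplit()]).
#' @param preprocess A [preprocessConfig()].
#' @param contrast Label column: \code{"remission_wk8"} or
#'   \code{"remission_wk56"}.
#' @param positive Positive class.
#' @param k Development CV folds.
#' @param seed Seed.
#' @return List with \code{params}, \code{development} (benchmarkReport)
#'   and \code{validation} (named metric vector).
#' @export
externalValidate <- function(spec, development, validation,
                             preprocess = preprocessConfig(),
                             contrast = "remission_wk8", positive = "RM",
                             k = 10L, seed = 1L) {
  if (ncol(validation) == 0L) stop("validation set is empty")
  dev_pp <- applyPreprocess(development, preprocess)
  stats <- S4Vectors::metadata(dev_pp)$scaling_stats
  val_pp <- applyPreprocess(validation, preprocess, frozen_stats = stats)
  dev_lab <- contrastSubset(dev_pp, contrast)
  val_lab <- contrastSubset(val_pp, contrast)
  if (length(unique(dev_lab$labels)) < 2L) {
    stop("development set must contain both classes")
  }
  Xd <- spectraMatrix(dev_pp)[dev_lab$keep, , drop = FALSE]
  Xv <- spectraMatrix(val_pp)[val_lab$keep, , drop = FALSE]
  dev_report <- runBenchmark(Xd, dev_lab$labels, algorithms = list(spec),
                             k = k, positive = positive,
                             sample_ids = dev_lab$sample_ids, seed = seed)
  gs <- gridSearch(spec, Xd, dev_lab$labels, positive = positive,
                   groups = dev_lab$sample_ids, seed = subSeed(seed, 53L))
  fit <- fitClassifier(spec$name, gs$params, Xd, dev_lab$labels, positive,
                       seed = subSeed(seed, 61L))
  sc <- fit$score(Xv)
  neg <- setdiff(sort(unique(dev_lab$labels)), positive)
  pred <- scoreToClass(spec$name, sc, positive, neg)
  m <- suppressWarnings(
    metricsFromConfusion(confusionCounts(val_lab$labels, pred, positive)))
  auc <- if (length(unique(val_lab$labels)) < 2L) NA_real_ else
    rocAuc(sc, val_lab$labels, positive)
  list(params = gs$params,
       development = dev_report,
       validation = c(m, roc_auc = auc))
}

# Extract labels for a contrast from a SpectraSet, dropping rows without a
# label (HC samples for remission contrasts, nothing for cohort contrast).
contrastSubset <- function(ss, contrast = c("cohort", "remission_wk8",
                                            "remission_wk56")) {
  contrast <- match.arg(contrast)
  meta <- sampleMeta(ss)
  lab <- meta[[contrast]]
  keep <- !is.na(lab)
  list(keep = which(keep), labels = as.character(lab[keep]),
       sample_ids = meta$sample_id[keep])
}
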