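test_that("confusion counts and inversions", {
  y <- c(rep("RM", 4), rep("NRM", 6))
  cc <- confusionCounts(y, y)
  expect_equal(cc, list(TP = 4L, FP = 0L, TN = 6L, FN = 0L))
  inv <- ifelse(y == "RM", "NRM", "RM")
  ci <- confusionCounts(y, inv)
  expect_equal(ci, list(TP = 0L, FP = 6L, TN = 0L, FN = 4L))
  expect_error(confusionCounts(character(), character()), "empty")
  expect_error(confusionCounts(y, y[1:3]), "length")
})

test_that("metric formulas agree with brute-force counting (length <= 8)", {
  for (n in c(2L, 3L, 5L, 8L)) {
    combos <- expand.grid(rep(list(c("RM", "NRM")), n),
                          stringsAsFactors = FALSE)
    set.seed(n)
    pick <- sample(nrow(combos), min(20, nrow(combos)))
    for (i in pick) for (j in pick) {
      yt <- unlist(combos[i, ]); yp <- unlist(combos[j, ])
      cc <- confusionCounts(yt, yp)
      m <- suppressWarnings(metricsFromConfusion(cc))
      # direct counting oracle
      acc <- mean(yt == yp)
      prec <- if (sum(yp == "RM") == 0) 0 else
        sum(yt == "RM" & yp == "RM") / sum(yp == "RM")
      rec <- if (sum(yt == "RM") == 0) 0 else
        sum(yt == "RM" & yp == "RM") / sum(yt == "RM")
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      expect_equal(unname(m), c(acc, prec, rec, f1), tolerance = 1e-12)
    }
  }
  expect_warning(
    expect_warning(metricsFromConfusion(list(TP = 0, FP = 0, TN = 3, FN = 2)),
                   "precision"),
    "F1")
})

test_that("worked confusion example matches the printed formulas", {
  m <- metricsFromConfusion(list(TP = 8, FN = 2, TN = 5, FP = 5))
  expect_equal(unname(m["accuracy"]), 0.65)
  expect_equal(unname(m["precision"]), 8 / 13, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 0.8)
  expect_equal(unname(m["f1"]), 2 * (8 / 13) * 0.8 / (8 / 13 + 0.8),
               tolerance = 1e-12)
})

test_that("ROC-AUC: perfect, inverted, random, monotone-invariant, ties", {
  y <- rep(c("NRM", "RM"), each = 10)
  s <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(rocAuc(s, y), 1)
  expect_equal(rocAuc(-s, y), 0)
  expect_equal(rocAuc(exp(5 * s), y), rocAuc(s, y))  # monotone transform

  set.seed(21)
  aucs <- vapply(1:40, function(i) {
    yy <- sample(rep(c("NRM", "RM"), each = 100))
    rocAuc(runif(200), yy)
  }, numeric(1))
  expect_gte(mean(aucs >= 0.4 & aucs <= 0.6), 0.95)

  # mid-rank ties: all-equal scores give 0.5
  expect_equal(rocAuc(rep(1, 20), y), 0.5)
  expect_error(rocAuc(s, rep("RM", 20)), "both classes")
})

test_that("kfoldSplit partitions, balances, stratifies and groups", {
  y62 <- rep(c("RM", "NRM"), c(15, 47))
  f <- kfoldSplit(62, 10, labels = y62, seed = 3)
  expect_setequal(unique(f), 1:10)
  expect_equal(sort(as.vector(table(f))), c(rep(6L, 8), 7L, 7L))
  # stratification within 1 of exact
  rm_per_fold <- table(factor(f[y62 == "RM"], levels = 1:10))
  expect_lte(diff(range(rm_per_fold)), 1)
  expect_identical(f, kfoldSplit(62, 10, labels = y62, seed = 3))

  g <- rep(1:20, each = 3)
  fg <- kfoldSplit(60, 5, labels = rep(c("A", "B"), 30), groups = g,
                   seed = 1)
  expect_true(all(tapply(fg, g, function(v) length(unique(v))) == 1))
  expect_error(kfoldSplit(5, 10), "exceed")
})

test_that("grid search returns the single point, honors tie-breaks", {
  d <- separableData(n = 30)
  one <- algorithmSpec("LR", grid = list(C = 1))
  gs <- gridSearch(one, d$X, d$y, inner_folds = 3, positive = "RM", seed = 1)
  expect_equal(gs$params$C, 1)

  # all-identical rows: every candidate ties -> simplest (smallest k)
  Xc <- matrix(1, 20, 4)
  yc <- rep(c("RM", "NRM"), 10)
  gk <- suppressWarnings(
    gridSearch(algorithmSpec("KNN", grid = list(k = c(7, 3, 5))), Xc, yc,
               inner_folds = 2, positive = "RM", seed = 1))
  expect_equal(gk$params$k, 3)
})

test_that("rbf SVM grid search solves a separable task", {
  d <- separableData(n = 40, gap = 5, seed = 2)
  gs <- gridSearch(algorithmSpec("SVM_rbf"), d$X, d$y, inner_folds = 5,
                   positive = "RM", seed = 2)
  expect_gte(gs$cv_accuracy, 0.95)
})

test_that("runBenchmark separates planted signal and keeps groups intact", {
  d <- separableData(n = 48, gap = 5, seed = 3)
  gid <- rep(1:16, each = 3)
  rep <- runBenchmark(d$X, d$y, algorithms = list(
    algorithmSpec("LR", grid = list(C = 1)),
    algorithmSpec("DT", grid = list(maxdepth = 3))),
    k = 4, positive = "RM", sample_ids = gid, seed = 4)
  df <- as.data.frame(rep)
  acc <- df$mean[df$algorithm == "LR" & df$split == "test" &
                   df$metric == "accuracy"]
  expect_gte(acc, 0.9)
  expect_true(all(df$metric %in% c("accuracy", "precision", "recall",
                                   "f1", "roc_auc")))
  expect_identical(attr(rep, "cv_unit"), "sample")
  expect_error(runBenchmark(d$X, rep("RM", 48)), "2 classes")
})

test_that("site split is disjoint and exhaustive; unknown site errors", {
  ss <- smallCohort(seed = 6, grid = buildGrid(1800, 900, 20),
                    n_hc = 4, n_uc = 6, uc_site_sizes = c(4L, 2L),
                    n_replicates = 2)
  sp <- siteSplit(ss, "site2")
  expect_equal(ncol(sp$development) + ncol(sp$validation), ncol(ss))
  expect_true(all(sampleMeta(sp$validation)$site_id == "site2"))
  expect_false(any(sampleMeta(sp$development)$site_id == "site2"))
  expect_error(siteSplit(ss, "nowhere"), "unknown")
})

test_that("external validation freezes development scaling statistics", {
  ss <- smallCohort(seed = 8, grid = buildGrid(1800, 900, 15))
  sp <- siteSplit(ss, "site2")
  res <- externalValidate(algorithmSpec("LR", grid = list(C = c(0.1, 1))),
                          sp$development, sp$validation,
                          preprocess = preprocessConfig(
                            normalization = "area", scaling = "pareto"),
                          contrast = "remission_wk8", k = 5, seed = 2)
  expect_true(all(c("accuracy", "precision", "recall", "f1", "roc_auc")
                  %in% names(res$validation)))
  expect_true(res$validation[["accuracy"]] >= 0 &&
                res$validation[["accuracy"]] <= 1)
  # frozen stats: validation preprocessing must use development columns
  dev_pp <- applyPreprocess(sp$development,
                            preprocessConfig(normalization = "area",
                                             scaling = "pareto"))
  st <- S4Vectors::metadata(dev_pp)$scaling_stats
  val_pp <- applyPreprocess(sp$validation,
                            preprocessConfig(normalization = "area",
                                             scaling = "pareto"),
                            frozen_stats = st)
  expect_equal(S4Vectors::metadata(val_pp)$scaling_stats$center, st$center)
  expect_error(externalValidate(algorithmSpec("LR"), sp$development,
                                sp$development[, 0], contrast = "cohort"),
               "empty")
})
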