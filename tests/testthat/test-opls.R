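test_that("OPLS with no orthogonal components equals 1-component NIPALS PLS", {
  set.seed(11)
  X <- matrix(rnorm(30 * 15), 30)
  y <- rep(c(0, 1), 15)
  m <- fitOpls(X, y, n_ortho = 0L, cv_folds = 0L)
  fitted <- m@yMean + m@coef * m@t
  expect_lt(max(abs(fitted - nipalsPls(X, y, 1))), 1e-8)
  pr <- predict(m, X)
  expect_lt(max(abs(pr$ypred - fitted)), 1e-10)
})

test_that("OPLS(k) fitted values match (k+1)-component NIPALS PLS", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(15:30, 1); p <- sample(20:50, 1)
    X <- matrix(rnorm(n * p), n)
    y <- sample(rep(c(0, 1), length.out = n))
    for (k in 1:2) {
      m <- fitOpls(X, y, n_ortho = k, cv_folds = 0L)
      fitted <- m@yMean + m@coef * m@t
      expect_lt(max(abs(fitted - nipalsPls(X, y, k + 1))), 1e-6)
      # predictive/orthogonal score orthogonality
      for (j in seq_len(k)) {
        expect_lt(abs(sum(m@t * m@To[, j])),
                  1e-8 * sqrt(sum(m@t^2) * sum(m@To[, j]^2)))
      }
      expect_equal(sqrt(sum(m@w^2)), 1, tolerance = 1e-12)
    }
  }
})

test_that("fit errors: single class, too many components, tiny data", {
  X <- matrix(rnorm(40), 10)
  expect_error(fitOpls(X, rep("A", 10)), "2 classes|single")
  expect_error(fitOpls(X, rep(c("A", "B"), 5), n_ortho = 9), "rank")
  expect_error(fitOpls(X[1:3, ], c("A", "B", "A")), "4 rows")
})

test_that("prediction respects centering and label-flip symmetry", {
  set.seed(13)
  X <- matrix(rnorm(24 * 8), 24)
  y <- rep(c(0, 1), 12)
  m <- fitOpls(X, y, n_ortho = 1L, cv_folds = 0L)
  # the mean training spectrum predicts the training class mean
  mu <- matrix(colMeans(X), 1)
  expect_equal(predict(m, mu)$ypred, mean(y), tolerance = 1e-10)
  # flipped coding mirrors ypred around 0.5
  m2 <- fitOpls(X, 1 - y, n_ortho = 1L, cv_folds = 0L)
  expect_equal(predict(m2, X)$ypred, 1 - predict(m, X)$ypred,
               tolerance = 1e-8)
  expect_error(predict(m, X[, 1:5]), "columns")
})

test_that("Q2Y: perfect structure near 1, permuted labels near or below 0", {
  set.seed(14)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 10, sd = 0.1), n)
  X[y == "B", 1] <- X[y == "B", 1] + 3
  expect_gt(q2y(X, y, n_ortho = 0L, folds = 5, seed = 1), 0.9)

  low <- vapply(1:20, function(s) {
    set.seed(100 + s)
    yperm <- sample(y)
    q2y(X, yperm, n_ortho = 0L, folds = 5, seed = s) <= 0.1
  }, logical(1))
  expect_gte(mean(low), 0.9)
})

test_that("autofit adds components only when they help", {
  # one y-correlated direction plus a strong y-orthogonal direction
  hits <- vapply(1:15, function(s) {
    set.seed(200 + s)
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    ortho <- rnorm(n, sd = 1)
    X <- cbind(outer(y - 0.5, rep(1, 5)) + matrix(rnorm(n * 5, sd = 0.3), n),
               outer(ortho, rep(1, 10)) + matrix(rnorm(n * 10, sd = 0.1), n))
    autofitOpls(X, y, max_ortho = 3, cv_folds = 5, seed = s) >= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  none <- vapply(1:50, function(s) {
    set.seed(300 + s)
    X <- matrix(rnorm(30 * 12), 30)
    y <- rep(c(0, 1), 15)
    autofitOpls(X, y, max_ortho = 3, cv_folds = 10, seed = s) == 0
  }, logical(1))
  expect_gte(mean(none), 0.9)

  set.seed(1)
  X <- matrix(rnorm(30 * 12), 30)
  expect_identical(autofitOpls(X, rep(c(0, 1), 15), max_ortho = 0), 0L)
})

test_that("permutation report is well-formed and intercepts behave", {
  set.seed(15)
  n <- 24
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 20, sd = 0.3), n)
  X[y == "B", 1:4] <- X[y == "B", 1:4] + 2
  rep <- permutationTest(X, y, n_ortho = 0L, n_permutations = 30,
                         cv_folds = 4, seed = 2)
  expect_s3_class(rep, "permutationReport")
  expect_equal(nrow(rep$permuted), 30L)
  expect_true(all(rep$p_values > 0 & rep$p_values <= 1))
  expect_true(rep$valid)  # strong separation validates
  expect_lt(rep$intercepts[["Q2Y"]], 0.05)
  expect_error(permutationTest(X, y, n_permutations = 0), ">= 1")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(16)
  X <- matrix(rnorm(20 * 10), 20)
  inside <- vapply(1:20, function(s) {
    set.seed(400 + s)
    y <- sample(rep(c("A", "B"), 10))
    r <- permutationTest(X, y, n_ortho = 0L, n_permutations = 40,
                         cv_folds = 4, seed = s)
    q <- r$observed[["Q2Y"]]
    qs <- r$permuted$Q2Y
    q >= quantile(qs, 0.025) & q <= quantile(qs, 0.975)
  }, logical(1))
  expect_gte(mean(inside), 0.75)  # ~95% with binomial noise at n = 20
})

test_that("CV-ANOVA boundary rules and null calibration", {
  y <- rep(c(0, 1), each = 10)
  ss <- sum((y - mean(y))^2)
  # tiny PRESS: overwhelming evidence
  good <- cvAnova(rep(1e-6, 20), y, n_components = 1)
  expect_lt(good$p, 1e-10)
  # PRESS = SS: p = 1 by convention
  resid <- y - mean(y)
  expect_equal(cvAnova(resid, y, n_components = 1)$p, 1)

  ps <- vapply(1:100, function(s) {
    set.seed(500 + s)
    X <- matrix(rnorm(20 * 8), 20)
    yy <- sample(rep(c(0, 1), 10))
    d <- ftirDA:::q2Details(X, yy, 0L, folds = 4, seed = s)
    cvAnova(d$residuals, yy, n_components = 1)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.10)
})

test_that("VIP: unit mean square, symmetry, informative-variable maximum", {
  set.seed(17)
  X <- matrix(rnorm(30 * 40), 30)
  y <- rep(c(0, 1), 15)
  m <- fitOpls(X, y, n_ortho = 1L, cv_folds = 0L)
  v <- vipScores(m)
  expect_lt(abs(mean(v^2) - 1), 1e-10)

  # one informative variable among 99 noise variables
  set.seed(18)
  X2 <- matrix(rnorm(60 * 100, sd = 0.5), 60)
  y2 <- rep(c(0, 1), each = 30)
  X2[, 7] <- X2[, 7] + 3 * y2
  m2 <- fitOpls(X2, y2, n_ortho = 0L, cv_folds = 0L)
  expect_identical(which.max(vipScores(m2)), 7L)
  expect_lt(abs(mean(vipScores(m2)^2) - 1), 1e-10)
})
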