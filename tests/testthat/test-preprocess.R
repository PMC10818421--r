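test_that("replicate averaging: 9 -> 3 spectra, identity on constants", {
  grid <- buildGrid(1800, 900, 100)
  md <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(sample_id = paste0("S", i), cohort = "UC",
               remission_wk8 = "RM", remission_wk56 = "NRM",
               site_id = "site1", replicate_index = 1:9)
  }))
  set.seed(1)
  a <- matrix(rnorm(18 * length(grid)), nrow = 18)
  ss <- SpectraSet(a, grid, md)
  avg <- averageReplicates(ss, 3L)
  expect_equal(ncol(avg), 6L)
  expect_equal(sampleMeta(avg)$replicate_index, rep(1:3, 2))
  # group means match a direct computation
  m <- spectraMatrix(avg)
  expect_equal(unname(m[1, ]),
               unname(colMeans(spectraMatrix(ss)[1:3, ])),
               tolerance = 1e-12)

  # identical replicates average to themselves
  a2 <- matrix(rep(a[1, ], each = 18), nrow = 18)
  avg2 <- averageReplicates(SpectraSet(a2, grid, md), 3L)
  expect_equal(unname(spectraMatrix(avg2)[4, ]), a[1, ], tolerance = 1e-12)

  md8 <- md[md$replicate_index <= 8 | md$sample_id == "S2", ]
  ss8 <- SpectraSet(a[md$replicate_index <= 8 | md$sample_id == "S2", ],
                    grid, md8)
  expect_error(averageReplicates(ss8, 3L), "S1")
})

test_that("ATR correction applies the linear penetration-depth factor", {
  grid <- buildGrid(2000, 500, 100)
  x <- rep(1, length(grid))
  out <- atrCorrection(x, grid, reference_wavenumber = 1000)
  expect_equal(out[nearestIndex(grid, 1000)], 1)
  expect_equal(out[nearestIndex(grid, 2000)], 2)
  expect_true(all(diff(out) < 0))  # strictly decreasing toward low nu
})

test_that("Savitzky-Golay derivatives are exact on polynomials", {
  grid <- buildGrid(1800, 900, 3)
  # cubic in wavenumber
  co <- c(2, 3e-3, -1e-6, 5e-10)
  y <- co[1] + co[2] * grid + co[3] * grid^2 + co[4] * grid^3
  d1 <- savgolDerivative(y, grid, order = 1L, window = 7L, polyorder = 3L)
  an1 <- co[2] + 2 * co[3] * grid + 3 * co[4] * grid^2
  interior <- 4:(length(grid) - 3)
  expect_lt(max(abs(d1 - an1)[interior] / pmax(abs(an1[interior]), 1e-12)),
            1e-8)
  d2 <- savgolDerivative(y, grid, order = 2L, window = 7L, polyorder = 3L)
  an2 <- 2 * co[3] + 6 * co[4] * grid
  expect_lt(max(abs(d2 - an2)[interior]), 1e-10)

  expect_equal(savgolDerivative(rep(5, length(grid)), grid, 1L),
               rep(0, length(grid)), tolerance = 1e-12)
  expect_error(savgolDerivative(y, grid, order = 1L, window = 6L), "odd")
  expect_error(savgolDerivative(y[1:5], grid[1:5], window = 7L), "smaller")
})

test_that("row normalizations satisfy their defining identities", {
  expect_equal(normalizeArea(c(2, 2, 2, 2)), rep(0.25, 4))
  expect_equal(normalizeArea(c(1, 3)), c(0.25, 0.75))
  expect_error(normalizeArea(c(0, 0)), "zero")

  expect_equal(normalizeMinmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(normalizeMinmax(c(5, 5, 5)), "constant")

  expect_equal(normalizeVector(c(3, 4)), c(0.6, 0.8))
  expect_error(normalizeVector(c(0, 0)), "zero")

  # property loop over random spectra
  set.seed(7)
  for (i in 1:25) {
    x <- runif(60, 0.01, 2)
    a <- normalizeArea(x)
    expect_equal(sum(a), 1, tolerance = 1e-9)
    expect_equal(normalizeArea(3.7 * x), a, tolerance = 1e-12)  # scale-inv
    mm <- normalizeMinmax(x)
    expect_equal(range(mm), c(0, 1))
    expect_equal(normalizeMinmax(2 * x + 5), mm, tolerance = 1e-12)
    v <- normalizeVector(x - mean(x))
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  }
})

test_that("amide normalization anchors the amide-I maximum at 1", {
  grid <- buildGrid(1800, 900, 10)
  x <- 0.2 + 0.6 * exp(-(grid - 1620)^2 / (2 * 15^2))
  out <- normalizeAmide(x, grid, c(1650, 1600))
  j <- nearestIndex(grid, 1620)
  expect_equal(out[j], 1)
  expect_equal(min(out), 0)
  # direct arithmetic: a value of 0.5 maps to (0.5 - min)/(amidemax - min)
  expect_equal(normalizeAmide(c(x[-1], 0.5), grid)[length(grid)],
               (0.5 - min(c(x[-1], 0.5))) /
                 (max((c(x[-1], 0.5))[grid <= 1650 & grid >= 1600]) -
                    min(c(x[-1], 0.5))), tolerance = 1e-12)
  # a global max outside the window exceeds 1
  x2 <- x + 1.2 * exp(-(grid - 1100)^2 / (2 * 15^2))
  expect_gt(max(normalizeAmide(x2, grid)), 1)
  expect_error(normalizeAmide(x, grid, c(4000, 3900)), "intersect")
})

test_that("column scaling: unit variance, pareto, constant-column rule", {
  set.seed(3)
  m <- matrix(rnorm(100, sd = 4), 20, 5)
  uv <- scaleColumns(m, "unit_variance")
  expect_equal(apply(uv, 2, sd), rep(1, 5), tolerance = 1e-12)
  pa <- scaleColumns(m, "pareto")
  expect_equal(apply(pa, 2, sd), sqrt(apply(m, 2, sd)), tolerance = 1e-12)
  mc <- scaleColumns(m, "mean_center")
  expect_equal(colMeans(mc), rep(0, 5), tolerance = 1e-12)

  m2 <- cbind(m, 7)  # constant column
  uv2 <- scaleColumns(m2, "unit_variance")
  expect_equal(uv2[, 6], rep(0, 20))
  expect_error(scaleColumns(m[1, , drop = FALSE], "pareto"), "2 rows")

  # frozen statistics are applied verbatim
  fr <- scaleColumns(m, "unit_variance",
                     center = rep(1, 5), scale = rep(2, 5))
  expect_equal(fr[1, ], (m[1, ] - 1) / 2, tolerance = 1e-12)
})

test_that("preprocess pipeline: identity config, stage properties, invariants", {
  ss <- smallCohort(seed = 4, grid = buildGrid(1800, 900, 10),
                    n_hc = 3, n_uc = 4, uc_site_sizes = 4L,
                    n_replicates = 3)
  ident <- applyPreprocess(ss, preprocessConfig(averaging_group_size = 1L))
  expect_equal(spectraMatrix(ident), spectraMatrix(ss), tolerance = 1e-15)

  cfg <- preprocessConfig(normalization = "area", scaling = "pareto")
  pp <- applyPreprocess(ss, cfg)
  pre <- S4Vectors::metadata(pp)$prescale
  expect_equal(rowSums(pre), rep(1, nrow(pre)), tolerance = 1e-9)
  expect_identical(preprocessProvenance(pp)$normalization, "area")
  # determinism
  pp2 <- applyPreprocess(ss, cfg)
  expect_identical(spectraMatrix(pp), spectraMatrix(pp2))

  expect_error(preprocessConfig(normalization = "vector"), "derivative")
  expect_silent(preprocessConfig(normalization = "vector",
                                 derivative_order = "first"))
  expect_error(preprocessConfig(sg_window = 6L), "odd")
})
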