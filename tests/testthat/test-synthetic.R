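test_that("forward model: peak location, superposition, pathlength scaling", {
  grid <- buildGrid(1800, 900, 3)
  b1 <- data.frame(center = 1629, sigma = 25, amplitude = 0.8,
                   assignment = "protein")
  b2 <- data.frame(center = 1080, sigma = 20, amplitude = 0.3,
                   assignment = "carbohydrate")
  s1 <- spectrumFromBands(b1, grid)
  expect_equal(which.max(s1), nearestIndex(grid, 1629))
  expect_equal(max(s1), 0.8, tolerance = 1e-6)

  s2 <- spectrumFromBands(b2, grid)
  s12 <- spectrumFromBands(rbind(b1, b2), grid)
  expect_equal(s12, s1 + s2, tolerance = 1e-12)

  expect_equal(spectrumFromBands(b1, grid, pathlength_factor = 2), 2 * s1,
               tolerance = 1e-12)
  expect_error(spectrumFromBands(data.frame(center = 500, sigma = 10,
                                            amplitude = 1), grid),
               "outside")
})

test_that("label assignment hits the printed prevalences exactly", {
  cfg <- cohortConfig(grid = testGrid())
  lab <- assignLabels(cfg)
  uc <- lab[lab$cohort == "UC", ]
  expect_equal(nrow(uc), 62L)
  expect_equal(sum(lab$cohort == "HC"), 30L)
  expect_equal(sum(uc$remission_wk8 == "RM"), 15L)   # round(0.242 * 62)
  expect_equal(sum(uc$remission_wk56 == "RM"), 26L)  # round(0.419 * 62)
  # printed one-decimal percentages
  expect_equal(round(100 * 15 / 62, 1), 24.2)
  expect_equal(round(100 * 26 / 62, 1), 41.9)
  # wk8 RM nested in wk56 RM when counts allow
  expect_true(all(uc$remission_wk56[uc$remission_wk8 == "RM"] == "RM"))
  expect_equal(sort(as.vector(table(uc$site_id)), decreasing = TRUE),
               c(51L, 11L))
  expect_true(all(is.na(lab$remission_wk8[lab$cohort == "HC"])))

  lab0 <- assignLabels(cohortConfig(grid = testGrid(),
                                    remission_rate_wk8 = 0,
                                    remission_rate_wk56 = 0))
  expect_equal(sum(lab0$remission_wk8 == "RM", na.rm = TRUE), 0L)
})

test_that("generateCohort is deterministic and has the right shape", {
  cfg <- smallCohortConfig(n_hc = 4, n_uc = 6, uc_site_sizes = c(4, 2),
                      n_replicates = 3, grid = buildGrid(1800, 900, 10),
                      seed = 9)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_equal(ncol(a), 10 * 3)
  expect_identical(spectraMatrix(a), spectraMatrix(b))
  expect_identical(sampleMeta(a), sampleMeta(b))
})

test_that("extending the cohort does not perturb existing samples", {
  g <- buildGrid(1800, 900, 10)
  small <- generateCohort(smallCohortConfig(n_hc = 3, n_uc = 4,
                                       uc_site_sizes = 4L,
                                       n_replicates = 2, grid = g,
                                       remission_rate_wk8 = 0.5,
                                       remission_rate_wk56 = 0.5,
                                       seed = 5))
  big <- generateCohort(smallCohortConfig(n_hc = 5, n_uc = 4,
                                     uc_site_sizes = 4L,
                                     n_replicates = 2, grid = g,
                                     remission_rate_wk8 = 0.5,
                                     remission_rate_wk56 = 0.5,
                                     seed = 5))
  ms <- spectraMatrix(small); mb <- spectraMatrix(big)
  ids <- sampleMeta(small)$sample_id
  shared <- which(sampleMeta(big)$sample_id %in% c("HC001", "HC002", "HC003"))
  expect_equal(mb[shared[1:2], ], ms[1:2, ], tolerance = 1e-15)
})

test_that("degenerate config (all variance off, folds 1) gives identical rows", {
  cfg <- smallCohortConfig(n_hc = 3, n_uc = 3, uc_site_sizes = 3L,
                      n_replicates = 2, grid = buildGrid(1800, 900, 10),
                      effects = nullEffects(), noise_sd = 0,
                      pathlength_sigma = 0, site_shift_sd = 0,
                      baseline_offset_range = 0, baseline_slope_range = 0,
                      amplitude_sigma = 0, background_bands = 0, seed = 3)
  m <- spectraMatrix(generateCohort(cfg))
  expect_true(all(abs(sweep(m, 2, m[1, ])) < 1e-15))
})

test_that("planted fold is recovered exactly as noise goes to zero", {
  cfg <- smallCohortConfig(n_hc = 10, n_uc = 10, uc_site_sizes = 10L,
                      grid = buildGrid(1800, 900, 5), n_replicates = 1,
                      effects = list(UC_vs_HC = c("1316" = 1.37)),
                      noise_sd = 0, pathlength_sigma = 0,
                      site_shift_sd = 0, baseline_offset_range = 0,
                      baseline_slope_range = 0, amplitude_sigma = 0,
                      background_bands = 0, seed = 2)
  ss <- generateCohort(cfg)
  m <- spectraMatrix(ss)
  meta <- sampleMeta(ss)
  j <- nearestIndex(wavenumbers(ss), 1316)
  ratio <- mean(m[meta$cohort == "UC", j]) / mean(m[meta$cohort == "HC", j])
  # other bands overlap 1316 slightly, diluting the pointwise ratio
  expect_equal(ratio, 1.37, tolerance = 0.01)
})

test_that("null cohorts give calibrated single-band t-tests", {
  g <- buildGrid(1400, 1000, 10)
  j <- NULL
  rejected <- vapply(1:200, function(s) {
    ss <- generateCohort(smallCohortConfig(
      n_hc = 8, n_uc = 8, uc_site_sizes = 8L, n_replicates = 1,
      grid = g, effects = nullEffects(), site_shift_sd = 0, seed = 1000 + s))
    m <- spectraMatrix(ss)
    meta <- sampleMeta(ss)
    if (is.null(j)) j <<- nearestIndex(wavenumbers(ss), 1244)
    studentsT(m[meta$cohort == "UC", j], m[meta$cohort == "HC", j])$p < 0.05
  }, logical(1))
  k <- sum(rejected)
  band <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})
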