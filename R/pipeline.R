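# Study orchestration: preprocessing grid search -> OPLS-DA model selection
# -> permutation validation -> classifier benchmark -> external validation
# -> marker table, with CSV/JSON reports.

#' Expand a preprocessing option grid
#'
#' @param normalization,scaling,derivative Character vectors of options.
#' @param atr_correction Logical vector of options.
#' @param averaging_group_size Replicate averaging group size.
#' @return List of [preprocessConfig()]s; combinations violating config
#'   invariants (e.g. vector normalization without a derivative) are
#'   dropped with a message.
#' @export
expandPreprocessGrid <- function(normalization = c("area", "minmax",
                                                   "amide", "vector"),
                                 scaling = c("mean_center", "pareto",
                                             "unit_variance"),
                                 derivative = "none",
                                 atr_correction = FALSE,
                                 averaging_group_size = 3L) {
  combos <- expand.grid(normalization = normalization, scaling = scaling,
                        derivative = derivative,
                        atr = atr_correction,
                        stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    cfg <- tryCatch(
      preprocessConfig(averaging_group_size = averaging_group_size,
                       atr_correction = combos$atr[i],
                       derivative_order = combos$derivative[i],
                       normalization = combos$normalization[i],
                       scaling = combos$scaling[i]),
      error = function(e) {
        message(sprintf("skipping %s + %s + %s: %s",
                        combos$normalization[i], combos$scaling[i],
                        combos$derivative[i], conditionMessage(e)))
        NULL
      })
    if (!is.null(cfg)) out[[length(out) + 1L]] <- cfg
  }
  if (!length(out)) stop("no valid preprocessing combination in the grid")
  out
}

#' Rank preprocessing combinations by OPLS-DA cross-validated performance
#'
#' Fits an OPLS-DA model (with automatic orthogonal-component selection)
#' for every preprocessing combination and ranks combinations by Q2Y,
#' breaking ties by R2Y.
#'
#' @param collection Raw \linkS4class{SpectraSet}.
#' @param grid List of [preprocessConfig()]s (see [expandPreprocessGrid()]).
#' @param contrast \code{"cohort"}, \code{"remission_wk8"} or
#'   \code{"remission_wk56"}.
#' @param positive Positive class (default the contrast's case group).
#' @param max_ortho,cv_folds,seed Passed to the OPLS fits.
#' @return \code{data.frame} ranked best-first with columns normalization,
#'   scaling, derivative, n_ortho, R2Y, Q2Y; the chosen config objects are
#'   in \code{attr(x, "configs")} (same order).
#' @export
preprocessingGridSearch <- function(collection, grid, contrast = "cohort",
                                    positive = NULL, max_ortho = 3L,
                                    cv_folds = 10L, seed = 1L) {
  if (length(grid) < 1L) stop("empty preprocessing grid")
  rows <- list(); cfgs <- list()
  for (cfg in grid) {
    pp <- applyPreprocess(collection, cfg)
    sub <- contrastSubset(pp, contrast)
    X <- spectraMatrix(pp)[sub$keep, , drop = FALSE]
    y <- sub$labels
    k <- autofitOpls(X, y, max_ortho = max_ortho, cv_folds = cv_folds,
                     seed = seed, positive = positive)
    m <- fitOpls(X, y, n_ortho = k, cv_folds = cv_folds, seed = seed,
                 positive = positive)
    rows[[length(rows) + 1L]] <- data.frame(
      normalization = cfg$normalization, scaling = cfg$scaling,
      derivative = cfg$derivative_order, n_ortho = k,
      R2Y = m@R2Y, Q2Y = m@Q2Y, stringsAsFactors = FALSE)
    cfgs[[length(cfgs) + 1L]] <- cfg
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$Q2Y, -out$R2Y)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "configs") <- cfgs[ord]
  out
}

#' Study configuration
#'
#' @param input A [cohortConfig()] (synthetic cohort) or a CSV path readable
#'   by [readSpectraCsv()].
#' @param preprocess_grid List of [preprocessConfig()]s to search.
#' @param contrasts Character vector of contrasts to analyse.
#' @param algorithms List of [algorithmSpec()]s for the benchmark.
#' @param validation_site Site id held out for external validation (NULL
#'   disables external validation).
#' @param k CV folds; \code{n_permutations} permutation count;
#'   \code{max_ortho} orthogonal-component cap; \code{seed} master seed.
#' @param n_permutations,max_ortho,seed See above.
#' @param output_dir Report directory (NULL: nothing written).
#' @return List of class \code{"studyConfig"}.
#' @export
studyConfig <- function(input = cohortConfig(),
                        preprocess_grid = expandPreprocessGrid(),
                        contrasts = c("cohort", "remission_wk8",
                                      "remission_wk56"),
                        algorithms = lapply(c("LR", "SVM_rbf", "DT"),
                                            algorithmSpec),
                        validation_site = "site2",
                        k = 10L, n_permutations = 100L, max_ortho = 3L,
                        seed = 1L, output_dir = NULL) {
  ok <- c("cohort", "remission_wk8", "remission_wk56")
  if (!all(contrasts %in% ok)) {
    stop("contrasts must be among: ", paste(ok, collapse = ", "))
  }
  structure(list(input = input, preprocess_grid = preprocess_grid,
                 contrasts = contrasts, algorithms = algorithms,
                 validation_site = validation_site, k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 max_ortho = as.integer(max_ortho), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "studyConfig")
}

writeAtomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full study pipeline
#'
#' Per contrast: preprocessing grid search, best-model OPLS-DA fit with
#' automatic component selection, permutation validation, CV-ANOVA, VIP /
#' t-test / fold-change marker table, classifier benchmark, and (for
#' remission contrasts with a configured validation site) site-based
#' external validation. All randomness derives from the single config
#' seed. When \code{output_dir} is set, per-contrast CSVs (benchmark,
#' markers, scores, permutations) and a study-level JSON report are
#' written atomically.
#'
#' @param config A [studyConfig()].
#' @return List of class \code{"studyReport"}, one element per contrast.
#' @export
runFullStudy <- function(config) {
  stopifnot(inherits(config, "studyConfig"))
  collection <- if (inherits(config$input, "cohortConfig")) {
    generateCohort(config$input)
  } else if (is.character(config$input)) {
    readSpectraCsv(config$input)
  } else stop("input must be a cohortConfig or a CSV path")
  if (!is.null(config$validation_site)) {
    sites <- unique(sampleMeta(collection)$site_id)
    if (!config$validation_site %in% sites) {
      stop(sprintf("validation site '%s' not present in the data",
                   config$validation_site))
    }
  }
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list()
  for (contrast in config$contrasts) {
    message(sprintf("[%s] preprocessing grid search (%d combinations)",
                    contrast, length(config$preprocess_grid)))
    ranked <- preprocessingGridSearch(
      collection, config$preprocess_grid, contrast,
      max_ortho = config$max_ortho, cv_folds = config$k,
      seed = subSeed(config$seed, 71L))
    best_cfg <- attr(ranked, "configs")[[1L]]
    pp <- applyPreprocess(collection, best_cfg)
    sub <- contrastSubset(pp, contrast)
    X <- spectraMatrix(pp)[sub$keep, , drop = FALSE]
    y <- sub$labels
    n_ortho <- ranked$n_ortho[1L]
    model <- fitOpls(X, y, n_ortho = n_ortho, cv_folds = config$k,
                     seed = subSeed(config$seed, 73L))
    message(sprintf("[%s] best: %s + %s (n_ortho = %d, R2Y %.3f, Q2Y %.3f)",
                    contrast, best_cfg$normalization, best_cfg$scaling,
                    n_ortho, model@R2Y, model@Q2Y))
    perm <- permutationTest(X, y, n_ortho = n_ortho,
                            n_permutations = config$n_permutations,
                            cv_folds = config$k,
                            seed = subSeed(config$seed, 79L))
    q2d <- q2Details(X, encodeLabels(y)$y01, n_ortho, folds = config$k,
                     seed = subSeed(config$seed, 73L))
    anova <- cvAnova(q2d$residuals, y, n_components = n_ortho + 1L)
    prescale <- S4Vectors::metadata(pp)$prescale[sub$keep, , drop = FALSE]
    markers <- buildMarkerTable(
      prescale, y, vipScores(model), wavenumbers(pp),
      positive = model@positive,
      bands = S4Vectors::metadata(pp)$cohort_config$bands)
    bench <- runBenchmark(X, y, algorithms = config$algorithms,
                          k = config$k, positive = model@positive,
                          sample_ids = sub$sample_ids,
                          seed = subSeed(config$seed, 83L))
    external <- NULL
    if (!is.null(config$validation_site) && contrast != "cohort") {
      halves <- siteSplit(collection, config$validation_site)
      external <- tryCatch(
        externalValidate(config$algorithms[[1L]], halves$development,
                         halves$validation, preprocess = best_cfg,
                         contrast = contrast, positive = model@positive,
                         k = config$k, seed = subSeed(config$seed, 89L)),
        error = function(e) {
          message(sprintf("[%s] external validation skipped: %s",
                          contrast, conditionMessage(e)))
          NULL
        })
    }
    scores <- data.frame(sample_id = sub$sample_ids, label = y,
                         t1 = model@t,
                         to1 = if (n_ortho > 0) model@To[, 1L] else NA_real_,
                         ypred = model@yMean + model@coef * model@t)
    res <- list(contrast = contrast, ranking = ranked,
                best_preprocess = best_cfg, n_ortho = n_ortho,
                R2Y = model@R2Y, Q2Y = model@Q2Y,
                permutation = perm, cv_anova = anova,
                markers = markers, benchmark = bench,
                external = external, scores = scores)
    report[[contrast]] <- res
    if (!is.null(out_dir)) {
      wf <- function(obj, name) {
        writeAtomic(function(p) utils::write.csv(obj, p, row.names = FALSE),
                    file.path(out_dir, sprintf("%s_%s.csv", name, contrast)))
      }
      wf(ranked, "preprocess_ranking")
      wf(markers, "markers")
      wf(as.data.frame(bench), "benchmark")
      wf(scores, "scores")
      wf(perm$permuted, "permutation")
    }
  }
  report <- structure(report, class = "studyReport", seed = config$seed)
  if (!is.null(out_dir)) {
    js <- lapply(report, function(r) list(
      contrast = r$contrast,
      best_preprocess = list(normalization = r$best_preprocess$normalization,
                             scaling = r$best_preprocess$scaling,
                             derivative = r$best_preprocess$derivative_order),
      n_ortho = r$n_ortho, R2Y = r$R2Y, Q2Y = r$Q2Y,
      permutation = list(intercepts = as.list(r$permutation$intercepts),
                         valid = r$permutation$valid,
                         p_values = as.list(r$permutation$p_values)),
      cv_anova = r$cv_anova,
      n_selected_markers = sum(r$markers$selected),
      external_validation = if (!is.null(r$external))
        as.list(r$external$validation) else NULL))
    writeAtomic(function(p) jsonlite::write_json(
      list(seed = config$seed, contrasts = js), p,
      auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, "report.json"))
  }
  report
}
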