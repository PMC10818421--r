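# Wide-CSV interchange: six metadata columns followed by one column per
# wavenumber (descending). This is the format every pipeline stage reads and
# writes.

#' Write a SpectraSet to a wide CSV file
#'
#' Columns are written in a fixed order: \code{sample_id}, \code{cohort},
#' \code{remission_wk8}, \code{remission_wk56}, \code{site_id},
#' \code{replicate_index}, then one absorbance column per wavenumber in
#' descending order. Missing remission labels are written as the literal
#' token \code{NA}. Numeric values are serialized at full (round-trippable)
#' precision, so \code{readSpectraCsv(writeSpectraCsv(x))} reproduces
#' \code{x} bit-exactly.
#'
#' @param collection A \linkS4class{SpectraSet}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @seealso [readSpectraCsv()]
#' @export
writeSpectraCsv <- function(collection, path) {
  stopifnot(methods::is(collection, "SpectraSet"))
  methods::validObject(collection)
  wn <- wavenumbers(collection)
  meta <- sampleMeta(collection)
  meta$remission_wk8[is.na(meta$remission_wk8)] <- "NA"
  meta$remission_wk56[is.na(meta$remission_wk56)] <- "NA"
  vals <- t(SummarizedExperiment::assay(collection, "absorbance"))
  # %.17g round-trips every double exactly through fread
  vals <- matrix(sprintf("%.17g", vals), nrow = nrow(vals),
                 ncol = ncol(vals))
  dt <- data.table::as.data.table(cbind(meta, as.data.frame(vals)))
  data.table::setnames(dt, c(metaCols, sprintf("%.10g", wn)))
  ok <- tryCatch({
    data.table::fwrite(dt, path, sep = ",", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) stop(sprintf("could not write '%s': %s", path, ok))
  invisible(path)
}

#' Read a SpectraSet from a wide CSV file
#'
#' Expects the layout written by [writeSpectraCsv()]: the six metadata
#' columns, then wavenumber columns whose header names form a uniform
#' monotonic grid. Ascending grids are accepted and stored descending.
#'
#' @param path CSV file path.
#' @return A \linkS4class{SpectraSet}.
#' @export
readSpectraCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  dt <- tryCatch(
    withCallingHandlers(
      data.table::fread(path, sep = ",", header = TRUE,
                        na.strings = "NA", fill = FALSE),
      warning = function(w) {
        # housekeeping notices from earlier interrupted reads are harmless
        if (grepl("cleaned up", conditionMessage(w), ignore.case = TRUE)) {
          invokeRestart("muffleWarning")
        } else {
          stop(sprintf("malformed CSV '%s': %s",
                       path, conditionMessage(w)))
        }
      }),
    error = function(e) stop(sprintf("malformed CSV '%s': %s",
                                     path, conditionMessage(e))))
  miss <- setdiff(metaCols, colnames(dt))
  if (length(miss)) {
    stop(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  }
  wn_cols <- setdiff(colnames(dt), metaCols)
  if (length(wn_cols) < 2L) stop("fewer than 2 wavenumber columns")
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn)) {
    stop(sprintf("non-numeric wavenumber column header(s): %s",
                 paste(utils::head(wn_cols[is.na(wn)], 3), collapse = ", ")))
  }
  assertWavenumberGrid(wn)
  vals <- as.matrix(dt[, wn_cols, with = FALSE])
  if (nrow(vals) == 0L) storage.mode(vals) <- "double"
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, wn_cols, with = FALSE], is.numeric, logical(1)))
    stop(sprintf("non-numeric absorbance in column(s): %s",
                 paste(utils::head(wn_cols[bad], 3), collapse = ", ")))
  }
  if (anyNA(vals)) {
    bad_rows <- which(rowSums(is.na(vals)) > 0)
    stop(sprintf("missing/non-numeric absorbance in data row(s): %s",
                 paste(utils::head(bad_rows, 5), collapse = ", ")))
  }
  meta <- as.data.frame(dt[, metaCols, with = FALSE])
  SpectraSet(t(vals), wn, meta)
}
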