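#' SpectraSet: replicate FT-IR spectra on a shared wavenumber grid
#'
#' A \linkS4class{SummarizedExperiment} subclass holding absorbance spectra as
#' the \code{"absorbance"} assay, with wavenumbers (cm\eqn{^{-1}}) as rows
#' (stored descending, matching acquisition order 4000 to 400) and individual
#' replicate spectra as columns. Column metadata carries the per-spectrum
#' sample annotation:
#' \describe{
#'   \item{sample_id}{sample identifier (character).}
#'   \item{cohort}{\code{"HC"} (healthy control) or \code{"UC"} (ulcerative
#'     colitis patient).}
#'   \item{remission_wk8, remission_wk56}{\code{"RM"}, \code{"NRM"} or
#'     \code{NA}; always \code{NA} for HC samples.}
#'   \item{site_id}{collection site (institution) identifier.}
#'   \item{replicate_index}{positive integer; \code{(sample_id,
#'     replicate_index)} pairs are unique.}
#' }
#' Preprocessing provenance, when present, lives in
#' \code{metadata(x)$preprocess}.
#'
#' @aliases SpectraSet-class
#' @seealso [SpectraSet()], [generateCohort()], [applyPreprocess()]
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

metaCols <- c("sample_id", "cohort", "remission_wk8", "remission_wk56",
              "site_id", "replicate_index")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'absorbance' is missing")
  }
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (!all(is.finite(a))) msg <- c(msg, "absorbance values must all be finite")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavenumber" %in% colnames(rd)) {
    return("rowData must contain a 'wavenumber' column")
  }
  wn <- rd$wavenumber
  ok <- tryCatch({ assertWavenumberGrid(wn); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  else if (wn[1L] < wn[length(wn)]) {
    msg <- c(msg, "wavenumber grid must be stored descending")
  }
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(metaCols, colnames(cd))
  if (length(miss)) {
    return(paste("colData is missing columns:", paste(miss, collapse = ", ")))
  }
  if (!all(cd$cohort %in% c("HC", "UC"))) {
    msg <- c(msg, "cohort must be 'HC' or 'UC'")
  }
  for (col in c("remission_wk8", "remission_wk56")) {
    v <- cd[[col]]
    if (!all(is.na(v) | v %in% c("RM", "NRM"))) {
      msg <- c(msg, sprintf("%s must be 'RM', 'NRM' or NA", col))
    }
    if (any(cd$cohort == "HC" & !is.na(v))) {
      msg <- c(msg, sprintf("HC samples must have %s = NA", col))
    }
  }
  if (any(cd$replicate_index < 1) ||
      any(cd$replicate_index != round(cd$replicate_index))) {
    msg <- c(msg, "replicate_index must be a positive integer")
  }
  key <- paste(cd$sample_id, cd$replicate_index, sep = "\r")
  if (anyDuplicated(key)) {
    msg <- c(msg, "(sample_id, replicate_index) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param absorbance Numeric matrix of absorbance values, wavenumbers in rows
#'   and spectra in columns (a spectra-in-rows matrix is accepted when its
#'   column count matches \code{length(wavenumbers)} and its row count does
#'   not).
#' @param wavenumbers Uniform wavenumber grid (cm\eqn{^{-1}}); reordered to
#'   descending storage if given ascending.
#' @param sampleData \code{data.frame} (or DataFrame) with one row per
#'   spectrum and the columns documented in \linkS4class{SpectraSet}.
#' @param metadata Optional named list stored as experiment metadata.
#' @return A \linkS4class{SpectraSet}.
#' @examples
#' g <- buildGrid(1800, 900, 4)
#' a <- matrix(runif(2 * length(g)), nrow = length(g))
#' md <- data.frame(sample_id = "S1", cohort = "HC",
#'                  remission_wk8 = NA_character_,
#'                  remission_wk56 = NA_character_,
#'                  site_id = "A", replicate_index = 1:2)
#' ss <- SpectraSet(a, g, md)
#' @export
SpectraSet <- function(absorbance, wavenumbers, sampleData,
                       metadata = list()) {
  assertWavenumberGrid(wavenumbers)
  absorbance <- as.matrix(absorbance)
  nw <- length(wavenumbers)
  if (nrow(absorbance) != nw) {
    if (ncol(absorbance) == nw) absorbance <- t(absorbance)
    else stop("absorbance dimensions do not match the wavenumber grid")
  }
  if (wavenumbers[1L] < wavenumbers[nw]) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[nw:1L, , drop = FALSE]
  }
  sampleData <- S4Vectors::DataFrame(sampleData)
  sampleData$sample_id <- as.character(sampleData$sample_id)
  sampleData$site_id <- as.character(sampleData$site_id)
  for (col in c("remission_wk8", "remission_wk56")) {
    v <- as.character(sampleData[[col]])
    v[!is.na(v) & v == "NA"] <- NA_character_
    sampleData[[col]] <- v
  }
  sampleData$replicate_index <- as.integer(sampleData$replicate_index)
  rownames(absorbance) <- NULL
  colnames(absorbance) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
    colData = sampleData,
    metadata = metadata)
  methods::new("SpectraSet", se)
}

#' @describeIn SpectraSet-accessors Wavenumber grid (descending, cm^-1).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @describeIn SpectraSet-accessors Spectra-in-rows absorbance matrix
#'   (one row per spectrum, one column per wavenumber).
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @describeIn SpectraSet-accessors Sample metadata as a data.frame.
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @describeIn SpectraSet-accessors Preprocessing provenance (a
#'   [preprocessConfig()] list) or NULL for raw spectra.
#' @export
setGeneric("preprocessProvenance",
           function(x) standardGeneric("preprocessProvenance"))

#' Accessors for SpectraSet objects
#'
#' @param x A \linkS4class{SpectraSet}.
#' @name SpectraSet-accessors
#' @return See the individual method descriptions.
NULL

#' @rdname SpectraSet-accessors
#' @export
setMethod("wavenumbers", "SpectraSet", function(x) {
  SummarizedExperiment::rowData(x)$wavenumber
})

#' @rdname SpectraSet-accessors
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "absorbance"))
  colnames(m) <- format(wavenumbers(x), trim = TRUE, scientific = FALSE)
  rownames(m) <- NULL
  m
})

#' @rdname SpectraSet-accessors
#' @export
setMethod("sampleMeta", "SpectraSet", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))[, metaCols, drop = FALSE]
})

#' @rdname SpectraSet-accessors
#' @export
setMethod("preprocessProvenance", "SpectraSet", function(x) {
  S4Vectors::metadata(x)$preprocess
})

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("SpectraSet: %d spectra (%d samples) x %d wavenumbers\n",
              ncol(object), length(unique(cd$sample_id)), length(wn)))
  cat(sprintf("  grid: %g .. %g cm^-1, spacing %g\n",
              wn[1L], wn[length(wn)], gridSpacing(wn)))
  cat(sprintf("  cohorts: %s\n",
              paste(sprintf("%s=%d", names(table(cd$cohort)),
                            table(cd$cohort)), collapse = " ")))
  pp <- preprocessProvenance(object)
  if (!is.null(pp)) {
    cat(sprintf("  preprocessed: derivative=%s normalization=%s scaling=%s\n",
                pp$derivative_order, pp$normalization, pp$scaling))
  }
})
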