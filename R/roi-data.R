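#' Construct a ROI-volume experiment
#'
#' Bundles a matrix of regional brain volumes with per-scan metadata into a
#' \link[SummarizedExperiment]{SummarizedExperiment}. Rows are regions of
#' interest (ROIs), columns are scans (one row of the tabular input per
#' scan). The assay is named \code{"volumes"}.
#'
#' @param volumes numeric matrix, ROIs in rows (rownames = ROI names),
#'   scans in columns. No missing values.
#' @param participantId character/factor, one entry per scan.
#' @param visitTime numeric years since baseline (0 for cross-sectional),
#'   non-negative, non-decreasing within participant.
#' @param diagnosis character, one of \code{"CN"}, \code{"MCI"},
#'   \code{"Dementia"}, or \code{NA} for prediction-only inputs.
#' @param age numeric years, finite.
#' @param sex binary code, 0/1.
#' @param tissue optional character vector per ROI, e.g. \code{"GM"},
#'   \code{"WM"}, \code{"VENT"}; stored in \code{rowData}.
#' @return a \code{SummarizedExperiment}.
#' @export
roiExperiment <- function(volumes, participantId, visitTime, diagnosis,
                          age, sex, tissue = NULL) {
  volumes <- as.matrix(volumes)
  if (is.null(rownames(volumes)))
    rownames(volumes) <- sprintf("ROI_%d", seq_len(nrow(volumes)))
  n <- ncol(volumes)
  stopifnot(length(participantId) == n, length(visitTime) == n,
            length(age) == n, length(sex) == n)
  if (missing(diagnosis) || is.null(diagnosis)) diagnosis <- rep(NA_character_, n)
  cd <- S4Vectors::DataFrame(
    participant_id = as.character(participantId),
    visit_time = as.numeric(visitTime),
    diagnosis = as.character(diagnosis),
    age = as.numeric(age),
    sex = as.numeric(sex))
  rd <- S4Vectors::DataFrame(row.names = rownames(volumes))
  if (!is.null(tissue)) rd$tissue <- tissue
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volumes = volumes), colData = cd, rowData = rd)
  validateROIExperiment(se)
  se
}

#' Validate a ROI-volume experiment
#'
#' Checks the invariants required by all downstream operations: complete
#' volume matrix, at least two ROIs, finite ages, 0/1 sex codes,
#' non-negative visit times that do not decrease within a participant.
#'
#' @param se a \code{SummarizedExperiment} as built by [roiExperiment()].
#' @return the object, invisibly; errors otherwise.
#' @export
validateROIExperiment <- function(se) {
  stopifnot(methods::is(se, "SummarizedExperiment"))
  if (!"volumes" %in% SummarizedExperiment::assayNames(se))
    stop("assay 'volumes' is required")
  v <- SummarizedExperiment::assay(se, "volumes")
  if (nrow(v) < 2L) stop("at least 2 ROIs are required")
  if (anyNA(v)) stop("missing ROI volumes are not allowed")
  cd <- SummarizedExperiment::colData(se)
  req <- c("participant_id", "visit_time", "diagnosis", "age", "sex")
  miss <- setdiff(req, colnames(cd))
  if (length(miss)) stop("missing colData columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(cd$age))) stop("age must be finite")
  if (any(!cd$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (any(cd$visit_time < 0)) stop("visit_time must be non-negative")
  dx <- cd$diagnosis
  if (any(!is.na(dx) & !dx %in% c("CN", "MCI", "Dementia")))
    stop("diagnosis must be CN, MCI, Dementia or NA")
  for (id in unique(cd$participant_id)) {
    vt <- cd$visit_time[cd$participant_id == id]
    if (is.unsorted(vt)) stop("visit_time must be non-decreasing within participant ", id)
  }
  invisible(se)
}

#' Read a ROI table from CSV/TSV
#'
#' Expected columns: \code{participant_id}, \code{visit_time},
#' \code{diagnosis}, \code{age}, \code{sex}, then ROI columns prefixed
#' \code{ROI_}. Header required, UTF-8, \code{.} decimal separator. The
#' separator is taken from the file extension (\code{.tsv}/\code{.txt} =
#' tab) unless given.
#'
#' @param path file path.
#' @param sep field separator; default inferred from extension.
#' @return a \code{SummarizedExperiment} (see [roiExperiment()]).
#' @export
readROITable <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  roiCols <- grep("^ROI_", colnames(df), value = TRUE)
  if (length(roiCols) < 2L) stop("no ROI_ columns found in ", path)
  vol <- t(as.matrix(df[, roiCols, drop = FALSE]))
  dxcol <- if ("diagnosis" %in% colnames(df)) df$diagnosis else NULL
  roiExperiment(vol, df$participant_id, df$visit_time, dxcol, df$age, df$sex)
}

#' Write a ROI table to CSV/TSV
#'
#' Inverse of [readROITable()]: one row per scan, metadata columns first,
#' then \code{ROI_}-prefixed volume columns.
#'
#' @param se a ROI \code{SummarizedExperiment}.
#' @param path output file path.
#' @param sep field separator; default inferred from extension.
#' @return \code{path}, invisibly.
#' @export
writeROITable <- function(se, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  vol <- t(SummarizedExperiment::assay(se, "volumes"))
  df <- cbind(cd[, c("participant_id", "visit_time", "diagnosis", "age", "sex")],
              as.data.frame(vol))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# scans x ROI matrix from an SE or a plain matrix (samples in rows,
# named ROI columns); the internal orientation used by the model code.
.sampleMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- t(SummarizedExperiment::assay(x, "volumes"))
    rownames(m) <- SummarizedExperiment::colData(x)$participant_id
    return(m)
  }
  m <- as.matrix(x)
  if (is.null(colnames(m))) stop("matrix input must have ROI column names")
  m
}

# subset helper by diagnosis
.diagnosisSubset <- function(se, dx) {
  se[, !is.na(SummarizedExperiment::colData(se)$diagnosis) &
       SummarizedExperiment::colData(se)$diagnosis == dx]
}
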