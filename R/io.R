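#' Write a subject's time courses as delimited text
#'
#' CSV with header \code{time_s, <roi1>, <roi2>} plus a JSON sidecar
#' (\code{<path>.json}) recording the sampling interval, labels and — for
#' simulated subjects — the generative settings and the exact ground-truth
#' correlation trajectory.
#'
#' @param x a \linkS4class{BivariateSeries} or \linkS4class{SimulatedSubject}.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeSubjectTimeseries <- function(x, path, sidecar = TRUE) {
  truth <- NULL; spec <- NULL
  if (is(x, "SimulatedSubject")) {
    truth <- x@trueCorrelation
    spec <- list(nTime = x@spec@nTime, tr = x@spec@tr,
                 meanParams = x@spec@meanParams, varParams = x@spec@varParams,
                 mode = x@spec@mode, seed = x@spec@seed)
    x <- x@series
  }
  stopifnot(is(x, "BivariateSeries"))
  df <- data.frame(time_s = (seq_len(nrow(x@values)) - 1) * x@tr, x@values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    meta <- list(tr = x@tr, labels = x@labels, n_time = nrow(x@values))
    if (!is.null(truth)) meta$true_correlation <- truth
    if (!is.null(spec)) meta$spec <- spec
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a subject's time courses from delimited text
#'
#' Expects a comma-separated file with a header row: a \code{time_s} column
#' plus one column per network. Non-numeric or missing cells are rejected
#' with the offending data row numbers.
#'
#' @param path CSV path.
#' @param tr sampling interval in seconds; inferred from \code{time_s} when
#'   NULL.
#' @param columns optional character(2) selecting which two network columns
#'   to keep; default: the first two non-time columns.
#' @return A \linkS4class{BivariateSeries}.
#' @export
readSubjectTimeseries <- function(path, tr = NULL, columns = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing required column 'time_s'")
  rois <- setdiff(names(df), "time_s")
  if (length(rois) < 2L) stop("need at least two network columns")
  if (is.null(columns)) columns <- rois[1:2]
  if (!all(columns %in% rois))
    stop("requested columns not present: ",
         paste(setdiff(columns, rois), collapse = ", "))
  sel <- df[, columns, drop = FALSE]
  for (cl in columns) {
    v <- sel[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric values in column '", cl, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (anyNA(v) || any(!is.finite(v)))
      stop("missing/non-finite values in column '", cl, "' at data row(s) ",
           paste(utils::head(which(is.na(v) | !is.finite(v)), 5),
                 collapse = ", "))
  }
  if (nrow(sel) < 50L)
    stop("only ", nrow(sel), " rows; at least 50 time points are required")
  if (is.null(tr)) {
    dt <- diff(df$time_s)
    if (any(abs(dt - dt[1]) > 1e-8))
      stop("time_s is not equally spaced; supply 'tr' explicitly")
    tr <- dt[1]
  }
  BivariateSeries(as.matrix(sel), tr = tr, labels = columns)
}

#' Write a simulated cohort to disk
#'
#' One CSV (plus sidecar) per subject and a manifest
#' (\code{manifest.csv}: subject_id, label, path).
#'
#' @param cohort a \linkS4class{SimulatedCohort}.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SimulatedCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort@manifest
  man$path <- file.path(dir, paste0(man$subject_id, ".csv"))
  for (i in seq_len(nrow(man)))
    writeSubjectTimeseries(cohort@subjects[[i]], man$path[i])
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest
#'
#' @param path manifest CSV with columns subject_id, label, path (relative
#'   paths are resolved against the manifest's directory).
#' @return data.frame with absolute subject paths.
#' @export
readCohortManifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !file.exists(man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}
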