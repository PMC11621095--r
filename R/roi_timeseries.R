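#' Region-of-interest time-series container
#'
#' One subject's preprocessing unit: a volumes x regions numeric matrix of
#' regional mean BOLD signals, the region labels, and the sampling interval.
#'
#' @param values numeric matrix, volumes x regions, finite entries.
#' @param region_labels character vector, one label per region. Defaults to
#'   the AAL-90 abbreviations when there are 90 columns, otherwise
#'   `R001, R002, ...`.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @return an object of class `roi_ts`.
#' @export
roi_timeseries <- function(values, region_labels = NULL, tr_seconds = 1.0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("time series contains non-finite values")
  if (is.null(region_labels)) {
    region_labels <- if (ncol(values) == 90) aal90_regions()$abbrev
                     else sprintf("R%03d", seq_len(ncol(values)))
  }
  if (length(region_labels) != ncol(values))
    stop("region_labels length (", length(region_labels),
         ") does not match region count (", ncol(values), ")")
  if (!(is.numeric(tr_seconds) && length(tr_seconds) == 1 && tr_seconds > 0))
    stop("tr_seconds must be a single positive number")
  colnames(values) <- region_labels
  structure(list(values = values,
                 region_labels = as.character(region_labels),
                 tr_seconds = tr_seconds),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("<roi_ts> ", nrow(x$values), " volumes x ", ncol(x$values),
      " regions, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

n_volumes <- function(ts) nrow(ts$values)
n_regions <- function(ts) ncol(ts$values)

#' @rdname roi_timeseries
#' @param ts an `roi_ts` object.
#' @param path file path for TSV read/write.
#' @export
write_roi_ts <- function(ts, path) write_matrix_tsv(ts$values, path)

#' @rdname roi_timeseries
#' @export
read_roi_ts <- function(path, region_labels = NULL, tr_seconds = 1.0) {
  roi_timeseries(read_matrix_tsv(path), region_labels, tr_seconds)
}
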