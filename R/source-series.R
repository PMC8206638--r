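#' Construct a set of ROI source time series
#'
#' Container for one subject/timepoint's region-of-interest (ROI) source
#' series: an N x T real matrix (row = ROI, column = sample) together with the
#' sampling rate and ROI labels. This is the input object of the connectivity
#' stage; everything upstream (beamforming, artifact handling) is outside the
#' package's boundary.
#'
#' @param data numeric matrix, N ROIs x T samples.
#' @param fs sampling rate in Hz.
#' @param roi_labels character vector of N unique labels; defaults to the
#'   matrix rownames, else `"ROI_01"`, ...
#' @param subject_id,timepoint labels carried through to downstream reports.
#' @return An object of class `source_series_set`.
#' @export
source_series_set <- function(data, fs, roi_labels = NULL,
                              subject_id = "S1", timepoint = "baseline") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("source series contain non-finite values")
  n <- nrow(data)
  t_len <- ncol(data)
  if (n < 2) stop("need at least 2 ROIs")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("sampling rate 'fs' must be a single positive number (Hz)")
  }
  if (t_len < 2 * fs) {
    stop("series too short: need at least 2 s of data (", 2 * fs,
         " samples at fs = ", fs, " Hz), got ", t_len)
  }
  if (is.null(roi_labels)) {
    roi_labels <- rownames(data)
    if (is.null(roi_labels)) roi_labels <- sprintf("ROI_%02d", seq_len(n))
  }
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != n) stop("roi_labels length must equal nrow(data)")
  if (anyDuplicated(roi_labels)) stop("roi_labels must be unique")
  rownames(data) <- roi_labels
  structure(
    list(data = data, fs = fs, roi_labels = roi_labels,
         subject_id = as.character(subject_id),
         timepoint = as.character(timepoint)),
    class = "source_series_set"
  )
}

#' @export
print.source_series_set <- function(x, ...) {
  cat("<source_series_set> subject", x$subject_id, "/", x$timepoint, "\n")
  cat("  ", nrow(x$data), "ROIs x", ncol(x$data), "samples at",
      x$fs, "Hz (", round(ncol(x$data) / x$fs, 2), "s )\n")
  invisible(x)
}
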