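#' Region-by-volume time-series panel
#'
#' Container for one subject's region-averaged fMRI signal: a numeric matrix
#' with one row per atlas region and one column per volume, plus the
#' repetition time.
#'
#' @param values numeric matrix, regions x volumes.
#' @param tr repetition time in seconds.
#' @param region_labels optional character vector, one per row.
#' @return object of class \code{ts_panel}.
#' @export
ts_panel <- function(values, tr, region_labels = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), tr > 0)
  if (is.null(region_labels)) {
    region_labels <- rownames(values)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(values)))
  }
  stopifnot(length(region_labels) == nrow(values))
  rownames(values) <- region_labels
  structure(list(values = values, tr = tr, region_labels = region_labels),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("ts_panel:", nrow(x$values), "regions x", ncol(x$values),
      "volumes, TR =", x$tr, "s\n")
  invisible(x)
}

#' @export
dim.ts_panel <- function(x) dim(x$values)
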