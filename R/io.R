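# Readers/writers for the plain-text artifact formats (UTF-8, header row,
# "NA" missing sentinel, '.' decimal) and the matched-pair exclusion pruning.

.manifest_cols <- c("subject_id", "site", "group", "pair_id", "age", "sex",
                    "anxiety", "depression", "medication", "severity",
                    "excluded", "exclusion_reason")

#' Write / read a cohort manifest CSV
#'
#' Fixed header: subject_id, site, group, pair_id, age, sex, anxiety,
#' depression, medication, severity, excluded, exclusion_reason. Missing
#' values are written as the "NA" sentinel.
#'
#' @param manifest manifest data.frame.
#' @param path file path.
#' @return \code{read_manifest} returns the manifest data.frame;
#'   \code{write_manifest} returns \code{path} invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(.manifest_cols %in% names(manifest)))
  utils::write.csv(manifest[, .manifest_cols], path, row.names = FALSE,
                   na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 0))
  missing <- setdiff(.manifest_cols, hdr)
  if (length(missing)) {
    stop("manifest ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = c(subject_id = "character",
                                        site = "character",
                                        group = "character",
                                        pair_id = "character",
                                        sex = "character",
                                        medication = "character",
                                        excluded = "character",
                                        exclusion_reason = "character"))
  out
}

#' Write / read a region x volume panel as TSV with a JSON sidecar
#'
#' The TSV holds one row per region (region label in the first column) and
#' one column per volume. The sidecar \code{<path>.json} records tr and any
#' extra metadata supplied.
#'
#' @param panel a \code{ts_panel}.
#' @param path TSV path.
#' @param meta named list of extra sidecar fields (e.g. site, seed).
#' @return \code{read_panel} returns a \code{ts_panel}; the writer returns
#'   \code{path} invisibly.
#' @export
write_panel <- function(panel, path, meta = list()) {
  stopifnot(inherits(panel, "ts_panel"))
  df <- data.frame(region = panel$region_labels, panel$values,
                   check.names = FALSE)
  colnames(df) <- c("region", paste0("v", seq_len(ncol(panel$values))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(tr = panel$tr), meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @param expected_regions optional region count to validate against.
#' @export
read_panel <- function(path, expected_regions = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cells in panel ", path)
  if (!is.null(expected_regions) && nrow(vals) != expected_regions) {
    stop("panel ", path, " has ", nrow(vals), " regions, expected ",
         expected_regions)
  }
  ts_panel(vals, tr = meta$tr, region_labels = df[[1]])
}

#' Write / read a 6-parameter motion trace TSV
#'
#' Columns tx, ty, tz (mm), rx, ry, rz (radians); one row per volume.
#'
#' @param motion motion data.frame.
#' @param path file path.
#' @return the reader returns the data.frame; the writer returns \code{path}
#'   invisibly.
#' @export
write_motion <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  utils::write.table(motion, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  out <- utils::read.delim(path)
  if (!identical(names(out), c("tx", "ty", "tz", "rx", "ry", "rz"))) {
    stop("malformed motion header in ", path)
  }
  out
}

#' Write / read the wm/csf nuisance TSV
#' @param nuisance data.frame with columns wm, csf.
#' @param path file path.
#' @return reader returns the data.frame; writer returns \code{path}.
#' @export
write_nuisance <- function(nuisance, path) {
  stopifnot(all(c("wm", "csf") %in% names(nuisance)))
  utils::write.table(nuisance[, c("wm", "csf")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nuisance
#' @export
read_nuisance <- function(path) {
  out <- utils::read.delim(path)
  if (!all(c("wm", "csf") %in% names(out))) {
    stop("malformed nuisance header in ", path)
  }
  out
}

#' Write / read a feature table as CSV pair
#'
#' \code{<path>} holds one row per subject with columns e0001..e<m>;
#' \code{<path>} with suffix \code{_meta.csv} holds subject_id, site, group
#' and the stage tag.
#'
#' @param table a \code{feature_table}.
#' @param path CSV path for the feature matrix.
#' @return reader returns a \code{feature_table}; writer returns \code{path}.
#' @export
write_features <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject_id = table$subjects$subject_id, table$features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- table$subjects
  meta$stage <- table$stage
  utils::write.csv(meta, sub("\\.csv$", "_meta.csv", path), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- utils::read.csv(sub("\\.csv$", "_meta.csv", path),
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  m <- ncol(x)
  n_regions <- (1 + sqrt(1 + 8 * m)) / 2
  if (n_regions != round(n_regions)) {
    stop("feature CSV has ", m, " edge columns, not a valid n*(n-1)/2")
  }
  feature_table(x, meta[, c("subject_id", "site", "group")],
                edge_index(n_regions), stage = meta$stage[1])
}

#' Write / read the simulation ground truth JSON
#'
#' Records the effect edges (1-based, i < j), per-edge expected direction,
#' the receiving group, per-site rotation parameters and the seed.
#'
#' @param truth truth list from \code{\link{simulate_cohort}}.
#' @param path JSON path.
#' @return reader returns the truth list; writer returns \code{path}.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$edges <- if (nrow(truth$edges)) {
    data.frame(i = truth$edges[, 1], j = truth$edges[, 2])
  } else data.frame(i = integer(0), j = integer(0))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$edges <- as.matrix(out$edges)
  out
}

#' Export a weight report in BrainNet-compatible .node/.edge text form
#'
#' The .node file lists one region per line (region index, top-k frequency as
#' node size); the .edge file is the dense top-k subgraph weight matrix.
#' Plain whitespace-delimited text, no rendering.
#'
#' @param report a \code{weight_report}.
#' @param index the \code{edge_index}.
#' @param node_path,edge_path output paths.
#' @return invisible NULL.
#' @export
export_brainnet <- function(report, index, node_path, edge_path) {
  freq <- region_frequency(report, index)
  freq <- freq[order(freq$region), ]
  utils::write.table(data.frame(region = freq$region, size = freq$frequency,
                                label = freq$label),
                     node_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  n <- attr(index, "n_regions")
  mat <- matrix(0, n, n)
  mat[cbind(report$top$i, report$top$j)] <- report$top$importance
  mat[cbind(report$top$j, report$top$i)] <- report$top$importance
  utils::write.table(mat, edge_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Prune a cohort to intact matched pairs
#'
#' Any pair with at least one excluded member is removed entirely: the
#' excluded subjects for their recorded reasons, their non-excluded partners
#' as "partner" removals. The ledger reports counts by reason. For example, a
#' 220-scan cohort with 31 primary exclusions structured as 7 both-excluded
#' pairs plus 17 single-excluded pairs loses 17 partners and keeps 172 scans.
#'
#' @param manifest manifest data.frame with excluded ("yes"/"no") and
#'   exclusion_reason columns; every subject needs a pair_id.
#' @return list with \code{manifest} (pruned), \code{ledger} (list:
#'   n_initial, n_excluded_by_reason, n_partner_removed, n_remaining) and
#'   \code{decisions} (per-subject keep/exclude data.frame).
#' @export
prune_matched_pairs <- function(manifest) {
  if (any(is.na(manifest$pair_id) | manifest$pair_id == "")) {
    stop("subject without a pair id: ",
         paste(manifest$subject_id[is.na(manifest$pair_id) |
                                     manifest$pair_id == ""], collapse = ", "))
  }
  excl <- manifest$excluded == "yes"
  bad_pairs <- unique(manifest$pair_id[excl])
  partner <- manifest$pair_id %in% bad_pairs & !excl
  decisions <- data.frame(
    subject_id = manifest$subject_id,
    decision = ifelse(excl | partner, "exclude", "keep"),
    reason = ifelse(excl, manifest$exclusion_reason,
                    ifelse(partner, "partner", NA_character_)),
    stringsAsFactors = FALSE
  )
  pruned <- manifest[!(excl | partner), , drop = FALSE]
  if (nrow(pruned) == 0) warning("all pairs excluded; empty cohort")
  ledger <- list(
    n_initial = nrow(manifest),
    n_excluded_by_reason = table(manifest$exclusion_reason[excl]),
    n_partner_removed = sum(partner),
    n_remaining = nrow(pruned)
  )
  list(manifest = pruned, ledger = ledger, decisions = decisions)
}
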