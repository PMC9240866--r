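# Connectivity featurization: Pearson correlation matrices, Fisher-Z
# transform, lexicographic edge vectorization into a subjects x edges feature
# table, and per-site connection-wise Z-score harmonization.

#' Pairwise Pearson correlation matrix of a panel
#'
#' @param panel a \code{ts_panel} with >= 3 volumes and positive per-region
#'   variance.
#' @return object of class \code{conn_matrix} at stage "raw": symmetric,
#'   unit diagonal, entries in [-1, 1].
#' @export
correlation_matrix <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  x <- panel$values
  if (ncol(x) < 3) stop("need at least 3 volumes")
  v <- apply(x, 1, stats::var)
  if (any(v <= 0)) {
    stop("zero-variance region(s): ",
         paste(panel$region_labels[v <= 0], collapse = ", "))
  }
  vals <- stats::cor(t(x))
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  structure(list(values = vals, stage = "raw",
                 region_labels = panel$region_labels),
            class = "conn_matrix")
}

#' Fisher-Z transform of a correlation matrix
#'
#' Elementwise inverse hyperbolic tangent. Correlations with |r| >= 1 - 1e-7
#' are clipped to that bound first so the transform stays finite. The
#' diagonal is carried through but excluded from feature extraction.
#'
#' @param matrix a \code{conn_matrix} at stage "raw".
#' @return a \code{conn_matrix} at stage "fisher".
#' @export
fisher_transform <- function(matrix) {
  stopifnot(inherits(matrix, "conn_matrix"))
  if (matrix$stage != "raw") stop("fisher_transform expects a raw-stage matrix")
  bound <- 1 - 1e-7
  v <- pmin(pmax(matrix$values, -bound), bound)
  matrix$values <- atanh(v)
  matrix$stage <- "fisher"
  matrix
}

#' Subjects-by-edges feature table
#'
#' @param features numeric matrix, one row per subject, one column per edge
#'   (length \code{n_edges(index)}).
#' @param subjects data.frame with columns subject_id, site, group aligned
#'   with feature rows.
#' @param index the \code{edge_index} used for vectorization.
#' @param stage "fisher" (raw Fisher-Z units) or "site_normalized".
#' @return object of class \code{feature_table}.
#' @export
feature_table <- function(features, subjects, index,
                          stage = c("fisher", "site_normalized")) {
  stage <- match.arg(stage)
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(subjects),
            ncol(features) == nrow(index),
            all(c("subject_id", "site", "group") %in% names(subjects)),
            all(subjects$group %in% c("patient", "control")))
  if (any(!is.finite(features))) stop("non-finite feature values")
  colnames(features) <- sprintf("e%04d", seq_len(ncol(features)))
  rownames(features) <- subjects$subject_id
  structure(list(features = features, subjects = subjects, index = index,
                 stage = stage),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "subjects x", ncol(x$features),
      "edges, stage =", x$stage, "\n")
  cat("  sites:", paste(sprintf("%s(%d)", names(table(x$subjects$site)),
                                table(x$subjects$site)), collapse = " "), "\n")
  invisible(x)
}

#' Subset a feature table by row
#' @param table a \code{feature_table}.
#' @param rows integer or logical row selector.
#' @return a \code{feature_table}.
#' @export
ft_subset <- function(table, rows) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$features[rows, , drop = FALSE],
                table$subjects[rows, , drop = FALSE],
                table$index, stage = table$stage)
}

#' Build the feature table from conditioned panels
#'
#' Runs correlation, Fisher-Z, and lexicographic upper-triangle vectorization
#' per subject. For 88 regions each subject yields 88*87/2 = 3828 features.
#'
#' @param panels named list of conditioned \code{ts_panel}s.
#' @param manifest cohort manifest with subject_id, site, group; only
#'   subjects present in \code{panels} are used, in manifest order.
#' @param index optional \code{edge_index}; derived from the first panel if
#'   missing.
#' @return a \code{feature_table} at stage "fisher".
#' @export
compute_features <- function(panels, manifest, index = NULL) {
  ids <- manifest$subject_id[manifest$subject_id %in% names(panels)]
  if (length(ids) == 0) stop("no manifest subjects found in panels")
  if (is.null(index)) index <- edge_index(nrow(panels[[ids[1]]]$values))
  rows <- t(vapply(ids, function(id) {
    vectorize_edges(fisher_transform(correlation_matrix(panels[[id]])), index)
  }, numeric(nrow(index))))
  feature_table(rows, manifest[match(ids, manifest$subject_id),
                               c("subject_id", "site", "group")],
                index, stage = "fisher")
}

#' Per-site connection-wise Z-score harmonization
#'
#' Within each site, each feature column is centred and scaled to unit sample
#' SD (n-1 denominator) over all subjects of that site, both groups together.
#' This removes any site-deterministic per-edge shift or scale. A strict mode
#' computes the per-site statistics on a designated training subset only and
#' applies them to the rest of the site, avoiding test-set distributional
#' leakage inside cross-validation; sites with no training rows fall back to
#' their own statistics (label-free, so no group leakage either way).
#'
#' @param table a \code{feature_table} at stage "fisher".
#' @param train optional logical/integer row selector: when supplied, site
#'   statistics come from these rows only (strict mode).
#' @return a \code{feature_table} at stage "site_normalized".
#' @export
site_normalize <- function(table, train = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$features
  site <- table$subjects$site
  trainmask <- rep(TRUE, nrow(x))
  if (!is.null(train)) {
    trainmask[] <- FALSE
    trainmask[train] <- TRUE
  }
  zerocols <- character(0)
  for (s in unique(site)) {
    rows <- which(site == s)
    if (length(rows) < 2) stop("site ", s, " has fewer than 2 subjects")
    ref <- rows[trainmask[rows]]
    if (length(ref) < 2) ref <- rows
    mu <- colMeans(x[ref, , drop = FALSE])
    sd <- apply(x[ref, , drop = FALSE], 2, stats::sd)
    bad <- sd == 0
    if (any(bad)) {
      zerocols <- union(zerocols, colnames(x)[bad])
      sd[bad] <- 1
    }
    x[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, mu), 2, sd, "/")
    if (any(bad)) x[rows, bad] <- 0
  }
  if (length(zerocols)) {
    warning("zero within-site SD in ", length(zerocols),
            " feature column(s); set to 0")
  }
  feature_table(x, table$subjects, table$index, stage = "site_normalized")
}
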