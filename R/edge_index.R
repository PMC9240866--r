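#' Lexicographic edge index for an undirected connectome
#'
#' Builds the bijection between ordered region pairs (i, j), i < j, 1-based,
#' and flat feature indices 1..m with m = n*(n-1)/2, in lexicographic order
#' ((1,2), (1,3), ..., (1,n), (2,3), ...). This is the ordering used to turn
#' the upper triangle of a connectivity matrix into a feature vector.
#'
#' @param n_regions number of atlas regions (>= 2).
#' @param labels optional character vector of region labels, length
#'   \code{n_regions}. Defaults to the bundled 88-region AAL-style labels
#'   when \code{n_regions == 88}, otherwise \code{"R1".."Rn"}.
#' @return an object of class \code{edge_index}: a data.frame with columns
#'   \code{k}, \code{i}, \code{j}, \code{label_i}, \code{label_j} and
#'   attribute \code{n_regions}.
#' @examples
#' idx <- edge_index(4)
#' idx$i  # 1 1 1 2 2 3
#' idx$j  # 2 3 4 3 4 4
#' @export
edge_index <- function(n_regions, labels = NULL) {
  stopifnot(is.numeric(n_regions), length(n_regions) == 1, n_regions >= 2)
  n_regions <- as.integer(n_regions)
  if (is.null(labels)) {
    labels <- if (n_regions == 88L) aal88_labels() else paste0("R", seq_len(n_regions))
  }
  if (length(labels) != n_regions) {
    stop("labels must have length n_regions (", n_regions, ")")
  }
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(a) (a + 1L):n_regions),
              use.names = FALSE)
  out <- data.frame(
    k = seq_along(i), i = i, j = j,
    label_i = labels[i], label_j = labels[j],
    stringsAsFactors = FALSE
  )
  attr(out, "n_regions") <- n_regions
  class(out) <- c("edge_index", "data.frame")
  out
}

#' Number of edges in an edge index
#' @param index an \code{edge_index}.
#' @return integer m = n*(n-1)/2.
#' @export
n_edges <- function(index) {
  stopifnot(inherits(index, "edge_index"))
  nrow(index)
}

#' Flat feature index of a region pair
#'
#' Closed-form lexicographic rank of the pair (i, j), i < j, among all
#' unordered pairs of \code{n_regions} regions.
#'
#' @param i,j 1-based region indices with \code{i < j} (vectorized).
#' @param n_regions region count.
#' @return integer vector of flat indices in 1..m.
#' @export
edge_to_k <- function(i, j, n_regions) {
  stopifnot(all(i >= 1), all(j > i), all(j <= n_regions))
  as.integer((i - 1) * n_regions - i * (i - 1) / 2 + (j - i))
}

#' Region pair of a flat feature index
#' @param k flat index in 1..m (vectorized).
#' @param index an \code{edge_index}.
#' @return data.frame with columns \code{i}, \code{j}.
#' @export
k_to_edge <- function(k, index) {
  stopifnot(all(k >= 1), all(k <= nrow(index)))
  index[k, c("i", "j")]
}

#' Extract the upper-triangle feature row of a connectivity matrix
#'
#' Vectorizes the strict upper triangle (diagonal excluded) in lexicographic
#' pair order, matching \code{edge_index}. For 88 regions the result has
#' 88*87/2 = 3828 entries.
#'
#' @param matrix a \code{conn_matrix} (see \code{\link{correlation_matrix}})
#'   or a plain symmetric numeric matrix.
#' @param index an \code{edge_index} for the same region count.
#' @return numeric vector of length \code{n_edges(index)}.
#' @export
vectorize_edges <- function(matrix, index) {
  vals <- if (inherits(matrix, "conn_matrix")) matrix$values else matrix
  stopifnot(is.matrix(vals), nrow(vals) == ncol(vals))
  if (nrow(vals) != attr(index, "n_regions")) {
    stop("matrix has ", nrow(vals), " regions but index expects ",
         attr(index, "n_regions"))
  }
  vals[cbind(index$i, index$j)]
}

#' Rebuild a symmetric matrix from an edge feature row
#'
#' Inverse of \code{\link{vectorize_edges}}: places entry k at positions
#' (i, j) and (j, i) of the k-th lexicographic pair. The diagonal is zero.
#'
#' @param row numeric vector of length \code{n_edges(index)}.
#' @param index an \code{edge_index}.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
matrixize_edges <- function(row, index) {
  n <- attr(index, "n_regions")
  if (length(row) != nrow(index)) {
    stop("row has length ", length(row), " but index has ", nrow(index), " edges")
  }
  out <- matrix(0, n, n)
  out[cbind(index$i, index$j)] <- row
  out[cbind(index$j, index$i)] <- row
  out
}
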