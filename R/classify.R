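# Linear soft-margin SVM (libsvm via e1071) and the four evaluation designs:
# intra-centre leave-one-out, pooled leave-one-out, inter-centre
# leave-one-site-out, transfer learning curves, and label-permutation
# significance testing. The patient class sits on the positive side of the
# decision function; a decision value of exactly 0 predicts "control".

.as_group_factor <- function(g) factor(as.character(g), levels = c("control", "patient"))

#' Fit a linear L2-regularized soft-margin SVM
#'
#' Minimizes the standard hinge-loss objective with an L2 penalty at fixed
#' cost C (no hyperparameter search; C defaults to 1). The returned weight
#' vector and bias are oriented so that \code{weights \%*\% x + bias > 0}
#' predicts "patient".
#'
#' @param x numeric feature matrix (subjects x features), finite.
#' @param y group labels ("patient"/"control"), both classes present.
#' @param C cost parameter (default 1).
#' @param tolerance solver termination tolerance (default 1e-6).
#' @return object of class \code{linear_svm}: list(weights, bias, C).
#' @export
fit_linear_svm <- function(x, y, C = 1, tolerance = 1e-6) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- .as_group_factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  m <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                  cost = C, scale = FALSE, tolerance = tolerance)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # libsvm orients the decision toward whichever class it saw first; flip so
  # that positive always means patient
  pr <- stats::predict(m, x[1, , drop = FALSE], decision.values = TRUE)
  pos_class <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
  if (pos_class != "patient") {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b, C = C), class = "linear_svm")
}

#' Decision values and predicted labels of a linear SVM
#'
#' @param object a \code{linear_svm}.
#' @param x feature matrix.
#' @param ... unused.
#' @return list with \code{decision} (numeric) and \code{label}
#'   ("patient" when decision > 0, else "control").
#' @export
predict.linear_svm <- function(object, x, ...) {
  d <- drop(as.matrix(x) %*% object$weights) + object$bias
  list(decision = d, label = ifelse(d > 0, "patient", "control"))
}

.cv_result <- function(scheme, scope, predictions, fold_weights) {
  structure(list(scheme = scheme, scope = scope, predictions = predictions,
                 fold_weights = fold_weights),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- mean(x$predictions$pred == x$predictions$truth)
  cat(sprintf("cv_result [%s%s]: %d test predictions, accuracy %.3f\n",
              x$scheme, if (!is.null(x$scope)) paste0(":", x$scope) else "",
              nrow(x$predictions), acc))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Intra-centre (one site) or pooled (all sites) LOO: each fold trains on
#' n-1 subjects and tests on the held-out one, until every subject in scope
#' has been tested once. Per-fold weight vectors are retained for the
#' discriminative-connection post-hocs.
#'
#' @param table a \code{feature_table}.
#' @param scope a site id for intra-centre CV, or NULL for pooled CV.
#' @param C SVM cost.
#' @param normalize "none" (table used as supplied, e.g. already
#'   site-normalized on the full cohort) or "strict" (per-site statistics
#'   recomputed from each fold's training rows; requires a fisher-stage
#'   table).
#' @param keep_weights retain per-fold weight vectors (default TRUE).
#' @return a \code{cv_result} with scheme "intra" or "pooled".
#' @export
loo_cv <- function(table, scope = NULL, C = 1,
                   normalize = c("none", "strict"), keep_weights = TRUE) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(table, "feature_table"))
  ft <- if (is.null(scope)) table else ft_subset(table, table$subjects$site == scope)
  n <- nrow(ft$features)
  if (n < 4) stop("scope must contain at least 4 subjects")
  if (length(unique(ft$subjects$group)) < 2) stop("both classes required")
  preds <- ft$subjects[, c("subject_id", "site", "group")]
  names(preds)[3] <- "truth"
  preds$pred <- NA_character_
  preds$decision <- NA_real_
  W <- if (keep_weights) matrix(NA_real_, n, ncol(ft$features)) else NULL
  for (i in seq_len(n)) {
    fi <- if (normalize == "strict") site_normalize(ft, train = -i) else ft
    model <- fit_linear_svm(fi$features[-i, , drop = FALSE],
                            fi$subjects$group[-i], C = C)
    pr <- predict(model, fi$features[i, , drop = FALSE])
    preds$pred[i] <- pr$label
    preds$decision[i] <- pr$decision
    if (keep_weights) W[i, ] <- model$weights
  }
  .cv_result(if (is.null(scope)) "pooled" else "intra", scope, preds, W)
}

#' Leave-one-site-out (inter-centre) cross-validation
#'
#' Each site is used once as the whole test set while the classifier is
#' trained on all other sites; probes generalization to an unseen scanner.
#'
#' @param table a \code{feature_table} with >= 2 sites, both classes per site.
#' @param C SVM cost.
#' @param normalize "none" or "strict" (site statistics from training sites'
#'   own rows; the held-out site is normalized with its own label-free
#'   statistics).
#' @param keep_weights retain the fold weight vector.
#' @return named list of \code{cv_result}s, one per held-out site
#'   (scheme "inter").
#' @export
loso_cv <- function(table, C = 1, normalize = c("none", "strict"),
                    keep_weights = TRUE) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(table, "feature_table"))
  sites <- unique(table$subjects$site)
  if (length(sites) < 2) stop("leave-one-site-out requires >= 2 sites")
  out <- lapply(sites, function(s) {
    test <- table$subjects$site == s
    ft <- if (normalize == "strict") site_normalize(table, train = !test) else table
    model <- fit_linear_svm(ft$features[!test, , drop = FALSE],
                            ft$subjects$group[!test], C = C)
    pr <- predict(model, ft$features[test, , drop = FALSE])
    preds <- ft$subjects[test, c("subject_id", "site", "group")]
    names(preds)[3] <- "truth"
    preds$pred <- pr$label
    preds$decision <- pr$decision
    .cv_result("inter", s, preds,
               if (keep_weights) matrix(model$weights, 1) else NULL)
  })
  stats::setNames(out, sites)
}

#' Transfer learning curve for one held-out site
#'
#' Starts from the plain leave-one-site-out split (k = 0), then iteratively
#' transfers one randomly chosen control and one patient (seeded) from the
#' test site into the training set, retrains, and re-evaluates on the
#' shrunken test set, stopping when fewer than 2 subjects would remain. For a
#' 15-pair site the maximum transferred count is 28 with 2 subjects left.
#'
#' @param table a \code{feature_table}.
#' @param held_out_site site id; must have >= 4 subjects, balanced groups.
#' @param seed integer seed for the transfer order.
#' @param C SVM cost.
#' @return object of class \code{learning_curve}: data.frame with columns
#'   k, n_test, accuracy, sensitivity, specificity; attribute "seed".
#' @export
transfer_learning_curve <- function(table, held_out_site, seed = 1, C = 1) {
  stopifnot(inherits(table, "feature_table"))
  test_rows <- which(table$subjects$site == held_out_site)
  if (length(test_rows) < 4) stop("held-out site must have >= 4 subjects")
  grp <- table$subjects$group[test_rows]
  pat <- test_rows[grp == "patient"]
  con <- test_rows[grp == "control"]
  if (length(pat) != length(con)) stop("held-out site must be balanced")
  ord_p <- with_seed(seed, list(sample(pat), sample(con)))
  pat <- ord_p[[1]]; con <- ord_p[[2]]
  base_train <- setdiff(seq_len(nrow(table$features)), test_rows)
  ks <- seq(0, length(test_rows) - 2, by = 2)
  rows <- lapply(ks, function(k) {
    moved <- c(if (k > 0) pat[seq_len(k / 2)], if (k > 0) con[seq_len(k / 2)])
    train <- c(base_train, moved)
    test <- setdiff(test_rows, moved)
    model <- fit_linear_svm(table$features[train, , drop = FALSE],
                            table$subjects$group[train], C = C)
    pr <- predict(model, table$features[test, , drop = FALSE])
    met <- confusion_metrics(pr$label, table$subjects$group[test])
    data.frame(k = k, n_test = length(test), accuracy = met$accuracy,
               sensitivity = met$sensitivity, specificity = met$specificity)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "site") <- held_out_site
  class(out) <- c("learning_curve", "data.frame")
  out
}

# Accuracy of a scheme run, used by the permutation test.
.scheme_accuracy <- function(table, scheme, scope, C, normalize) {
  preds <- switch(scheme,
    pooled = loo_cv(table, NULL, C = C, normalize = normalize,
                    keep_weights = FALSE)$predictions,
    intra = loo_cv(table, scope, C = C, normalize = normalize,
                   keep_weights = FALSE)$predictions,
    inter = {
      res <- loso_cv(table, C = C, normalize = normalize, keep_weights = FALSE)
      if (!is.null(scope)) res[[scope]]$predictions
      else do.call(rbind, lapply(res, `[[`, "predictions"))
    },
    stop("unknown scheme: ", scheme))
  mean(preds$pred == preds$truth)
}

#' Permutation test of classification accuracy
#'
#' Re-runs the full cross-validation scheme with group labels permuted
#' uniformly at random (optionally within site) and reports
#' p = (1 + #\{null accuracy >= observed\}) / (n_permutations + 1).
#'
#' @param table a \code{feature_table}.
#' @param scheme "pooled", "intra" or "inter".
#' @param scope site id for intra (or to score a single inter fold);
#'   NULL otherwise.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed.
#' @param within_site permute labels within each site instead of globally.
#' @param C SVM cost.
#' @param normalize passed to the scheme (see \code{\link{loo_cv}}).
#' @return list with \code{p_value}, \code{observed} accuracy, \code{null}
#'   (numeric vector of permuted accuracies), \code{n_permutations},
#'   \code{seed}.
#' @export
permutation_test <- function(table, scheme = c("pooled", "intra", "inter"),
                             scope = NULL, n_permutations = 1000, seed = 1,
                             within_site = FALSE, C = 1,
                             normalize = c("none", "strict")) {
  scheme <- match.arg(scheme)
  normalize <- match.arg(normalize)
  stopifnot(n_permutations >= 1)
  observed <- .scheme_accuracy(table, scheme, scope, C, normalize)
  site <- table$subjects$site
  null <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    perm <- table
    if (within_site) {
      g <- perm$subjects$group
      for (s in unique(site)) {
        rows <- which(site == s)
        g[rows] <- g[sample(rows)]
      }
      perm$subjects$group <- g
    } else {
      perm$subjects$group <- sample(perm$subjects$group)
    }
    .scheme_accuracy(perm, scheme, scope, C, normalize)
  }, numeric(1)))
  list(p_value = (1 + sum(null >= observed)) / (n_permutations + 1),
       observed = observed, null = null,
       n_permutations = n_permutations, seed = seed)
}
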