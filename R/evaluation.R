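# Performance metrics, discriminative-connection reports, site/group ANOVA
# diagnostics, and the confounder logistic regression. The patient group is
# the positive class throughout: sensitivity is patient detection.

#' Confusion counts and headline metrics
#'
#' accuracy = (TP + TN)/n, sensitivity = TP/(TP + FN),
#' specificity = TN/(TN + FP), with patient as the positive class.
#' A zero-denominator sensitivity or specificity is reported as NA with a
#' warning.
#'
#' @param predictions predicted labels ("patient"/"control").
#' @param truth true labels, same length.
#' @return list with \code{counts} (TP, TN, FP, FN, n), \code{accuracy},
#'   \code{sensitivity}, \code{specificity}.
#' @export
confusion_metrics <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth), length(truth) > 0)
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  tp <- sum(predictions == "patient" & truth == "patient")
  tn <- sum(predictions == "control" & truth == "control")
  fp <- sum(predictions == "patient" & truth == "control")
  fn <- sum(predictions == "control" & truth == "patient")
  n <- tp + tn + fp + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive cases; sensitivity undefined"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative cases; specificity undefined"); NA_real_
  }
  list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn, n = n),
       accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec)
}

#' Area under the ROC curve with interpretive band
#'
#' AUC is the probability that a randomly drawn patient receives a higher
#' decision value than a randomly drawn control, computed by pairwise
#' counting with ties scored 1/2 (equivalently, the normalized Mann-Whitney
#' statistic). Bands: >= 0.9 "perfect" (approaching perfect separation),
#' [0.7, 0.9) "moderate", (0.5, 0.7) "low", <= 0.5 "uninformative".
#'
#' @param decision numeric decision values.
#' @param truth labels ("patient"/"control"), both present.
#' @return list with \code{auc} and \code{band}.
#' @export
roc_auc <- function(decision, truth) {
  stopifnot(length(decision) == length(truth))
  truth <- as.character(truth)
  pat <- truth == "patient"
  if (!any(pat) || all(pat)) stop("both classes required for AUC")
  r <- rank(decision)
  np <- sum(pat)
  nc <- sum(!pat)
  auc <- (sum(r[pat]) - np * (np + 1) / 2) / (np * nc)
  band <- if (auc >= 0.9) "perfect"
  else if (auc >= 0.7) "moderate"
  else if (auc > 0.5) "low"
  else "uninformative"
  list(auc = auc, band = band)
}

#' Full metrics report of a cross-validation result
#'
#' @param cv a \code{cv_result}.
#' @param p_value optional permutation p-value to attach.
#' @return list combining \code{\link{confusion_metrics}} and
#'   \code{\link{roc_auc}} over the aggregated fold predictions.
#' @export
metrics_report <- function(cv, p_value = NULL) {
  pr <- cv$predictions
  met <- confusion_metrics(pr$pred, pr$truth)
  auc <- roc_auc(pr$decision, pr$truth)
  c(list(scheme = cv$scheme, scope = cv$scope), met, auc,
    list(p_value = p_value))
}

#' Median fold-weight importance and top discriminative connections
#'
#' Per edge, importance is the signed median across cross-validation folds of
#' the fold's SVM weight; edges are ranked by absolute importance
#' (deterministic tie-break: lower edge index first) and the top k extracted.
#' The alternative "abs_median" aggregation takes the median of absolute
#' fold weights instead.
#'
#' @param cv a \code{cv_result} fitted with \code{keep_weights = TRUE}.
#' @param index the \code{edge_index} of the feature space.
#' @param k number of top connections to report (default 30).
#' @param method "signed_median" (default) or "abs_median".
#' @return object of class \code{weight_report}: list with \code{importance}
#'   (per-edge numeric), \code{top} (data.frame rank, k, i, j, label_i,
#'   label_j, importance), \code{k}, \code{method}.
#' @export
aggregate_weights <- function(cv, index, k = 30,
                              method = c("signed_median", "abs_median")) {
  method <- match.arg(method)
  if (is.null(cv$fold_weights)) stop("cv_result has no fold weights")
  W <- cv$fold_weights
  stopifnot(ncol(W) == nrow(index))
  importance <- if (method == "signed_median") apply(W, 2, stats::median)
  else apply(abs(W), 2, stats::median)
  k <- min(k, length(importance))
  ord <- order(-abs(importance), seq_along(importance))[seq_len(k)]
  top <- data.frame(rank = seq_len(k), k = ord,
                    i = index$i[ord], j = index$j[ord],
                    label_i = index$label_i[ord], label_j = index$label_j[ord],
                    importance = importance[ord], stringsAsFactors = FALSE)
  structure(list(importance = importance, top = top, k = k, method = method),
            class = "weight_report")
}

#' Region frequency within the top discriminative connections
#'
#' Counts, per region, the number of incident top-k edges: the nodal degree
#' of the top-k subgraph. Counts sum to 2k.
#'
#' @param report a \code{weight_report}.
#' @param index the \code{edge_index}.
#' @return data.frame with region, label, frequency, sorted by decreasing
#'   frequency.
#' @export
region_frequency <- function(report, index) {
  stopifnot(inherits(report, "weight_report"), nrow(report$top) > 0)
  n <- attr(index, "n_regions")
  counts <- tabulate(c(report$top$i, report$top$j), nbins = n)
  labels <- unique(data.frame(region = c(index$i, index$j),
                              label = c(index$label_i, index$label_j)))
  labels <- labels[order(labels$region), ]
  out <- data.frame(region = seq_len(n), label = labels$label,
                    frequency = counts, stringsAsFactors = FALSE)
  out[order(-out$frequency, out$region), ]
}

#' Hyper-/hypo-connectivity direction of selected edges
#'
#' Compares group mean connectivity per edge on fisher-stage (pre-harmonized)
#' features: patients above controls is "hyper", below is "hypo", exact
#' equality is reported as "tie".
#'
#' @param table a \code{feature_table}; fisher stage expected (harmonized
#'   features no longer carry interpretable connectivity units; a warning is
#'   issued if supplied).
#' @param edges two-column matrix of region pairs (i < j) or vector of flat
#'   edge indices.
#' @return data.frame with k, i, j, mean_patient, mean_control, direction.
#' @export
direction_of_difference <- function(table, edges) {
  stopifnot(inherits(table, "feature_table"))
  if (table$stage != "fisher") {
    warning("direction computed on ", table$stage,
            "-stage features; fisher-stage connectivity is the intended input")
  }
  n <- attr(table$index, "n_regions")
  if (is.matrix(edges) || is.data.frame(edges)) {
    edges <- as.matrix(edges)
    kk <- edge_to_k(edges[, 1], edges[, 2], n)
  } else kk <- as.integer(edges)
  if (any(kk < 1 | kk > nrow(table$index))) stop("edge outside index")
  pat <- table$subjects$group == "patient"
  mp <- colMeans(table$features[pat, kk, drop = FALSE])
  mc <- colMeans(table$features[!pat, kk, drop = FALSE])
  data.frame(k = kk, i = table$index$i[kk], j = table$index$j[kk],
             mean_patient = mp, mean_control = mc,
             direction = ifelse(mp > mc, "hyper",
                                ifelse(mp < mc, "hypo", "tie")),
             stringsAsFactors = FALSE)
}

# Type-III two-factor ANOVA engine shared by the per-connection and scalar
# variants. Effects (sum-to-zero) coding; each effect is tested by comparing
# the full model against the model with that effect's columns removed.
.factorial_anova_engine <- function(Y, group, site) {
  group <- factor(group)
  site <- factor(site)
  if (nlevels(group) < 2 || nlevels(site) < 2) stop("need >= 2 levels per factor")
  if (any(table(group, site) == 0)) stop("empty group x site cell")
  Y <- as.matrix(Y)
  X <- stats::model.matrix(~ group * site,
                           contrasts.arg = list(group = "contr.sum",
                                                site = "contr.sum"))
  assign <- attr(X, "assign")
  qr_full <- qr(X)
  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  df_res <- nrow(X) - qr_full$rank
  effects <- c(group = 1L, site = 2L, interaction = 3L)
  out <- lapply(names(effects), function(e) {
    drop <- assign == effects[[e]]
    qr_red <- qr(X[, !drop, drop = FALSE])
    rss_red <- colSums(qr.resid(qr_red, Y)^2)
    df1 <- sum(drop)
    Fstat <- ((rss_red - rss_full) / df1) / (rss_full / df_res)
    p <- stats::pf(Fstat, df1, df_res, lower.tail = FALSE)
    list(F = Fstat, p = p, df1 = df1)
  })
  names(out) <- names(effects)
  out$df_res <- df_res
  out
}

#' Connection-wise two-factor ANOVA with FDR correction
#'
#' Per feature column, a type-III two-factor ANOVA (group, site, interaction
#' under effects coding); p-values are Benjamini-Hochberg adjusted per effect
#' family across all features. Used as the harmonization diagnostic: counts
#' of FDR-significant site effects should collapse to the false-positive
#' scale after per-site Z-scoring while true group effects persist.
#'
#' @param table a \code{feature_table}, or a plain subjects x features matrix.
#' @param group,site factor vectors (taken from the table when omitted).
#' @param alpha FDR level (default 0.05).
#' @return object of class \code{anova_report}: list with \code{stats}
#'   (data.frame of per-feature F/p/p_adj for each effect), \code{n_significant}
#'   (named counts at \code{alpha} after FDR), \code{alpha}.
#' @export
connectionwise_anova <- function(table, group = NULL, site = NULL, alpha = 0.05) {
  if (inherits(table, "feature_table")) {
    Y <- table$features
    if (is.null(group)) group <- table$subjects$group
    if (is.null(site)) site <- table$subjects$site
  } else Y <- as.matrix(table)
  res <- .factorial_anova_engine(Y, group, site)
  stats_df <- data.frame(
    feature = seq_len(ncol(Y)),
    F_group = res$group$F, p_group = res$group$p,
    p_adj_group = stats::p.adjust(res$group$p, "BH"),
    F_site = res$site$F, p_site = res$site$p,
    p_adj_site = stats::p.adjust(res$site$p, "BH"),
    F_interaction = res$interaction$F, p_interaction = res$interaction$p,
    p_adj_interaction = stats::p.adjust(res$interaction$p, "BH")
  )
  structure(list(
    stats = stats_df,
    n_significant = c(group = sum(stats_df$p_adj_group < alpha),
                      site = sum(stats_df$p_adj_site < alpha),
                      interaction = sum(stats_df$p_adj_interaction < alpha)),
    alpha = alpha
  ), class = "anova_report")
}

#' Scalar type-III factorial ANOVA (group x site)
#'
#' Type-III sums of squares under effects coding, used for scalar per-subject
#' diagnostics such as mean framewise displacement or age. Constant input is
#' reported as a degenerate no-variance case rather than an error.
#'
#' @param values numeric vector, one value per subject.
#' @param group,site factor vectors.
#' @return data.frame with effect, df, F, p (all NA with a "no variance"
#'   message attribute when the input is constant).
#' @export
scalar_factorial_anova <- function(values, group, site) {
  if (stats::var(values) == 0) {
    out <- data.frame(effect = c("group", "site", "interaction"),
                      df = NA_integer_, F = NA_real_, p = NA_real_)
    attr(out, "note") <- "no variance in response"
    return(out)
  }
  res <- .factorial_anova_engine(matrix(values, ncol = 1), group, site)
  data.frame(effect = c("group", "site", "interaction"),
             df = c(res$group$df1, res$site$df1, res$interaction$df1),
             F = c(res$group$F, res$site$F, res$interaction$F),
             p = c(res$group$p, res$site$p, res$interaction$p))
}

#' Logistic regression of classification correctness on clinical covariates
#'
#' Fits one binomial GLM per covariate plus one combined model, predicting
#' whether a subject was classified correctly. Rows with missing covariates
#' are removed listwise per model (glm's default NA handling). Complete
#' separation or non-convergence is flagged, not raised; covariates constant
#' across subjects yield an undefined (NA) coefficient and are flagged.
#'
#' @param correct logical (or 0/1) vector: subject classified correctly.
#' @param covariates data.frame of covariates (e.g. anxiety, depression,
#'   medication, severity); factors/characters allowed.
#' @return object of class \code{confounder_report}: named list of models,
#'   each with \code{coefficients} (term, estimate, se, z, p), \code{n_used},
#'   \code{converged}, \code{flags}.
#' @export
confounder_logistic <- function(correct, covariates) {
  correct <- as.logical(correct)
  stopifnot(length(correct) == nrow(covariates))
  fit_one <- function(df) {
    keep <- stats::complete.cases(df) & !is.na(correct)
    n_used <- sum(keep)
    if (n_used < 10) {
      return(list(coefficients = NULL, n_used = n_used, converged = FALSE,
                  flags = "fewer than 10 usable rows"))
    }
    dat <- cbind(correct = correct[keep], df[keep, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(correct ~ ., data = dat,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    flags <- character(0)
    if (!fit$converged) flags <- c(flags, "did not converge")
    mu <- stats::fitted(fit)
    if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
      flags <- c(flags, "possible complete separation")
    }
    aliased <- setdiff(names(stats::coef(fit))[is.na(stats::coef(fit))], "")
    if (length(aliased)) {
      flags <- c(flags, paste("undefined coefficient:",
                              paste(aliased, collapse = ", ")))
    }
    list(coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                   se = co[, 2], z = co[, 3], p = co[, 4],
                                   row.names = NULL),
         n_used = n_used,
         converged = fit$converged && !length(flags),
         flags = if (length(flags)) flags else NA_character_)
  }
  models <- lapply(names(covariates), function(v) fit_one(covariates[v]))
  names(models) <- names(covariates)
  models$combined <- fit_one(covariates)
  structure(models, class = "confounder_report")
}
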