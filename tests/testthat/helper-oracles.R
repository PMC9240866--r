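# Independent oracles used by the tests; these never call the code paths
# they check.

# Brute-force soft-margin SVM via the dual quadratic program (kernlab::ipop).
svm_qp_oracle <- function(x, y, C = 1) {
  x <- as.matrix(x)
  yy <- ifelse(y == "patient", 1, -1)
  n <- nrow(x)
  H <- (yy %o% yy) * tcrossprod(x) + diag(1e-10, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(yy, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 9,
                       maxiter = 200)
  a <- kernlab::primal(sol)
  w <- drop(t(x) %*% (a * yy))
  sv <- which(a > 1e-6 & a < C - 1e-6)
  b <- if (length(sv)) {
    mean(yy[sv] - x[sv, , drop = FALSE] %*% w)
  } else {
    -(max((x %*% w)[yy == -1]) + min((x %*% w)[yy == 1])) / 2
  }
  list(weights = w, bias = b)
}

# Trapezoidal ROC-curve integration, independent of the pairwise-count AUC.
auc_trapezoid_oracle <- function(decision, truth) {
  pat <- truth == "patient"
  thr <- sort(unique(decision), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(decision[pat] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(decision[!pat] >= t), numeric(1))
  tpr <- c(0, tpr, 1)
  fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Feature table with pure-noise features and balanced labels (one site).
make_null_table <- function(n = 16, n_regions = 10, seed = 1, site = "A") {
  idx <- edge_index(n_regions)
  with_seed(seed, {
    x <- matrix(rnorm(n * nrow(idx)), n, nrow(idx))
    subj <- data.frame(subject_id = sprintf("%s%03d", site, seq_len(n)),
                       site = site,
                       group = rep(c("patient", "control"), n / 2),
                       stringsAsFactors = FALSE)
    feature_table(x, subj, idx, stage = "fisher")
  })
}
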