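test_that("identical fold weights aggregate to themselves; median resists outliers", {
  idx <- edge_index(5)
  w <- seq(-1, 0.8, length.out = 10)
  W <- matrix(w, 9, 10, byrow = TRUE)
  rep1 <- aggregate_weights(fake_cv(W), idx, k = 3)
  expect_equal(rep1$importance, w)
  W2 <- rbind(W, 100 * w)  # one wild fold among nine identical ones
  rep2 <- aggregate_weights(fake_cv(W2), idx, k = 3)
  expect_equal(rep2$importance, w)
  # ranking is by absolute importance, ties broken toward lower edge index
  expect_equal(rep1$top$k[1], which.max(abs(w)))
  Wt <- matrix(c(0.5, -0.5, 0.1, rep(0, 7)), 3, 10, byrow = TRUE)
  rept <- aggregate_weights(fake_cv(Wt), idx, k = 2)
  expect_equal(rept$top$k, c(1L, 2L))
  expect_error(aggregate_weights(fake_cv(NULL), idx), "no fold weights")
})

test_that("abs-median aggregation is available as the alternative", {
  idx <- edge_index(4)
  W <- rbind(c(1, -1, 0, 0, 0, 0), c(-1, -1, 0, 0, 0, 0), c(1, -1, 0, 0, 0, 0))
  r <- aggregate_weights(fake_cv(W), idx, k = 2, method = "abs_median")
  expect_equal(r$importance[1:2], c(1, 1))
})

test_that("weight report is invariant to subject (fold) ordering", {
  idx <- edge_index(5)
  set.seed(3)
  W <- matrix(rnorm(80), 8, 10)
  r1 <- aggregate_weights(fake_cv(W), idx, k = 4)
  r2 <- aggregate_weights(fake_cv(W[sample(8), ]), idx, k = 4)
  expect_equal(r1$importance, r2$importance)
  expect_equal(r1$top, r2$top)
})

test_that("region frequency is the nodal degree of the top-k subgraph", {
  idx <- edge_index(6)
  star_k <- edge_to_k(c(1, 1, 1), c(2, 3, 4), 6)
  W <- matrix(0, 3, nrow(idx))
  W[, star_k] <- 1
  rep_star <- aggregate_weights(fake_cv(W), idx, k = 3)
  freq <- region_frequency(rep_star, idx)
  expect_equal(freq$frequency[freq$region == 1], 3)
  expect_equal(freq$frequency[freq$region %in% 2:4], rep(1, 3))
  expect_equal(sum(freq$frequency), 2 * 3)  # handshake identity
  # chain 1-2, 2-3, 3-4 has max degree 2, star has 3
  chain_k <- edge_to_k(c(1, 2, 3), c(2, 3, 4), 6)
  Wc <- matrix(0, 3, nrow(idx)); Wc[, chain_k] <- 1
  freq_c <- region_frequency(aggregate_weights(fake_cv(Wc), idx, k = 3), idx)
  expect_equal(max(freq_c$frequency), 2)
  expect_gt(max(freq$frequency), max(freq_c$frequency))
})

test_that("hyper/hypo direction compares group means with an explicit tie rule", {
  ft <- make_null_table(n = 10, n_regions = 4, seed = 2)
  pat <- ft$subjects$group == "patient"
  ft$features[pat, 2] <- ft$features[!pat, 2] + 0.2
  ft$features[pat, 3] <- ft$features[!pat, 3] - 0.2
  ft$features[, 4] <- 1
  d <- direction_of_difference(ft, rbind(c(1, 3), c(1, 4), c(2, 3)))
  expect_equal(d$direction, c("hyper", "hypo", "tie"))
  expect_equal(d$mean_patient[1] - d$mean_control[1], 0.2, tolerance = 1e-12)
  expect_error(direction_of_difference(ft, 99), "outside index")
  ftn <- suppressWarnings(site_normalize(ft))  # column 4 is constant
  expect_warning(direction_of_difference(ftn, 1), "fisher-stage")
})

test_that("scalar type-III ANOVA matches car::Anova and type-I on balanced designs", {
  set.seed(6)
  n <- 40
  group <- rep(c("patient", "control"), each = n / 2)
  site <- rep(rep(c("A", "B"), each = n / 4), 2)
  y <- rnorm(n) + ifelse(site == "B", 1.5, 0)
  ours <- scalar_factorial_anova(y, group, site)
  fit <- lm(y ~ g * s, data = data.frame(y = y, g = factor(group), s = factor(site)),
            contrasts = list(g = "contr.sum", s = "contr.sum"))
  ca <- car::Anova(fit, type = 3)
  expect_equal(ours$F, ca$`F value`[2:4], tolerance = 1e-10)
  expect_equal(ours$p, ca$`Pr(>F)`[2:4], tolerance = 1e-10)
  # balanced design: type I agrees
  t1 <- anova(lm(y ~ factor(group) * factor(site)))
  expect_equal(ours$F, t1$`F value`[1:3], tolerance = 1e-10)
  # site-shifted means: site significant, group not
  expect_lt(ours$p[ours$effect == "site"], 0.01)
  expect_gt(ours$p[ours$effect == "group"], 0.05)
})

test_that("scalar ANOVA handles degenerate inputs", {
  out <- scalar_factorial_anova(rep(3, 20), rep(c("a", "b"), 10),
                                rep(c("x", "y"), each = 10))
  expect_true(all(is.na(out$F)))
  expect_equal(attr(out, "note"), "no variance in response")
  expect_error(scalar_factorial_anova(rnorm(10), rep("a", 10), rep(c("x", "y"), 5)),
               ">= 2 levels")
  expect_error(
    scalar_factorial_anova(rnorm(12), c(rep("a", 6), rep("b", 6)),
                           c(rep("x", 6), rep("y", 6))), "empty")
})

test_that("connection-wise ANOVA under the null keeps FDR counts near zero", {
  set.seed(8)
  n <- 48
  Y <- matrix(rnorm(n * 500), n, 500)
  group <- rep(c("patient", "control"), n / 2)
  site <- rep(c("A", "B", "C", "D"), each = n / 4)
  rep0 <- connectionwise_anova(Y, group, site)
  expect_lte(sum(rep0$n_significant), 3)
})

test_that("injected group effects are detected and site offsets vanish after normalization", {
  st <- build_small_study(n_regions = 12, n_pairs = 10, n_edges = 5,
                          delta = 0.5, seed = 19)
  truth_k <- edge_to_k(st$truth$edges[, 1], st$truth$edges[, 2], 12)
  pre <- connectionwise_anova(st$fisher)
  post <- connectionwise_anova(st$normalized)
  expect_gt(pre$n_significant["site"], 5)
  expect_lte(post$n_significant["site"], 2)
  expect_gte(sum(post$stats$p_adj_group[truth_k] < 0.05), 4)
})

test_that("confounder logistic regression: listwise deletion, flags, calibration", {
  set.seed(9)
  n <- 100
  cov <- data.frame(anxiety = rnorm(n, 60, 15), depression = rnorm(n, 10, 5))
  cov$anxiety[1:20] <- NA  # 20% missing
  correct <- runif(n) < 0.7
  rep1 <- confounder_logistic(correct, cov)
  expect_equal(rep1$anxiety$n_used, 80)
  expect_equal(rep1$depression$n_used, 100)
  expect_equal(rep1$combined$n_used, 80)
  # constant covariate -> undefined coefficient, flagged
  rep2 <- confounder_logistic(correct, data.frame(sev = rep(2, n)))
  expect_true(any(grepl("undefined coefficient", rep2$sev$flags)))
  # complete separation flagged, not an error
  sep <- data.frame(x = ifelse(correct, 10, -10))
  rep3 <- confounder_logistic(correct, sep)
  expect_false(rep3$x$converged)
  # too few rows flagged
  rep4 <- confounder_logistic(correct[1:5], data.frame(x = rnorm(5)))
  expect_equal(rep4$x$flags, "fewer than 10 usable rows")
})

test_that("null covariates reject near the nominal rate", {
  set.seed(10)
  ps <- replicate(100, {
    correct <- runif(200) < 0.6
    x <- rnorm(200)
    r <- confounder_logistic(correct, data.frame(x = x))
    r$x$coefficients$p[r$x$coefficients$term == "x"]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
})
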