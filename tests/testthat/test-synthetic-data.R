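two_site_config <- function(n_pairs = 3, seed = 1, ...) {
  sites <- list(site_profile("A", n_volumes = 60, noise_sd = 0.3),
                site_profile("B", n_volumes = 80, noise_sd = 0.5))
  cohort_config(n_regions = 10, sites = sites, n_pairs_per_site = n_pairs,
                seed = seed, ...)
}

test_that("cohort counts are forced by the configuration", {
  co <- simulate_cohort(two_site_config(3))
  m <- co$manifest
  expect_equal(nrow(m), 12)
  expect_equal(as.integer(table(m$site)), c(6L, 6L))
  expect_equal(as.integer(table(m$site, m$group)[, "patient"]), c(3L, 3L))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_cohort(two_site_config(4, seed = 7))
  b <- simulate_cohort(two_site_config(4, seed = 7))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$subject_seeds, b$subject_seeds)
  s1 <- simulate_study(two_site_config(2, seed = 7))
  s2 <- simulate_study(two_site_config(2, seed = 7))
  expect_identical(s1$panels, s2$panels)
  expect_identical(s1$motion, s2$motion)
})

test_that("matched pairs are intact: one control per patient, same site, age-matched", {
  co <- simulate_cohort(two_site_config(5, seed = 3))
  m <- co$manifest
  for (pid in unique(m$pair_id)) {
    pr <- m[m$pair_id == pid, ]
    expect_equal(nrow(pr), 2)
    expect_setequal(pr$group, c("patient", "control"))
    expect_equal(length(unique(pr$site)), 1)
    expect_equal(length(unique(pr$sex)), 1)
    expect_lte(abs(diff(pr$age)), 2)
  }
})

test_that("covariate missingness matches the configured rate", {
  cm <- default_covariate_model()
  cm$anxiety$missing <- 0.2
  cfg <- two_site_config(250, seed = 5, covariate_model = cm)
  co <- simulate_cohort(cfg)
  expect_equal(mean(is.na(co$manifest$anxiety)), 0.2, tolerance = 0.2)
  expect_lt(abs(mean(is.na(co$manifest$anxiety)) - 0.2), 0.04)
})

test_that("effect edges must be valid for the region count", {
  eff <- effect_spec(rbind(c(1, 50)), delta = 0.5)
  expect_error(cohort_config(n_regions = 10,
                             sites = list(site_profile("A", n_volumes = 60)),
                             n_pairs_per_site = 2, effect = eff, seed = 1),
               "beyond n_regions")
  expect_error(effect_spec(rbind(c(1, 2), c(1, 2)), delta = 1), "duplicate")
  expect_error(effect_spec(rbind(c(3, 2)), delta = 1))
})

test_that("latent covariance: no effect and no mixing give identical groups and sites", {
  base <- make_base_loadings(12, 4, seed = 2)
  s1 <- site_profile("A", n_volumes = 60, mixing_strength = 0)
  s2 <- site_profile("B", n_volumes = 60, mixing_strength = 0)
  cp <- latent_covariance("patient", s1, NULL, base)
  cc <- latent_covariance("control", s2, NULL, base)
  expect_equal(cp, cc)
})

test_that("a positive delta raises the patient covariance on exactly that edge", {
  base <- make_base_loadings(12, 4, seed = 2)
  site <- site_profile("A", n_volumes = 60, mixing_strength = 0)
  eff <- effect_spec(rbind(c(3, 8)), delta = 0.6)
  cp <- latent_covariance("patient", site, eff, base)
  cc <- latent_covariance("control", site, eff, base)
  expect_equal(cp[3, 8] - cc[3, 8], 0.6)
  # off-effect off-diagonal entries untouched
  off <- upper.tri(cp) & !(row(cp) == 3 & col(cp) == 8)
  expect_equal(cp[off], cc[off])
  # negative delta lowers it
  effn <- effect_spec(rbind(c(3, 8)), delta = -0.4)
  cpn <- latent_covariance("patient", site, effn, base)
  expect_equal(cpn[3, 8] - cc[3, 8], -0.4)
})

test_that("latent covariance is PSD by construction for any mixing", {
  base <- make_base_loadings(15, 5, seed = 4)
  for (mix in c(0, 0.5, 1)) {
    site <- site_profile("X", n_volumes = 60, mixing_strength = mix)
    eff <- effect_spec(rbind(c(1, 2), c(4, 9)), delta = c(0.8, -0.5))
    cv <- latent_covariance("patient", site, eff, base, psi = 0.2)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(cv, t(cv))
  }
})

test_that("site rotations are orthogonal and strength-0 is the identity", {
  R <- site_rotation(20, 0.7, seed = 9)
  expect_equal(crossprod(R), diag(20), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(R, diag(20))))
  expect_identical(site_rotation(20, 0, seed = 9), diag(20))
})

test_that("panel dimensions follow the site profile (300-volume site)", {
  site <- site_profile("III", tr = 2, n_volumes = 300)
  base <- make_base_loadings(10, 4, seed = 1)
  rec <- list(subject_id = "III_P01", site = "III", group = "patient")
  sub <- simulate_subject(rec, site, NULL, base, seed = 5)
  expect_equal(dim(sub$panel$values), c(10, 300))
  expect_equal(nrow(sub$motion), 300)
  expect_equal(nrow(sub$nuisance), 300)
  expect_error(simulate_subject(rec, site_profile("IV", n_volumes = 225),
                                NULL, base, seed = 5), "belongs to site")
})

test_that("empirical covariance converges to the latent covariance", {
  # ar 0, identity affine, no observation noise, long panel
  site <- site_profile("A", n_volumes = 10000, noise_sd = 0, ar_coeff = 0)
  base <- make_base_loadings(6, 3, seed = 8)
  Sigma <- latent_covariance("control", site, NULL, base)
  rec <- list(subject_id = "A_C01", site = "A", group = "control")
  sub <- simulate_subject(rec, site, NULL, base, seed = 21)
  emp <- stats::cov(t(sub$panel$values))
  expect_equal(emp, Sigma, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("without spikes the framewise displacement stays below threshold", {
  site <- site_profile("A", n_volumes = 200)
  base <- make_base_loadings(5, 3, seed = 1)
  mm <- default_motion_model(spike_prob = 0)
  rec <- list(subject_id = "A_P01", site = "A", group = "patient")
  sub <- simulate_subject(rec, site, NULL, base, seed = 3, motion_model = mm)
  fd <- framewise_displacement(sub$motion)
  expect_lt(max(fd$fd), 0.5)
  # spikes of 0.8 mm produce analytic FD exceedances
  mm2 <- default_motion_model(spike_prob = 0.2, spike_mag = 0.8)
  sub2 <- simulate_subject(rec, site, NULL, base, seed = 3, motion_model = mm2)
  expect_gt(framewise_displacement(sub2$motion)$n_above, 0)
})

test_that("group effect is recoverable from Fisher-Z connectivity at large delta", {
  st <- build_small_study(n_regions = 12, n_pairs = 15, n_edges = 4,
                          delta = 0.8, seed = 17)
  truth_k <- edge_to_k(st$truth$edges[, 1], st$truth$edges[, 2], 12)
  pat <- st$fisher$subjects$group == "patient"
  for (e in seq_along(truth_k)) {
    diffmean <- mean(st$fisher$features[pat, truth_k[e]]) -
      mean(st$fisher$features[!pat, truth_k[e]])
    if (st$truth$direction[e] == "hyper") expect_gt(diffmean, 0)
    else expect_lt(diffmean, 0)
  }
})

test_that("mixing creates genuine site structure: site is predictable from features", {
  st <- build_small_study(n_regions = 15, n_pairs = 8, n_edges = 0,
                          delta = 0, mixing = c(0.3, 0.45, 0.6, 0.4), seed = 23)
  x <- st$fisher$features
  site <- factor(st$fisher$subjects$site)
  n <- nrow(x)
  test <- with_seed(1, sample(n, 16))
  m <- e1071::svm(x[-test, ], site[-test], kernel = "linear", cost = 1)
  acc <- mean(predict(m, x[test, ]) == site[test])
  expect_gt(acc, 0.5)  # chance is 0.25 with four sites
})
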