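# Shared small-cohort builders. Simulation -> preprocessing -> features for a
# 4-site study at reduced region count, used by the integration-level tests.

small_effect <- function(n_regions, n_edges, delta, seed) {
  idx <- edge_index(n_regions)
  with_seed(seed, {
    ek <- sample(nrow(idx), n_edges)
    effect_spec(cbind(idx$i[ek], idx$j[ek]),
                delta = delta * sample(c(1, -1), n_edges, replace = TRUE))
  })
}

# Full pipeline on a simulated study; returns fisher + harmonized tables and
# the ground truth. "mixing" selects the non-harmonizable site-effect
# condition; delta the latent group effect per truth edge.
build_small_study <- function(n_regions = 30, n_pairs = 10, n_edges = 10,
                              delta = 0.25, mixing = c(0, 0, 0, 0),
                              seed = 11) {
  eff <- small_effect(n_regions, n_edges, delta, seed)
  cfg <- cohort_config(n_regions = n_regions,
                       sites = default_site_profiles(mixing = mixing),
                       n_pairs_per_site = n_pairs, effect = eff, seed = seed)
  study <- simulate_study(cfg)
  ids <- study$manifest$subject_id
  panels <- lapply(stats::setNames(ids, ids), function(id) {
    preprocess_panel(study$panels[[id]], study$motion[[id]],
                     study$nuisance[[id]])
  })
  fisher <- compute_features(panels, study$manifest)
  list(fisher = fisher, normalized = site_normalize(fisher),
       truth = study$truth, manifest = study$manifest, config = cfg)
}

cv_accuracy <- function(cv) mean(cv$predictions$pred == cv$predictions$truth)

# Minimal cv_result wrapper around a given fold-weight matrix, for post-hoc
# aggregation tests.
fake_cv <- function(W, scope = NULL) {
  structure(list(scheme = "pooled", scope = scope,
                 predictions = data.frame(), fold_weights = W),
            class = "cv_result")
}
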