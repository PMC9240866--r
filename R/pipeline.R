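# End-to-end orchestration of the validation experiments on a simulated
# cohort: simulate -> motion QC -> matched-pair pruning -> preprocessing ->
# featurization -> site harmonization -> cross-validation scheme(s) ->
# metrics, optional permutation test, and discriminative-connection post-hocs.

#' Experiment run configuration
#'
#' @param cohort a \code{cohort_config} describing the simulated study.
#' @param preproc a \code{preproc_config}.
#' @param schemes subset of c("intra", "pooled", "inter", "learning_curve"),
#'   or "all".
#' @param normalization "full" (site statistics over each full site, as the
#'   harmonization is defined) or "strict" (recomputed from training rows in
#'   every fold).
#' @param n_permutations permutations for the pooled-scheme significance test
#'   (0 disables it).
#' @param top_k top connections in the weight report.
#' @param C SVM cost.
#' @param out_dir output directory for serialized artifacts, or NULL to skip
#'   writing.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_config(),
                       preproc = preproc_config(),
                       schemes = "all",
                       normalization = c("full", "strict"),
                       n_permutations = 0,
                       top_k = 30, C = 1, out_dir = NULL) {
  normalization <- match.arg(normalization)
  all_schemes <- c("intra", "pooled", "inter", "learning_curve")
  if (identical(schemes, "all")) schemes <- all_schemes
  stopifnot(all(schemes %in% all_schemes))
  structure(list(cohort = cohort, preproc = preproc, schemes = schemes,
                 normalization = normalization,
                 n_permutations = n_permutations,
                 top_k = top_k, C = C, out_dir = out_dir),
            class = "run_config")
}

#' Run a full simulated multi-site classification experiment
#'
#' Executes the configured stages and (when \code{out_dir} is set) writes the
#' manifest, QC report, feature table, per-scheme prediction tables and
#' metrics, the weight report with BrainNet-style exports, and a
#' machine-readable run log echoing configuration and seeds. Deterministic
#' given \code{config$cohort$seed}.
#'
#' @param config a \code{run_config}.
#' @return report bundle: list with manifest, qc, ledger, features (fisher
#'   and normalized), per-scheme \code{cv_result}s and metrics, optional
#'   permutation result, weight report and edge directions.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study <- simulate_study(config$cohort)
  manifest <- study$manifest

  qc <- qc_cohort(study$motion, config$preproc)
  bad <- qc$subject_id[qc$decision == "exclude"]
  manifest$excluded[manifest$subject_id %in% bad] <- "yes"
  manifest$exclusion_reason[manifest$subject_id %in% bad] <- "motion"
  pruned <- prune_matched_pairs(manifest)
  keep_ids <- pruned$manifest$subject_id
  if (length(keep_ids) < 8) stop("stage prune: fewer than 8 subjects remain")

  panels <- lapply(stats::setNames(keep_ids, keep_ids), function(id) {
    tryCatch(
      preprocess_panel(study$panels[[id]], study$motion[[id]],
                       study$nuisance[[id]], config$preproc),
      error = function(e) stop("stage preprocess, subject ", id, ": ",
                               conditionMessage(e))
    )
  })
  fisher <- compute_features(panels, pruned$manifest)
  normalized <- site_normalize(fisher)
  cv_table <- if (config$normalization == "full") normalized else fisher
  strict <- if (config$normalization == "strict") "strict" else "none"

  results <- list()
  metrics <- list()
  if ("intra" %in% config$schemes) {
    for (s in unique(cv_table$subjects$site)) {
      cv <- loo_cv(cv_table, scope = s, C = config$C, normalize = strict)
      results[[paste0("intra_", s)]] <- cv
      metrics[[paste0("intra_", s)]] <- metrics_report(cv)
    }
  }
  if ("pooled" %in% config$schemes) {
    cv <- loo_cv(cv_table, C = config$C, normalize = strict)
    results$pooled <- cv
    metrics$pooled <- metrics_report(cv)
  }
  if ("inter" %in% config$schemes) {
    for (cv in loso_cv(cv_table, C = config$C, normalize = strict)) {
      results[[paste0("inter_", cv$scope)]] <- cv
      metrics[[paste0("inter_", cv$scope)]] <- metrics_report(cv)
    }
  }
  curves <- list()
  if ("learning_curve" %in% config$schemes) {
    for (s in unique(cv_table$subjects$site)) {
      curves[[s]] <- transfer_learning_curve(cv_table, s,
                                             seed = config$cohort$seed,
                                             C = config$C)
    }
  }
  perm <- NULL
  if (config$n_permutations > 0 && "pooled" %in% config$schemes) {
    perm <- permutation_test(cv_table, "pooled",
                             n_permutations = config$n_permutations,
                             seed = config$cohort$seed, C = config$C,
                             normalize = strict)
    metrics$pooled$p_value <- perm$p_value
  }

  weights <- NULL
  directions <- NULL
  if (!is.null(results$pooled)) {
    weights <- aggregate_weights(results$pooled, fisher$index, k = config$top_k)
    directions <- direction_of_difference(fisher, weights$top$k)
  }

  bundle <- list(manifest = pruned$manifest, qc = qc, ledger = pruned$ledger,
                 truth = study$truth, fisher = fisher, normalized = normalized,
                 results = results, metrics = metrics, curves = curves,
                 permutation = perm, weights = weights,
                 directions = directions, config = config)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config)
  invisible(bundle)
}

.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  write_manifest(bundle$manifest, p("manifest.csv"))
  utils::write.csv(bundle$qc, p("qc_report.csv"), row.names = FALSE, na = "NA")
  write_features(bundle$normalized, p("features.csv"))
  for (nm in names(bundle$results)) {
    utils::write.csv(bundle$results[[nm]]$predictions,
                     p(paste0("predictions_", nm, ".csv")), row.names = FALSE)
  }
  for (nm in names(bundle$curves)) {
    utils::write.csv(bundle$curves[[nm]],
                     p(paste0("learning_curve_", nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(bundle$metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  if (!is.null(bundle$weights)) {
    top <- bundle$weights$top
    top$direction <- bundle$directions$direction
    utils::write.csv(top, p("weight_report.csv"), row.names = FALSE)
    export_brainnet(bundle$weights, bundle$fisher$index,
                    p("top_connections.node"), p("top_connections.edge"))
  }
  log <- list(
    seed = config$cohort$seed,
    normalization = config$normalization,
    schemes = config$schemes,
    n_subjects_initial = bundle$ledger$n_initial,
    n_subjects_final = bundle$ledger$n_remaining,
    n_partner_removed = bundle$ledger$n_partner_removed,
    n_features = ncol(bundle$fisher$features),
    n_permutations = config$n_permutations,
    C = config$C,
    package_version = as.character(utils::packageVersion("multisitefc"))
  )
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
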