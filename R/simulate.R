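# Synthetic multi-site cohort simulator.
#
# Generative model: a shared factor model for region signals. Controls draw
# from Sigma = (R L)(R L)' + psi*I where L are base factor loadings and R a
# site-specific rotation; patients get extra rank-1 loading columns that
# raise/lower the latent covariance on a configured set of edges. Two site
# effect families are exposed:
#   * per-site observation noise / signal units ("affine" family) -- shifts
#     every correlation of a site in a site-deterministic way and is removed
#     by per-site connection-wise Z-scoring;
#   * loading rotation ("mixing" family, mixing_strength > 0) -- relocates
#     covariance structure (including the group effect) onto different edges
#     per site, which no per-edge harmonization can undo.

#' Run code under a temporary RNG seed
#'
#' Evaluates \code{expr} with the RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so seeded sub-draws do not perturb an
#' enclosing simulation stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Site acquisition/effect profile
#'
#' Describes one centre: acquisition timing plus the site-effect parameters
#' of the generative model.
#'
#' @param site_id short site label.
#' @param tr repetition time in seconds (> 0).
#' @param n_volumes number of volumes (>= 30).
#' @param affine_offset per-region additive signal offset (scalar or length
#'   n_regions; arbitrary units).
#' @param affine_scale per-region positive multiplicative gain.
#' @param mixing_strength scalar in [0, 1]; 0 means no loading rotation,
#'   larger values rotate the latent factor loadings further, creating site
#'   structure that per-edge harmonization cannot remove.
#' @param noise_sd positive observation-noise SD; differing values across
#'   sites attenuate correlations differently (a harmonizable site effect).
#' @param ar_coeff temporal AR(1) coefficient in [0, 0.95].
#' @param rotation_seed integer seed for the site rotation; defaults to a
#'   deterministic hash of \code{site_id}.
#' @return object of class \code{site_profile}.
#' @export
site_profile <- function(site_id, tr = 2, n_volumes = 150,
                         affine_offset = 0, affine_scale = 1,
                         mixing_strength = 0, noise_sd = 0.5,
                         ar_coeff = 0.3, rotation_seed = NULL) {
  stopifnot(tr > 0, n_volumes >= 30,
            all(affine_scale > 0),
            mixing_strength >= 0, mixing_strength <= 1,
            noise_sd > 0 || noise_sd == 0,
            ar_coeff >= 0, ar_coeff <= 0.95)
  if (is.null(rotation_seed)) {
    rotation_seed <- (sum(utf8ToInt(as.character(site_id))) * 131L) %% 100000L
  }
  structure(list(site_id = as.character(site_id), tr = tr,
                 n_volumes = as.integer(n_volumes),
                 affine_offset = affine_offset, affine_scale = affine_scale,
                 mixing_strength = mixing_strength, noise_sd = noise_sd,
                 ar_coeff = ar_coeff, rotation_seed = as.integer(rotation_seed)),
            class = "site_profile")
}

#' Four-centre default site profiles
#'
#' The default acquisition geometry mirrors a four-centre 3T study: all sites
#' at TR = 2 s with 150, 150, 300 and 225 volumes. Noise levels and signal
#' units differ across sites (harmonizable effects); \code{mixing} sets the
#' per-site rotation strengths (non-harmonizable effects).
#'
#' @param mixing numeric length-4 vector of mixing strengths (default all 0).
#' @param noise_sd numeric length-4 vector of observation-noise SDs.
#' @return list of four \code{site_profile} objects named I-IV.
#' @export
default_site_profiles <- function(mixing = c(0, 0, 0, 0),
                                  noise_sd = c(0.3, 0.7, 1.1, 0.9)) {
  vols <- c(150L, 150L, 300L, 225L)
  offs <- c(0, 30, -20, 50)
  scl <- c(1, 1.4, 0.8, 1.2)
  ids <- c("I", "II", "III", "IV")
  lapply(1:4, function(s) {
    site_profile(ids[s], tr = 2, n_volumes = vols[s],
                 affine_offset = offs[s], affine_scale = scl[s],
                 mixing_strength = mixing[s], noise_sd = noise_sd[s])
  })
}

#' Ground-truth group effect on a set of edges
#'
#' @param edges two-column matrix (or data.frame) of 1-based region pairs
#'   with i < j; no duplicates.
#' @param delta signed latent-coupling increment per edge (scalar recycled
#'   or per-edge vector). Positive delta makes the receiving group
#'   hyper-connected on that edge.
#' @param group which group receives the increment ("patient" or "control").
#' @return object of class \code{effect_spec}.
#' @export
effect_spec <- function(edges, delta, group = "patient") {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  stopifnot(ncol(edges) == 2, all(edges[, 1] < edges[, 2]),
            group %in% c("patient", "control"))
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges in effect_spec")
  delta <- rep_len(delta, nrow(edges))
  structure(list(edges = edges, delta = delta, group = group),
            class = "effect_spec")
}

#' Default patient/control covariate model
#'
#' Group-wise means/SDs for anxiety and depression questionnaire scores, a
#' medication-intake probability, an ordinal 0-5 severity score (patients
#' only), and per-covariate missingness fractions, loosely patterned on a
#' mixed FND cohort (anxious, mildly depressed patients, roughly half
#' medicated, mostly mild-to-moderate severity).
#'
#' @return named list consumed by \code{\link{simulate_cohort}}.
#' @export
default_covariate_model <- function() {
  list(
    anxiety = list(patient = c(mean = 75, sd = 20), control = c(mean = 63, sd = 18),
                   missing = 0.17),
    depression = list(patient = c(mean = 12, sd = 8), control = c(mean = 7, sd = 5),
                      missing = 0.09),
    medication = list(patient = 0.45, control = 0.08, missing = 0.05),
    severity = list(patient = c(mean = 2, sd = 1), missing = 0.02)
  )
}

#' Default head-motion model
#'
#' Mean-reverting random walk on 6 rigid-body parameters with occasional
#' translation spike steps. Step SDs give typical framewise displacement
#' well below the 0.5 mm threshold; each spike contributes an analytic FD of
#' \code{spike_mag} mm at its volume.
#'
#' @param step_sd_trans translation step SD in mm.
#' @param step_sd_rot rotation step SD in radians.
#' @param spike_prob per-volume probability of a translation spike.
#' @param spike_mag spike step magnitude in mm.
#' @param ar mean-reversion coefficient of the walk.
#' @return named list.
#' @export
default_motion_model <- function(step_sd_trans = 0.02, step_sd_rot = 2e-4,
                                 spike_prob = 0.02, spike_mag = 0.8, ar = 0.95) {
  list(step_sd_trans = step_sd_trans, step_sd_rot = step_sd_rot,
       spike_prob = spike_prob, spike_mag = spike_mag, ar = ar)
}

#' Cohort simulation configuration
#'
#' @param n_regions number of atlas regions (default 88).
#' @param sites list of \code{site_profile}s.
#' @param n_pairs_per_site patients (= controls) per site; scalar or one
#'   value per site; each >= 2. Default 23, 24, 24, 15 for the four default
#'   sites (a 172-scan cohort).
#' @param effect an \code{effect_spec}, or NULL for a no-effect cohort.
#' @param n_factors latent factor count (default \code{max(4, n_regions %/% 6)}).
#' @param psi diagonal noise added to the latent covariance.
#' @param age_range, in years, ages sampled uniformly.
#' @param sex_ratio probability that a pair is female (FND cohorts are
#'   female-predominant; default 0.72).
#' @param matching_tolerance maximum patient/control age difference within a
#'   pair, years.
#' @param covariate_model see \code{\link{default_covariate_model}}.
#' @param motion_model see \code{\link{default_motion_model}}.
#' @param seed integer RNG seed; recorded in the output.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_regions = 88,
                          sites = default_site_profiles(),
                          n_pairs_per_site = c(23, 24, 24, 15),
                          effect = NULL,
                          n_factors = NULL, psi = 0.4,
                          age_range = c(18, 65), sex_ratio = 0.72,
                          matching_tolerance = 2,
                          covariate_model = default_covariate_model(),
                          motion_model = default_motion_model(),
                          seed = 1) {
  stopifnot(n_regions >= 2, length(sites) >= 1,
            all(vapply(sites, inherits, TRUE, "site_profile")))
  n_pairs_per_site <- rep_len(as.integer(n_pairs_per_site), length(sites))
  if (any(n_pairs_per_site < 2)) stop("need at least 2 pairs per site")
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "effect_spec"))
    if (any(effect$edges > n_regions)) {
      stop("effect_spec contains region indices beyond n_regions = ", n_regions)
    }
  }
  if (is.null(n_factors)) n_factors <- max(4L, n_regions %/% 6L)
  structure(list(n_regions = as.integer(n_regions), sites = sites,
                 n_pairs_per_site = n_pairs_per_site, effect = effect,
                 n_factors = as.integer(n_factors), psi = psi,
                 age_range = age_range, sex_ratio = sex_ratio,
                 matching_tolerance = matching_tolerance,
                 covariate_model = covariate_model,
                 motion_model = motion_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Site-specific orthogonal rotation
#'
#' Composes seeded random Givens (plane) rotations whose angles scale with
#' \code{strength}, giving a smooth path from the identity (strength 0) to a
#' thorough mixing of region coordinates (strength 1). Exactly orthogonal by
#' construction.
#'
#' @param p dimension.
#' @param strength scalar in [0, 1].
#' @param seed integer seed; the plane pairs and base angles are functions of
#'   the seed only, so the same site stays on one rotation path as strength
#'   varies.
#' @return p x p orthogonal matrix.
#' @export
site_rotation <- function(p, strength, seed) {
  R <- diag(p)
  if (strength == 0 || p < 2) return(R)
  with_seed(seed, {
    nrot <- 3L * p
    a <- sample.int(p, nrot, replace = TRUE)
    b <- sample.int(p - 1L, nrot, replace = TRUE)
    b <- ifelse(b >= a, b + 1L, b)
    theta <- strength * stats::runif(nrot, pi / 4, pi / 2)
    for (r in seq_len(nrot)) {
      ct <- cos(theta[r]); st <- sin(theta[r])
      ra <- R[a[r], ]; rb <- R[b[r], ]
      R[a[r], ] <- ct * ra - st * rb
      R[b[r], ] <- st * ra + ct * rb
    }
  })
  R
}

#' Base factor loadings for the cohort
#'
#' @param n_regions region count.
#' @param n_factors latent factor count.
#' @param seed integer seed.
#' @return n_regions x n_factors matrix with unit-scale row variances.
#' @export
make_base_loadings <- function(n_regions, n_factors, seed) {
  with_seed(seed, matrix(stats::rnorm(n_regions * n_factors, sd = 1 / sqrt(n_factors)),
                         n_regions, n_factors))
}

#' Latent region covariance for one group at one site
#'
#' Builds the covariance as loadings x loadings' + psi*I, guaranteeing
#' positive semidefiniteness. The receiving group of the effect gets one
#' extra rank-1 loading column per effect edge (sqrt(|delta|) at region i,
#' sign(delta)*sqrt(|delta|) at region j), so group covariances differ only
#' on/through the configured edges. The site rotation is applied to all
#' loadings before the outer product.
#'
#' @param group "patient" or "control".
#' @param site a \code{site_profile}.
#' @param effect an \code{effect_spec} or NULL.
#' @param base base loading matrix (full column rank).
#' @param psi diagonal noise variance (> 0).
#' @return symmetric positive-definite matrix.
#' @export
latent_covariance <- function(group, site, effect, base, psi = 0.4) {
  p <- nrow(base)
  L <- base
  if (!is.null(effect) && identical(group, effect$group)) {
    extra <- matrix(0, p, nrow(effect$edges))
    for (e in seq_len(nrow(effect$edges))) {
      d <- effect$delta[e]
      extra[effect$edges[e, 1], e] <- sqrt(abs(d))
      extra[effect$edges[e, 2], e] <- sign(d) * sqrt(abs(d))
    }
    L <- cbind(L, extra)
  }
  if (site$mixing_strength > 0) {
    L <- site_rotation(p, site$mixing_strength, site$rotation_seed) %*% L
  }
  tcrossprod(L) + diag(psi, p)
}

#' Simulate the cohort manifest and ground truth
#'
#' Draws per-site balanced patient/control pairs with matched age and sex,
#' samples clinical covariates with configured missingness ("NA" sentinel on
#' disk), and returns the ground truth needed to score downstream recovery:
#' effect edges with expected hyper/hypo direction plus the per-site rotation
#' parameters.
#'
#' @param config a \code{cohort_config}.
#' @return list with elements \code{manifest} (data.frame, one row per
#'   subject), \code{truth} (list: edges, delta, direction, group, sites,
#'   seed), and \code{subject_seeds} (integer vector aligned with manifest
#'   rows, used by \code{\link{simulate_study}}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cm <- config$covariate_model
  rows <- list()
  with_seed(config$seed, {
    for (s in seq_along(config$sites)) {
      site <- config$sites[[s]]
      np <- config$n_pairs_per_site[s]
      for (pr in seq_len(np)) {
        pair_id <- sprintf("%s_pair%02d", site$site_id, pr)
        age_p <- round(stats::runif(1, config$age_range[1], config$age_range[2]), 1)
        age_c <- round(min(max(age_p + stats::runif(1, -config$matching_tolerance,
                                                    config$matching_tolerance),
                               config$age_range[1]), config$age_range[2]), 1)
        sex <- if (stats::runif(1) < config$sex_ratio) "F" else "M"
        for (grp in c("patient", "control")) {
          g <- grp
          anx <- stats::rnorm(1, cm$anxiety[[g]]["mean"], cm$anxiety[[g]]["sd"])
          dep <- stats::rnorm(1, cm$depression[[g]]["mean"], cm$depression[[g]]["sd"])
          med <- if (stats::runif(1) < cm$medication[[g]]) "yes" else "no"
          sev <- if (g == "patient") {
            min(max(round(stats::rnorm(1, cm$severity$patient["mean"],
                                       cm$severity$patient["sd"])), 0), 5)
          } else NA_real_
          if (stats::runif(1) < cm$anxiety$missing) anx <- NA_real_
          if (stats::runif(1) < cm$depression$missing) dep <- NA_real_
          if (stats::runif(1) < cm$medication$missing) med <- NA_character_
          if (g == "patient" && stats::runif(1) < cm$severity$missing) sev <- NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sprintf("%s_%s%02d", site$site_id,
                                 if (g == "patient") "P" else "C", pr),
            site = site$site_id, group = g, pair_id = pair_id,
            age = if (g == "patient") age_p else age_c, sex = sex,
            anxiety = round(anx, 1), depression = round(dep, 1),
            medication = med, severity = sev,
            excluded = "no", exclusion_reason = NA_character_,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    manifest <- do.call(rbind, rows)
    subject_seeds <- sample.int(.Machine$integer.max - 1L, nrow(manifest))
    eff <- config$effect
    truth <- list(
      edges = if (is.null(eff)) matrix(integer(0), 0, 2) else eff$edges,
      delta = if (is.null(eff)) numeric(0) else eff$delta,
      direction = if (is.null(eff)) character(0) else
        ifelse(eff$delta > 0, "hyper", "hypo"),
      group = if (is.null(eff)) NA_character_ else eff$group,
      sites = lapply(config$sites, function(st) list(
        site_id = st$site_id, mixing_strength = st$mixing_strength,
        rotation_seed = st$rotation_seed)),
      seed = config$seed
    )
    list(manifest = manifest, truth = truth, subject_seeds = subject_seeds)
  })
}

#' Simulate one subject's time-series, motion and nuisance signals
#'
#' Draws an AR(1)-filtered multivariate normal panel from the subject's
#' latent covariance, adds observation noise, and applies the site's
#' per-region affine offset/scale. The motion trace is a mean-reverting
#' random walk with optional translation spike steps; white-matter and CSF
#' nuisance traces are noisy mixtures of the global signal.
#'
#' @param record one manifest row (list or single-row data.frame).
#' @param site the subject's \code{site_profile}.
#' @param effect an \code{effect_spec} or NULL.
#' @param base base loading matrix.
#' @param seed integer seed for this subject.
#' @param psi diagonal latent noise variance.
#' @param motion_model see \code{\link{default_motion_model}}.
#' @return list with \code{panel} (a \code{ts_panel}), \code{motion}
#'   (data.frame tx,ty,tz,rx,ry,rz) and \code{nuisance} (data.frame wm,csf).
#' @export
simulate_subject <- function(record, site, effect, base, seed,
                             psi = 0.4, motion_model = default_motion_model()) {
  if (!identical(as.character(record$site), site$site_id)) {
    stop("record belongs to site ", record$site, ", not ", site$site_id)
  }
  p <- nrow(base)
  tt <- site$n_volumes
  Sigma <- latent_covariance(as.character(record$group), site, effect, base, psi)
  ch <- chol(Sigma)
  with_seed(seed, {
    x <- crossprod(ch, matrix(stats::rnorm(p * tt), p, tt))
    if (site$ar_coeff > 0) {
      a <- site$ar_coeff
      s <- sqrt(1 - a^2)
      y <- x
      for (t in 2:tt) y[, t] <- a * y[, t - 1] + s * x[, t]
      x <- y
    }
    if (site$noise_sd > 0) x <- x + site$noise_sd * matrix(stats::rnorm(p * tt), p, tt)
    vals <- rep_len(site$affine_scale, p) * x + rep_len(site$affine_offset, p)
    panel <- ts_panel(vals, tr = site$tr)

    mm <- motion_model
    steps <- cbind(matrix(stats::rnorm(tt * 3, sd = mm$step_sd_trans), tt, 3),
                   matrix(stats::rnorm(tt * 3, sd = mm$step_sd_rot), tt, 3))
    if (mm$spike_prob > 0) {
      hit <- which(stats::runif(tt) < mm$spike_prob)
      hit <- hit[hit > 1]
      steps[hit, 1] <- steps[hit, 1] + mm$spike_mag * sample(c(-1, 1), length(hit),
                                                             replace = TRUE)
    }
    mo <- matrix(0, tt, 6)
    mo[1, ] <- steps[1, ]
    for (t in 2:tt) mo[t, ] <- mm$ar * mo[t - 1, ] + steps[t, ]
    motion <- as.data.frame(mo)
    names(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

    glob <- colMeans(x)
    nuisance <- data.frame(
      wm = 0.5 * glob + stats::rnorm(tt, sd = 0.5),
      csf = 0.4 * glob + stats::rnorm(tt, sd = 0.6)
    )
    list(panel = panel, motion = motion, nuisance = nuisance)
  })
}

#' Simulate a full multi-site study in memory
#'
#' Convenience wrapper: manifest + truth from \code{\link{simulate_cohort}},
#' shared base loadings, then one call to \code{\link{simulate_subject}} per
#' subject with per-subject seeds drawn from the cohort stream. Deterministic
#' given \code{config$seed}.
#'
#' @param config a \code{cohort_config}.
#' @return list with \code{manifest}, \code{truth}, \code{base} (loadings),
#'   and per-subject lists \code{panels}, \code{motion}, \code{nuisance}
#'   named by subject id.
#' @export
simulate_study <- function(config) {
  co <- simulate_cohort(config)
  base <- make_base_loadings(config$n_regions, config$n_factors,
                             config$seed + 104729L)
  site_by_id <- stats::setNames(config$sites,
                                vapply(config$sites, `[[`, "", "site_id"))
  n <- nrow(co$manifest)
  panels <- motion <- nuisance <- vector("list", n)
  for (r in seq_len(n)) {
    rec <- co$manifest[r, ]
    sub <- simulate_subject(rec, site_by_id[[rec$site]], config$effect, base,
                            seed = co$subject_seeds[r], psi = config$psi,
                            motion_model = config$motion_model)
    panels[[r]] <- sub$panel
    motion[[r]] <- sub$motion
    nuisance[[r]] <- sub$nuisance
  }
  names(panels) <- names(motion) <- names(nuisance) <- co$manifest$subject_id
  list(manifest = co$manifest, truth = co$truth, base = base,
       panels = panels, motion = motion, nuisance = nuisance,
       config = config)
}
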