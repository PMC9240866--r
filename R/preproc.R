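# Time-series conditioning: motion QC by framewise displacement, subject
# exclusion, winsorization + linear detrending, temporal filtering, and
# nuisance regression. Fixed order when applied through preprocess_panel():
# FD/exclusion -> winsorize -> detrend -> filter -> nuisance regression.

#' Preprocessing configuration
#'
#' @param winsor_upper_percentile upper clip percentile in (50, 100);
#'   default 95.
#' @param winsor_two_sided if TRUE (default) also clip at the mirrored lower
#'   percentile; outlier spikes are signed, so symmetric clipping is the
#'   default reading of "winsorized to the 95th percentile".
#' @param filter_mode "bandpass" (zero-phase Butterworth) or "wavelet"
#'   (MODWT subband reconstruction).
#' @param band pass band in Hz, default c(0.01, 0.08); must lie below the
#'   Nyquist frequency 1/(2*tr).
#' @param fd_threshold framewise-displacement threshold in mm (default 0.5).
#' @param sphere_radius radius in mm used to convert rotations to arc
#'   displacement (default 50).
#' @param max_fd_fraction exclude a subject when the fraction of volumes
#'   with FD above threshold strictly exceeds this (default 0.25).
#' @param max_mean_fd exclude when mean FD strictly exceeds this (default
#'   Inf, i.e. rule disabled).
#' @return object of class \code{preproc_config}.
#' @export
preproc_config <- function(winsor_upper_percentile = 95,
                           winsor_two_sided = TRUE,
                           filter_mode = c("bandpass", "wavelet"),
                           band = c(0.01, 0.08),
                           fd_threshold = 0.5,
                           sphere_radius = 50,
                           max_fd_fraction = 0.25,
                           max_mean_fd = Inf) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(winsor_upper_percentile > 50, winsor_upper_percentile < 100,
            length(band) == 2, band[1] > 0, band[1] < band[2],
            fd_threshold > 0, sphere_radius > 0,
            max_fd_fraction > 0)
  structure(list(winsor_upper_percentile = winsor_upper_percentile,
                 winsor_two_sided = winsor_two_sided,
                 filter_mode = filter_mode, band = band,
                 fd_threshold = fd_threshold, sphere_radius = sphere_radius,
                 max_fd_fraction = max_fd_fraction, max_mean_fd = max_mean_fd),
            class = "preproc_config")
}

#' Framewise displacement (Power method)
#'
#' FD at volume t >= 2 is the sum of absolute backward differences of the
#' three translations (mm) plus \code{sphere_radius} times the sum of
#' absolute differences of the three rotations (radians), i.e. rotations are
#' converted to arc displacement on a reference sphere. FD of the first
#' volume is 0 by convention.
#'
#' @param motion data.frame or matrix with 6 columns (tx, ty, tz in mm;
#'   rx, ry, rz in radians), one row per volume.
#' @param sphere_radius sphere radius in mm (default 50).
#' @param threshold high-motion threshold in mm (default 0.5).
#' @return object of class \code{fd_summary}: list with \code{fd} (per-volume
#'   series), \code{mean_fd}, \code{n_above}, \code{threshold}.
#' @export
framewise_displacement <- function(motion, sphere_radius = 50, threshold = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 volumes to compute FD")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, mean_fd = mean(fd), n_above = sum(fd > threshold),
                 threshold = threshold),
            class = "fd_summary")
}

#' Motion-based subject exclusion decision
#'
#' Excludes when the fraction of volumes above the FD threshold strictly
#' exceeds \code{max_fd_fraction}, or the mean FD strictly exceeds
#' \code{max_mean_fd}. Values exactly at a limit keep the subject.
#'
#' @param summary an \code{fd_summary}.
#' @param max_fd_fraction maximum tolerated fraction of high-motion volumes.
#' @param max_mean_fd maximum tolerated mean FD in mm.
#' @return list with \code{keep} (logical) and \code{reason} ("motion" or NA).
#' @export
motion_exclude <- function(summary, max_fd_fraction = 0.25, max_mean_fd = Inf) {
  stopifnot(inherits(summary, "fd_summary"))
  frac <- summary$n_above / length(summary$fd)
  keep <- !(frac > max_fd_fraction || summary$mean_fd > max_mean_fd)
  list(keep = keep, reason = if (keep) NA_character_ else "motion")
}

#' Winsorize and linearly detrend each region's series
#'
#' Per region: values above the upper percentile are clipped to it (and, in
#' the default two-sided mode, values below the mirrored lower percentile are
#' clipped to that), then the least-squares line over time is removed --
#' slope and intercept -- leaving zero-mean rows. Constant rows come back as
#' all zeros.
#'
#' @param panel a \code{ts_panel} with >= 3 volumes.
#' @param winsor_upper_percentile upper percentile (default 95).
#' @param two_sided clip both tails (default TRUE).
#' @return a \code{ts_panel}.
#' @export
winsorize_detrend <- function(panel, winsor_upper_percentile = 95,
                              two_sided = TRUE) {
  stopifnot(inherits(panel, "ts_panel"), ncol(panel$values) >= 3)
  x <- panel$values
  tt <- ncol(x)
  tcen <- seq_len(tt) - (tt + 1) / 2
  sst <- sum(tcen^2)
  up <- winsor_upper_percentile / 100
  for (r in seq_len(nrow(x))) {
    row <- x[r, ]
    hi <- stats::quantile(row, up, names = FALSE, type = 7)
    row[row > hi] <- hi
    if (two_sided) {
      lo <- stats::quantile(x[r, ], 1 - up, names = FALSE, type = 7)
      row[row < lo] <- lo
    }
    slope <- sum(tcen * row) / sst
    x[r, ] <- row - mean(row) - slope * tcen
  }
  ts_panel(x, tr = panel$tr, region_labels = panel$region_labels)
}

#' Temporal filtering of a panel
#'
#' Bandpass mode applies a zero-phase (forward-backward) Butterworth bandpass
#' of the configured order; wavelet mode reconstructs the panel from the
#' maximal-overlap discrete wavelet transform detail levels whose nominal
#' frequency interval [1/(2^(j+1) tr), 1/(2^j tr)] overlaps the band.
#'
#' @param panel a \code{ts_panel}.
#' @param mode "bandpass" or "wavelet".
#' @param band pass band in Hz (default c(0.01, 0.08)).
#' @param order Butterworth order for bandpass mode (default 2).
#' @param wavelet wavelet filter name for wavelet mode (default "la8").
#' @return a \code{ts_panel}.
#' @export
temporal_filter <- function(panel, mode = c("bandpass", "wavelet"),
                            band = c(0.01, 0.08), order = 2, wavelet = "la8") {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "ts_panel"))
  nyq <- 1 / (2 * panel$tr)
  if (band[2] >= nyq) {
    stop("band upper edge ", band[2], " Hz is at/above Nyquist ", nyq, " Hz")
  }
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band")
  x <- panel$values
  if (mode == "bandpass") {
    bf <- signal::butter(order, band / nyq, type = "pass")
    for (r in seq_len(nrow(x))) {
      # demean first: DC carries no pass-band signal and inflates the
      # forward-backward transient of a narrow-band IIR filter
      x[r, ] <- signal::filtfilt(bf, x[r, ] - mean(x[r, ]))
    }
  } else {
    for (r in seq_len(nrow(x))) {
      x[r, ] <- modwt_subband(x[r, ], tr = panel$tr, band = band,
                              wavelet = wavelet)
    }
  }
  ts_panel(x, tr = panel$tr, region_labels = panel$region_labels)
}

#' Regress motion and tissue nuisance signals out of a panel
#'
#' Per region, removes the ordinary least-squares projection onto
#' [intercept, 6 motion parameters, white-matter signal, CSF signal].
#' Residuals are orthogonal to every regressor. Collinear regressor columns
#' are dropped with a warning.
#'
#' @param panel a \code{ts_panel}.
#' @param motion 6-column motion trace (rows = volumes).
#' @param nuisance data.frame/matrix with columns wm and csf.
#' @return a \code{ts_panel} of residuals.
#' @export
nuisance_regression <- function(panel, motion, nuisance) {
  stopifnot(inherits(panel, "ts_panel"))
  tt <- ncol(panel$values)
  motion <- as.matrix(motion)
  nuisance <- as.matrix(nuisance)
  if (nrow(motion) != tt || nrow(nuisance) != tt) {
    stop("regressor row counts (", nrow(motion), ", ", nrow(nuisance),
         ") do not match panel volume count (", tt, ")")
  }
  X <- cbind(intercept = 1, motion, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " collinear nuisance regressor(s)")
    qrX <- qr(X[, keep, drop = FALSE])
  }
  resid <- t(qr.resid(qrX, t(panel$values)))
  ts_panel(resid, tr = panel$tr, region_labels = panel$region_labels)
}

#' Full conditioning of one subject's panel
#'
#' Applies the fixed preprocessing order: winsorize + detrend, temporal
#' filter, nuisance regression. Motion QC is a separate upstream decision
#' (see \code{\link{qc_cohort}}).
#'
#' @param panel a \code{ts_panel}.
#' @param motion 6-column motion trace.
#' @param nuisance wm/csf data.frame.
#' @param config a \code{preproc_config}.
#' @return a conditioned \code{ts_panel}.
#' @export
preprocess_panel <- function(panel, motion, nuisance,
                             config = preproc_config()) {
  stopifnot(inherits(config, "preproc_config"))
  out <- winsorize_detrend(panel, config$winsor_upper_percentile,
                           config$winsor_two_sided)
  out <- temporal_filter(out, mode = config$filter_mode, band = config$band)
  nuisance_regression(out, motion, nuisance)
}

#' Motion QC over a cohort
#'
#' Computes the FD summary and exclusion decision for every subject.
#'
#' @param motion_list named list of motion traces (names = subject ids).
#' @param config a \code{preproc_config}.
#' @return data.frame with subject_id, mean_fd, n_above, n_volumes, decision
#'   ("keep"/"exclude"), reason.
#' @export
qc_cohort <- function(motion_list, config = preproc_config()) {
  rows <- lapply(names(motion_list), function(id) {
    fs <- framewise_displacement(motion_list[[id]],
                                 sphere_radius = config$sphere_radius,
                                 threshold = config$fd_threshold)
    dec <- motion_exclude(fs, config$max_fd_fraction, config$max_mean_fd)
    data.frame(subject_id = id, mean_fd = fs$mean_fd, n_above = fs$n_above,
               n_volumes = length(fs$fd),
               decision = if (dec$keep) "keep" else "exclude",
               reason = dec$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
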