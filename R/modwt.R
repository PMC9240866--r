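# Maximal-overlap discrete wavelet transform (MODWT), pyramid algorithm with
# circular boundary handling, plus multiresolution analysis (MRA) and the
# subband filter used as the wavelet alternative to bandpass filtering.
# Filters follow the usual convention: wavelet filter h_l = (-1)^l g_{L-1-l}
# from the scaling filter g, both divided by sqrt(2) at each level.

# Scaling filters. "la8" is the 8-tap least-asymmetric (symlet) filter,
# "d4" the 4-tap extremal-phase Daubechies filter.
.modwt_filters <- list(
  la8 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
          0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
          -0.01260396726203783, 0.03222310060404270),
  d4 = c(0.48296291314469025, 0.83651630373746899, 0.22414386804185735,
         -0.12940952255092145)
)

.modwt_gh <- function(wavelet) {
  g <- .modwt_filters[[wavelet]]
  if (is.null(g)) stop("unknown wavelet filter: ", wavelet)
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g / sqrt(2), h = h / sqrt(2))
}

.circ_lag <- function(x, s) {
  # x[t - s] with circular indexing, vectorized over t
  n <- length(x)
  x[((seq_len(n) - 1 - s) %% n) + 1]
}

#' Maximal-overlap discrete wavelet transform
#'
#' Non-decimated wavelet decomposition to \code{J} levels with circular
#' boundary treatment. Level j wavelet coefficients nominally cover the
#' frequency interval [1/(2^(j+1) dt), 1/(2^j dt)] for sampling interval dt.
#'
#' @param x numeric vector.
#' @param J decomposition depth; requires \code{2^J <= length(x)}.
#' @param wavelet "la8" (default) or "d4".
#' @return list with \code{W} (length(x) x J matrix of wavelet coefficients),
#'   \code{V} (level-J scaling coefficients), \code{J}, \code{wavelet}.
#' @export
modwt <- function(x, J, wavelet = "la8") {
  n <- length(x)
  if (2^J > n) stop("2^J exceeds series length")
  f <- .modwt_gh(wavelet)
  L <- length(f$g)
  W <- matrix(0, n, J)
  V <- x
  for (j in seq_len(J)) {
    step <- 2^(j - 1)
    Wj <- numeric(n)
    Vj <- numeric(n)
    for (l in 0:(L - 1)) {
      shifted <- .circ_lag(V, step * l)
      Wj <- Wj + f$h[l + 1] * shifted
      Vj <- Vj + f$g[l + 1] * shifted
    }
    W[, j] <- Wj
    V <- Vj
  }
  list(W = W, V = V, J = J, wavelet = wavelet)
}

#' Inverse maximal-overlap discrete wavelet transform
#'
#' @param decomp result of \code{\link{modwt}} (possibly with some
#'   coefficient sets zeroed).
#' @return numeric vector reconstructing the original series.
#' @export
imodwt <- function(decomp) {
  f <- .modwt_gh(decomp$wavelet)
  L <- length(f$g)
  n <- nrow(decomp$W)
  V <- decomp$V
  for (j in decomp$J:1) {
    step <- 2^(j - 1)
    Wj <- decomp$W[, j]
    Vprev <- numeric(n)
    for (l in 0:(L - 1)) {
      Vprev <- Vprev + f$h[l + 1] * .circ_lag(Wj, -step * l) +
        f$g[l + 1] * .circ_lag(V, -step * l)
    }
    V <- Vprev
  }
  V
}

#' MODWT multiresolution analysis
#'
#' Additive decomposition x = D_1 + ... + D_J + S_J, where detail D_j is the
#' reconstruction from level-j wavelet coefficients alone and S_J from the
#' level-J scaling coefficients alone.
#'
#' @param x numeric vector.
#' @param J decomposition depth.
#' @param wavelet filter name.
#' @return length(x) x (J+1) matrix with columns D1..DJ, SJ.
#' @export
modwt_mra <- function(x, J, wavelet = "la8") {
  dec <- modwt(x, J, wavelet)
  n <- length(x)
  out <- matrix(0, n, J + 1)
  zeroW <- matrix(0, n, J)
  for (j in seq_len(J)) {
    d <- dec
    d$W <- zeroW
    d$W[, j] <- dec$W[, j]
    d$V <- numeric(n)
    out[, j] <- imodwt(d)
  }
  d <- dec
  d$W <- zeroW
  out[, J + 1] <- imodwt(d)
  colnames(out) <- c(paste0("D", seq_len(J)), paste0("S", J))
  out
}

#' Wavelet subband filter
#'
#' Reconstructs a series from the MODWT detail levels whose nominal frequency
#' interval [1/(2^(j+1) tr), 1/(2^j tr)] overlaps the requested band, giving
#' a zero-phase subband approximation to a bandpass filter.
#'
#' @param x numeric vector.
#' @param tr sampling interval in seconds.
#' @param band numeric length-2 pass band in Hz.
#' @param wavelet filter name (default "la8").
#' @return filtered numeric vector (same length as x).
#' @export
modwt_subband <- function(x, tr, band = c(0.01, 0.08), wavelet = "la8") {
  if (band[2] >= 1 / (2 * tr)) stop("band upper edge at/above Nyquist")
  Jmax <- floor(log2(length(x)))
  lo <- 1 / (2^(seq_len(Jmax) + 1) * tr)
  hi <- 1 / (2^seq_len(Jmax) * tr)
  keep <- which(lo < band[2] & hi > band[1])
  if (length(keep) == 0) stop("no MODWT level overlaps the band ",
                              band[1], "-", band[2], " Hz at tr = ", tr)
  J <- max(keep)
  mra <- modwt_mra(x, J, wavelet)
  rowSums(mra[, keep, drop = FALSE])
}
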