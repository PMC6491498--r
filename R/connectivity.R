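# Quality-control exclusion and wavelet cross-correlation connectivity.

# Daubechies-4 scaling (g) and wavelet (h) filters, quadrature-mirror
# related: h_l = (-1)^l g_{L-1-l}.
d4Filters <- function() {
  s3 <- sqrt(3)
  g <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  h <- c(g[4], -g[3], g[2], -g[1])
  list(g = g, h = h)
}

# Circular MODWT pyramid up to level J: returns detail coefficients W_j
# (list) and the level-J smooth V_J. Filters are rescaled by 1/sqrt(2)
# per the maximal-overlap (non-decimated) convention; at level j the
# filter taps are spaced 2^(j-1) samples apart.
modwtPyramid <- function(x, J) {
  f <- d4Filters()
  gt <- f$g / sqrt(2)
  ht <- f$h / sqrt(2)
  n <- length(x)
  v <- x
  w <- vector("list", J)
  for (j in seq_len(J)) {
    offset <- 2^(j - 1)
    wj <- numeric(n)
    vj <- numeric(n)
    idx0 <- seq_len(n) - 1
    for (l in 0:3) {
      idx <- ((idx0 - offset * l) %% n) + 1
      wj <- wj + ht[l + 1] * v[idx]
      vj <- vj + gt[l + 1] * v[idx]
    }
    w[[j]] <- wj
    v <- vj
  }
  list(W = w, V = v)
}

# Number of boundary-affected MODWT coefficients at level j for a
# length-4 filter: L_j - 1 with L_j = (2^j - 1)(L - 1) + 1.
modwtBoundaryCount <- function(j, filterLength = 4L) {
  (2^j - 1) * (filterLength - 1)
}

#' Maximal-overlap discrete wavelet coefficients at one scale
#'
#' Computes MODWT (Daubechies-4) detail coefficients at scale `j` with a
#' reflection boundary: the series is extended by its mirror image, the
#' circular transform is applied, and the filter-width-dependent
#' boundary-affected leading coefficients are discarded.
#'
#' @param x numeric series.
#' @param j wavelet scale (>= 1); requires `length(x) >= 2^(j+1)`.
#' @return numeric vector of interior (boundary-free) coefficients.
#' @examples
#' w <- modwtCoefficients(sin(2 * pi * 0.1 * (1:256) * 2), 2)
#' length(w)
#' @export
modwtCoefficients <- function(x, j) {
  n <- length(x)
  if (n < 2^(j + 1))
    stop("series too short for scale ", j, ": need >= ", 2^(j + 1),
         " samples, got ", n)
  xe <- c(x, rev(x))
  p <- modwtPyramid(xe, j)
  w <- p$W[[j]][seq_len(n)]
  nb <- modwtBoundaryCount(j)
  if (nb >= n) stop("series too short for scale ", j)
  w[(nb + 1):n]
}

#' Per-scale wavelet variance
#'
#' Variance of MODWT detail coefficients (boundary coefficients dropped)
#' at scales 1..`maxScale`; the per-scale shares decompose the signal's
#' variance across dyadic frequency bands.
#'
#' @param x numeric series.
#' @param maxScale deepest scale to compute.
#' @return numeric vector of detail variances, one per scale.
#' @examples
#' v <- waveletVariance(rnorm(256), 4)
#' @export
waveletVariance <- function(x, maxScale = 4L) {
  vapply(seq_len(maxScale),
         function(j) stats::var(modwtCoefficients(x, j)), numeric(1))
}

#' Exclude subjects by motion spike percentage
#'
#' Partitions a subject table into retained and excluded sets using the
#' despiking spike-percentage quality metric: a subject is excluded iff
#' `spike_pct` is strictly greater than `thresholdPct` (study threshold:
#' 10%).
#'
#' @param subjects data.frame with columns `subject_id` and `spike_pct`.
#' @param thresholdPct exclusion threshold in percent.
#' @return list with data.frames `retained` and `excluded` (exhaustive,
#'   disjoint).
#' @examples
#' subs <- data.frame(subject_id = c("a", "b"), spike_pct = c(3, 12))
#' excludeBySpikePct(subs)$retained$subject_id
#' @export
excludeBySpikePct <- function(subjects, thresholdPct = 10) {
  if (!"spike_pct" %in% names(subjects))
    stop("subjects table has no spike_pct column")
  bad <- is.na(subjects$spike_pct)
  if (any(bad))
    stop("missing spike_pct for subject(s): ",
         paste(subjects$subject_id[bad], collapse = ", "))
  out <- subjects$spike_pct > thresholdPct
  list(retained = subjects[!out, , drop = FALSE],
       excluded = subjects[out, , drop = FALSE])
}

#' Select the wavelet scale best matching a target frequency band
#'
#' For sampling frequency fs = 1/TR, dyadic scale j covers
#' \[fs/2^(j+1), fs/2^j\] Hz. Returns the scale whose band has maximal
#' frequency overlap with the target band (study band 0.0675-0.125 Hz;
#' at TR = 2.2 s this selects scale 2). Scale selection is computed from
#' the TR rather than hard-coded because repetition times vary across
#' sites.
#'
#' @param trSeconds repetition time in seconds.
#' @param targetBand length-2 numeric, target band (Hz).
#' @param waveletFamily filter family (only `"d4"` implemented).
#' @param maxScale deepest scale considered.
#' @return a [WaveletBand].
#' @examples
#' selectWaveletScale(2.2)   # scale 2: 0.0568-0.1136 Hz
#' @export
selectWaveletScale <- function(trSeconds, targetBand = c(0.0675, 0.125),
                               waveletFamily = "d4", maxScale = 10L) {
  if (!(is.numeric(trSeconds) && length(trSeconds) == 1L &&
        is.finite(trSeconds) && trSeconds > 0))
    stop("tr_seconds (trSeconds) must be a positive number")
  stopifnot(length(targetBand) == 2L, targetBand[1] < targetBand[2])
  waveletFamily <- match.arg(waveletFamily)
  fs <- 1 / trSeconds
  nyquist <- fs / 2
  if (targetBand[1] >= nyquist)
    stop("target band (", targetBand[1], "-", targetBand[2],
         " Hz) lies entirely above the Nyquist frequency (",
         signif(nyquist, 4), " Hz)")
  overlap <- vapply(seq_len(maxScale), function(j) {
    lo <- fs / 2^(j + 1)
    hi <- fs / 2^j
    max(0, min(hi, targetBand[2]) - max(lo, targetBand[1]))
  }, numeric(1))
  j <- which.max(overlap)
  new("WaveletBand", scaleIndex = as.integer(j), fLow = fs / 2^(j + 1),
      fHigh = fs / 2^j, waveletFamily = waveletFamily)
}

#' Wavelet cross-correlation connectivity matrix
#'
#' Pearson correlation, for every region pair, of the MODWT detail
#' coefficients at the band's scale (boundary-affected coefficients
#' discarded). Constant (zero-variance) regional signals make the
#' correlation undefined and raise an error naming the offending
#' region(s) rather than silently producing NaN.
#'
#' @param ts a [ParcellatedTimeSeries].
#' @param band a [WaveletBand] (typically from [selectWaveletScale()]
#'   with the same TR).
#' @return a [ConnectivityMatrix].
#' @examples
#' band <- selectWaveletScale(2)
#' ts <- simulateBold(diag(5), 128, 2, band, seed = 2)
#' conn <- waveletCorrelationMatrix(ts, band)
#' @export
waveletCorrelationMatrix <- function(ts, band) {
  stopifnot(is(ts, "ParcellatedTimeSeries"), is(band, "WaveletBand"))
  sig <- ts@signal
  j <- band@scaleIndex
  coefs <- apply(sig, 1, modwtCoefficients, j = j)   # time' x regions
  sds <- apply(coefs, 2, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  if (length(degenerate))
    stop("constant (zero-variance) signal in region(s): ",
         paste(degenerate, collapse = ", "),
         "; wavelet correlation undefined")
  v <- stats::cor(coefs)
  v[v > 1] <- 1
  v[v < -1] <- -1
  v <- (v + t(v)) / 2
  diag(v) <- 1
  new("ConnectivityMatrix", subjectId = ts@subjectId, values = v)
}
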