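# Welch cross-spectral estimation, band power maps and seed-based
# magnitude-squared coherence maps.

#' Welch estimator parameters
#'
#' Defaults give 1 Hz resolution on the study's 600 Hz / 7000-sample series:
#' 600-sample Hann segments with 50% overlap (22 segments).
#'
#' @param segment_length segment length in samples.
#' @param overlap_fraction fractional overlap in `[0, 1)`.
#' @param window taper name; `"hann"` or `"rectangular"`.
#' @param sampling_rate sampling rate in Hz.
#' @return An object of class `welch_params`.
#' @export
welch_params <- function(segment_length = 600, overlap_fraction = 0.5,
                         window = c("hann", "rectangular"),
                         sampling_rate = 600) {
  window <- match.arg(window)
  stopifnot(segment_length >= 2, overlap_fraction >= 0, overlap_fraction < 1,
            sampling_rate > 0)
  structure(list(segment_length = as.integer(segment_length),
                 overlap_fraction = overlap_fraction, window = window,
                 sampling_rate = sampling_rate),
            class = "welch_params")
}

welch_window <- function(params) {
  n <- params$segment_length
  switch(params$window,
         hann = 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1))),
         rectangular = rep(1, n))
}

welch_starts <- function(n_samples, params) {
  seg <- params$segment_length
  if (n_samples < seg)
    stop("insufficient data: series of length ", n_samples,
         " is shorter than one Welch segment (", seg, ")")
  step <- max(1L, as.integer(round(seg * (1 - params$overlap_fraction))))
  seq.int(1L, n_samples - seg + 1L, by = step)
}

# Windowed segment FFTs for a time x series matrix.
# Returns only the one-sided bins: array [n_freq, n_seg, n_series], the bin
# centre frequencies, and the density scale 1 / (fs * sum(w^2)) (one-sided
# doubling is applied by callers per bin).
welch_seg_ffts <- function(X, params) {
  X <- as.matrix(X)
  n <- nrow(X)
  starts <- welch_starts(n, params)
  w <- welch_window(params)
  seg <- params$segment_length
  n_freq <- seg %/% 2 + 1L
  out <- array(0i, dim = c(n_freq, length(starts), ncol(X)))
  for (k in seq_along(starts)) {
    block <- X[starts[k] + seq_len(seg) - 1L, , drop = FALSE] * w
    out[, k, ] <- stats::mvfft(block)[seq_len(n_freq), , drop = FALSE]
  }
  freqs <- (seq_len(n_freq) - 1L) * params$sampling_rate / seg
  onesided <- rep(2, n_freq)
  onesided[1L] <- 1
  if (seg %% 2 == 0) onesided[n_freq] <- 1
  list(fft = out, freqs = freqs, n_seg = length(starts),
       scale = 1 / (params$sampling_rate * sum(w^2)), onesided = onesided)
}

band_bins <- function(freqs, band) {
  which(freqs >= band[1] & freqs <= band[2])
}

#' Welch cross-spectral density of two series
#'
#' Averages `Conj(FFT(x_seg)) * FFT(y_seg)` over windowed, overlapping
#' segments with one-sided density scaling, so `welch_cross_spectrum(x, x)`
#' is the Welch power spectral density of `x` (real, nonnegative) and
#' integrates to the series variance (Parseval).
#'
#' @param x,y numeric series of equal length.
#' @param params a [welch_params()].
#' @return Complex vector over one-sided frequency bins with attribute
#'   `freqs` (Hz).
#' @export
welch_cross_spectrum <- function(x, y, params = welch_params()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  sf <- welch_seg_ffts(cbind(x, y), params)
  cross <- rowMeans(Conj(sf$fft[, , 1, drop = FALSE]) *
                    sf$fft[, , 2, drop = FALSE], dims = 1)
  cross <- cross * sf$scale * sf$onesided
  if (identical(x, y)) cross <- complex(real = Re(cross))
  attr(cross, "freqs") <- sf$freqs
  cross
}

#' Band-averaged magnitude-squared coherence of two series
#'
#' Per frequency bin, `|<XY*>|^2 / (<|X|^2> <|Y|^2>)` with segment-averaged
#' spectra (the classical Welch MS coherence, bounded in `[0, 1]` bin-wise),
#' then the arithmetic mean over bins whose centre lies in `band`.
#'
#' @param x,y numeric series of equal length.
#' @param band `c(low, high)` in Hz.
#' @param params a [welch_params()].
#' @return Scalar in `[0, 1]`.
#' @export
ms_coherence <- function(x, y, band = c(9, 14), params = welch_params()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  sf <- welch_seg_ffts(cbind(x, y), params)
  bins <- band_bins(sf$freqs, band)
  if (!length(bins)) stop("no Welch bins fall inside the requested band")
  Fx <- sf$fft[bins, , 1, drop = FALSE]
  Fy <- sf$fft[bins, , 2, drop = FALSE]
  cross <- rowMeans(Conj(Fx) * Fy, dims = 1)
  px <- rowMeans(abs(Fx)^2, dims = 1)
  py <- rowMeans(abs(Fy)^2, dims = 1)
  if (any(px <= 0) || any(py <= 0))
    stop("undefined coherence: zero autospectrum inside the band")
  mean(pmin(1, abs(cross)^2 / (px * py)))
}

new_spectral_map <- function(values, kind, band, seed_vertex = NA_integer_,
                             excluded = integer(0)) {
  values[excluded] <- NA_real_
  structure(list(values = values, kind = kind, band = band,
                 seed_vertex = seed_vertex, excluded = excluded),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("spectral_map (%s, %g-%g Hz): %d vertices%s\n", x$kind,
              x$band[1], x$band[2], length(x$values),
              if (length(x$excluded))
                sprintf(", %d excluded", length(x$excluded)) else ""))
  invisible(x)
}

#' Band power map over source vertices
#'
#' Welch autospectral density per vertex, averaged over the bins of `band`
#' (9-14 Hz alpha band by default).
#'
#' @param estimated_sources sources x time matrix (e.g. from
#'   [apply_inverse()]).
#' @param band `c(low, high)` Hz.
#' @param params a [welch_params()].
#' @return A `spectral_map` of kind `"power"` (values >= 0).
#' @export
power_map <- function(estimated_sources, band = c(9, 14),
                      params = welch_params()) {
  sf <- welch_seg_ffts(t(estimated_sources), params)
  bins <- band_bins(sf$freqs, band)
  if (!length(bins)) stop("no Welch bins fall inside the requested band")
  p <- apply(abs(sf$fft[bins, , , drop = FALSE])^2, 3, mean) *
    sf$scale * mean(sf$onesided[bins])
  # mean over segments and bins per vertex; onesided factor is constant
  # inside any band excluding DC/Nyquist
  new_spectral_map(p, "power", band)
}

#' Seed-based coherence map over source vertices
#'
#' Band-averaged Welch magnitude-squared coherence of every vertex's series
#' against the series at `seed_vertex`.  Vertices in `excluded` (the
#' reference patch, in the study's usage) are marked non-evaluable (`NA`).
#'
#' @param estimated_sources sources x time matrix.
#' @param seed_vertex reference vertex index.
#' @param band `c(low, high)` Hz.
#' @param params a [welch_params()].
#' @param excluded integer vertex indices to mark non-evaluable.
#' @return A `spectral_map` of kind `"coherence"` (values in `[0, 1]`).
#' @export
coherence_map <- function(estimated_sources, seed_vertex, band = c(9, 14),
                          params = welch_params(), excluded = integer(0)) {
  n_src <- nrow(estimated_sources)
  stopifnot(seed_vertex >= 1, seed_vertex <= n_src)
  sf <- welch_seg_ffts(t(estimated_sources), params)
  bins <- band_bins(sf$freqs, band)
  if (!length(bins)) stop("no Welch bins fall inside the requested band")
  Fv <- sf$fft[bins, , , drop = FALSE]             # [bin, seg, vertex]
  Fs <- Fv[, , seed_vertex, drop = FALSE]          # [bin, seg, 1]
  ps <- rowMeans(abs(Fs)^2, dims = 1)
  if (any(ps <= 0))
    stop("undefined coherence: seed autospectrum is zero inside the band")
  vals <- vapply(seq_len(n_src), function(v) {
    cross <- rowMeans(Conj(Fs[, , 1, drop = FALSE]) *
                      Fv[, , v, drop = FALSE], dims = 1)
    pv <- rowMeans(abs(Fv[, , v, drop = FALSE])^2, dims = 1)
    if (any(pv <= 0)) return(0)
    mean(pmin(1, abs(cross)^2 / (ps * pv)))
  }, numeric(1))
  new_spectral_map(vals, "coherence", band, seed_vertex = seed_vertex,
                   excluded = excluded)
}

#' Export a spectral map as a tab-separated vertex/value table
#'
#' With `threshold_fraction` set (e.g. `0.2`), values are normalized to the
#' map maximum and zeroed below that fraction of the maximum, mirroring the
#' usual display convention for source maps.
#'
#' @param map a `spectral_map`.
#' @param path output file.
#' @param threshold_fraction optional fraction of the maximum below which
#'   normalized values are zeroed.
#' @export
write_map_table <- function(map, path, threshold_fraction = NULL) {
  vals <- map$values
  if (!is.null(threshold_fraction)) {
    m <- max(vals, na.rm = TRUE)
    vals <- vals / m
    vals[!is.na(vals) & vals < threshold_fraction] <- 0
  }
  df <- data.frame(vertex = seq_along(vals), value = vals)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
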