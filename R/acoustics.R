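as_samples <- function(waveform) {
  if (inherits(waveform, "waveform")) waveform$samples else as.numeric(waveform)
}
wave_rate <- function(waveform, sample_rate) {
  if (inherits(waveform, "waveform")) waveform$sample_rate else sample_rate
}

#' Power spectral density by the averaged-periodogram (Welch) method
#'
#' Hann-windowed overlapping segments, one-sided density normalized so that
#' the integral over frequency recovers the signal's mean power.
#'
#' @param waveform A `waveform` object from [synth_audio()] or a numeric
#'   vector (then supply `sample_rate`).
#' @param segment_length Samples per segment (default 1024).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param sample_rate Sampling rate in Hz when `waveform` is a bare vector.
#' @return Tibble with columns `frequency` (Hz, 0 to Nyquist) and `power`
#'   (density, power per Hz).
#' @export
psd_welch <- function(waveform, segment_length = 1024, overlap = 0.5,
                      sample_rate = NULL) {
  x <- as_samples(waveform)
  fs <- wave_rate(waveform, sample_rate)
  if (is.null(fs)) stop("sample_rate required for a bare numeric vector")
  n <- length(x)
  if (n < segment_length)
    stop("signal (", n, " samples) shorter than segment_length (",
         segment_length, ")")
  hop <- max(1L, round(segment_length * (1 - overlap)))
  starts <- seq(1L, n - segment_length + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(segment_length) - 1) /
                        (segment_length - 1)))  # Hann
  norm <- fs * sum(w^2)
  nfreq <- segment_length %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1)] * w
    P <- abs(fft(seg))^2 / norm
    P <- P[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist when present)
    dbl <- seq(2, nfreq - (segment_length %% 2 == 0))
    P[dbl] <- 2 * P[dbl]
    acc <- acc + P
  }
  tibble::tibble(frequency = (seq_len(nfreq) - 1) * fs / segment_length,
                 power = acc / length(starts))
}

#' Harmonics-to-noise ratio by windowed autocorrelation
#'
#' Frame-wise acoustic periodicity: each Hann-windowed frame's normalized
#' autocorrelation is divided by the window's own normalized
#' autocorrelation, and the maximum `r` over candidate lags (down to the
#' minimum fundamental `min_f0`) gives `HNR = 10 log10(r / (1 - r))` dB.
#' `r` is clipped away from 0 and 1 before the ratio. All-zero frames are
#' skipped.
#'
#' @param waveform A `waveform` object or numeric vector.
#' @param frame_length_s Frame length, seconds (default 0.04; must cover at
#'   least two periods of `min_f0`).
#' @param hop_s Hop between frames, seconds (default 0.01).
#' @param min_f0 Lowest fundamental considered, Hz (default 75).
#' @param sample_rate Sampling rate for bare vectors.
#' @return A list with `track` (tibble: `time`, `r`, `hnr_db`) and
#'   `max_hnr` (dB).
#' @export
hnr <- function(waveform, frame_length_s = 0.04, hop_s = 0.01, min_f0 = 75,
                sample_rate = NULL) {
  x <- as_samples(waveform)
  fs <- wave_rate(waveform, sample_rate)
  if (is.null(fs)) stop("sample_rate required for a bare numeric vector")
  flen <- round(frame_length_s * fs)
  if (flen < 2 * fs / min_f0)
    stop("frame must cover at least two periods of min_f0")
  hop <- max(1L, round(hop_s * fs))
  lag_max <- floor(fs / min_f0)
  lag_min <- 2L
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(flen) - 1) / (flen - 1)))
  # normalized autocorrelation of the window itself (for the Boersma
  # correction r_x = r_xw / r_w)
  nfft <- 2^ceiling(log2(2 * flen))
  acf_fft <- function(v) {
    sp <- fft(c(v, rep(0, nfft - flen)))
    ac <- Re(fft(Mod(sp)^2, inverse = TRUE)) / nfft
    ac / ac[1]
  }
  rw <- acf_fft(w)
  eps <- 1e-6
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  rows <- purrr::map(starts, function(s) {
    fr <- x[s:(s + flen - 1)]
    if (all(fr == 0)) return(NULL)
    fr <- (fr - mean(fr)) * w
    if (all(fr == 0)) return(NULL)
    rx <- acf_fft(fr)
    lags <- lag_min:lag_max
    r <- max(rx[lags + 1] / rw[lags + 1])
    r <- min(max(r, eps), 1 - eps)
    tibble::tibble(time = (s - 1 + flen / 2) / fs, r = r,
                   hnr_db = 10 * log10(r / (1 - r)))
  })
  track <- dplyr::bind_rows(rows)
  list(track = track,
       max_hnr = if (nrow(track)) max(track$hnr_db) else NA_real_)
}

#' Closed-form HNR of a correlation value
#'
#' `10 log10(r / (1 - r))`; 0 dB at `r = 0.5`.
#'
#' @param r Normalized autocorrelation peak in (0, 1).
#' @return HNR in dB.
#' @export
hnr_db <- function(r) 10 * log10(r / (1 - r))

#' Amplitude envelope of a waveform
#'
#' Magnitude of the analytic signal (Hilbert transform via FFT), smoothed
#' with a moving average of `smooth_ms` milliseconds and peak-normalized
#' to 1.
#'
#' @param waveform A `waveform` object or numeric vector.
#' @param smooth_ms Moving-average window, milliseconds (default 20).
#' @param sample_rate Sampling rate for bare vectors.
#' @return Tibble with columns `time` (s) and `amplitude` (max exactly 1).
#' @export
sound_envelope <- function(waveform, smooth_ms = 20, sample_rate = NULL) {
  if (smooth_ms <= 0) stop("smooth_ms must be > 0")
  x <- as_samples(waveform)
  fs <- wave_rate(waveform, sample_rate)
  if (is.null(fs)) stop("sample_rate required for a bare numeric vector")
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(fft(X * h, inverse = TRUE) / n)
  k <- max(1L, round(smooth_ms / 1000 * fs))
  if (k > 1) {
    # centered moving average via cumulative sums; windows are clipped (and
    # renormalized) at the edges
    half <- k %/% 2
    cs <- c(0, cumsum(env))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    env <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  env <- env / max(env)
  tibble::tibble(time = (seq_len(n) - 1) / fs, amplitude = env)
}

#' Attack time of an amplitude envelope
#'
#' Relative time (0 to 1) from sound onset to the first local maximum of
#' the normalized envelope with height at least `min_height`. If no local
#' maximum qualifies, the global maximum is used and the result flagged.
#'
#' @param envelope Tibble from [sound_envelope()] (columns `time`,
#'   `amplitude`, peak-normalized).
#' @param duration_s Sound duration, seconds (default: last envelope time).
#' @param min_height Minimum height of a qualifying peak (default 0.5).
#' @param window_s Half-width of the neighborhood a peak must dominate,
#'   seconds (default 0.05); guards against micro-wiggles of a smoothed
#'   noisy envelope being taken for peaks.
#' @return Relative attack time in `[0, 1]` with attribute `fallback`
#'   (TRUE if the global maximum was used).
#' @export
attack_time <- function(envelope, duration_s = NULL, min_height = 0.5,
                        window_s = 0.05) {
  a <- envelope$amplitude
  t <- envelope$time
  if (is.null(duration_s)) duration_s <- t[length(t)]
  n <- length(a)
  dt <- if (n > 1) t[2] - t[1] else 1
  w <- max(1L, round(window_s / dt))
  left <- c(-Inf, a[-n])
  right <- c(a[-1], -Inf)
  cand <- which(a >= left & a >= right & a >= min_height)
  t_star <- NA_real_
  for (i in cand) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    if (a[i] >= max(a[lo:hi])) { t_star <- t[i]; break }
  }
  if (is.na(t_star)) {
    t_star <- t[which.max(a)]
    fallback <- TRUE
  } else fallback <- FALSE
  structure(min(max(t_star / duration_s, 0), 1), fallback = fallback)
}

#' One-way ANOVA of an acoustic feature across sound categories
#'
#' Classical one-way fixed-effects ANOVA of a per-sound feature across the
#' four sound categories (9 sounds each gives df = (3, 32)), with
#' Benjamini-Hochberg-adjusted pairwise post-hoc t-tests.
#'
#' @param data Tibble with one row per sound.
#' @param value Name of the feature column (string).
#' @param category Name of the grouping column (string, default
#'   `"category"`).
#' @return A list with `anova` (tibble: `F`, `df1`, `df2`, `p`) and
#'   `posthoc` (tibble of pairwise comparisons with `p_adj`).
#' @export
category_feature_anova <- function(data, value, category = "category") {
  g <- split(data[[value]], data[[category]])
  an <- one_way_anova(g)
  ph <- pairwise.t.test(data[[value]], data[[category]],
                        p.adjust.method = "none", pool.sd = FALSE)
  pm <- ph$p.value
  posthoc <- tibble::tibble(
    group1 = rep(rownames(pm), ncol(pm)),
    group2 = rep(colnames(pm), each = nrow(pm)),
    p = as.vector(pm)
  )
  posthoc <- posthoc[!is.na(posthoc$p), , drop = FALSE]
  posthoc$p_adj <- p.adjust(posthoc$p, method = "BH")
  list(anova = an, posthoc = posthoc)
}

#' Write or read a mono PCM16 WAV file
#'
#' Minimal RIFF/WAVE support for the package's audio fixtures: 16-bit PCM,
#' single channel. Stereo files are averaged to mono on read.
#'
#' @param waveform A `waveform` object or numeric vector in `[-1, 1]`.
#' @param path File path.
#' @param sample_rate Sampling rate for bare vectors.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a
#'   `waveform` object.
#' @export
write_wav <- function(waveform, path, sample_rate = NULL) {
  x <- as_samples(waveform)
  fs <- wave_rate(waveform, sample_rate)
  if (is.null(fs)) stop("sample_rate required for a bare numeric vector")
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (riff != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; n_chan <- 1L; bits <- 16L; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      n_chan <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- len - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      if (bits != 16) stop("only 16-bit PCM supported")
      samples <- readBin(con, "integer", len / 2, size = 2,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", len))
    }
  }
  if (is.null(samples) || is.null(fs)) stop("malformed WAV file")
  x <- samples / 32767
  if (n_chan > 1) {
    x <- colMeans(matrix(x, nrow = n_chan))
  }
  structure(list(samples = x, sample_rate = fs, kind = "file",
                 duration_s = length(x) / fs), class = "waveform")
}
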