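#' Configuration of the synthetic voxel-pattern generator
#'
#' Captures the statistical structure the decoding pipeline assumes: each
#' category label at each tier of the taxonomy contributes a fixed,
#' participant-specific, unit-norm "prototype" pattern over voxels, scaled by
#' a per-tier amplitude; trials add run-level offsets and i.i.d. Gaussian
#' noise on top. With all amplitudes at zero the generator is
#' label-exchangeable, which is the basis of the permutation-test
#' calibration checks.
#'
#' @param n_participants Number of simulated participants (default 18, the
#'   study's sample size).
#' @param n_voxels Voxels per region of interest (default 80).
#' @param tier_amplitudes Named numeric vector of per-tier signal amplitudes
#'   (names among `superordinate`, `intermediate`, `subordinate`,
#'   `exemplar`); missing tiers default to 0.
#' @param noise_sd Trial-level Gaussian noise standard deviation (default 1).
#' @param run_offset_sd Standard deviation of the per-run additive offset
#'   pattern (default 0.2).
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 18, n_voxels = 80,
                             tier_amplitudes = c(superordinate = 0,
                                                 intermediate = 0,
                                                 subordinate = 0,
                                                 exemplar = 0),
                             noise_sd = 1, run_offset_sd = 0.2,
                             seed = 1L) {
  amp <- c(superordinate = 0, intermediate = 0, subordinate = 0, exemplar = 0)
  if (length(tier_amplitudes)) {
    bad <- setdiff(names(tier_amplitudes), names(amp))
    if (length(bad)) stop("unknown tier(s): ", paste(bad, collapse = ", "))
    amp[names(tier_amplitudes)] <- tier_amplitudes
  }
  if (any(amp < 0)) stop("tier amplitudes must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_voxels < 2) stop("n_voxels must be >= 2")
  structure(list(n_participants = as.integer(n_participants),
                 n_voxels = as.integer(n_voxels),
                 tier_amplitudes = amp, noise_sd = noise_sd,
                 run_offset_sd = run_offset_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

unit_vector <- function(n) {
  v <- rnorm(n)
  v / sqrt(sum(v^2))
}

#' Simulate event-wise voxel patterns for a cohort
#'
#' Draws, for each participant, one unit-norm prototype pattern per category
#' label per tier, then builds every sound trial's voxel vector as the
#' amplitude-weighted sum of its labels' prototypes plus a per-run offset
#' pattern and i.i.d. Gaussian noise. Patterns are mean-free and spatially
#' distributed, so category information is carried by the multivoxel pattern
#' rather than by the regional mean signal.
#'
#' @param config A [synthetic_config()].
#' @param schedule Trial schedule from [generate_schedule()].
#' @param tree Taxonomy from [build_taxonomy()].
#' @return A tibble with one row per participant x sound trial: columns
#'   `participant`, `run`, `trial`, `exemplar`, `subordinate`,
#'   `intermediate`, `superordinate`, and a matrix column `beta`
#'   (trials x voxels).
#' @examples
#' tree <- build_taxonomy()
#' sched <- generate_schedule(tree, seed = 1)
#' cfg <- synthetic_config(n_participants = 2, n_voxels = 10, seed = 1)
#' dat <- simulate_event_patterns(cfg, sched, tree)
#' dim(dat$beta)
#' @export
simulate_event_patterns <- function(config, schedule, tree) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_taxonomy(tree)
  snd <- schedule[schedule$kind == "sound", , drop = FALSE]
  labs <- tibble::tibble(
    exemplar = snd$exemplar,
    subordinate = labels_for_level(schedule, tree, "subordinate"),
    intermediate = labels_for_level(schedule, tree, "intermediate"),
    superordinate = labels_for_level(schedule, tree, "superordinate")
  )
  n_trials <- nrow(snd)
  nv <- config$n_voxels
  amp <- config$tier_amplitudes

  with_seed(config$seed, {
    parts <- purrr::map(seq_len(config$n_participants), function(p) {
      signal <- matrix(0, n_trials, nv)
      for (tier in tier_levels) {
        a <- amp[[tier]]
        lv <- unique(tree[[if (tier == "exemplar") "exemplar" else tier]])
        protos <- matrix(0, length(lv), nv,
                         dimnames = list(lv, NULL))
        for (l in lv) protos[l, ] <- unit_vector(nv)
        if (a > 0) signal <- signal + a * protos[labs[[tier]], , drop = FALSE]
      }
      runs <- sort(unique(snd$run))
      offs <- matrix(rnorm(length(runs) * nv, sd = config$run_offset_sd),
                     length(runs), nv, dimnames = list(runs, NULL))
      beta <- signal + offs[as.character(snd$run), , drop = FALSE] +
        matrix(rnorm(n_trials * nv, sd = config$noise_sd), n_trials, nv)
      out <- tibble::tibble(participant = p, run = snd$run, trial = snd$trial)
      out <- dplyr::bind_cols(out, labs)
      out$beta <- unname(beta)
      out
    })
    dplyr::bind_rows(parts)
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma BOLD impulse response (response peak near 5 s,
#' undershoot near 15 s), evaluated at times `t` in seconds.
#'
#' @param t Numeric vector of times (s).
#' @return Numeric vector of the same length, zero for `t < 0`.
#' @export
hrf_double_gamma <- function(t) {
  h <- ifelse(t < 0, 0,
              stats::dgamma(t, shape = 6, rate = 1) -
                stats::dgamma(t, shape = 16, rate = 1) / 6)
  h
}

#' Simulate BOLD time series from event betas
#'
#' Builds, per participant and run, a voxel time series as the design-matrix
#' product of the event regressors (event boxcar convolved with the
#' hemodynamic response, sampled at the repetition time) with that run's
#' event betas, plus AR(1) Gaussian noise. Used to exercise the beta
#' estimator end-to-end.
#'
#' @param dataset Event-pattern tibble from [simulate_event_patterns()].
#' @param schedule The schedule the dataset was generated from.
#' @param tr_s Repetition time, seconds (default 2.0).
#' @param hrf Hemodynamic response kernel function of time in seconds.
#' @param ar1_coeff AR(1) coefficient of the noise, `|ar1_coeff| < 1`.
#' @param noise_sd Innovation standard deviation of the noise.
#' @param pad_s Seconds of rest appended after the last event so its
#'   response is sampled (default 16).
#' @param seed Integer seed.
#' @return A tibble with one row per participant x run: columns
#'   `participant`, `run`, `n_timepoints`, and a list column `timeseries`
#'   of timepoint x voxel matrices.
#' @export
simulate_timeseries <- function(dataset, schedule, tr_s = 2.0,
                                hrf = hrf_double_gamma, ar1_coeff = 0.3,
                                noise_sd = 1, pad_s = 16, seed = 1L) {
  if (abs(ar1_coeff) >= 1) stop("|ar1_coeff| must be < 1")
  if (tr_s <= 0) stop("tr_s must be > 0")
  with_seed(seed, {
    out <- dataset |>
      dplyr::group_by(.data$participant, .data$run) |>
      dplyr::group_map(function(df, key) {
        run_sched <- schedule[schedule$kind == "sound" &
                                schedule$run == key$run, , drop = FALSE]
        stopifnot(nrow(run_sched) == nrow(df))
        n_tp <- ceiling((max(run_sched$onset_s + run_sched$duration_s) +
                           pad_s) / tr_s)
        X <- build_design(run_sched, hrf = hrf, tr_s = tr_s,
                          n_timepoints = n_tp, drift_order = 0)
        ev <- attr(X, "event_cols")
        signal <- X[, ev, drop = FALSE] %*% df$beta
        noise <- matrix(0, n_tp, ncol(df$beta))
        innov <- matrix(rnorm(n_tp * ncol(df$beta), sd = noise_sd),
                        n_tp, ncol(df$beta))
        noise[1, ] <- innov[1, ] / sqrt(1 - ar1_coeff^2)
        for (i in seq_len(n_tp)[-1])
          noise[i, ] <- ar1_coeff * noise[i - 1, ] + innov[i, ]
        tibble::tibble(participant = key$participant, run = key$run,
                       n_timepoints = n_tp,
                       timeseries = list(signal + noise))
      }, .keep = TRUE) |>
      dplyr::bind_rows()
    out
  })
}

#' Synthesize a test waveform
#'
#' Builds simple audio fixtures for the acoustic-feature module: `harmonic`
#' is a sum of harmonics of `f0` (optionally mixed with noise via
#' `harmonicity`), `noise` is white noise, and `am_noise` is white noise
#' under an amplitude envelope whose first peak sits at
#' `attack_frac * duration_s`. All waveforms are peak-normalized to 1 and
#' shaped by a short onset ramp except `am_noise`, whose envelope is the
#' point of the fixture.
#'
#' @param kind One of `"harmonic"`, `"noise"`, `"am_noise"`.
#' @param f0 Fundamental frequency, Hz (harmonic kind); must be below the
#'   Nyquist frequency.
#' @param duration_s Duration in seconds (default 2.5; the stimuli ranged
#'   from 2 to 3 s).
#' @param sample_rate Sampling rate, Hz.
#' @param attack_frac Relative position of the first envelope peak
#'   (am_noise kind).
#' @param harmonicity Proportion of harmonic power (harmonic kind), in
#'   `[0, 1]`.
#' @param n_harmonics Number of harmonics summed (capped below Nyquist).
#' @param seed Integer seed.
#' @return A list of class `waveform` with elements `samples` (amplitudes in
#'   `[-1, 1]`), `sample_rate`, `kind`, `duration_s`.
#' @export
synth_audio <- function(kind = c("harmonic", "noise", "am_noise"),
                        f0 = 440, duration_s = 2.5, sample_rate = 44100,
                        attack_frac = 0.1, harmonicity = 1,
                        n_harmonics = 10, seed = 1L) {
  kind <- match.arg(kind)
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  with_seed(seed, {
    x <- switch(kind,
      harmonic = {
        if (f0 <= 0 || f0 >= sample_rate / 2)
          stop("f0 must lie in (0, sample_rate/2) to avoid aliasing")
        k_max <- min(n_harmonics, floor((sample_rate / 2 - 1) / f0))
        h <- rowSums(sapply(seq_len(k_max),
                            function(k) sin(2 * pi * k * f0 * t) / k))
        h <- h / stats::sd(h)
        if (harmonicity < 1) {
          w <- rnorm(n)
          h <- sqrt(harmonicity) * h + sqrt(1 - harmonicity) * w / stats::sd(w)
        }
        # 10 ms raised-cosine onset/offset ramps
        ramp <- pmin(1, t / 0.01, rev(t) / 0.01)
        h * ramp
      },
      noise = rnorm(n),
      am_noise = {
        stopifnot(attack_frac > 0, attack_frac < 1)
        t_peak <- attack_frac * duration_s
        env <- ifelse(t <= t_peak, t / t_peak,
                      0.3 + 0.7 * exp(-(t - t_peak) / (0.15 * duration_s)))
        rnorm(n) * env
      })
    x <- x / max(abs(x))
    structure(list(samples = x, sample_rate = sample_rate, kind = kind,
                   duration_s = duration_s),
              class = "waveform")
  })
}
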