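#' Class parameters for the synthetic EEG generator
#'
#' Describes the spectral composition of one subject class. Each channel is a
#' mixture of `1/f^beta` colored background noise and a set of narrowband
#' oscillatory components; the mixing weight of the oscillatory part controls
#' the spectral complexity of the channel, and hence its normalized spectral
#' entropy: the larger `narrowband_fraction`, the more spectral mass is
#' concentrated in narrow bands and the lower the entropy.
#'
#' @param narrowband_fraction fraction in `[0,1]` of the signal mixture given
#'   to the oscillatory components (before per-channel unit-variance
#'   normalization).
#' @param n_oscillators number of narrowband components per channel.
#' @param osc_band length-2 numeric, frequency range (Hz) from which component
#'   center frequencies are drawn.
#' @param noise_exponent spectral slope `beta` of the `1/f^beta` background
#'   (1 = pink noise, the default for both classes; class contrast is carried
#'   by `narrowband_fraction` only).
#' @param channel_effect 16-vector of per-channel multipliers in `[0,1]`
#'   applied to `narrowband_fraction`; a zero entry makes that channel pure
#'   background noise.
#' @param osc_bw spectral half-width (Hz, Gaussian sigma) of each narrowband
#'   component; components are slowly amplitude-modulated processes of
#'   bandwidth about `2*osc_bw`, not pure tones, so the entropy contrast is
#'   graded rather than saturated.
#' @return An object of class `eeg_class_params`.
#' @export
class_params <- function(narrowband_fraction = 0.5,
                         n_oscillators = 4,
                         osc_band = c(4, 30),
                         noise_exponent = 1,
                         channel_effect = rep(1, N_CHANNELS),
                         osc_bw = 0.5) {
  stopifnot(length(narrowband_fraction) == 1,
            narrowband_fraction >= 0, narrowband_fraction <= 1,
            n_oscillators >= 1,
            length(osc_band) == 2, osc_band[1] > 0, osc_band[1] < osc_band[2],
            length(channel_effect) == N_CHANNELS,
            all(channel_effect >= 0), all(channel_effect <= 1),
            osc_bw > 0)
  structure(list(narrowband_fraction = narrowband_fraction,
                 n_oscillators = as.integer(n_oscillators),
                 osc_band = as.numeric(osc_band),
                 noise_exponent = as.numeric(noise_exponent),
                 channel_effect = as.numeric(channel_effect),
                 osc_bw = as.numeric(osc_bw)),
            class = "eeg_class_params")
}

#' Cohort specification for synthetic two-class EEG data
#'
#' @param n_per_class subjects per class (class 0 = control-like, higher
#'   entropy; class 1 = case-like, lower entropy).
#' @param duration_s recording length per subject in seconds (>= 8).
#' @param fs sampling rate in Hz (> 80 so the 0.5-40 Hz band exists).
#' @param params_class0,params_class1 [class_params()] for the two classes.
#' @param seed integer root seed; per-subject child streams are derived from
#'   it by counter, so a subject's recording does not depend on cohort size.
#' @return An object of class `eeg_cohort_spec`.
#' @export
cohort_spec <- function(n_per_class, duration_s, fs = 1000,
                        params_class0 = class_params(0.2),
                        params_class1 = class_params(0.6),
                        seed = 1) {
  stopifnot(n_per_class >= 1, duration_s >= 8, fs > 80)
  for (p in list(params_class0, params_class1)) {
    stopifnot(inherits(p, "eeg_class_params"))
    if (p$osc_band[2] >= fs / 2)
      stop("osc_band must lie below the Nyquist frequency", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 duration_s = as.numeric(duration_s),
                 fs = as.numeric(fs),
                 params_class0 = params_class0,
                 params_class1 = params_class1,
                 seed = as.integer(seed)),
            class = "eeg_cohort_spec")
}

#' Preset cohort specifications
#'
#' Convenience presets documenting the effect-size calibrations used in the
#' package's own experiments (these are the package's choices for a synthetic
#' testbed, not clinical effect sizes): `"strong"` contrasts
#' `narrowband_fraction` 0.1 (class 0) vs 0.8 (class 1), `"mid"` 0.2 vs 0.5,
#' `"null"` uses pure `1/f` noise (`narrowband_fraction` 0) for both classes,
#' so recordings carry neither class structure nor subject-specific
#' oscillator signatures and any classifier should sit at chance.
#'
#' @param effect one of `"strong"`, `"mid"`, `"null"`.
#' @inheritParams cohort_spec
#' @export
cohort_preset <- function(effect = c("strong", "mid", "null"),
                          n_per_class = 20, duration_s = 60, fs = 1000,
                          seed = 1) {
  effect <- match.arg(effect)
  fr <- switch(effect,
               strong = c(0.1, 0.8),
               mid = c(0.2, 0.5),
               null = c(0, 0))
  cohort_spec(n_per_class, duration_s, fs,
              params_class0 = class_params(fr[1]),
              params_class1 = class_params(fr[2]),
              seed = seed)
}

# Deterministic child seed for subject `counter` under root `seed`.
child_seed <- function(seed, counter) {
  as.integer((abs(as.numeric(seed)) %% 65521) * 17389 +
               as.numeric(counter) * 7919) %% 2147483629L
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Real signal of length n synthesized from a one-sided complex spectrum
# amplitude envelope `amp` (length floor(n/2)+1, amp[1] is DC) with iid
# standard complex Gaussian coefficients drawn from the current RNG stream.
spectral_noise <- function(n, amp) {
  nh <- length(amp)
  re <- stats::rnorm(nh); im <- stats::rnorm(nh)
  coef <- complex(real = re, imaginary = im) * amp
  coef[1] <- complex(real = re[1] * amp[1], imaginary = 0)
  full <- complex(length.out = n)
  full[seq_len(nh)] <- coef
  if (n %% 2 == 0) {
    full[nh] <- complex(real = Re(coef[nh]), imaginary = 0)
    full[n:(nh + 1)] <- Conj(coef[2:(nh - 1)])
  } else {
    full[n:(nh + 1)] <- Conj(coef[2:nh])
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

unit_var <- function(x) {
  s <- stats::sd(x)
  if (s == 0) x else (x - mean(x)) / s
}

#' Generate one synthetic EEG recording
#'
#' Each channel is `(1 - g) * colored noise + g * oscillations` with
#' `g = narrowband_fraction * channel_effect[n]`, followed by per-channel
#' unit-variance normalization (so amplitude carries no class information;
#' only spectral shape does). The background is `1/f^beta` noise; the
#' oscillatory part is a sum of narrowband Gaussian processes centered at
#' subject-specific random frequencies in `osc_band`. Identical
#' `(params, duration_s, fs, seed)` give bit-identical output.
#'
#' @param params an [class_params()] object.
#' @param duration_s recording length in seconds (must fit one 4-s window).
#' @param fs sampling rate, Hz.
#' @param seed integer seed for this recording.
#' @param subject_id,label passed through to [eeg_recording()].
#' @param mains_hz optional mains interference frequency; if non-`NULL`, a
#'   sinusoid at this frequency (10% amplitude) is injected into every channel
#'   to exercise the notch filter. Off by default.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(params, duration_s, fs = 1000, seed = 1,
                               subject_id = "S0", label = NA_integer_,
                               mains_hz = NULL) {
  stopifnot(inherits(params, "eeg_class_params"))
  n <- round(duration_s * fs)
  if (n < 4 * fs)
    stop("recording too short: need at least one 4-s window (duration_s >= 4)",
         call. = FALSE)
  freqs <- seq(0, floor(n / 2)) * fs / n
  beta <- params$noise_exponent
  noise_amp <- c(0, freqs[-1]^(-beta / 2))

  with_seed(seed, {
    centers <- stats::runif(params$n_oscillators,
                            params$osc_band[1], params$osc_band[2])
    osc_amps <- lapply(centers, function(fc)
      exp(-(freqs - fc)^2 / (2 * params$osc_bw^2)))
    data <- matrix(0, N_CHANNELS, n)
    for (ch in seq_len(N_CHANNELS)) {
      g <- params$narrowband_fraction * params$channel_effect[ch]
      bg <- unit_var(spectral_noise(n, noise_amp))
      osc <- 0
      for (a in osc_amps) osc <- osc + spectral_noise(n, a)
      osc <- unit_var(osc)
      x <- (1 - g) * bg + g * osc
      if (!is.null(mains_hz))
        x <- x + 0.1 * sd(x) * sqrt(2) *
          sin(2 * pi * mains_hz * seq_len(n) / fs + stats::runif(1, 0, 2 * pi))
      data[ch, ] <- unit_var(x)
    }
    eeg_recording(data, fs, subject_id = subject_id, label = label)
  })
}

#' Generate a labeled two-class synthetic cohort
#'
#' @param spec an [cohort_spec()] (or [cohort_preset()]).
#' @param mains_hz see [generate_recording()].
#' @return List of `2 * n_per_class` [eeg_recording()] objects: class-0
#'   subjects `HC01..` (label 0) followed by class-1 subjects `MC01..`
#'   (label 1). Each subject uses a child seed derived from `spec$seed` by
#'   counter, so recordings are reproducible independently of cohort size.
#' @export
generate_cohort <- function(spec, mains_hz = NULL) {
  stopifnot(inherits(spec, "eeg_cohort_spec"))
  n <- spec$n_per_class
  recs <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    cls <- if (i <= n) 0L else 1L
    params <- if (cls == 0L) spec$params_class0 else spec$params_class1
    id <- sprintf("%s%02d", if (cls == 0L) "HC" else "MC",
                  if (cls == 0L) i else i - n)
    recs[[i]] <- generate_recording(params, spec$duration_s, spec$fs,
                                    seed = child_seed(spec$seed, i),
                                    subject_id = id, label = cls,
                                    mains_hz = mains_hz)
  }
  recs
}

#' Write a synthetic cohort to EDF files plus a manifest
#'
#' One EDF file per subject (16 signals, physical dimension uV) and a
#' `manifest.csv` with columns subject_id, label, seed, file and the class
#' parameters serialized as JSON.
#'
#' @param spec an [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort_edf <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_cohort(spec)
  rows <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    file <- file.path(dir, paste0(rec$subject_id, ".edf"))
    write_edf(rec, file)
    params <- if (rec$label == 0L) spec$params_class0 else spec$params_class1
    data.frame(subject_id = rec$subject_id, label = rec$label,
               seed = child_seed(spec$seed, i), file = basename(file),
               params = as.character(jsonlite::toJSON(unclass(params),
                                                      auto_unbox = TRUE)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
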