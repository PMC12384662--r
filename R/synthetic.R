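# Synthetic single-channel EEG for the three clinical states, written in the
# same ASCII dialect as the Bonn corpus so the whole pipeline runs with no
# download. The generator targets the statistical structure the classifier
# exploits (spectral shape, transient spikes, rhythmic high-amplitude
# spike-wave discharges), not a physiologically detailed neural-mass model.

#' Configuration of the synthetic EEG generator
#'
#' Defaults mirror the Bonn file geometry (173.61 Hz, 4096 points, 100
#' files per class) and encode one realisation per clinical state:
#' \describe{
#'   \item{background}{1/f^beta noise (beta = 1) plus a 10 Hz alpha
#'     component; unit-sd signal scaled by `base_amplitude`.}
#'   \item{interictal}{steeper spectrum (beta = 1.4), reduced alpha, plus
#'     Poisson-timed biphasic sharp transients (default 1.5 events/s,
#'     70 ms wide, amplitude multiplier 3); overall scale 1.3x background,
#'     reflecting the different texture of intracranial depth recordings.}
#'   \item{ictal}{rhythmic spike-wave train at 3.5 Hz (sharp spike plus
#'     slow wave), amplitude multiplier 5, over attenuated background.}
#' }
#'
#' @param fs sampling rate in Hz.
#' @param file_len samples per file.
#' @param n_files_per_class files generated per class.
#' @param classes subset of `c("background", "interictal", "ictal")`.
#' @param base_amplitude ADC units per unit sd (integer-quantized output).
#' @param alpha_freq,alpha_amp background alpha frequency (Hz) / amplitude.
#' @param bg_beta,ii_beta spectral exponents of background / interictal.
#' @param ii_alpha_frac alpha amplitude of the interictal state relative to
#'   background (matching it, with equal betas, scale 1 and spike rate 0,
#'   makes interictal collapse onto background for the same seed).
#' @param spike_rate interictal spike rate (events per second).
#' @param spike_width_ms interictal spike width (milliseconds).
#' @param spike_mult interictal spike amplitude multiplier (vs background sd).
#' @param ii_scale interictal overall amplitude scale.
#' @param ictal_freq ictal rhythm frequency in Hz (3-5 Hz range).
#' @param ictal_mult ictal amplitude multiplier.
#' @param seed master seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(fs = BONN_FS, file_len = BONN_FILE_LEN,
                         n_files_per_class = 100L,
                         classes = c("background", "interictal", "ictal"),
                         base_amplitude = 40, alpha_freq = 10, alpha_amp = 1,
                         bg_beta = 1.0, ii_beta = 1.4, ii_alpha_frac = 0.4,
                         spike_rate = 1.5, spike_width_ms = 70,
                         spike_mult = 3, ii_scale = 1.3,
                         ictal_freq = 3.5, ictal_mult = 5, seed = 1L) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (fs <= 0 || file_len < 2L) stopf("need fs > 0 and file_len >= 2")
  if (spike_mult <= 1 || ictal_mult <= spike_mult)
    stopf("amplitude multipliers must satisfy ictal > interictal > 1")
  structure(list(fs = fs, file_len = as.integer(file_len),
                 n_files_per_class = as.integer(n_files_per_class),
                 classes = classes, base_amplitude = base_amplitude,
                 alpha_freq = alpha_freq, alpha_amp = alpha_amp,
                 bg_beta = bg_beta, ii_beta = ii_beta,
                 ii_alpha_frac = ii_alpha_frac,
                 spike_rate = spike_rate, spike_width_ms = spike_width_ms,
                 spike_mult = spike_mult, ii_scale = ii_scale,
                 ictal_freq = ictal_freq, ictal_mult = ictal_mult,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^beta noise of length n with unit sd, via spectral shaping of white
# noise (FFT filter).
pink_noise <- function(n, beta) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  f <- c(1, seq_len(n - 1))            # DC bin kept finite
  f <- pmin(f, n - f + 1)              # symmetric frequency index
  sp <- sp / f^(beta / 2)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

unit_sd <- function(x) x / stats::sd(x)

#' Generate one synthetic background (normal) EEG recording
#'
#' 1/f^beta noise plus an alpha-band sinusoid with random phase, scaled to
#' unit sd and then by the configured base amplitude. Deterministic per
#' (config, seed).
#'
#' @param cfg a [synth_config].
#' @param seed integer seed for this recording.
#' @return an [eeg_recording] with set label "background".
#' @export
gen_background <- function(cfg, seed) {
  set.seed(seed)
  n <- cfg$file_len
  t <- seq_len(n) / cfg$fs
  x <- pink_noise(n, cfg$bg_beta) +
    cfg$alpha_amp * sin(2 * pi * cfg$alpha_freq * t + stats::runif(1, 0, 2 * pi))
  eeg_recording(cfg$base_amplitude * unit_sd(x), fs = cfg$fs,
                set_label = "background",
                source_id = sprintf("synth-bg-%d", seed))
}

# Biphasic triangular sharp transient: positive lobe then a shallower
# negative after-wave, total width w samples.
spike_shape <- function(w) {
  up <- ceiling(w * 0.4)
  down <- w - up
  c(seq(0, 1, length.out = up), seq(1, -0.5, length.out = ceiling(down / 2)),
    seq(-0.5, 0, length.out = down - ceiling(down / 2)))[seq_len(w)]
}

#' Generate one synthetic interictal EEG recording
#'
#' Background-like activity with a steeper spectral slope and reduced alpha,
#' plus Poisson-timed biphasic sharp transients of the configured width and
#' amplitude multiplier. With `spike_rate = 0` (and matching spectral
#' parameters) the signal reduces to the background generator for the same
#' seed.
#'
#' @param cfg a [synth_config].
#' @param seed integer seed for this recording.
#' @return an [eeg_recording] with set label "interictal".
#' @export
gen_interictal <- function(cfg, seed) {
  set.seed(seed)
  n <- cfg$file_len
  t <- seq_len(n) / cfg$fs
  x <- pink_noise(n, cfg$ii_beta) +
    cfg$ii_alpha_frac * cfg$alpha_amp *
      sin(2 * pi * cfg$alpha_freq * t + stats::runif(1, 0, 2 * pi))
  x <- unit_sd(x)
  n_spk <- stats::rpois(1, cfg$spike_rate * n / cfg$fs)
  if (n_spk > 0) {
    w <- max(3L, as.integer(round(cfg$spike_width_ms / 1000 * cfg$fs)))
    shape <- spike_shape(w)
    starts <- sort(sample.int(max(1L, n - w), n_spk, replace = TRUE))
    for (s in starts) {
      sgn <- sample(c(-1, 1), 1)
      amp <- cfg$spike_mult * stats::runif(1, 0.8, 1.2)
      x[s:(s + w - 1L)] <- x[s:(s + w - 1L)] + sgn * amp * shape
    }
  }
  rec <- eeg_recording(cfg$base_amplitude * cfg$ii_scale * x, fs = cfg$fs,
                       set_label = "interictal",
                       source_id = sprintf("synth-ii-%d", seed))
  rec$n_events <- n_spk   # realized Poisson spike count, for diagnostics
  rec
}

#' Generate one synthetic ictal EEG recording
#'
#' A high-amplitude rhythmic spike-wave train at the configured rhythm
#' frequency (sharp spike plus slow half-wave each cycle, random phase),
#' scaled by the ictal multiplier and superimposed on attenuated background
#' activity.
#'
#' @param cfg a [synth_config].
#' @param seed integer seed for this recording.
#' @return an [eeg_recording] with set label "ictal".
#' @export
gen_ictal <- function(cfg, seed) {
  set.seed(seed)
  n <- cfg$file_len
  period <- cfg$fs / cfg$ictal_freq
  phase <- stats::runif(1, 0, period)
  ph <- ((seq_len(n) - 1 + phase) %% period) / period   # cycle phase in [0,1)
  spike_frac <- 0.18
  spike <- ifelse(ph < spike_frac,
                  1 - abs(ph / spike_frac * 2 - 1),      # triangular spike
                  0)
  wave <- ifelse(ph >= spike_frac,
                 -0.45 * sin(pi * (ph - spike_frac) / (1 - spike_frac)),
                 0)
  sw <- unit_sd(spike + wave) * stats::runif(1, 0.9, 1.1)
  x <- cfg$ictal_mult * sw + 0.5 * pink_noise(n, cfg$bg_beta)
  eeg_recording(cfg$base_amplitude * x, fs = cfg$fs,
                set_label = "ictal",
                source_id = sprintf("synth-ict-%d", seed))
}

gen_one <- function(cfg, class, seed) {
  switch(class,
         background = gen_background(cfg, seed),
         interictal = gen_interictal(cfg, seed),
         ictal = gen_ictal(cfg, seed),
         stopf("unknown synthetic class %s", class))
}

#' Generate a batch of synthetic recordings in memory
#'
#' @param cfg a [synth_config].
#' @param class one of "background", "interictal", "ictal".
#' @param n number of recordings.
#' @param seed master seed; per-file seeds are derived from it.
#' @return list of [eeg_recording] objects.
#' @export
gen_recordings <- function(cfg, class, n = cfg$n_files_per_class,
                           seed = cfg$seed) {
  lapply(seq_len(n), function(k)
    gen_one(cfg, class, derive_seed(seed, sprintf("%s%d", class, k))))
}

#' Write a synthetic dataset as Bonn-format ASCII files
#'
#' One subdirectory per requested class, `n_files_per_class` files each,
#' one integer-quantized amplitude per line, readable by [read_bonn_file()]
#' unchanged. The configuration is serialised as JSON next to the data for
#' provenance. Byte-identical for the same master seed.
#'
#' @param cfg a [synth_config].
#' @param out_dir output directory (created if absent).
#' @return named character vector of class directories, invisibly.
#' @export
gen_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  dirs <- character(0)
  for (cls in cfg$classes) {
    d <- file.path(out_dir, cls)
    dir.create(d, showWarnings = FALSE)
    recs <- gen_recordings(cfg, cls)
    for (k in seq_along(recs))
      write_bonn_file(round(recs[[k]]$samples),
                      file.path(d, sprintf("%s%03d.txt", toupper(substr(cls, 1, 1)), k)))
    dirs[cls] <- d
    log_msg("synth", "class %s: %d files in %s (seed %d)",
            cls, length(recs), d, cfg$seed)
  }
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "synth_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dirs)
}

# Map from Bonn set labels to synthetic classes: scalp sets A/B emulate
# normal background, intracranial interictal sets C/D the spiking state,
# and E the ictal state.
SYNTH_SET_CLASS <- c(A = "background", B = "background",
                     C = "interictal", D = "interictal", E = "ictal")

#' Generate a five-set synthetic surrogate of the Bonn corpus in memory
#'
#' Sets A and B carry background activity, C and D interictal activity, and
#' E ictal activity (distinct seeds per set). This surrogate has the same
#' file geometry as the real corpus, so every downstream stage (case
#' assembly, segmentation, training) runs unchanged; it is synthetic data
#' and is labelled as such.
#'
#' @param cfg a [synth_config].
#' @param n_files_per_set files per set (default from `cfg`).
#' @param seed master seed (default from `cfg`).
#' @param sets subset of A..E to generate.
#' @return named list: set label -> list of recordings.
#' @export
gen_bonn_surrogate <- function(cfg, n_files_per_set = cfg$n_files_per_class,
                               seed = cfg$seed, sets = names(SYNTH_SET_CLASS)) {
  out <- list()
  for (s in sets) {
    recs <- gen_recordings(cfg, SYNTH_SET_CLASS[[s]], n_files_per_set,
                           seed = derive_seed(seed, paste0("set", s)))
    out[[s]] <- lapply(recs, function(r) { r$set_label <- s; r })
  }
  out
}
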