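#' Generate species syllable templates
#'
#' Each synthetic species is a set of 2-4 spectro-temporal syllable kernels
#' (stationary tone, up-chirp, down-chirp or harmonic stack, each with a
#' centre frequency, bandwidth, duration and sweep rate), a song rate
#' (events/s) and a relative amplitude. Templates are abstract but
#' spectro-temporally structured, so learned bases have chirp-like regularities
#' to discover. All frequencies stay inside (500 Hz, Nyquist).
#'
#' @param n_species Number of species.
#' @param sample_rate Sample rate the templates are rendered at (Hz).
#' @param seed Integer seed.
#' @return List of `species_template` objects named `sp01`, `sp02`, ...
#' @export
make_species_templates <- function(n_species, sample_rate = 22050, seed = 1L) {
  stopifnot(n_species >= 1)
  nyq <- sample_rate / 2
  with_seed(seed, {
    lapply(stats::setNames(seq_len(n_species),
                           sprintf("sp%02d", seq_len(n_species))), function(s) {
      n_syl <- sample(2:4, 1)
      syllables <- lapply(seq_len(n_syl), function(i) {
        type <- sample(c("tone", "up_chirp", "down_chirp", "harmonic"), 1)
        cf <- stats::runif(1, 1200, 0.55 * nyq)
        dur <- stats::runif(1, 0.08, 0.25)
        sweep <- switch(type,
                        tone = 0,
                        up_chirp = stats::runif(1, 2000, 8000),
                        down_chirp = -stats::runif(1, 2000, 8000),
                        harmonic = 0)
        list(type = type, centre_hz = cf, bandwidth_hz = stats::runif(1, 50, 300),
             duration_s = dur, sweep_hz_per_s = sweep,
             n_harmonics = if (type == "harmonic") sample(2:3, 1) else 1L)
      })
      structure(list(syllables = syllables,
                     song_rate = stats::runif(1, 0.8, 2.0),
                     amplitude = stats::runif(1, 0.6, 1.0)),
                class = "species_template")
    })
  })
}

# Render one syllable as a windowed (co)sine sweep at the template's rate.
render_syllable <- function(syl, sample_rate) {
  n <- max(2L, round(syl$duration_s * sample_rate))
  t <- seq_len(n) / sample_rate
  nyq <- sample_rate / 2
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))  # Hann envelope
  x <- numeric(n)
  for (h in seq_len(syl$n_harmonics)) {
    f <- pmin(pmax(h * (syl$centre_hz + syl$sweep_hz_per_s * t), 600), 0.95 * nyq)
    phase <- 2 * pi * cumsum(f) / sample_rate
    x <- x + sin(phase) / h
  }
  x * env
}

# Additive background noise: white, or pink (1/f magnitude shaping via FFT).
render_noise <- function(n, colour = "pink") {
  w <- stats::rnorm(n)
  if (colour == "white") return(w)
  spec <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # mirror for the negative frequencies
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Synthesise one recording from species templates
#'
#' Syllable events for each named species are placed by a Poisson process at
#' the species' song rate (at least one event per listed species), on top of
#' background noise at a configured signal-to-noise ratio.
#'
#' @param templates List from [make_species_templates()].
#' @param species Character vector of species present (subset of
#'   `names(templates)`); may be empty for a noise-only recording.
#' @param duration_s Recording duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param snr_db Signal-to-noise ratio in dB (signal power over noise power).
#' @param noise `"pink"` or `"white"`.
#' @param seed Integer seed.
#' @param source_id Recording identifier.
#' @return An [audio_clip()] with an `events` attribute (data.frame of placed
#'   events: species, onset_s, duration_s).
#' @export
synth_recording <- function(templates, species, duration_s, sample_rate = 22050,
                            snr_db = 20, noise = "pink", seed = 1L,
                            source_id = "synth") {
  n <- round(duration_s * sample_rate)
  min_dur <- if (length(species) > 0)
    min(vapply(templates[species], function(tp)
      min(vapply(tp$syllables, `[[`, 0, "duration_s")), 0)) else 0
  if (length(species) > 0 && duration_s < min_dur)
    stopf("recording of %.2f s too short to place any syllable", duration_s)
  with_seed(seed, {
    sig <- numeric(n)
    events <- list()
    for (sp in species) {
      tp <- templates[[sp]]
      n_events <- max(1L, stats::rpois(1, tp$song_rate * duration_s))
      for (e in seq_len(n_events)) {
        syl <- tp$syllables[[sample.int(length(tp$syllables), 1)]]
        x <- render_syllable(syl, sample_rate) * tp$amplitude
        start <- sample.int(max(1L, n - length(x)), 1)
        idx <- start:(start + length(x) - 1L)
        sig[idx] <- sig[idx] + x
        events[[length(events) + 1L]] <- data.frame(
          species = sp, onset_s = start / sample_rate,
          duration_s = length(x) / sample_rate)
      }
    }
    bg <- render_noise(n, noise)
    sig_p <- mean(sig^2)
    if (sig_p > 0) {
      bg <- bg * sqrt(sig_p / (mean(bg^2) * 10^(snr_db / 10)))
    } else {
      bg <- bg * 0.05
    }
    y <- sig + bg
    y <- y / max(abs(y)) * 0.9
    clip <- audio_clip(y, sample_rate, source_id = source_id)
    attr(clip, "events") <- if (length(events) > 0) do.call(rbind, events)
      else data.frame(species = character(0), onset_s = numeric(0),
                      duration_s = numeric(0))
    clip
  })
}

#' Generate a full synthetic dataset (audio, annotations, folds)
#'
#' Two regimes emulate the structure of real bird-sound corpora:
#' `single_label_clip` — short clips, one species each, higher SNR, random
#' 2-fold assignment; `multilabel_chorus` — long recordings with several
#' concurrently vocalising species, lower SNR, and recordings grouped into
#' three synthetic "recordists" with group-preserving 3-fold assignment.
#' Annotations exactly reflect the species with placed events.
#'
#' @param n_species Number of species (>= 2).
#' @param n_recordings Number of recordings.
#' @param regime `"single_label_clip"` or `"multilabel_chorus"`.
#' @param seed Integer seed; everything is reproducible from it.
#' @param duration_s Recording duration (defaults: 10 s clips, 12 s chorus).
#'   The clip default leaves the two-layer feature path well-posed: after
#'   factor-8 max-pooling a shorter clip yields almost no layer-2 patches.
#' @param sample_rate Sample rate in Hz.
#' @param snr_db SNR (defaults: 20 dB clips, 10 dB chorus).
#' @param noise Noise colour.
#' @param dir If non-`NULL`, WAV files plus `annotations.csv`, `folds.csv` and
#'   `events.json` are written there.
#' @return List with `clips` (named list of [audio_clip()]), `annotations`
#'   (an [annotation_set()]), `folds` (named integer vector), `templates`,
#'   `events` (data.frame) and `dir`.
#' @export
generate_dataset <- function(n_species, n_recordings,
                             regime = c("single_label_clip", "multilabel_chorus"),
                             seed = 1L,
                             duration_s = NULL, sample_rate = 22050,
                             snr_db = NULL, noise = "pink", dir = NULL) {
  regime <- match.arg(regime)
  stopifnot(n_species >= 2, n_recordings >= 2)
  duration_s <- duration_s %||% if (regime == "single_label_clip") 10 else 12
  snr_db <- snr_db %||% if (regime == "single_label_clip") 20 else 10
  templates <- make_species_templates(n_species, sample_rate, seed = seed)
  sp_names <- names(templates)

  ids <- sprintf("rec%03d", seq_len(n_recordings))
  plan <- with_seed(seed + 1L, {
    lapply(seq_len(n_recordings), function(i) {
      if (regime == "single_label_clip") {
        sample(sp_names, 1)
      } else {
        sample(sp_names, sample(2:min(4, n_species), 1))
      }
    })
  })
  clips <- list(); labels <- list(); all_events <- list()
  for (i in seq_len(n_recordings)) {
    clip <- synth_recording(templates, plan[[i]], duration_s, sample_rate,
                            snr_db = snr_db, noise = noise,
                            seed = seed + 1000L + i, source_id = ids[i])
    ev <- attr(clip, "events")
    clips[[ids[i]]] <- clip
    labels[[i]] <- sort(unique(ev$species))  # annotation = species with placed events
    if (nrow(ev) > 0) all_events[[length(all_events) + 1L]] <- cbind(recording_id = ids[i], ev)
  }
  mode <- if (regime == "single_label_clip") "single_label" else "multilabel"
  ann <- annotation_set(ids, labels, vocabulary = sp_names, mode = mode)

  folds <- with_seed(seed + 2L, {
    if (regime == "single_label_clip") {
      stats::setNames(sample(rep_len(1:2, n_recordings)), ids)
    } else {
      recordist <- rep_len(1:3, n_recordings)  # recordings grouped by recordist
      stats::setNames(recordist[sample.int(n_recordings)], ids)
    }
  })
  events <- if (length(all_events) > 0) do.call(rbind, all_events)
    else data.frame(recording_id = character(0), species = character(0),
                    onset_s = numeric(0), duration_s = numeric(0))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids)
      write_wav(clips[[id]]$samples, sample_rate, file.path(dir, paste0(id, ".wav")))
    utils::write.csv(data.frame(
      recording_id = ids,
      labels = vapply(labels, paste, "", collapse = ";")),
      file.path(dir, "annotations.csv"), row.names = FALSE)
    utils::write.csv(data.frame(recording_id = ids, fold = folds[ids]),
                     file.path(dir, "folds.csv"), row.names = FALSE)
    jsonlite::write_json(events, file.path(dir, "events.json"), dataframe = "rows")
  }
  list(clips = clips, annotations = ann, folds = folds, templates = templates,
       events = events, regime = regime, sample_rate = sample_rate, dir = dir)
}

#' Planted-direction patch data for dictionary-recovery tests
#'
#' Data points are positive scalar multiples (log-normal magnitudes) of
#' `k_true` planted unit directions plus isotropic Gaussian noise at the given
#' SNR, mirroring the angular-cluster structure spherical k-means is designed
#' to recover.
#'
#' @param k_true Number of planted directions (<= `dim`).
#' @param dim Ambient dimensionality.
#' @param n Number of points.
#' @param snr_db Signal-to-noise ratio in dB (`Inf` for noise-free).
#' @param seed Integer seed.
#' @return List with `x` (n x dim), `directions` (k_true x dim unit rows) and
#'   `assignment` (integer vector).
#' @export
planted_dictionary_data <- function(k_true, dim, n, snr_db = 20, seed = 1L) {
  stopifnot(k_true <= dim, n >= k_true)
  with_seed(seed, {
    d <- matrix(stats::rnorm(k_true * dim), k_true, dim)
    d <- unit_rows(d)
    assignment <- sample(rep_len(seq_len(k_true), n))
    mag <- stats::rlnorm(n, meanlog = 0, sdlog = 0.25)
    x <- d[assignment, , drop = FALSE] * mag
    if (is.finite(snr_db)) {
      noise <- matrix(stats::rnorm(n * dim), n, dim)
      noise <- noise * sqrt(mean(x^2) / (mean(noise^2) * 10^(snr_db / 10)))
      x <- x + noise
    }
    list(x = x, directions = d, assignment = assignment)
  })
}
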