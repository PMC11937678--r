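# Synthetic-data generators: EEG sessions with a task-attenuated alpha
# oscillator over sensorimotor cortex, SEP recordings built from component
# templates, and Bernoulli typing outcomes following an exponential
# speed-accuracy trade-off. Every generator is fully determined by its seed,
# so downstream stages are testable by parameter recovery.

#' Configuration for a synthetic EEG motor-imagery session
#'
#' Defines the signal model: a 1/f (aperiodic) background plus an alpha-band
#' oscillator at the individual alpha frequency (IAF), projected with maximum
#' gain on the center channel (C3) and attenuated gain on its large-Laplacian
#' neighbors. The oscillator is an amplitude-modulated sinusoid with random
#' phase per trial and a finite coherence time: slow mean-reverting
#' frequency modulation gives the alpha line a near-Gaussian spectral width
#' (`alpha_linewidth`), as in real EEG; set it to 0 for an analytically
#' exact pure tone. During task periods the
#' oscillator power is multiplied by `1 - erd_depth` (event-related
#' desynchronization), entered through a short onset ramp to avoid a step
#' discontinuity.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param n_trials Number of trials; each trial is rest (5 s), ready (1 s),
#'   task (6 s), blank (5 s) = 17 s.
#' @param trial_timing Named numeric vector of period durations in seconds.
#' @param center_channel Center electrode of the Laplacian montage.
#' @param neighbor_channels Large-Laplacian neighbor electrodes.
#' @param neighbor_gain Gain of the alpha oscillator on neighbor channels
#'   (center gain is 1).
#' @param iaf_true True alpha peak frequency in Hz (8-13).
#' @param alpha_amplitude Oscillator amplitude on the center channel, uV.
#' @param alpha_linewidth Full width at half maximum of the alpha spectral
#'   line, Hz (slow frequency modulation); 0 disables the modulation.
#' @param erd_depth Fractional task-period power attenuation in \[0, 1\].
#' @param aperiodic_offset,aperiodic_exponent Parameters of the aperiodic
#'   power spectral density `10^offset / f^exponent` (uV^2/Hz). Use
#'   `aperiodic_offset = -Inf` for no background.
#' @param noise_sd SD of additional white measurement noise, uV.
#' @param erd_ramp_s Duration of the linear ERD onset ramp at task start, s.
#' @param seed Integer seed; fully determines the generated session.
#' @return A list of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(sampling_rate = 1000,
                           n_trials = 20,
                           trial_timing = c(rest = 5, ready = 1, task = 6, blank = 5),
                           center_channel = "C3",
                           neighbor_channels = c("F3", "P3", "T7", "Cz"),
                           neighbor_gain = 0.3,
                           iaf_true = 10,
                           alpha_amplitude = 5,
                           alpha_linewidth = 0.5,
                           erd_depth = 0.3,
                           aperiodic_offset = 0,
                           aperiodic_exponent = 1.5,
                           noise_sd = 0.2,
                           erd_ramp_s = 0.2,
                           seed = 1L) {
  if (erd_depth < 0 || erd_depth > 1) {
    stop("erd_depth must lie in [0, 1]", call. = FALSE)
  }
  if (iaf_true < 8 || iaf_true > 13) {
    stop("iaf_true must lie in the alpha band [8, 13] Hz", call. = FALSE)
  }
  if (!all(c("rest", "ready", "task", "blank") %in% names(trial_timing))) {
    stop("trial_timing must name rest, ready, task and blank periods", call. = FALSE)
  }
  cfg <- list(
    sampling_rate = sampling_rate, n_trials = n_trials,
    trial_timing = trial_timing,
    center_channel = center_channel, neighbor_channels = neighbor_channels,
    neighbor_gain = neighbor_gain,
    iaf_true = iaf_true, alpha_amplitude = alpha_amplitude,
    alpha_linewidth = alpha_linewidth, erd_depth = erd_depth,
    aperiodic_offset = aperiodic_offset,
    aperiodic_exponent = aperiodic_exponent,
    noise_sd = noise_sd, erd_ramp_s = erd_ramp_s, seed = seed
  )
  class(cfg) <- "eeg_sim_config"
  cfg
}

# 1/f-shaped Gaussian noise with one-sided PSD 10^offset / f^exponent
# (uV^2/Hz), generated by spectral shaping of white noise.
colored_noise <- function(n, fs, offset, exponent) {
  if (!is.finite(offset)) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)              # fold to physical frequency of each bin
  amp <- sqrt(10^offset * fs / 2) * ifelse(f > 0, f^(-exponent / 2), 0)
  Re(stats::fft(X * amp, inverse = TRUE)) / n
}

#' Generate a synthetic EEG motor-imagery session
#'
#' @param config An [eeg_sim_config()].
#' @return An object of class `eeg_recording`: list with `signal`
#'   (channels x samples matrix, uV), `sampling_rate`, `channel_labels` and
#'   `events` (data frame with `onset_sample`, `label`, `trial`; onsets are
#'   1-based sample indices).
#' @export
generate_eeg_session <- function(config) {
  stopifnot(inherits(config, "eeg_sim_config"))
  fs <- config$sampling_rate
  timing <- config$trial_timing[c("rest", "ready", "task", "blank")]
  trial_s <- sum(timing)
  trial_n <- round(trial_s * fs)
  n_total <- config$n_trials * trial_n
  channels <- unique(c(config$center_channel, config$neighbor_channels))
  if (!config$center_channel %in% channels) {
    stop("channel set must include the center channel", call. = FALSE)
  }

  with_seed(config$seed, {
    # ERD envelope (amplitude scale): sqrt(1 - d) during task, linear onset ramp
    t_rel <- (seq_len(trial_n) - 1) / fs
    task_on <- sum(timing[c("rest", "ready")])
    task_off <- task_on + timing[["task"]]
    env_trial <- rep(1, trial_n)
    depth_amp <- sqrt(1 - config$erd_depth)
    in_ramp <- t_rel >= task_on & t_rel < task_on + config$erd_ramp_s
    in_task <- t_rel >= task_on + config$erd_ramp_s & t_rel < task_off
    if (config$erd_ramp_s > 0) {
      env_trial[in_ramp] <- 1 + (depth_amp - 1) * (t_rel[in_ramp] - task_on) / config$erd_ramp_s
    }
    env_trial[in_task] <- depth_amp

    # Alpha oscillator: amplitude-modulated sinusoid; a slow mean-reverting
    # (AR-1, tau = 0.5 s) frequency deviation gives the line its
    # near-Gaussian width, and its phase runs continuously (the short
    # coherence time decorrelates trials without reset discontinuities,
    # whose splatter would contaminate the aperiodic background). The pure
    # tone (linewidth 0) keeps an independent random phase per trial.
    env_full <- rep(env_trial, config$n_trials)
    t_abs <- (seq_len(n_total) - 1) / fs
    sig_f <- config$alpha_linewidth / (2 * sqrt(2 * log(2)))
    if (config$alpha_linewidth > 0) {
      ar <- exp(-1 / (fs * 0.5))
      innov <- stats::rnorm(n_total, 0, sig_f * sqrt(1 - ar^2))
      f_dev <- as.numeric(stats::filter(innov, ar, method = "recursive",
                                        init = stats::rnorm(1, 0, sig_f)))
      phase <- stats::runif(1, 0, 2 * pi) + 2 * pi * cumsum(f_dev) / fs
      alpha <- config$alpha_amplitude * env_full *
        sin(2 * pi * config$iaf_true * t_abs + phase)
    } else {
      alpha <- numeric(n_total)
      for (k in seq_len(config$n_trials)) {
        idx <- (k - 1) * trial_n + seq_len(trial_n)
        phase <- stats::runif(1, 0, 2 * pi)
        alpha[idx] <- config$alpha_amplitude * env_trial *
          sin(2 * pi * config$iaf_true * t_abs[idx] + phase)
      }
    }

    gains <- stats::setNames(rep(config$neighbor_gain, length(channels)), channels)
    gains[config$center_channel] <- 1

    sig <- matrix(0, nrow = length(channels), ncol = n_total,
                  dimnames = list(channels, NULL))
    for (ch in channels) {
      bg <- colored_noise(n_total, fs, config$aperiodic_offset,
                          config$aperiodic_exponent)
      wn <- if (config$noise_sd > 0) stats::rnorm(n_total, sd = config$noise_sd) else 0
      sig[ch, ] <- gains[ch] * alpha + bg + wn
    }

    onsets <- cumsum(c(0, utils::head(rep(timing, config$n_trials), -1)))
    events <- data.frame(
      onset_sample = as.integer(round(onsets * fs)) + 1L,
      label = rep(c("rest", "ready", "task", "blank"), config$n_trials),
      trial = rep(seq_len(config$n_trials), each = 4L)
    )

    structure(list(signal = sig, sampling_rate = fs,
                   channel_labels = channels, events = events,
                   config = config),
              class = "eeg_recording")
  })
}

#' Configuration for a synthetic SEP session
#'
#' Components are negative-going Gaussian-windowed deflections at fixed
#' post-stimulus latencies, each on its own montage, superposed over white
#' noise. Defaults follow median-nerve somatosensory evoked potentials:
#' N9 (brachial plexus, EPi-EPc), N13 (cervical cord, C2S-Fz) and
#' N20 (primary somatosensory cortex, CPc-Fz).
#'
#' @param sampling_rate Hz.
#' @param n_stimuli Number of stimulus presentations.
#' @param stim_rate Stimulation rate, Hz.
#' @param components Data frame with columns `name`, `montage`, `latency_ms`,
#'   `amplitude_uv` (positive number; deflection is negative-going) and
#'   `width_ms` (full width at half maximum of the Gaussian template).
#' @param noise_sd White noise SD per montage trace, uV.
#' @param seed Integer seed.
#' @return A list of class `sep_sim_config`.
#' @export
sep_sim_config <- function(sampling_rate = 10000,
                           n_stimuli = 1000,
                           stim_rate = 2,
                           components = data.frame(
                             name = c("N9", "N13", "N20"),
                             montage = c("EPi-EPc", "C2S-Fz", "CPc-Fz"),
                             latency_ms = c(9, 13, 20),
                             amplitude_uv = c(3, 2, 2.5),
                             width_ms = c(3, 3.5, 2.5)
                           ),
                           noise_sd = 8,
                           seed = 1L) {
  if (any(components$latency_ms <= 0 | components$latency_ms >= 300)) {
    stop("component latencies must be positive and < 300 ms", call. = FALSE)
  }
  isi_ms <- 1000 / stim_rate
  sigma_ms <- components$width_ms / (2 * sqrt(2 * log(2)))
  if (any(components$latency_ms + 5 * sigma_ms > isi_ms)) {
    stop("component templates overlap the next stimulus interval", call. = FALSE)
  }
  cfg <- list(sampling_rate = sampling_rate, n_stimuli = n_stimuli,
              stim_rate = stim_rate, components = components,
              noise_sd = noise_sd, seed = seed)
  class(cfg) <- "sep_sim_config"
  cfg
}

#' Generate a synthetic SEP session
#'
#' @param config A [sep_sim_config()].
#' @return Object of class `sep_recording`: `traces` (montages x samples, uV),
#'   `sampling_rate`, `montages`, `stim_onsets` (1-based sample indices).
#' @export
generate_sep_session <- function(config) {
  stopifnot(inherits(config, "sep_sim_config"))
  fs <- config$sampling_rate
  isi_n <- round(fs / config$stim_rate)
  pad_n <- fs                                 # 1 s lead-in/out
  n_total <- 2L * pad_n + (config$n_stimuli - 1L) * isi_n + isi_n
  onsets <- pad_n + (seq_len(config$n_stimuli) - 1L) * isi_n + 1L
  montages <- unique(config$components$montage)

  with_seed(config$seed, {
    traces <- matrix(0, nrow = length(montages), ncol = n_total,
                     dimnames = list(montages, NULL))
    tmpl_t <- seq(0, 0.05, by = 1 / fs)       # 50 ms template support
    for (i in seq_len(nrow(config$components))) {
      comp <- config$components[i, ]
      sigma_s <- comp$width_ms / (2 * sqrt(2 * log(2))) / 1000
      tmpl <- -comp$amplitude_uv *
        exp(-(tmpl_t - comp$latency_ms / 1000)^2 / (2 * sigma_s^2))
      m <- comp$montage
      for (on in onsets) {
        idx <- on + seq_along(tmpl) - 1L
        traces[m, idx] <- traces[m, idx] + tmpl
      }
    }
    if (config$noise_sd > 0) {
      traces <- traces + matrix(stats::rnorm(length(traces), sd = config$noise_sd),
                                nrow = nrow(traces))
    }
    structure(list(traces = traces, sampling_rate = fs,
                   montages = montages, stim_onsets = onsets,
                   config = config),
              class = "sep_recording")
  })
}

#' Configuration for synthetic typing-task outcomes
#'
#' Success of each word trial is Bernoulli with probability
#' `a_true * exp(-b_true * x) + c_true`, where `x` is the movement-time
#' condition in seconds.
#'
#' @param a_true,b_true,c_true True speed-accuracy trade-off parameters.
#' @param conditions Movement-time limits in seconds.
#' @param n_blocks Number of blocks.
#' @param words_per_block Words per block (split evenly over conditions,
#'   order pseudo-randomized within block).
#' @param cpm Simulated typing capacity, characters per minute; used to pick
#'   word lengths via the 80-100 percent capacity rule.
#' @param seed Integer seed.
#' @return A list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(a_true = 0.9, b_true = 0.8, c_true = 0.05,
                                conditions = c(2, 4, 6),
                                n_blocks = 5, words_per_block = 30,
                                cpm = 150, seed = 1L) {
  p <- a_true * exp(-b_true * conditions) + c_true
  if (any(p < 0 | p > 1)) {
    stop("a*exp(-b*x)+c must lie in [0, 1] for every condition", call. = FALSE)
  }
  if (words_per_block %% length(conditions) != 0) {
    stop("words_per_block must be a multiple of the number of conditions",
         call. = FALSE)
  }
  cfg <- list(a_true = a_true, b_true = b_true, c_true = c_true,
              conditions = conditions, n_blocks = n_blocks,
              words_per_block = words_per_block, cpm = cpm, seed = seed)
  class(cfg) <- "behavior_sim_config"
  cfg
}

#' Generate a synthetic typing-task behavior table
#'
#' @param config A [behavior_sim_config()].
#' @param word_list Optional frequency-ranked word list (`word`, `length`)
#'   from which presented words are drawn; defaults to the bundled list.
#'   `NULL` skips word assignment.
#' @return Data frame with one row per word trial: `block`, `condition_s`,
#'   `word_length`, `word`, `success`.
#' @export
generate_behavior <- function(config, word_list = bundled_word_list()) {
  stopifnot(inherits(config, "behavior_sim_config"))
  per_cond <- config$words_per_block / length(config$conditions)
  pick_word <- function(len) {
    if (is.null(word_list)) return(NA_character_)
    cand <- word_list$word[word_list$length == len]
    if (length(cand) == 0) {        # nearest available length
      i <- which.min(abs(word_list$length - len))
      cand <- word_list$word[word_list$length == word_list$length[i]]
    }
    cand[sample.int(length(cand), 1L)]
  }
  with_seed(config$seed, {
    rows <- lapply(seq_len(config$n_blocks), function(b) {
      cond <- sample(rep(config$conditions, per_cond))
      len <- vapply(cond, function(x) {
        rng <- select_word_lengths(config$cpm, x)
        sample(seq(rng[1], rng[2]), 1L)
      }, numeric(1))
      p <- config$a_true * exp(-config$b_true * cond) + config$c_true
      data.frame(block = b, condition_s = cond, word_length = len,
                 word = vapply(len, pick_word, character(1)),
                 success = stats::rbinom(length(cond), 1L, p))
    })
    do.call(rbind, rows)
  })
}
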