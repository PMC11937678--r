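# Shared fixtures, built in code. Sessions are kept small; the full-scale
# study conditions live in test-acceptance.R.

small_eeg <- function(erd_depth = 0.4, n_trials = 3, seed = 101, ...) {
  generate_eeg_session(eeg_sim_config(erd_depth = erd_depth,
                                      n_trials = n_trials, seed = seed, ...))
}

noiseless_eeg <- function(erd_depth = 0.3, n_trials = 2, seed = 101, ...) {
  generate_eeg_session(eeg_sim_config(
    erd_depth = erd_depth, n_trials = n_trials, seed = seed,
    noise_sd = 0, aperiodic_offset = -Inf, alpha_linewidth = 0, ...))
}

small_sep <- function(n_stimuli = 120, noise_sd = 5, seed = 202, ...) {
  generate_sep_session(sep_sim_config(n_stimuli = n_stimuli,
                                      noise_sd = noise_sd, seed = seed, ...))
}

# Synthetic PSD built directly from the spectral model (log10 domain).
model_psd <- function(freq = seq(2, 40, by = 0.5), offset = 0, exponent = 1.5,
                      peaks = data.frame(cf = 10, height = 0.6, sd = 1)) {
  logp <- offset - exponent * log10(freq)
  for (i in seq_len(nrow(peaks))) {
    logp <- logp + peaks$height[i] *
      exp(-(freq - peaks$cf[i])^2 / (2 * peaks$sd[i]^2))
  }
  structure(list(freq = freq, psd = 10^logp), class = "psd")
}

# Balanced 2x2 mixed-design long table with configurable effects.
mixed_data <- function(n_per_group = 6, g_eff = 0, w_eff = 0, i_eff = 0,
                       subj_sd = 1, noise_sd = 1) {
  n <- 2 * n_per_group
  subj <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("verum", "sham"), each = n_per_group)
  base <- stats::rnorm(n, sd = subj_sd)
  d <- expand.grid(subject = subj, within = c("pre", "post"),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject, subj)]
  post <- d$within == "post"
  d$value <- base[match(d$subject, subj)] +
    g_eff * (d$group == "verum") + w_eff * post +
    i_eff * (d$group == "verum" & post) +
    stats::rnorm(nrow(d), sd = noise_sd)
  d
}
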