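# Two-group pre/post synthetic study: per-subject EEG, SEP and behavior
# session configurations with known group-specific pre-to-post changes in
# ERD depth, N20 amplitude and saturation speed, plus the end-to-end
# endpoint extraction that feeds the mixed ANOVA.

#' Generate a two-group pre/post study dataset (configurations)
#'
#' Builds per-subject, per-evaluation session configurations for EEG, SEP
#' and behavior with subject-level variability and group-specific
#' pre-to-post effect deltas. The returned object is lightweight: sessions
#' are materialized on demand (deterministically, from stored per-session
#' seeds) by [group_endpoints()] or [materialize_session()].
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param effect_spec Named list with elements `verum` and `sham`, each a
#'   named vector of pre-to-post deltas: `erd_depth` (fractional ERD
#'   deepening), `n20_amplitude` (uV added to the N20 template), `sat_b`
#'   (added decay rate, 1/s).
#' @param n_trials EEG trials per session.
#' @param n_stimuli SEP stimuli per session.
#' @param seed Integer seed; fully determines the dataset.
#' @return List of class `group_dataset`: `subjects` (data frame of ground
#'   truth), `configs` (nested per subject / evaluation), `effect_spec`,
#'   `seed`.
#' @export
generate_group_dataset <- function(n_per_group = 10,
                                   effect_spec = list(
                                     verum = c(erd_depth = 0.15,
                                               n20_amplitude = 0.8,
                                               sat_b = 0.35),
                                     sham = c(erd_depth = 0,
                                              n20_amplitude = 0,
                                              sat_b = 0)),
                                   n_trials = 6, n_stimuli = 150,
                                   seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  groups <- names(effect_spec)
  n_subj <- n_per_group * length(groups)

  with_seed(seed, {
    subjects <- data.frame(
      subject = sprintf("S%02d", seq_len(n_subj)),
      group = rep(groups, each = n_per_group),
      iaf = sample(9:12, n_subj, replace = TRUE),
      erd_pre = clamp(stats::rnorm(n_subj, 0.30, 0.05), 0.1, 0.6),
      n20_amp_pre = clamp(stats::rnorm(n_subj, 2.0, 0.3), 1.0, 3.5),
      sat_b_pre = clamp(stats::rnorm(n_subj, 0.35, 0.06), 0.2, 0.55)
    )
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_subj * 6),
                    nrow = n_subj)

    configs <- lapply(seq_len(n_subj), function(i) {
      delta <- effect_spec[[subjects$group[i]]]
      lapply(stats::setNames(1:2, c("eval1", "eval2")), function(tm) {
        post <- tm == 2
        comp <- sep_sim_config()$components
        comp$amplitude_uv[comp$name == "N20"] <-
          subjects$n20_amp_pre[i] + if (post) delta[["n20_amplitude"]] else 0
        list(
          eeg = eeg_sim_config(
            n_trials = n_trials,
            iaf_true = subjects$iaf[i],
            erd_depth = clamp(subjects$erd_pre[i] +
                                if (post) delta[["erd_depth"]] else 0, 0, 1),
            seed = seeds[i, 1 + post]
          ),
          sep = sep_sim_config(
            n_stimuli = n_stimuli, components = comp,
            seed = seeds[i, 3 + post]
          ),
          behavior = behavior_sim_config(
            a_true = 1.2, c_true = 0.05,
            b_true = subjects$sat_b_pre[i] + if (post) delta[["sat_b"]] else 0,
            words_per_block = 150,
            seed = seeds[i, 5 + post]
          )
        )
      })
    })
    names(configs) <- subjects$subject
    structure(list(subjects = subjects, configs = configs,
                   effect_spec = effect_spec, seed = seed),
              class = "group_dataset")
  })
}

#' Materialize one subject's sessions
#'
#' @param dataset A `group_dataset`.
#' @param subject Subject id.
#' @param time `"eval1"` or `"eval2"`.
#' @return List with `eeg`, `sep`, `behavior` generated data.
#' @export
materialize_session <- function(dataset, subject, time = c("eval1", "eval2")) {
  time <- match.arg(time)
  cfg <- dataset$configs[[subject]][[time]]
  list(eeg = generate_eeg_session(cfg$eeg),
       sep = generate_sep_session(cfg$sep),
       behavior = generate_behavior(cfg$behavior))
}

#' Run the analysis pipeline over a group dataset and extract endpoints
#'
#' For each subject and evaluation: the subject's individual alpha frequency
#' is identified once, by spectral parameterization of the pre-training
#' Laplacian C3 spectrum, and the offline time-frequency ERSP map yields the
#' block-average ERSP at that (integer-bin) IAF; the SEP chain yields the
#' z-scored N20 amplitude; the behavior table yields the fitted saturation
#' speed.
#'
#' @param dataset A `group_dataset`.
#' @param verbose Print one line per subject.
#' @return Long data frame: `subject`, `group`, `time`, `measure`
#'   (`ersp_foi`, `n20_z`, `sat_b`), `value`.
#' @export
group_endpoints <- function(dataset, verbose = FALSE) {
  out <- list()
  for (i in seq_len(nrow(dataset$subjects))) {
    subj <- dataset$subjects$subject[i]
    foi <- NULL
    for (time in c("eval1", "eval2")) {
      ses <- materialize_session(dataset, subj, time)
      map <- ersp_timefreq_map(ses$eeg)
      if (is.null(foi)) {
        # IAF from the parameterized pre-training spectrum, snapped to the
        # 1-Hz bins of the map; fall back to the TF calibration if no peak
        psd <- welch_psd(large_laplacian(ses$eeg), ses$eeg$sampling_rate,
                         segment_s = 2)
        iaf <- find_iaf(parameterize_spectrum(psd))
        foi <- if (is.na(iaf)) calibrate_foi(map) else round(iaf)
      }
      ersp_val <- block_average_ersp(map, foi = foi)
      comp <- extract_all(ses$sep)
      n20 <- comp$amplitude_z[comp$component == "N20"]
      rates <- success_rates(ses$behavior)
      fit <- fit_sat_curve(rates$condition_s, rates$rate)
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, group = dataset$subjects$group[i], time = time,
        measure = c("ersp_foi", "n20_z", "sat_b"),
        value = c(ersp_val, n20, fit$b)
      )
    }
    if (verbose) message(subj, " done")
  }
  do.call(rbind, out)
}

#' Group x time interaction tests for every endpoint
#'
#' @param endpoints Output of [group_endpoints()].
#' @return Data frame: one interaction row per measure, with `F`, `df1`,
#'   `df2`, `p`, `eta_sq`.
#' @export
group_interaction_tests <- function(endpoints) {
  out <- lapply(split(endpoints, endpoints$measure), function(d) {
    res <- mixed_anova_2x2(d, subject = "subject", group = "group",
                           within = "time", value = "value")
    cbind(measure = d$measure[1], res[res$effect == "interaction", ])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
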