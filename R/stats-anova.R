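# Mixed 2x2 repeated-measures ANOVA (one between-subject factor, one
# within-subject factor, two levels each) from an explicit sums-of-squares
# decomposition, and its aligned-rank-transform variant.

check_mixed_design <- function(data, subject, group, within, value) {
  need <- c(subject, group, within, value)
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[[value]])) stop("missing values in the endpoint", call. = FALSE)
  g_lv <- unique(data[[group]]); w_lv <- unique(data[[within]])
  if (length(g_lv) != 2 || length(w_lv) != 2) {
    stop("design must be 2 (group) x 2 (within)", call. = FALSE)
  }
  tab <- table(data[[subject]], data[[within]])
  if (any(tab != 1)) {
    stop("every subject needs exactly one value per within level (no imputation)",
         call. = FALSE)
  }
  sg <- unique(data[, c(subject, group)])
  if (any(table(sg[[group]]) < 2)) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mixed 2x2 repeated-measures ANOVA
#'
#' Classical univariate decomposition for one between-subject factor (group)
#' and one within-subject factor (e.g. time or condition), two levels each.
#' The between stratum tests group against subjects-within-groups; the
#' within stratum tests the within factor and the group x within interaction
#' against the subject x within residual. All tested effects have
#' `df = (1, N - 2)`. Both classical eta-squared (SS_effect / SS_total) and
#' partial eta-squared are reported.
#'
#' @param data Long-format data frame.
#' @param subject,group,within,value Column names.
#' @return Data frame of class `anova_2x2`: one row per effect (`group`,
#'   `within`, `interaction`) with `F`, `df1`, `df2`, `p`, `eta_sq`,
#'   `eta_sq_partial`. The full SS table is attached as attribute `"ss"`.
#' @export
mixed_anova_2x2 <- function(data, subject = "subject", group = "group",
                            within = "within", value = "value") {
  check_mixed_design(data, subject, group, within, value)
  y <- data[[value]]
  s <- as.character(data[[subject]])
  g <- as.character(data[[group]])
  w <- as.character(data[[within]])

  grand <- mean(y)
  n_subj <- length(unique(s))
  m_subj <- tapply(y, s, mean)
  m_g <- tapply(y, g, mean)
  m_w <- tapply(y, w, mean)
  m_gw <- tapply(y, list(g, w), mean)
  subj_group <- tapply(g, s, function(v) v[1])
  n_g <- table(subj_group)                     # subjects per group

  ss_group <- 2 * sum(n_g * (m_g[names(n_g)] - grand)^2)
  ss_subj <- 2 * sum((m_subj - m_g[subj_group[names(m_subj)]])^2)
  ss_within <- n_subj * sum((m_w - grand)^2)
  ss_int <- sum(vapply(names(n_g), function(gi) {
    n_g[[gi]] * sum((m_gw[gi, ] - m_g[[gi]] - m_w + grand)^2)
  }, numeric(1)))
  ss_total <- sum((y - grand)^2)
  ss_err <- ss_total - ss_group - ss_subj - ss_within - ss_int
  ss_err <- max(ss_err, 0)

  df_err <- n_subj - 2L
  safe_f <- function(ss_e, ms_err) if (ms_err > 0) ss_e / ms_err else 0
  ms_subj <- ss_subj / df_err
  ms_err <- ss_err / df_err
  eff <- data.frame(
    effect = c("group", "within", "interaction"),
    F = c(safe_f(ss_group, ms_subj), safe_f(ss_within, ms_err),
          safe_f(ss_int, ms_err)),
    df1 = 1L, df2 = df_err
  )
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  ss_eff <- c(ss_group, ss_within, ss_int)
  err_eff <- c(ss_subj, ss_err, ss_err)
  eff$eta_sq <- if (ss_total > 0) ss_eff / ss_total else 0
  eff$eta_sq_partial <- ifelse(ss_eff + err_eff > 0, ss_eff / (ss_eff + err_eff), 0)
  attr(eff, "ss") <- data.frame(
    term = c("group", "subjects_within_groups", "within", "interaction",
             "error", "total"),
    ss = c(ss_group, ss_subj, ss_within, ss_int, ss_err, ss_total)
  )
  class(eff) <- c("anova_2x2", "data.frame")
  eff
}

#' Aligned-rank-transform mixed 2x2 ANOVA
#'
#' Nonparametric sensitivity analysis: for each effect, responses are
#' aligned (cell-mean residual plus that effect's own estimate), ranked with
#' mid-ranks for ties, and the ranks are analyzed with the same mixed 2x2
#' ANOVA; only the aligned-for effect's row is retained.
#'
#' @inheritParams mixed_anova_2x2
#' @return Data frame of class `anova_2x2` with one row per effect, each
#'   computed from its own aligned ranking.
#' @export
art_anova <- function(data, subject = "subject", group = "group",
                      within = "within", value = "value") {
  check_mixed_design(data, subject, group, within, value)
  y <- data[[value]]
  g <- as.character(data[[group]])
  w <- as.character(data[[within]])
  grand <- mean(y)
  m_g <- tapply(y, g, mean)
  m_w <- tapply(y, w, mean)
  m_gw <- tapply(y, list(g, w), mean)
  cell <- m_gw[cbind(g, w)]
  resid <- y - cell
  estimates <- list(
    group = m_g[g] - grand,
    within = m_w[w] - grand,
    interaction = cell - m_g[g] - m_w[w] + grand
  )
  rows <- lapply(names(estimates), function(effect) {
    d2 <- data
    d2[[value]] <- rank(resid + estimates[[effect]], ties.method = "average")
    res <- mixed_anova_2x2(d2, subject, group, within, value)
    res[res$effect == effect, ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_2x2", "data.frame")
  out
}
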