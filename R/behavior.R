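# Touch-typing behavioral analysis: word-length selection from typing
# capacity, per-condition success rates, exponential speed-accuracy
# trade-off fitting and saturation-speed extraction.

#' Bundled frequency-ranked word list
#'
#' A small synthetic stand-in for a frequency-ranked basic-vocabulary word
#' list, bundled so typing-task simulations can present actual words of the
#' required lengths (columns `word`, `rank`, `length`).
#'
#' @return Data frame with one row per word.
#' @export
bundled_word_list <- function() {
  utils::read.table(system.file("extdata", "wordlist_synthetic.tsv",
                                package = "smrpipe"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Word lengths matching 80-100 percent of typing capacity
#'
#' Capacity is `cpm / 60 * time_limit` characters; usable word lengths are
#' `ceil(0.8 * capacity)` to `floor(capacity)` (at least 1 character). If
#' rounding empties the interval it is widened to the nearest feasible
#' length with a warning.
#'
#' @param cpm Typing speed, characters per minute.
#' @param time_limit_s Movement-time limit, s.
#' @return Integer vector `c(min_len, max_len)`.
#' @export
select_word_lengths <- function(cpm, time_limit_s) {
  if (cpm <= 0) stop("cpm must be positive", call. = FALSE)
  capacity <- cpm / 60 * time_limit_s
  lo <- max(1L, as.integer(ceiling(0.8 * capacity)))
  hi <- max(1L, as.integer(floor(capacity)))
  if (lo > hi) {
    warning("80-100% capacity interval empty after rounding; widened to nearest length")
    lo <- hi <- max(1L, as.integer(round(capacity)))
  }
  c(min_len = lo, max_len = hi)
}

#' Per-condition success rates of a behavior table
#'
#' @param table Data frame with columns `condition_s` and `success` (and
#'   optionally `block`).
#' @param per_block Also return per-block rates.
#' @return Data frame `condition_s`, `rate`, `n` (pooled over blocks), or a
#'   list with `pooled` and `per_block` when `per_block = TRUE`.
#' @export
success_rates <- function(table, per_block = FALSE) {
  if (nrow(table) == 0) stop("empty behavior table", call. = FALSE)
  agg <- stats::aggregate(success ~ condition_s, data = table,
                          FUN = function(s) c(rate = mean(s), n = length(s)))
  pooled <- data.frame(condition_s = agg$condition_s,
                       rate = agg$success[, "rate"],
                       n = as.integer(agg$success[, "n"]))
  if (!per_block) return(pooled)
  pb <- stats::aggregate(success ~ block + condition_s, data = table, FUN = mean)
  names(pb)[names(pb) == "success"] <- "rate"
  list(pooled = pooled, per_block = pb)
}

#' Fit the exponential speed-accuracy trade-off curve
#'
#' Nonlinear least-squares fit of `y = a * exp(-b * x) + c` to per-condition
#' accuracies, with bounded parameters and multi-start initialization over
#' the decay rate. The parameter `b` is the saturation speed: the rate at
#' which accuracy plateaus as the time limit grows.
#'
#' @param x Conditions (time limits, s).
#' @param y Accuracies in `[0, 1]`, same length as `x`.
#' @param b_starts Multi-start grid for `b`.
#' @param lower,upper Parameter bounds, order `(a, b, c)`.
#' @return List of class `sat_fit`: `a`, `b`, `c`, `rss`, `converged`.
#' @export
fit_sat_curve <- function(x, y, b_starts = c(0.1, 0.5, 1, 2),
                          lower = c(0, 0, 0), upper = c(1.5, 10, 1)) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need >= 3 (x, y) points", call. = FALSE)
  }
  best <- NULL
  resid_fn <- function(p) y - (p[1] * exp(-p[2] * x) + p[3])
  for (b0 in b_starts) {
    a0 <- clamp(max(y) - min(y), lower[1] + 1e-6, upper[1])
    c0 <- clamp(min(y), lower[3], upper[3])
    fit <- try(minpack.lm::nls.lm(
      par = c(a0, b0, c0), lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) {
      p <- fit$par
      best <- list(a = p[1], b = p[2], c = p[3], rss = rss,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    warning("speed-accuracy fit failed to converge from every start")
    best <- list(a = NA_real_, b = NA_real_, c = NA_real_, rss = NA_real_,
                 converged = FALSE)
  }
  class(best) <- "sat_fit"
  best
}

#' Saturation speed of a fitted speed-accuracy curve
#'
#' @param fit A `sat_fit`.
#' @param boundary_tol Values of `b` below this are flagged as boundary
#'   estimates with a warning.
#' @return The decay rate `b` (1/s).
#' @export
saturation_speed <- function(fit, boundary_tol = 1e-6) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (fit$b <= boundary_tol) {
    warning("saturation speed at the lower boundary (flat curve)")
  }
  fit$b
}
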