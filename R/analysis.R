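#' Per-period Phi and reward rates for a session
#'
#' Splits the session into equal periods (8 by default, for finer temporal
#' resolution than whole-session Phi), computes [robust_phi()] per period,
#' and normalizes each Phi by the number of neurons actually used, since a
#' smaller system has a smaller state repertoire and generates less
#' information. Reward rates are normalized by period duration because
#' session lengths differ.
#'
#' @param session a [session_data] with reward events.
#' @param config list of settings: `method` ("mib", "atomic", "louvain"),
#'   `bin_size` (s, default 0.03), `lag_bins` (default 1), `n_periods`
#'   (default 8), `top_k` (optional 15-neuron restriction), `alpha`, `seed`,
#'   `reward_label` (default "reward"), `session_id`, `day`.
#' @return data frame of period records: `session_id`, `day`,
#'   `period_index` (0-based), `phi_normalized`, `n_neurons_used`,
#'   `reward_rate` (rewards per second), `duration_s`, `n_removed`. Periods
#'   where Phi is uncomputable yield `NA` phi with a warning and are later
#'   excluded from correlations.
#' @export
period_phi <- function(session, config = list()) {
  stopifnot(inherits(session, "session_data"))
  cfg <- utils::modifyList(list(
    method = "atomic", bin_size = 0.03, lag_bins = 1, n_periods = 8,
    top_k = NULL, alpha = 0.05, seed = 0, normalize = TRUE, cap = 15,
    reward_label = "reward", session_id = "session", day = 1L), config)
  binned <- binarize(session, cfg$bin_size)
  periods <- split_periods(binned, cfg$n_periods)
  rewards <- session$events$time_s[session$events$label == cfg$reward_label]
  results <- vector("list", length(periods))
  out <- lapply(seq_along(periods), function(p) {
    b <- periods[[p]]
    dur <- ncol(b$states) * b$bin_size
    t0 <- b$t_start
    n_rew <- sum(rewards >= t0 - .TIME_EPS & rewards < t0 + dur - .TIME_EPS)
    res <- tryCatch(
      robust_phi(b, method = cfg$method, lag_bins = cfg$lag_bins,
                 top_k = cfg$top_k, alpha = cfg$alpha, seed = cfg$seed,
                 normalize = cfg$normalize, cap = cfg$cap),
      error = function(e) e)
    if (inherits(res, "condition")) {
      warning(sprintf("period %d failed: %s", p - 1L, conditionMessage(res)))
      data.frame(session_id = cfg$session_id, day = cfg$day,
                 period_index = p - 1L, phi_normalized = NA_real_,
                 n_neurons_used = NA_integer_, reward_rate = n_rew / dur,
                 duration_s = dur, n_removed = NA_integer_)
    } else {
      results[[p]] <<- res
      nu <- length(res$neurons_used)
      data.frame(session_id = cfg$session_id, day = cfg$day,
                 period_index = p - 1L, phi_normalized = res$phi / nu,
                 n_neurons_used = nu, reward_rate = n_rew / dur,
                 duration_s = dur,
                 n_removed = nrow(attr(res, "removal_log")))
    }
  })
  records <- do.call(rbind, out)
  attr(records, "phi_results") <- results
  records
}

#' Average period records across the sessions of a day
#'
#' Days with two sessions get the arithmetic mean of the two sessions'
#' values per period; single-session days pass through. Missing Phi values
#' are ignored in the mean.
#'
#' @param records a period-record data frame (rows from [period_phi()]) with
#'   a `day` column.
#' @return data frame keyed by (`day`, `period_index`) with averaged
#'   `phi_normalized` and `reward_rate`.
#' @export
day_average <- function(records) {
  stopifnot(all(c("day", "period_index", "phi_normalized", "reward_rate")
                %in% names(records)))
  agg <- stats::aggregate(
    cbind(phi_normalized, reward_rate) ~ day + period_index,
    data = records, FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  agg[order(agg$day, agg$period_index), , drop = FALSE]
}

#' Spearman rank correlation with Student-t significance test
#'
#' Rho is the Pearson correlation of mid-rank-transformed values; the null
#' of no association is tested two-sided with
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on `n - 2` degrees of freedom.
#' Pairs with a missing member are dropped.
#'
#' @param x,y numeric vectors of equal length (at least 4 complete pairs).
#' @param alpha_corrected significance threshold the report is judged
#'   against (e.g. a Bonferroni-corrected level).
#' @return object of class `correlation_report`: `rho`, `p_value`, `n`,
#'   `alpha_corrected`, `significant`.
#' @export
spearman_correlation <- function(x, y, alpha_corrected = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4 || length(y) != n) stop("need at least 4 complete pairs")
  if (max(x) == min(x) || max(y) == min(y))
    stop("undefined correlation: constant input")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n,
                 alpha_corrected = alpha_corrected,
                 significant = p < alpha_corrected),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  stars <- if (x$p_value < x$alpha_corrected / 5) "**"
           else if (x$significant) "*" else "ns"
  cat(sprintf("correlation_report: rho = %.4f, p = %.4g (n = %d) %s at alpha %.4g\n",
              x$rho, x$p_value, x$n, stars, x$alpha_corrected))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level.
#' @param n_hypotheses number of tested hypotheses; with the conventional
#'   family of 15 tests, `0.05/15 = 0.0034` (4 d.p.).
#' @return `alpha / n_hypotheses`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_hypotheses = 1) {
  stopifnot(alpha > 0, alpha < 1, n_hypotheses >= 1)
  alpha / n_hypotheses
}

#' Correlate per-period Phi with reward rate
#'
#' Applies [spearman_correlation()] to the complete `(phi_normalized,
#' reward_rate)` pairs of a period-record table, judged against the
#' Bonferroni-corrected level `alpha / n_hypotheses`.
#'
#' @param records period records from [period_phi()] (possibly several
#'   sessions row-bound, or [day_average()] output).
#' @param n_hypotheses Bonferroni family size (default 15).
#' @param alpha family-wise level (default 0.05).
#' @return a `correlation_report`.
#' @export
correlate_phi_rewards <- function(records, n_hypotheses = 15, alpha = 0.05) {
  stopifnot(all(c("phi_normalized", "reward_rate") %in% names(records)))
  spearman_correlation(records$phi_normalized, records$reward_rate,
                       alpha_corrected = bonferroni_alpha(alpha, n_hypotheses))
}
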