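#' Bernoulli variance of a binary activity sequence
#'
#' For on-fraction `p`, the Bernoulli variance is `p(1-p)`: zero for a
#' neuron always on or always off, maximal (1/4) when on and off bins are
#' equally frequent. Being order-free, it misses long on/off runs, but it is
#' cheap and is the ranking used both for top-k selection and for the
#' rank-deficiency removal loop.
#'
#' @param binned_row binary vector (a row of a [binned_matrix]).
#' @param neuron_id optional label carried into the result.
#' @return list with `neuron_id`, `on_fraction`, `bernoulli_variance`.
#' @export
bernoulli_variance <- function(binned_row, neuron_id = NA_character_) {
  if (!length(binned_row)) stop("empty sequence")
  p <- mean(binned_row)
  list(neuron_id = neuron_id, on_fraction = p, bernoulli_variance = p * (1 - p))
}

.row_variances <- function(binned) {
  p <- rowMeans(binned$states)
  p * (1 - p)
}

#' Keep the k most variable neurons
#'
#' Rows with the `k` largest Bernoulli variances are kept, preserving their
#' original relative order; ties at the cutoff go to the lower original row
#' index. Mirrors the 15-neuron restriction that makes the brute-force
#' bipartition search tractable.
#'
#' @param binned a [binned_matrix].
#' @param k number of neurons to keep (default 15).
#' @return a [binned_matrix] with at most `k` rows.
#' @export
select_top_k <- function(binned, k = 15) {
  stopifnot(inherits(binned, "binned_matrix"), k >= 2)
  N <- nrow(binned$states)
  if (k >= N) {
    if (k > N) warning("fewer than k neurons available; returning all")
    return(binned)
  }
  v <- .row_variances(binned)
  keep <- sort(order(-v, seq_len(N))[seq_len(k)])
  binned_matrix(binned$states[keep, , drop = FALSE], binned$bin_size,
                binned$neuron_ids[keep], binned$t_start)
}

#' Phi with automatic removal of rank-deficiency-causing neurons
#'
#' Attempts the full Phi computation for the chosen partition method. When a
#' covariance block is numerically singular (typically an almost-always-off
#' neuron), the neuron with the lowest Bernoulli variance over the analyzed
#' window is removed and the computation retried, until a valid value is
#' obtained or fewer than two neurons remain.
#'
#' @param binned a [binned_matrix] (a session period, usually).
#' @param method `"mib"` (brute-force bipartition search), `"atomic"`, or
#'   `"louvain"`.
#' @param lag_bins lag in bins.
#' @param top_k optional: restrict to the `top_k` most variable neurons
#'   before starting (the 15-neuron approximation and its Louvain/atomic
#'   hybrids).
#' @param alpha edge significance level for the Louvain method.
#' @param seed Louvain seed.
#' @param normalize passed to [phi_ar()]/[mib_search()].
#' @param cap bipartition enumeration cap for `"mib"`.
#' @return a `phi_result`; `neurons_used` holds the survivors and attribute
#'   `"removal_log"` a data frame of removals (neuron_id, variance, attempt).
#' @export
robust_phi <- function(binned, method = c("mib", "atomic", "louvain"),
                       lag_bins = 1, top_k = NULL, alpha = 0.05, seed = 0,
                       normalize = TRUE, cap = 15) {
  method <- match.arg(method)
  stopifnot(inherits(binned, "binned_matrix"))
  if (!is.null(top_k)) binned <- select_top_k(binned, top_k)
  removal_log <- data.frame(neuron_id = character(0), variance = numeric(0),
                            attempt = integer(0))
  attempt <- 0L
  cur <- binned
  repeat {
    attempt <- attempt + 1L
    if (nrow(cur$states) < 2)
      stop("system degenerate: fewer than 2 usable neurons")
    res <- tryCatch({
      model <- estimate_gaussian_model(cur, lag_bins)
      switch(method,
        mib = mib_search(model, normalize = normalize, cap = cap),
        atomic = phi_ar(model, atomic_partition(nrow(cur$states)),
                        normalize = normalize),
        louvain = phi_ar(model,
                         louvain_partition(cur, alpha = alpha, seed = seed),
                         normalize = normalize))
    }, phispike_rank_deficient = function(e) e)
    if (!inherits(res, "condition")) {
      attr(res, "removal_log") <- removal_log
      return(res)
    }
    v <- .row_variances(cur)
    drop_i <- order(v, seq_along(v))[1]     # lowest variance, ties to low index
    removal_log <- rbind(removal_log, data.frame(
      neuron_id = cur$neuron_ids[drop_i], variance = v[drop_i],
      attempt = attempt))
    cur <- binned_matrix(cur$states[-drop_i, , drop = FALSE], cur$bin_size,
                         cur$neuron_ids[-drop_i], cur$t_start)
  }
}
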