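## big-integer helpers (non-negative, base-1e9 limbs, little-endian numeric
## vectors) — enough for Bell-triangle addition at any practical n
.BIG_BASE <- 1e9

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% .BIG_BASE
    s[i] <- s[i] %% .BIG_BASE
  }
  if (carry > 0) s <- c(s, carry)
  s
}

big_to_string <- function(a) {
  a <- rev(a)
  paste0(sub("^0+(?=.)", "", paste0(sprintf("%09.0f", a), collapse = ""),
             perl = TRUE))
}

#' Number of unordered bipartitions of an n-element system
#'
#' The Stirling number of the second kind with two parts,
#' \eqn{S_n(2) = 2^{n-1} - 1}: the size of the search space of the
#' minimum-information bipartition.
#'
#' @param n system size, at least 2.
#' @return exact integer-valued numeric (`n <= 53`).
#' @export
count_bipartitions <- function(n) {
  if (n < 2) stop("n must be at least 2")
  if (n > 53) stop("result exceeds exact double-precision range")
  2^(n - 1) - 1
}

#' Bell number: count of all set partitions
#'
#' The full minimum-information-partition search space grows as the Bell
#' number \eqn{B_n}, which quickly leaves double precision
#' (\eqn{B_{25} \approx 4.6\times 10^{18}}), so the value is computed exactly
#' with the Bell-triangle recurrence on big integers and returned as a
#' decimal string.
#'
#' @param n non-negative integer.
#' @return exact decimal string, e.g. `bell_number(10)` is `"115975"`.
#' @export
bell_number <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("1")
  row <- list(1)  # triangle row: list of big ints (numeric limb vectors)
  for (i in seq_len(n)) {
    prev <- row
    row <- vector("list", i + 1)
    row[[1]] <- prev[[length(prev)]]
    for (k in seq_len(i)) row[[k + 1]] <- big_add(row[[k]], prev[[k]])
  }
  big_to_string(row[[1]])
}

#' Enumerate all unordered bipartitions
#'
#' Each bipartition appears exactly once in canonical form: the subset
#' containing index 1 is listed first and subsets are internally sorted.
#' Order is by size of the first subset, then lexicographic — a deterministic
#' tie-breaking order for the minimum search.
#'
#' @param n system size.
#' @param cap refuse enumeration above this size (default 15, the practical
#'   brute-force limit on commodity hardware; a hardware statement, not a
#'   method constant).
#' @return list of [phi_partition] objects of length `2^(n-1) - 1`.
#' @export
enumerate_bipartitions <- function(n, cap = 15) {
  if (n < 2) stop("n must be at least 2")
  if (n > cap)
    stop("system size ", n, " exceeds enumeration cap ", cap,
         "; use an approximate partition (atomic or louvain)")
  rest <- seq_len(n)[-1]
  out <- vector("list", count_bipartitions(n))
  pos <- 0L
  for (s1 in seq_len(n - 1)) {
    picks <- if (s1 == 1) list(integer(0)) else
      utils::combn(rest, s1 - 1, simplify = FALSE)
    for (p in picks) {
      first <- c(1L, p)
      pos <- pos + 1L
      out[[pos]] <- phi_partition(list(first, setdiff(seq_len(n), first)))
    }
  }
  out
}

#' Brute-force minimum information bipartition search
#'
#' Evaluates [phi_ar()] for every bipartition and returns the result with the
#' minimal (by default normalized) Phi — the system's informational weakest
#' cut. Bipartitions whose covariance blocks are rank-deficient are skipped
#' and counted in the result's warnings; the search fails only when every
#' bipartition fails.
#'
#' @param model a `gaussian_model`.
#' @param normalize minimize the normalized value (default) or the raw one.
#' @param cap enumeration cap, passed to [enumerate_bipartitions()].
#' @return the minimizing `phi_result`; ties go to the first candidate in
#'   canonical enumeration order.
#' @export
mib_search <- function(model, normalize = TRUE, cap = 15) {
  stopifnot(inherits(model, "gaussian_model"))
  N <- length(model$neuron_ids)
  parts <- enumerate_bipartitions(N, cap = cap)
  best <- NULL
  skipped <- 0L
  for (p in parts) {
    res <- tryCatch(phi_ar(model, p, normalize = normalize),
                    phispike_rank_deficient = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    if (is.null(best) || res$phi < best$phi) best <- res
  }
  if (is.null(best))
    stop_rank_deficient("all bipartitions rank-deficient")
  if (skipped > 0)
    best$warnings <- c(best$warnings,
                       sprintf("skipped_bipartitions=%d", skipped))
  best
}
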