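#' Second-order (Gaussian) model of a binned state sequence
#'
#' All autoregressive Phi terms derive from two matrices: the equal-time
#' covariance of the state vectors and the lagged cross-covariance between
#' states `lag_bins` apart. Means are removed per neuron over the usable
#' window (the first `bins - lag_bins` time points), so that a neuron copied
#' forward by exactly `lag_bins` reproduces its own variance in the lagged
#' matrix.
#'
#' @param binned a [binned_matrix] (or any numeric matrix via `as_matrix`).
#' @param lag_bins lag between past and future states, in bins (>= 1).
#' @return object of class `gaussian_model` with fields `cov0` (N x N
#'   equal-time covariance), `covlag` (`covlag[i, j] = cov(X_t[i],
#'   X_{t+lag}[j])`), `lag_bins`, `n_samples`, `neuron_ids`, and `degenerate`
#'   (ids of neurons constant over the window — flagged, not dropped).
#' @export
estimate_gaussian_model <- function(binned, lag_bins = 1) {
  X <- if (inherits(binned, "binned_matrix")) binned$states else as.matrix(binned)
  ids <- if (inherits(binned, "binned_matrix")) binned$neuron_ids else
    rownames(X) %||% paste0("n", seq_len(nrow(X)))
  N <- nrow(X); Tn <- ncol(X)
  stopifnot(lag_bins >= 1)
  if (Tn < lag_bins + N + 2)
    stop("too few bins: need at least lag_bins + N + 2 columns")
  n <- Tn - lag_bins
  X0 <- t(X[, seq_len(n), drop = FALSE])            # samples x neurons, past
  X1 <- t(X[, lag_bins + seq_len(n), drop = FALSE]) # future
  X0c <- scale(X0, center = TRUE, scale = FALSE)
  X1c <- scale(X1, center = TRUE, scale = FALSE)
  cov0 <- crossprod(X0c) / (n - 1)
  covlag <- crossprod(X0c, X1c) / (n - 1)
  cov0 <- (cov0 + t(cov0)) / 2
  degenerate <- ids[apply(X0, 2, function(v) max(v) == min(v))]
  dimnames(cov0) <- dimnames(covlag) <- list(ids, ids)
  structure(list(cov0 = cov0, covlag = covlag, lag_bins = lag_bins,
                 n_samples = n, neuron_ids = ids, degenerate = degenerate),
            class = "gaussian_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a Gaussian model from known matrices
#'
#' Used for analytic models (e.g. a VAR(1) process whose stationary
#' covariance is known in closed form) and in tests.
#'
#' @param cov0 equal-time covariance, symmetric PSD.
#' @param covlag lagged cross-covariance, `covlag[i, j] = cov(X_t[i],
#'   X_{t+lag}[j])`.
#' @param lag_bins lag in bins.
#' @param n_samples nominal sample count (only recorded).
#' @param neuron_ids optional labels.
#' @return a `gaussian_model`.
#' @export
gaussian_model <- function(cov0, covlag, lag_bins = 1, n_samples = Inf,
                           neuron_ids = NULL) {
  cov0 <- as.matrix(cov0); covlag <- as.matrix(covlag)
  stopifnot(nrow(cov0) == ncol(cov0), all(dim(cov0) == dim(covlag)),
            lag_bins >= 1)
  if (max(abs(cov0 - t(cov0))) > 1e-10) stop("cov0 must be symmetric")
  ids <- neuron_ids %||% rownames(cov0) %||% paste0("n", seq_len(nrow(cov0)))
  dimnames(cov0) <- dimnames(covlag) <- list(ids, ids)
  structure(list(cov0 = (cov0 + t(cov0)) / 2, covlag = covlag,
                 lag_bins = lag_bins, n_samples = n_samples,
                 neuron_ids = as.character(ids), degenerate = character(0)),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("gaussian_model: %d neurons, lag %d bins, %s samples%s\n",
              length(x$neuron_ids), x$lag_bins, format(x$n_samples),
              if (length(x$degenerate))
                paste0(" (degenerate: ", paste(x$degenerate, collapse = ","), ")")
              else ""))
  invisible(x)
}

#' Residual covariance of the linear self-prediction of a subset
#'
#' For the neurons in `subset`, regresses their future state on their own past
#' state (least squares, no intercept after mean removal) and returns the
#' covariance of the residuals:
#' \deqn{\Sigma(E) = S_{00} - S_{01}^T S_{00}^{-1} S_{01}}
#' where \eqn{S_{00}}, \eqn{S_{01}} are the subset blocks of the equal-time
#' and lagged covariance. A singular or ill-conditioned \eqn{S_{00}}
#' (determinant <= 0 or condition number > 1e12) raises a rank-deficiency
#' condition which [robust_phi()] converts into neuron removal.
#'
#' @param model a `gaussian_model`.
#' @param subset integer indices (1-based) of the neurons to predict.
#' @return the residual covariance matrix of the subset.
#' @export
residual_covariance <- function(model, subset) {
  stopifnot(inherits(model, "gaussian_model"), length(subset) >= 1)
  S00 <- model$cov0[subset, subset, drop = FALSE]
  S01 <- model$covlag[subset, subset, drop = FALSE]
  logdet_pd(S00, "subset covariance")  # rank gate
  E <- S00 - crossprod(S01, solve(S00, S01))
  (E + t(E)) / 2
}

#' A partition of neuron indices into disjoint subsets
#'
#' @param subsets list of disjoint, non-empty integer vectors covering
#'   `1..n`.
#' @return object of class `phi_partition`.
#' @export
phi_partition <- function(subsets) {
  subsets <- lapply(subsets, function(s) sort(as.integer(s)))
  if (!length(subsets) || any(lengths(subsets) == 0))
    stop("subsets must be non-empty")
  all_idx <- sort(unlist(subsets))
  n <- length(all_idx)
  if (any(duplicated(all_idx)) || !identical(all_idx, seq_len(n)))
    stop("subsets must be disjoint and cover 1..n")
  structure(list(subsets = subsets, r = length(subsets), n = n),
            class = "phi_partition")
}

#' The atomic (all-singletons) partition
#'
#' Every neuron forms its own subset — the fastest Phi approximation; it
#' ignores information generated jointly by neuron clusters.
#'
#' @param n system size.
#' @return a [phi_partition] with `r = n`.
#' @export
atomic_partition <- function(n) {
  stopifnot(n >= 1)
  phi_partition(as.list(seq_len(n)))
}

#' @export
print.phi_partition <- function(x, ...) {
  cat(sprintf("phi_partition: %d subsets of %d elements: %s\n", x$r, x$n,
              paste(vapply(x$subsets, function(s)
                paste0("{", paste(s, collapse = ","), "}"), character(1)),
                collapse = " | ")))
  invisible(x)
}

#' Autoregressive integrated information for a given partition
#'
#' The information lost when the linear self-prediction of the whole system
#' is replaced by independent self-predictions of the partition's subsets:
#' \deqn{\Phi_{raw} = \tfrac12 \ln\frac{\det\Sigma(X)}{\det\Sigma(E_X)}
#'   - \sum_{k=1}^{r} \tfrac12 \ln\frac{\det\Sigma(M_k)}{\det\Sigma(E_{M_k})}}
#' (natural logarithms). The normalization factor
#' \eqn{L(M) = \tfrac12 \ln[\min_k (2\pi e)^{|M_k|}\det\Sigma(M_k)]}
#' diminishes the influence of unequal subset sizes; the normalized value is
#' `phi_raw / L(M)`. The original formulation is a bipartition; the sum is
#' generalized here to any number of subsets so the same expression serves
#' the atomic and community partitions.
#'
#' @param model a `gaussian_model`.
#' @param partition a [phi_partition] over the model's neurons.
#' @param normalize divide by L(M)? If L(M) <= 1e-9 the raw value is returned
#'   with a `"normalization_degenerate"` warning flag instead of dividing.
#' @return object of class `phi_result`: fields `phi`, `phi_raw`,
#'   `normalization`, `partition`, `neurons_used`, `lag_bins`, `warnings`.
#' @export
phi_ar <- function(model, partition, normalize = TRUE) {
  stopifnot(inherits(model, "gaussian_model"),
            inherits(partition, "phi_partition"))
  N <- length(model$neuron_ids)
  if (partition$n != N) stop("partition size does not match model")
  warnings <- character(0)
  if (partition$r < 2) {
    return(structure(list(phi = 0, phi_raw = 0, normalization = NA_real_,
                          partition = partition,
                          neurons_used = model$neuron_ids,
                          lag_bins = model$lag_bins,
                          warnings = "single-subset partition: phi is 0 by definition"),
                     class = "phi_result"))
  }
  whole <- seq_len(N)
  ld_cov_whole <- logdet_pd(model$cov0, "system covariance")
  E_whole <- residual_covariance(model, whole)
  ld_res_whole <- logdet_pd(E_whole, "system residual covariance")
  term_whole <- 0.5 * (ld_cov_whole - ld_res_whole)
  term_parts <- 0
  norm_terms <- numeric(partition$r)
  for (k in seq_len(partition$r)) {
    s <- partition$subsets[[k]]
    ld_cov <- logdet_pd(model$cov0[s, s, drop = FALSE], "subset covariance")
    Ek <- residual_covariance(model, s)
    ld_res <- logdet_pd(Ek, "subset residual covariance")
    term_parts <- term_parts + 0.5 * (ld_cov - ld_res)
    norm_terms[k] <- length(s) * log(2 * pi * exp(1)) + ld_cov
  }
  phi_raw <- term_whole - term_parts
  if (!is.finite(phi_raw)) stop("non-finite phi value")
  L <- 0.5 * min(norm_terms)
  if (normalize && L > .NORM_EPS) {
    phi <- phi_raw / L
  } else {
    phi <- phi_raw
    if (normalize) {
      warnings <- c(warnings, "normalization_degenerate")
      L <- NA_real_
    } else L <- NA_real_
  }
  structure(list(phi = phi, phi_raw = phi_raw, normalization = L,
                 partition = partition, neurons_used = model$neuron_ids,
                 lag_bins = model$lag_bins, warnings = warnings),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("phi_result: phi = %.6g (raw %.6g, L = %s), %d neurons, r = %d, lag %d bins\n",
              x$phi, x$phi_raw,
              if (is.na(x$normalization)) "NA" else sprintf("%.4g", x$normalization),
              length(x$neurons_used), x$partition$r, x$lag_bins))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a phi_result to JSON
#'
#' @param x a `phi_result`.
#' @param path optional file; if `NULL`, the JSON string is returned.
#' @export
phi_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "phi_result"))
  obj <- list(
    phi = x$phi, phi_raw = x$phi_raw,
    normalization = if (is.na(x$normalization)) NULL else x$normalization,
    lag_bins = x$lag_bins,
    partition = lapply(x$partition$subsets, function(s) x$neurons_used[s]),
    neurons_used = x$neurons_used,
    warnings = x$warnings
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
  }
}

#' Discrete-entropy Phi for tiny binary systems
#'
#' Plug-in estimator of the classic conditional-entropy formulation
#' \deqn{\Phi = \sum_{k=1}^{r} H(M_{t,k} \mid M_{t+\Delta t,k})
#'   - H(X_t \mid X_{t+\Delta t})}
#' over the empirical joint distribution of `(X_t, X_{t+lag})`, in nats.
#' Exact state-space enumeration limits this to at most 10 binary nodes; it
#' serves as an independent oracle for the autoregressive estimator, not as a
#' practical method.
#'
#' @param binned a [binned_matrix] with at most 10 neurons.
#' @param lag_bins lag in bins.
#' @param partition a [phi_partition].
#' @return the discrete Phi value for this partition (no partition search).
#' @export
phi_discrete <- function(binned, lag_bins, partition) {
  stopifnot(inherits(binned, "binned_matrix"),
            inherits(partition, "phi_partition"), lag_bins >= 1)
  X <- binned$states
  N <- nrow(X)
  if (N > 10) stop("oracle restricted to small systems (N <= 10)")
  if (partition$n != N) stop("partition size does not match data")
  Tn <- ncol(X)
  n <- Tn - lag_bins
  if (n < 2) stop("too few bins for the requested lag")
  code <- function(rows) {
    ## integer encoding of the sub-state of `rows` at past and future times
    w <- 2^(seq_along(rows) - 1)
    past <- drop(w %*% X[rows, seq_len(n), drop = FALSE])
    fut <- drop(w %*% X[rows, lag_bins + seq_len(n), drop = FALSE])
    list(past = past, fut = fut)
  }
  cond_entropy <- function(rows) {
    z <- code(rows)
    joint <- table(z$past, z$fut) / n
    margB <- table(z$fut) / n
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    H(as.numeric(joint)) - H(as.numeric(margB))
  }
  if (partition$r < 2) return(0)
  sum(vapply(partition$subsets, cond_entropy, numeric(1))) -
    cond_entropy(seq_len(N))
}
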