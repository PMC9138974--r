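# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (plain det()/solve(), recursive enumeration,
# direct formula transcription) so agreement is evidence, not tautology.

## stationary VAR(1) model with known second-order statistics:
## X_{t+1} = A X_t + e, e ~ N(0, Q); Sigma0 solves the discrete Lyapunov
## equation and cov(X_t, X_{t+1}) = Sigma0 t(A)
random_var_model <- function(n, seed, spectral = 0.6, lag = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  A <- A * spectral / max(Mod(eigen(A, only.values = TRUE)$values))
  B <- matrix(rnorm(n * n, sd = 0.3), n)
  Q <- diag(n) + B %*% t(B)
  S0 <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Q)), n)
  S0 <- (S0 + t(S0)) / 2
  list(A = A, Q = Q, cov0 = S0, covlag = S0 %*% t(A),
       model = gaussian_model(S0, S0 %*% t(A), lag_bins = lag))
}

simulate_var <- function(A, Q, n_samples, seed, burn = 200) {
  set.seed(seed)
  n <- nrow(A)
  L <- chol(Q)
  X <- matrix(0, n, n_samples + burn)
  for (t in 2:(n_samples + burn))
    X[, t] <- A %*% X[, t - 1] + drop(t(L) %*% rnorm(n))
  X[, burn + seq_len(n_samples), drop = FALSE]
}

## direct transcription of the phi formula: no log-space determinants,
## explicit inverse
naive_phi_ar <- function(cov0, covlag, subsets, normalize = TRUE) {
  resid <- function(s) {
    S00 <- cov0[s, s, drop = FALSE]
    S01 <- covlag[s, s, drop = FALSE]
    S00 - t(S01) %*% solve(S00) %*% S01
  }
  term <- function(s) 0.5 * log(det(cov0[s, s, drop = FALSE]) / det(resid(s)))
  all_idx <- seq_len(nrow(cov0))
  raw <- term(all_idx) - sum(vapply(subsets, term, numeric(1)))
  L <- 0.5 * log(min(vapply(subsets, function(s)
    (2 * pi * exp(1))^length(s) * det(cov0[s, s, drop = FALSE]), numeric(1))))
  if (normalize && L > 1e-9) raw / L else raw
}

## naive bitmask double-loop bipartition minimum
naive_mib <- function(cov0, covlag, normalize = TRUE) {
  n <- nrow(cov0)
  best <- Inf
  best_parts <- NULL
  for (mask in 0:(2^(n - 1) - 2)) {
    s1 <- c(1L, which(bitwAnd(mask, 2^(0:(n - 2))) > 0) + 1L)
    s2 <- setdiff(seq_len(n), s1)
    v <- naive_phi_ar(cov0, covlag, list(s1, s2), normalize)
    if (v < best) { best <- v; best_parts <- list(s1, s2) }
  }
  list(phi = best, subsets = best_parts)
}

## all set partitions of 1..n by recursion (Bell(n) of them)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], as.integer(n))
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(as.integer(n)))
  }
  out
}

## direct ordered-pair transcription of the modularity formula
naive_modularity <- function(W, comm) {
  m <- sum(W) / 2
  k <- rowSums(W)
  tot <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (comm[i] == comm[j]) tot <- tot + W[i, j] - k[i] * k[j] / (2 * m)
  tot / (2 * m)
}

## two disconnected unit-weight triangles on nodes 1:3 and 4:6
two_triangles <- function() {
  W <- matrix(0, 6, 6)
  for (tri in list(1:3, 4:6)) {
    e <- cbind(tri, tri[c(2, 3, 1)])
    W[e] <- 1
    W[e[, 2:1]] <- 1
  }
  W
}

rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

## binned fixture of independent Bernoulli rows
coin_binned <- function(n_neurons, n_bins, p = 0.5, seed = 1) {
  set.seed(seed)
  binned_matrix(matrix(rbinom(n_neurons * n_bins, 1, p), n_neurons),
                bin_size = 0.03)
}

## small session written to temp CSVs; returns the paths
write_temp_session <- function(session, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_session_csv(session, dir)
}
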