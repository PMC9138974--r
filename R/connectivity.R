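#' Significance-thresholded spike-correlation connectivity matrix
#'
#' For each neuron pair, the Pearson correlation of the binary bin sequences
#' at zero lag is tested against the null of no relationship (two-sided
#' p-value from the t transform with `bins - 2` degrees of freedom). The
#' connectivity weight is `|r|` when `p < alpha` and exactly 0 otherwise.
#' Constant neurons have undefined correlations and get all-zero rows.
#'
#' @param binned a [binned_matrix] with at least 2 neurons and 10 bins.
#' @param alpha edge significance level (default 0.05); no multiple-testing
#'   correction is applied across the `N(N-1)/2` pair tests.
#' @param method `"pearson"` (default) or `"spearman"` rank correlation.
#' @return object of class `connectivity_matrix`: fields `weights`
#'   (symmetric, zero diagonal), `alpha`, `neuron_ids`.
#' @export
connectivity_matrix <- function(binned, alpha = 0.05,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(binned, "binned_matrix"))
  X <- t(binned$states)
  n <- nrow(X); N <- ncol(X)
  if (N < 2) stop("need at least 2 neurons")
  if (n < 10) stop("need at least 10 bins")
  stopifnot(alpha > 0, alpha < 1)
  if (method == "spearman") X <- apply(X, 2, rank)
  r <- suppressWarnings(stats::cor(X))
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  A <- ifelse(p < alpha, abs(r), 0)
  diag(A) <- 0
  dimnames(A) <- list(binned$neuron_ids, binned$neuron_ids)
  structure(list(weights = A, alpha = alpha, neuron_ids = binned$neuron_ids),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectivity_matrix: %d neurons, %d significant edges (alpha %.3g)\n",
              length(x$neuron_ids), ne, x$alpha))
  invisible(x)
}

#' Write a connectivity matrix as an edge list or dense CSV
#'
#' @param A a `connectivity_matrix`.
#' @param path output file.
#' @param layout `"edges"` (i,j,weight rows for significant pairs) or
#'   `"dense"`.
#' @export
write_connectivity_csv <- function(A, path, layout = c("edges", "dense")) {
  layout <- match.arg(layout)
  stopifnot(inherits(A, "connectivity_matrix"))
  if (layout == "edges") {
    idx <- which(upper.tri(A$weights) & A$weights > 0, arr.ind = TRUE)
    df <- data.frame(i = A$neuron_ids[idx[, 1]], j = A$neuron_ids[idx[, 2]],
                     weight = A$weights[idx])
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(neuron_id = A$neuron_ids, A$weights,
                                check.names = FALSE), path, row.names = FALSE)
  }
  invisible(path)
}

## modularity of a community labeling over a general weighted matrix
## (self-loops permitted; used on aggregated graphs during Louvain).
## m = sum(W)/2, k_i = row sums; M = sum_c [ Sin_c/(2m) - (Stot_c/(2m))^2 ]
.modularity_general <- function(W, comm) {
  m2 <- sum(W)               # 2m
  if (m2 <= 0) stop("empty graph")
  k <- rowSums(W)
  M <- 0
  for (c in unique(comm)) {
    idx <- which(comm == c)
    M <- M + sum(W[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  M
}

#' Modularity of a community assignment
#'
#' Newman modularity
#' \deqn{M = \frac{1}{2m}\sum_{i,j}\left(A_{ij} -
#'   \frac{k_i k_j}{2m}\right)\delta(c_i, c_j)}
#' with `m` half the total weight of the symmetric matrix (each undirected
#' edge counted once) and `k_i` the weighted degree.
#'
#' @param A a `connectivity_matrix` (or plain symmetric matrix).
#' @param communities integer vector of community ids, one per node, or a
#'   `community_assignment`.
#' @return the modularity value.
#' @export
modularity_score <- function(A, communities) {
  W <- if (inherits(A, "connectivity_matrix")) A$weights else as.matrix(A)
  if (inherits(communities, "community_assignment"))
    communities <- communities$community_of
  stopifnot(length(communities) == nrow(W))
  .modularity_general(W, communities)
}

## one Louvain level: greedy local moves on weight matrix W (may have
## self-loops). Returns community vector (not relabeled). Node visit order is
## shuffled once from the current RNG stream.
.louvain_one_level <- function(W, init = seq_len(nrow(W))) {
  n <- nrow(W)
  m2 <- sum(W)                      # 2m
  k <- rowSums(W)
  comm <- init
  tot <- vapply(seq_len(n), function(c) sum(k[comm == c]), numeric(1))
  order_ <- sample.int(n)
  repeat {
    improved <- FALSE
    for (i in order_) {
      ci <- comm[i]
      ## weights from i to each community (excluding the self-loop)
      wrow <- W[i, ]
      wrow[i] <- 0
      nb <- which(wrow > 0)
      links <- tapply(wrow[nb], comm[nb], sum)
      tot[ci] <- tot[ci] - k[i]
      cand <- as.integer(names(links))
      gain <- as.numeric(links) / m2 * 2 - tot[cand] * k[i] / (m2^2) * 2
      ## gain of staying in (returning to) the old community
      stay <- if (as.character(ci) %in% names(links))
        links[[as.character(ci)]] / m2 * 2 - tot[ci] * k[i] / (m2^2) * 2
      else -tot[ci] * k[i] / (m2^2) * 2
      best <- ci; best_gain <- stay
      if (length(cand)) {
        o <- order(-gain, cand)     # deterministic tie-break: lowest id
        if (gain[o[1]] > best_gain + 1e-12) {
          best <- cand[o[1]]; best_gain <- gain[o[1]]
        }
      }
      comm[i] <- best
      tot[best] <- tot[best] + k[i]
      if (best != ci) improved <- TRUE
    }
    if (!improved) break
  }
  comm
}

## one full multi-level pass (levels + flat refinement) under one visit-order
## seed; returns flat community labels contiguous from 1
.louvain_once <- function(W, seed) {
  flat <- seq_len(nrow(W))
  with_seed(seed, {
    Wl <- W
    repeat {
      comm <- .louvain_one_level(Wl)
      labels <- match(comm, unique(comm))
      flat <- labels[flat]
      if (length(unique(labels)) == nrow(Wl)) break
      ## aggregate: W'_{cd} = sum of weights between communities c and d
      G <- outer(labels, seq_len(max(labels)), "==") * 1
      Wl <- t(G) %*% Wl %*% G
      if (nrow(Wl) == 1) break
    }
    ## final refinement at the flat (original-node) level: keep applying
    ## single-node moves until none improves the modularity
    repeat {
      before <- .modularity_general(W, flat)
      flat <- .louvain_one_level(W, init = flat)
      flat <- match(flat, unique(flat))
      if (.modularity_general(W, flat) <= before + 1e-12) break
    }
  })
  flat
}

#' Louvain community detection (from scratch)
#'
#' Full two-phase Louvain modularity maximization: greedy local moves of
#' nodes between neighboring communities (moves accepted while the
#' modularity gain exceeds 1e-12), aggregation of communities into
#' super-nodes, recursion until the modularity stops improving, and a final
#' refinement sweep of single-node moves on the original graph. Because the
#' greedy pass is visit-order dependent, the optimizer restarts from
#' `n_restarts` seeded orders (derived deterministically from `seed`) and
#' keeps the assignment with the greatest modularity.
#'
#' @param A a `connectivity_matrix` (or symmetric weight matrix) with at
#'   least one positive weight.
#' @param seed base RNG seed for the node visit orders (default 0).
#' @param n_restarts number of seeded restarts (default 8).
#' @return object of class `community_assignment`: `community_of` (integer
#'   ids contiguous from 0) and `modularity`.
#' @export
louvain <- function(A, seed = 0, n_restarts = 8) {
  W <- if (inherits(A, "connectivity_matrix")) A$weights else as.matrix(A)
  if (sum(W) <= 0) stop("empty graph")
  best <- NULL
  best_M <- -Inf
  for (r in seq_len(n_restarts)) {
    flat <- .louvain_once(W, seed + r - 1L)
    M <- .modularity_general(W, flat)
    if (M > best_M + 1e-12) { best <- flat; best_M <- M }
  }
  ids <- best - 1L   # contiguous from 0 by construction of match()
  structure(list(community_of = as.integer(ids), modularity = best_M,
                 seed = seed),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("community_assignment: %d communities over %d nodes, modularity %.4f\n",
              length(unique(x$community_of)), length(x$community_of),
              x$modularity))
  invisible(x)
}

#' Community partition of a binned recording
#'
#' Builds the significance-thresholded correlation network and splits it into
#' dense communities with [louvain()]; the communities become the subsets
#' over which Phi is evaluated. Zero-degree (isolated) nodes each form their
#' own subset. If the graph is empty or a single community results, the
#' atomic partition is returned with a warning, since Phi over one subset is
#' degenerately zero.
#'
#' @param binned a [binned_matrix].
#' @param alpha edge significance level.
#' @param seed Louvain seed.
#' @return a [phi_partition].
#' @export
louvain_partition <- function(binned, alpha = 0.05, seed = 0) {
  A <- connectivity_matrix(binned, alpha = alpha)
  n <- length(A$neuron_ids)
  if (sum(A$weights) <= 0) {
    warning("no significant edges: falling back to atomic partition")
    return(atomic_partition(n))
  }
  ca <- louvain(A, seed = seed)
  subsets <- split(seq_len(n), ca$community_of)
  if (length(subsets) < 2) {
    warning("single community found: falling back to atomic partition")
    return(atomic_partition(n))
  }
  phi_partition(unname(subsets))
}
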