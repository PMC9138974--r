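#' Specification for synthetic spike-train generation
#'
#' Defaults emulate the statistical shape of the target recordings: a
#' mid-range count of simultaneously recorded units (16, within the 15-56
#' band), a 16-minute session, sparse spiking (on-probability 0.1 per
#' 0.03 s bin, ~3.3 Hz), and optional planted community structure.
#'
#' @param n_neurons number of units (default 16).
#' @param duration_s session length in seconds (default 960, i.e. 16 min).
#' @param bin_size bin width in seconds (default 0.03).
#' @param base_rate baseline on-probability per bin (default 0.1).
#' @param coupling coupling strength in `[0, 1)`: increment to a neuron's
#'   on-probability per unit mean parent activity at lag `delay_bins`.
#' @param delay_bins interaction delay in bins (default 1).
#' @param communities integer block sizes summing to `n_neurons`; `NULL`
#'   means one block.
#' @param between_coupling coupling weight on between-community edges.
#' @param seed RNG seed.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_neurons = 16, duration_s = 960, bin_size = 0.03,
                           base_rate = 0.1, coupling = 0, delay_bins = 1,
                           communities = NULL, between_coupling = 0,
                           seed = 0) {
  if (is.null(communities)) communities <- n_neurons
  stopifnot(n_neurons >= 1, duration_s > 0, bin_size > 0,
            base_rate >= 0, base_rate <= 1, coupling >= 0, coupling < 1,
            delay_bins >= 1, between_coupling >= 0,
            sum(communities) == n_neurons)
  structure(list(n_neurons = n_neurons, duration_s = duration_s,
                 bin_size = bin_size, base_rate = base_rate,
                 coupling = coupling, delay_bins = as.integer(delay_bins),
                 communities = as.integer(communities),
                 between_coupling = between_coupling,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

.neuron_names <- function(n) sprintf("n%03d", seq_len(n))

## community membership vector and the parent weight matrix implied by a spec
.parent_weights <- function(spec) {
  memb <- rep(seq_along(spec$communities), spec$communities)
  same <- outer(memb, memb, "==")
  W <- ifelse(same, spec$coupling, spec$between_coupling)
  diag(W) <- 0
  list(W = W, membership = memb)
}

## convert a binary state matrix to a session: spikes at bin centers, so
## binarize() at the generating bin size round-trips the states exactly
.states_to_session <- function(states, spec, events = NULL) {
  n_bins <- ncol(states)
  ids <- .neuron_names(nrow(states))
  trains <- lapply(seq_len(nrow(states)), function(i)
    (which(states[i, ] == 1) - 0.5) * spec$bin_size)
  names(trains) <- ids
  session_data(trains, events = events, t_start = 0,
               t_end = n_bins * spec$bin_size)
}

## core binary linear-threshold dynamics: on-probability of neuron i at bin t
## is clip(base_rate + sum_j W_ij s_j(t - delay) / n_parents_i), with the
## uniform innovations drawn up front so that coupling = 0 reproduces the
## independent generator draw-for-draw. `scale_t` optionally modulates W
## per bin (used for period-varying coupling).
.simulate_dynamics <- function(spec, n_bins, W, scale_t = NULL,
                               base_t = NULL) {
  N <- spec$n_neurons
  U <- matrix(stats::runif(N * n_bins), nrow = N, ncol = n_bins)
  deg <- pmax(rowSums(W != 0), 1)
  S <- matrix(0L, N, n_bins)
  d <- spec$delay_bins
  n_clip <- 0L
  static <- all(W == 0)
  for (t in seq_len(n_bins)) {
    base <- if (is.null(base_t)) spec$base_rate else base_t[t]
    if (t <= d || static) {
      p <- rep(base, N)
    } else {
      w <- if (is.null(scale_t)) 1 else scale_t[t]
      p <- base + w * drop(W %*% S[, t - d]) / deg
      n_clip <- n_clip + sum(p < 0 | p > 1)
      p <- pmin(pmax(p, 0), 1)
    }
    S[, t] <- as.integer(U[, t] < p)
  }
  if (n_clip > 0.01 * N * n_bins)
    warning(sprintf("probability clipped in %.1f%% of bins",
                    100 * n_clip / (N * n_bins)))
  S
}

#' Generate independent Bernoulli spike trains
#'
#' Each neuron is an independent Bernoulli(`base_rate`) bin process; spike
#' times sit at bin centers. The null model: no integration, Phi should
#' hover near zero.
#'
#' @param spec a [generator_spec] with `coupling = 0`.
#' @return a [session_data].
#' @export
gen_independent <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$coupling != 0) stop("gen_independent requires coupling = 0")
  n_bins <- floor(spec$duration_s / spec$bin_size + .TIME_EPS)
  S <- with_seed(spec$seed, {
    U <- matrix(stats::runif(spec$n_neurons * n_bins),
                nrow = spec$n_neurons, ncol = n_bins)
    matrix(as.integer(U < spec$base_rate), nrow = spec$n_neurons)
  })
  .states_to_session(S, spec)
}

#' Generate coupled binary-network spike trains
#'
#' Binary linear-threshold dynamics: neuron `i` turns on at bin `t` with
#' probability `clip(base_rate + coupling * mean of its parents' states at
#' t - delay_bins)`. Parents are all other members of the neuron's community
#' (weight `coupling`) plus all members of other communities (weight
#' `between_coupling`). With `coupling = 0` and `between_coupling = 0` the
#' output is draw-for-draw identical to [gen_independent()] at the same
#' seed.
#'
#' @param spec a [generator_spec].
#' @return a [session_data].
#' @export
gen_coupled <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n_bins <- floor(spec$duration_s / spec$bin_size + .TIME_EPS)
  pw <- .parent_weights(spec)
  S <- with_seed(spec$seed, .simulate_dynamics(spec, n_bins, pw$W))
  out <- .states_to_session(S, spec)
  attr(out, "membership") <- pw$membership
  out
}

#' Generate a learning-like session with period-varying coupling and rewards
#'
#' Concatenates `n_periods` blocks in which the coupling is scaled by a
#' seeded random permutation of an increasing schedule `c_p`, emulating a
#' session whose degree of neural integration varies over time. The per-bin
#' baseline is compensated to `base_rate * (1 - c_p)` so that the mean-field
#' stationary firing rate `b_p / (1 - c_p)` stays at `base_rate` in every
#' period: coupling then changes the correlational structure (what Phi
#' measures) without confounding it with overall activity level, which would
#' otherwise move the normalization factor L(M). Reward events form a
#' Poisson process whose rate increases with `c_p` in proportion to
#' `phi_reward_link`: at `link = 1` the rate spreads 3x from the least- to
#' the most-coupled period, at `link = 0` the rate is constant (rewards
#' independent of integration — the null).
#'
#' @param spec a [generator_spec]; `spec$coupling` is the maximal coupling.
#' @param phi_reward_link strength of the planted Phi-reward association
#'   (>= 0).
#' @param n_periods number of equal blocks (default 8).
#' @param reward_base_rate baseline reward rate, events per second
#'   (default 0.05, i.e. one reward per ~20 s).
#' @return a [session_data] with reward events; attributes
#'   `"coupling_schedule"` and `"reward_rates"` record the planted values.
#' @export
gen_session_with_rewards <- function(spec, phi_reward_link = 0,
                                     n_periods = 8,
                                     reward_base_rate = 0.05) {
  stopifnot(inherits(spec, "generator_spec"), phi_reward_link >= 0,
            n_periods >= 1)
  n_bins <- floor(spec$duration_s / spec$bin_size + .TIME_EPS)
  n_bins <- (n_bins %/% n_periods) * n_periods
  per_len <- n_bins %/% n_periods
  pw <- .parent_weights(spec)
  out <- with_seed(spec$seed, {
    sched <- sample(seq(0.25, 1, length.out = n_periods))
    scale_t <- rep(sched, each = per_len)
    base_t <- spec$base_rate * (1 - spec$coupling * rep(sched, each = per_len))
    S <- .simulate_dynamics(spec, n_bins, pw$W, scale_t = scale_t,
                            base_t = base_t)
    spread <- if (max(sched) > min(sched))
      (sched - min(sched)) / (max(sched) - min(sched)) else rep(0, n_periods)
    rates <- reward_base_rate * (1 + 2 * phi_reward_link * spread)
    dur_p <- per_len * spec$bin_size
    ev <- do.call(rbind, lapply(seq_len(n_periods), function(p) {
      k <- stats::rpois(1, rates[p] * dur_p)
      if (k == 0) return(NULL)
      data.frame(time_s = sort(stats::runif(k, (p - 1) * dur_p, p * dur_p)),
                 label = "reward")
    }))
    list(S = S, sched = sched, rates = rates, ev = ev)
  })
  sess <- .states_to_session(out$S, spec, events = out$ev)
  attr(sess, "coupling_schedule") <- out$sched * spec$coupling
  attr(sess, "reward_rates") <- out$rates
  sess
}

#' Write a session to spike/event CSV files with a JSON sidecar
#'
#' @param session a [session_data].
#' @param dir output directory (created if needed).
#' @param spec optional [generator_spec] recorded in the sidecar.
#' @return invisibly, the paths written.
#' @export
write_session_csv <- function(session, dir, spec = NULL) {
  stopifnot(inherits(session, "session_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "spikes.csv")
  ev <- file.path(dir, "events.csv")
  long <- do.call(rbind, lapply(names(session$trains), function(id) {
    if (!length(session$trains[[id]])) return(NULL)
    data.frame(neuron_id = id, time_s = session$trains[[id]])
  }))
  if (is.null(long)) stop("session has no spikes to write")
  utils::write.csv(long, sp, row.names = FALSE)
  utils::write.csv(session$events, ev, row.names = FALSE)
  side <- list(t_start = session$t_start, t_end = session$t_end,
               n_neurons = length(session$trains))
  if (!is.null(spec)) side$generator <- unclass(spec)
  jsonlite::write_json(side, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(spikes = sp, events = ev))
}
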