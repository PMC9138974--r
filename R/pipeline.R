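#' Run configuration for the end-to-end pipeline
#'
#' @param method one of `"mib15"` (brute-force bipartition on the 15 most
#'   variable neurons), `"atomic"`, `"louvain"` (full neuron set), or the
#'   15-neuron-restricted hybrids `"atomic15"`, `"louvain15"`.
#' @param bin_size bin width, seconds.
#' @param lag_bins integer lag, or `"auto"` to pick it by [sweep_dt()].
#' @param n_periods periods per session.
#' @param alpha edge significance level (Louvain methods).
#' @param n_hypotheses Bonferroni family size.
#' @param seed master seed: all pipeline randomness derives from it.
#' @param cap bipartition enumeration cap.
#' @param grid lag grid used when `lag_bins = "auto"`.
#' @return a `run_config` list.
#' @export
run_config <- function(method = c("mib15", "atomic", "louvain",
                                  "atomic15", "louvain15"),
                       bin_size = 0.03, lag_bins = 1, n_periods = 8,
                       alpha = 0.05, n_hypotheses = 15, seed = 0, cap = 15,
                       grid = 1:40) {
  method <- match.arg(method)
  base <- c(mib15 = "mib", atomic = "atomic", louvain = "louvain",
            atomic15 = "atomic", louvain15 = "louvain")[[method]]
  top_k <- if (grepl("15$", method)) 15 else NULL
  structure(list(method = method, base_method = base, top_k = top_k,
                 bin_size = bin_size, lag_bins = lag_bins,
                 n_periods = n_periods, alpha = alpha,
                 n_hypotheses = n_hypotheses, seed = as.integer(seed),
                 cap = cap, grid = grid),
            class = "run_config")
}

#' End-to-end analysis of one session
#'
#' Loads spike and event tables, optionally picks the lag by Phi
#' maximization, computes per-period Phi with the configured partition
#' method, correlates Phi with reward rate, and writes `periods.csv`,
#' per-period `phi_period_<i>.json`, `sweep.csv` (when the lag is "auto"),
#' `correlation.json`, and `run_log.json` into `out_dir`. Outputs are
#' byte-identical for identical config and inputs.
#'
#' @param config a [run_config].
#' @param spikes path to a long-CSV spike table (`neuron_id,time_s`).
#' @param events optional path to an event table (`time_s,label`).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the period-record data frame.
#' @export
run_pipeline <- function(config, spikes, events = NULL, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  session <- load_spike_table(spikes)
  if (!is.null(events)) {
    ev <- load_event_table(events)
    session <- session_data(session$trains, ev, session$t_start,
                            max(session$t_end,
                                if (nrow(ev)) max(ev$time_s) + .TIME_EPS else 0))
  }
  lag <- config$lag_bins
  sweep <- NULL
  if (identical(lag, "auto")) {
    binned <- binarize(session, config$bin_size)
    sweep <- sweep_dt(list(binned), method = config$base_method,
                      grid = config$grid, top_k = config$top_k,
                      alpha = config$alpha, seed = config$seed,
                      cap = config$cap)
    write_sweep_csv(sweep, file.path(out_dir, "sweep.csv"))
    lag <- sweep$optimal_lag_bins
  }
  cfg <- list(method = config$base_method, bin_size = config$bin_size,
              lag_bins = lag, n_periods = config$n_periods,
              top_k = config$top_k, alpha = config$alpha,
              seed = config$seed, cap = config$cap)
  records <- period_phi(session, cfg)
  utils::write.csv(records, file.path(out_dir, "periods.csv"),
                   row.names = FALSE)
  results <- attr(records, "phi_results")
  for (i in seq_along(results)) {
    if (!is.null(results[[i]]))
      phi_result_json(results[[i]],
                      file.path(out_dir, sprintf("phi_period_%d.json", i - 1L)))
  }
  report <- tryCatch(
    correlate_phi_rewards(records, n_hypotheses = config$n_hypotheses),
    error = function(e) e)
  if (inherits(report, "condition")) {
    jsonlite::write_json(list(error = conditionMessage(report)),
                         file.path(out_dir, "correlation.json"),
                         auto_unbox = TRUE)
  } else {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log <- list(config = unclass(config)[setdiff(names(unclass(config)), "grid")],
              lag_bins_used = lag,
              n_periods_ok = sum(is.finite(records$phi_normalized)),
              removals_per_period = records$n_removed)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(records)
}

## ---- command-line interface -------------------------------------------

.cli_opts <- function(args) {
  ## parse --key value pairs into a named list
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      stop("missing value for --", key)
    out[[gsub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

.opt <- function(o, name, default = NULL) {
  if (!is.null(o[[name]])) o[[name]] else default
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic session),
#' `binarize`, `phi` (whole-recording Phi), `sweep-dt`, `run` (full
#' pipeline), `correlate` (period table to correlation report). Invoke via
#' the `phi-spike` script under `inst/cli/`, or directly:
#' `Rscript -e 'phispike::cli_main(commandArgs(TRUE))' simulate --out d`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status 0 on success (invisibly); errors propagate to a
#'   non-zero exit under `Rscript`.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: phi-spike <simulate|binarize|phi|sweep-dt|run|correlate> [--opt value ...]")
  cmd <- args[[1]]
  o <- .cli_opts(args[-1])
  num <- function(name, default) as.numeric(.opt(o, name, default))
  switch(cmd,
    simulate = {
      spec <- generator_spec(
        n_neurons = num("n_neurons", 16), duration_s = num("duration", 960),
        bin_size = num("bin_size", 0.03), base_rate = num("base_rate", 0.1),
        coupling = num("coupling", 0.3), delay_bins = num("delay_bins", 1),
        seed = num("seed", 0))
      sess <- gen_session_with_rewards(spec, phi_reward_link = num("link", 1))
      write_session_csv(sess, .opt(o, "out", "."), spec = spec)
    },
    binarize = {
      s <- load_spike_table(.opt(o, "spikes"))
      write_binned_csv(binarize(s, num("bin_size", 0.03)),
                       .opt(o, "out", "binned.csv"))
    },
    phi = {
      s <- load_spike_table(.opt(o, "spikes"))
      b <- binarize(s, num("bin_size", 0.03))
      r <- robust_phi(b, method = .opt(o, "method", "atomic"),
                      lag_bins = num("lag", 1),
                      top_k = if (!is.null(o$top_k)) num("top_k", 15),
                      seed = num("seed", 0))
      phi_result_json(r, .opt(o, "out", "phi.json"))
    },
    `sweep-dt` = {
      s <- load_spike_table(.opt(o, "spikes"))
      b <- binarize(s, num("bin_size", 0.03))
      sw <- sweep_dt(list(b), method = .opt(o, "method", "atomic"),
                     grid = seq_len(num("grid_max", 40)),
                     seed = num("seed", 0))
      write_sweep_csv(sw, .opt(o, "out", "sweep.csv"))
    },
    run = {
      lag_raw <- .opt(o, "lag", "1")
      cfg <- run_config(method = .opt(o, "method", "atomic"),
                        bin_size = num("bin_size", 0.03),
                        lag_bins = if (identical(lag_raw, "auto")) "auto"
                                   else as.integer(lag_raw),
                        n_periods = num("n_periods", 8),
                        alpha = num("alpha", 0.05),
                        n_hypotheses = num("n_hypotheses", 15),
                        seed = num("seed", 0))
      run_pipeline(cfg, .opt(o, "spikes"), .opt(o, "events"),
                   .opt(o, "out", "."))
    },
    correlate = {
      rec <- utils::read.csv(.opt(o, "periods"))
      rep_ <- correlate_phi_rewards(rec, n_hypotheses = num("n_hypotheses", 15))
      print(rep_)
      jsonlite::write_json(unclass(rep_), .opt(o, "out", "correlation.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
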