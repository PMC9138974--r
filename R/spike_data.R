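#' Session container for spike and event data
#'
#' Bundles a set of spike trains with behavioral events and the session time
#' window. Spike times are seconds from the recording clock; all times must
#' fall inside `[t_start, t_end]`.
#'
#' @param trains named list of numeric vectors; names are neuron identifiers,
#'   values are spike times in seconds (sorted internally).
#' @param events data frame with columns `time_s` and `label`, or `NULL` for
#'   an event-free session.
#' @param t_start,t_end session window in seconds, `t_end > t_start`.
#' @return an object of class `session_data`.
#' @export
session_data <- function(trains, events = NULL, t_start = 0, t_end = NULL) {
  stopifnot(is.list(trains), length(trains) >= 1, !is.null(names(trains)))
  if (is.null(events)) {
    events <- data.frame(time_s = numeric(0), label = character(0),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("time_s", "label") %in% names(events)))
  trains <- trains[order(names(trains))]
  trains <- lapply(trains, function(x) {
    x <- sort(as.numeric(x))
    if (any(!is.finite(x)) || any(x < 0)) stop("spike times must be finite and non-negative")
    if (any(diff(x) < .TIME_EPS) && length(x) > 1) x <- x[c(TRUE, diff(x) >= .TIME_EPS)]
    x
  })
  if (is.null(t_end)) {
    tmax <- suppressWarnings(max(c(unlist(trains), events$time_s), na.rm = TRUE))
    t_end <- if (is.finite(tmax)) tmax + .TIME_EPS else t_start + 1
  }
  if (!(t_end > t_start)) stop("t_end must exceed t_start")
  bad <- vapply(trains, function(x) any(x < t_start - .TIME_EPS | x > t_end + .TIME_EPS), logical(1))
  if (any(bad)) stop("spike times outside [t_start, t_end] for: ",
                     paste(names(trains)[bad], collapse = ", "))
  structure(list(trains = trains, events = events,
                 t_start = t_start, t_end = t_end),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("session_data: %d neurons, %d spikes, %d events, window [%.3f, %.3f] s\n",
              length(x$trains), sum(lengths(x$trains)), nrow(x$events),
              x$t_start, x$t_end))
  invisible(x)
}

#' Load a spike table from disk
#'
#' Two layouts are supported. `long_csv` is a comma-separated file with header
#' `neuron_id,time_s`, one spike per row. `per_neuron_dir` is a directory with
#' one whitespace-separated list of spike times per file, the file name being
#' the neuron identifier.
#'
#' @param path file (long_csv) or directory (per_neuron_dir).
#' @param format one of `"long_csv"`, `"per_neuron_dir"`.
#' @param t_start,t_end optional session window; defaults to `[0, max time]`.
#' @return a [session_data] object; the number of spikes loaded is recorded in
#'   attribute `"n_loaded"`.
#' @export
load_spike_table <- function(path, format = c("long_csv", "per_neuron_dir"),
                             t_start = 0, t_end = NULL) {
  format <- match.arg(format)
  if (format == "long_csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("neuron_id", "time_s") %in% names(df)))
      stop("expected header 'neuron_id,time_s' in ", path)
    if (nrow(df) == 0) stop("no spikes in ", path)
    tt <- suppressWarnings(as.numeric(df$time_s))
    bad <- which(!is.finite(tt) | tt < 0)
    if (length(bad))
      stop("malformed spike row at line ", bad[1] + 1L, " of ", path)
    trains <- split(tt, as.character(df$neuron_id))
  } else {
    if (!dir.exists(path)) stop("directory not found: ", path)
    files <- list.files(path, full.names = TRUE)
    if (!length(files)) stop("no spikes in ", path)
    trains <- lapply(files, function(f) {
      x <- suppressWarnings(as.numeric(scan(f, what = character(), quiet = TRUE)))
      if (any(!is.finite(x)) || any(x < 0))
        stop("malformed spike time in ", f)
      x
    })
    names(trains) <- basename(files)
    if (sum(lengths(trains)) == 0) stop("no spikes in ", path)
  }
  out <- session_data(trains, events = NULL, t_start = t_start, t_end = t_end)
  attr(out, "n_loaded") <- sum(lengths(out$trains))
  out
}

#' Load a behavioral event table
#'
#' CSV with header `time_s,label`, e.g. reward deliveries.
#'
#' @param path CSV file path.
#' @return data frame with columns `time_s`, `label`, sorted by time.
#' @export
load_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "label") %in% names(df)))
    stop("expected header 'time_s,label' in ", path)
  df$time_s <- suppressWarnings(as.numeric(df$time_s))
  if (any(!is.finite(df$time_s)) && nrow(df))
    stop("malformed event time in ", path)
  df[order(df$time_s), c("time_s", "label"), drop = FALSE]
}

#' Construct a binned binary state matrix
#'
#' @param states 0/1 matrix, neurons in rows, time bins in columns.
#' @param bin_size bin width, seconds.
#' @param neuron_ids row labels.
#' @param t_start left edge of bin 0, seconds.
#' @return object of class `binned_matrix`.
#' @export
binned_matrix <- function(states, bin_size, neuron_ids = rownames(states),
                          t_start = 0) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) stop("states must be 0/1")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(states)))
  stopifnot(length(neuron_ids) == nrow(states), bin_size > 0)
  storage.mode(states) <- "integer"
  rownames(states) <- neuron_ids
  structure(list(states = states, bin_size = bin_size,
                 neuron_ids = as.character(neuron_ids), t_start = t_start),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("binned_matrix: %d neurons x %d bins (bin %.3g s, start %.3f s), on-fraction %.3f\n",
              nrow(x$states), ncol(x$states), x$bin_size, x$t_start,
              mean(x$states)))
  invisible(x)
}

#' Binarize spike trains into on/off time bins
#'
#' The session window is split into equal bins of width `bin_size`; a bin is
#' "on" (1) for a neuron iff at least one of its spikes falls into the
#' half-open interval `[t_start + i*bin, t_start + (i+1)*bin)`. A trailing
#' partial bin is discarded. The default 0.03 s mirrors the empirical
#' compromise between preserving fine spike patterns and avoiding almost-empty
#' bins.
#'
#' @param session a [session_data] object.
#' @param bin_size bin width in seconds (default 0.03).
#' @return a [binned_matrix]; rows ordered by neuron id.
#' @export
binarize <- function(session, bin_size = 0.03) {
  stopifnot(inherits(session, "session_data"), bin_size > 0)
  dur <- session$t_end - session$t_start
  n_bins <- floor(dur / bin_size + .TIME_EPS)
  if (n_bins < 2) stop("fewer than 2 bins: bin_size too large for session")
  ids <- names(session$trains)
  states <- matrix(0L, nrow = length(ids), ncol = n_bins,
                   dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    idx <- floor((session$trains[[i]] - session$t_start) / bin_size + .TIME_EPS)
    idx <- idx[idx >= 0 & idx < n_bins]
    states[i, unique(idx) + 1L] <- 1L
  }
  binned_matrix(states, bin_size, ids, session$t_start)
}

#' Split a binned matrix into contiguous equal periods
#'
#' Periods are contiguous, disjoint blocks of columns covering the session in
#' order; when the bin count is not divisible, the leftover bins go to the
#' earliest periods so lengths differ by at most one.
#'
#' @param binned a [binned_matrix].
#' @param n_periods number of periods (default 8).
#' @return list of [binned_matrix] objects, in temporal order.
#' @export
split_periods <- function(binned, n_periods = 8) {
  stopifnot(inherits(binned, "binned_matrix"), n_periods >= 1)
  nb <- ncol(binned$states)
  if (n_periods > nb) stop("n_periods exceeds number of bins")
  base <- nb %/% n_periods
  len <- rep(base, n_periods) + c(rep(1L, nb %% n_periods),
                                  rep(0L, n_periods - nb %% n_periods))
  ends <- cumsum(len)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(n_periods), function(p) {
    binned_matrix(binned$states[, starts[p]:ends[p], drop = FALSE],
                  binned$bin_size, binned$neuron_ids,
                  binned$t_start + (starts[p] - 1L) * binned$bin_size)
  })
}

#' Write a binned matrix as a dense CSV for inspection
#'
#' @param binned a [binned_matrix].
#' @param path output file.
#' @export
write_binned_csv <- function(binned, path) {
  stopifnot(inherits(binned, "binned_matrix"))
  df <- data.frame(neuron_id = binned$neuron_ids, binned$states,
                   check.names = FALSE)
  names(df)[-1] <- paste0("bin", seq_len(ncol(binned$states)) - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
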