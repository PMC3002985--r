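#' Experiment configuration
#'
#' Bundles everything needed for a reproducible grid run: protocol, the
#' arrangements and delay grid, trials per condition, the accepted-trial
#' target, the master seed and the model parameters.  Per-condition child
#' seeds are derived deterministically from the master seed, so any single
#' condition can be re-run in isolation and reproduce its rows of the
#' full-grid output.
#'
#' @param protocol Protocol name (see [build_protocol()]).
#' @param arrangements Character vector of arrangements.
#' @param delays Delay grid (ms).
#' @param n_trials Simulated trials per condition.
#' @param target_n Accepted trials kept per condition (first `target_n` in
#'   seed order); the filter yield may leave fewer.
#' @param seed Master seed (mandatory).
#' @param params [ca1_params()] object.
#' @param max_intra_isi Burst segmentation threshold (ms).
#' @return Object of class `ca1_config`.
#' @export
experiment_config <- function(protocol = "initial",
                              arrangements = ca1_arrangements(),
                              delays = delay_grid("full"),
                              n_trials = 100, target_n = 62, seed,
                              params = ca1_params(), max_intra_isi = 50) {
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  stopifnot(inherits(params, "ca1_params"), n_trials >= 1)
  structure(list(protocol = protocol, arrangements = arrangements,
                 delays = delays, n_trials = as.integer(n_trials),
                 target_n = as.integer(target_n), seed = as.integer(seed),
                 params = params, max_intra_isi = max_intra_isi),
            class = "ca1_config")
}

# deterministic child seed; kept below 2^31 - 1 and positive
child_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 101) %%
               2147483629 + 1)
}

#' Enumerate the simulation grid of a configuration
#'
#' One row per simulated pattern (arrangement x delay x trial) with its
#' deterministic child seed; no simulation is performed.
#'
#' @param config A [experiment_config()] object.
#' @return A `data.frame` with columns `arrangement`, `delay`, `trial`,
#'   `seed`.
#' @export
enumerate_grid <- function(config) {
  stopifnot(inherits(config, "ca1_config"))
  g <- expand.grid(trial = seq_len(config$n_trials),
                   delay = config$delays,
                   arrangement = config$arrangements,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("arrangement", "delay", "trial")]
  g$seed <- child_seed(config$seed, seq_len(nrow(g)))
  g
}

#' Simulate one condition of the grid
#'
#' Simulates `n_trials` trials (fresh layout per trial, calibration runs
#' included), applies the trial filter, and keeps at most `target_n`
#' accepted records in seed order.
#'
#' @param config A [experiment_config()] object.
#' @param arrangement,delay The condition.
#' @param seeds Optional explicit per-trial seeds (defaults to the child
#'   seeds of [enumerate_grid()]).
#' @return List of accepted `ca1_trial` records (attribute `yield`).
#' @export
run_condition_trials <- function(config, arrangement, delay, seeds = NULL) {
  stopifnot(inherits(config, "ca1_config"))
  proto <- build_protocol(config$protocol, delay = delay)
  if (is.null(seeds)) {
    g <- enumerate_grid(config)
    seeds <- g$seed[g$arrangement == arrangement & g$delay == delay]
  }
  records <- lapply(seeds, function(s) {
    layout <- generate_layout(arrangement, seed = s,
                              branch_sd = config$params$branch_sd)
    # distinct sub-seeds for the three conditions of one record
    simulate_trial(proto, layout, config$params, seed = s * 3L %% 2147483647L)
  })
  acc <- filter_trials(records)
  yield <- attr(acc, "yield")
  if (!length(acc))
    warning("no accepted trials for ", arrangement, " at delay ", delay,
            " ms", call. = FALSE)
  out <- acc[seq_len(min(length(acc), config$target_n))]
  attr(out, "yield") <- yield
  out
}

#' Run the full experiment grid
#'
#' Simulates every arrangement x delay condition of the configuration,
#' applies the trial filter, and assembles per-condition summaries, ISI
#' series and median signatures.
#'
#' @param config A [experiment_config()] object.
#' @param out_dir Optional directory; when given, tidy CSV tables (spike
#'   times, summaries) are written there.
#' @param keep_records Keep the raw trial records (memory permitting).
#' @param verbose Log one line per condition to `stderr`.
#' @return Object of class `ca1_grid_result`: `summaries` (data frame, one
#'   row per condition), `series` (named list of [isi_series()]),
#'   `signatures` ([signature_matrix()] over conditions with bursting
#'   activity), `spike_table` (long data frame), `config`.
#' @export
run_grid <- function(config, out_dir = NULL, keep_records = FALSE,
                     verbose = FALSE) {
  stopifnot(inherits(config, "ca1_config"))
  conds <- expand.grid(delay = config$delays,
                       arrangement = config$arrangements,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summaries <- vector("list", nrow(conds))
  series <- list()
  sigs <- list(); sig_arr <- character(0); sig_delay <- numeric(0)
  spike_rows <- list()
  records_out <- list()
  for (i in seq_len(nrow(conds))) {
    arr <- conds$arrangement[i]; dl <- conds$delay[i]
    recs <- run_condition_trials(config, arr, dl)
    if (!length(recs)) next
    key <- paste(arr, dl, sep = "_")
    if (verbose)
      message(sprintf("[%s] delay %g ms: %d accepted (yield %.2f)",
                      arr, dl, length(recs), attr(recs, "yield")))
    smry <- condition_summary(recs, config$max_intra_isi)
    smry$yield <- attr(recs, "yield")
    summaries[[i]] <- smry
    tisis <- lapply(recs, function(r)
      trial_isis(r$spikes, config$max_intra_isi))
    if (any(lengths(tisis) > 0)) {
      series[[key]] <- isi_series(tisis)
      sigs[[length(sigs) + 1L]] <- median_signature(tisis)
      sig_arr <- c(sig_arr, arr); sig_delay <- c(sig_delay, dl)
    }
    spike_rows[[key]] <- data.frame(
      arrangement = arr, delay = dl,
      trial = rep(seq_along(recs), vapply(recs, function(r)
        length(r$spikes), integer(1))),
      seed = rep(vapply(recs, `[[`, integer(1), "seed"),
                 vapply(recs, function(r) length(r$spikes), integer(1))),
      time = unlist(lapply(recs, `[[`, "spikes")),
      stringsAsFactors = FALSE)
    if (keep_records) records_out[[key]] <- recs
  }
  summaries <- do.call(rbind, summaries[!vapply(summaries, is.null,
                                                logical(1))])
  spike_table <- if (length(spike_rows)) do.call(rbind, spike_rows) else
    data.frame()
  rownames(spike_table) <- NULL
  signatures <- if (length(sigs) >= 1)
    signature_matrix(sigs, sig_arr, sig_delay) else NULL
  res <- structure(list(summaries = summaries, series = series,
                        signatures = signatures, spike_table = spike_table,
                        records = if (keep_records) records_out else NULL,
                        config = config),
                   class = "ca1_grid_result")
  if (!is.null(out_dir)) write_grid_result(res, out_dir)
  res
}

#' @export
print.ca1_grid_result <- function(x, ...) {
  cat("ca1_grid_result:", nrow(x$summaries), "conditions (protocol",
      x$config$protocol, ")\n")
  print(head(x$summaries, 10))
  invisible(x)
}

#' Mechanism blockade comparison
#'
#' Runs a condition under control parameters and under blockade of one
#' mechanism, and reports average firing frequency and duty cycle with
#' percentage changes.
#'
#' @param config A [experiment_config()] object (its `arrangements` and
#'   `delays` define the conditions compared).
#' @param mechanism One of [ca1_mechanisms()].
#' @param fraction Blocked fraction (default 0.9).
#' @return Data frame with one row per condition and columns for control
#'   and blocked firing frequency and duty cycle plus percentage changes.
#' @export
blockade_experiment <- function(config, mechanism, fraction = 0.9) {
  stopifnot(inherits(config, "ca1_config"))
  blocked_params <- block_mechanism(config$params, mechanism, fraction)
  blocked_cfg <- config
  blocked_cfg$params <- blocked_params
  rows <- list()
  for (arr in config$arrangements) for (dl in config$delays) {
    ctrl <- run_condition_trials(config, arr, dl)
    blk <- run_condition_trials(blocked_cfg, arr, dl)
    s_c <- condition_summary(ctrl, config$max_intra_isi)
    s_b <- condition_summary(blk, config$max_intra_isi)
    rows[[paste(arr, dl)]] <- data.frame(
      arrangement = arr, delay = dl, mechanism = mechanism,
      fraction = fraction,
      ff_control = s_c$ff, ff_blocked = s_b$ff,
      ff_change_pct = 100 * (s_b$ff - s_c$ff) / max(s_c$ff, 1e-12),
      duty_control = s_c$duty, duty_blocked = s_b$duty,
      duty_change_pct = 100 * (s_b$duty - s_c$duty) /
        max(s_c$duty, 1e-12),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
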