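#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings, with crossings closer than the refractory
#' merge window collapsed into one spike.
#'
#' @param trace Uniformly sampled somatic voltage (mV).
#' @param threshold Detection threshold (mV).
#' @param dt Sampling step (ms).
#' @param merge_window Minimum separation (ms) between detected spikes.
#' @return Spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(trace, threshold = -54, dt = 0.1,
                          merge_window = 2) {
  if (any(!is.finite(trace))) stop("non-finite samples in trace",
                                   call. = FALSE)
  above <- trace >= threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  times <- (cross - 1L) * dt
  if (length(times) < 2L) return(times)
  # successive sub-window crossings merge transitively
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] > merge_window)
    out <- c(out, t)
  out
}

#' Average firing frequency over repetition trials
#'
#' The mean over trials of spike count divided by trial duration.
#'
#' @param trials List of spike-time vectors (one per trial).
#' @param duration Trial duration in seconds.
#' @return Average firing frequency (Hz).
#' @export
average_ff <- function(trials, duration) {
  if (!length(trials)) stop("empty trial list", call. = FALSE)
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  mean(vapply(trials, length, integer(1))) / duration
}

#' Segment a spike train into bursts
#'
#' Maximal runs of spikes whose consecutive inter-spike intervals are at
#' most `max_intra_isi` form burst candidates; runs of a single spike are
#' singleton events and are excluded from burst statistics.  The default
#' 50 ms criterion separates the 100 Hz-plateau-driven bursts from the 1 Hz
#' baseline events.
#'
#' @param spikes Sorted spike times (ms).
#' @param max_intra_isi Intra-burst ISI threshold (ms).
#' @return An object of class `burst_set`: `bursts` (list of spike-time
#'   vectors, each of length >= 2), `onsets`, `intra_isis` (list of ISI
#'   vectors), `n_singletons`.
#' @export
segment_bursts <- function(spikes, max_intra_isi = 50) {
  if (length(spikes) && is.unsorted(spikes, strictly = TRUE))
    stop("'spikes' must be strictly increasing", call. = FALSE)
  if (!length(spikes)) {
    return(structure(list(bursts = list(), onsets = numeric(0),
                          intra_isis = list(), n_singletons = 0L,
                          max_intra_isi = max_intra_isi),
                     class = "burst_set"))
  }
  grp <- cumsum(c(1, as.integer(diff(spikes) > max_intra_isi)))
  runs <- split(spikes, grp)
  is_burst <- lengths(runs) >= 2L
  bursts <- unname(runs[is_burst])
  structure(list(
    bursts = bursts,
    onsets = vapply(bursts, `[`, numeric(1), 1L),
    intra_isis = lapply(bursts, diff),
    n_singletons = sum(!is_burst),
    max_intra_isi = max_intra_isi
  ), class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat("burst_set:", length(x$bursts), "bursts,", x$n_singletons,
      "singletons (criterion", x$max_intra_isi, "ms)\n")
  invisible(x)
}

#' Mean intra-burst inter-spike interval over trials
#'
#' Per trial, the mean of all intra-burst ISIs; averaged over the trials
#' that contain at least one burst.  Trials without bursting activity are
#' excluded; if no trial bursts the result is undefined (`NA` with
#' attribute `n_bursting = 0`), never zero.
#'
#' @param burst_sets List of [segment_bursts()] results, one per trial.
#' @return Mean burst ISI (ms) with attribute `n_bursting`, the number of
#'   contributing trials.
#' @export
mean_burst_isi <- function(burst_sets) {
  per_trial <- vapply(burst_sets, function(bs) {
    isis <- unlist(bs$intra_isis)
    if (length(isis)) mean(isis) else NA_real_
  }, numeric(1))
  ok <- !is.na(per_trial)
  if (!any(ok)) {
    warning("no trial exhibits bursting activity; mean burst ISI undefined")
    return(structure(NA_real_, n_bursting = 0L))
  }
  structure(mean(per_trial[ok]), n_bursting = sum(ok))
}

#' Burst duty cycle
#'
#' For each pair of consecutive bursts, the ratio of the active phase (time
#' from the first to the last spike of the burst) to the inter-burst period
#' (first spike of the burst to first spike of the next); averaged over
#' pairs.  A 'burstiness' measure in (0, 1].
#'
#' @param burst_set A [segment_bursts()] result with at least two bursts;
#'   otherwise the value is undefined (`NA` with attribute
#'   `n_pairs = 0`).
#' @return Mean duty cycle, with attribute `n_pairs`.
#' @export
duty_cycle <- function(burst_set) {
  b <- burst_set$bursts
  if (length(b) < 2L) {
    return(structure(NA_real_, n_pairs = 0L))
  }
  spans <- vapply(b, function(s) s[length(s)] - s[1], numeric(1))
  periods <- diff(burst_set$onsets)
  structure(mean(spans[-length(spans)] / periods),
            n_pairs = length(periods))
}

#' Time to first spike
#'
#' Latency of the first spike of a trial relative to the first stimulation
#' event of the chosen pathway.  Relative to the SLM onset the latency
#' grows linearly with the SLM-SR delay; relative to the SR onset it
#' isolates the integration latency.  A spike preceding the reference gives
#' a negative value, kept with its sign.
#'
#' @param trial A `ca1_trial` record (or any list with `spikes`,
#'   `slm_onset`, `sr_onset`).
#' @param reference `"SLM_onset"` or `"SR_onset"`.
#' @return Latency in ms, or `NA` (flagged via attribute `no_spike`) when
#'   the trial contains no spike.
#' @export
time_to_first_spike <- function(trial, reference = c("SLM_onset",
                                                     "SR_onset")) {
  reference <- match.arg(reference)
  if (!length(trial$spikes)) return(structure(NA_real_, no_spike = TRUE))
  ref <- if (reference == "SLM_onset") trial$slm_onset else trial$sr_onset
  trial$spikes[1] - ref
}

#' Local variation of an ISI sequence
#'
#' The Shinomoto local-variation statistic
#' `LV = 3/(n-1) * sum(((T_i - T_{i+1}) / (T_i + T_{i+1}))^2)`:
#' 0 for perfectly regular trains, about 1 for Poisson trains.
#'
#' @param isis Inter-spike intervals (ms), all > 0, length >= 2.
#' @return LV (dimensionless, >= 0).
#' @export
local_variation <- function(isis) {
  if (length(isis) < 2L) stop("need at least two ISIs", call. = FALSE)
  if (any(isis <= 0)) stop("all ISIs must be > 0", call. = FALSE)
  a <- isis[-length(isis)]
  b <- isis[-1]
  3 / (length(isis) - 1) * sum(((a - b) / (a + b))^2)
}

#' Filter trials by the single-pathway calibration rule
#'
#' Keeps trials where SLM stimulation alone stayed subthreshold and SR
#' stimulation alone fired at 1-3 Hz, both assessed at the soma.
#'
#' @param records List of `ca1_trial` records carrying calibration flags.
#' @param rate_range Admissible SR-alone firing range (Hz).
#' @return The accepted records, with attribute `yield` (fraction
#'   accepted).
#' @export
filter_trials <- function(records, rate_range = c(1, 3)) {
  ok <- vapply(records, function(r) {
    if (is.null(r$slm_subthreshold) || is.na(r$slm_subthreshold) ||
        is.null(r$sr_alone_rate) || is.na(r$sr_alone_rate))
      stop("record lacks calibration fields; simulate with calibrate = TRUE",
           call. = FALSE)
    isTRUE(r$slm_subthreshold) &&
      r$sr_alone_rate >= rate_range[1] && r$sr_alone_rate <= rate_range[2]
  }, logical(1))
  structure(records[ok], yield = mean(ok))
}

#' Summarise one (arrangement, delay) condition
#'
#' Computes the per-condition response statistics from a set of accepted
#' trials: average firing frequency, mean burst ISI, mean duty cycle,
#' time-to-first-spike samples and local variation.
#'
#' @param records Accepted `ca1_trial` records of one condition.
#' @param max_intra_isi Burst segmentation threshold (ms).
#' @return A one-row `data.frame`.
#' @export
condition_summary <- function(records, max_intra_isi = 50) {
  stopifnot(length(records) > 0)
  dur_s <- records[[1]]$duration / 1000
  spikes <- lapply(records, `[[`, "spikes")
  bsets <- lapply(spikes, segment_bursts, max_intra_isi = max_intra_isi)
  duties <- vapply(bsets, function(b) as.numeric(duty_cycle(b)), numeric(1))
  ttfs_slm <- vapply(records, function(r)
    as.numeric(time_to_first_spike(r, "SLM_onset")), numeric(1))
  ttfs_sr <- vapply(records, function(r)
    as.numeric(time_to_first_spike(r, "SR_onset")), numeric(1))
  lv <- vapply(spikes, function(s) {
    isis <- diff(s)
    if (length(isis) >= 2) local_variation(isis) else NA_real_
  }, numeric(1))
  n_bursts <- vapply(bsets, function(b) length(b$bursts), numeric(1))
  data.frame(
    arrangement = records[[1]]$arrangement,
    delay = records[[1]]$delay,
    protocol = records[[1]]$protocol,
    n_trials = length(records),
    ff = average_ff(spikes, dur_s),
    burst_isi = as.numeric(mean_burst_isi(bsets)),
    n_bursting = attr(mean_burst_isi(bsets), "n_bursting"),
    burst_rate = mean(n_bursts) / dur_s,
    duty = mean(duties, na.rm = TRUE),
    ttfs_slm_median = median(ttfs_slm, na.rm = TRUE),
    ttfs_sr_median = median(ttfs_sr, na.rm = TRUE),
    lv = mean(lv, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}
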