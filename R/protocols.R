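#' Build a layer-specific stimulation protocol
#'
#' Constructs the event-time program for one experiment: distal (SLM)
#' high-frequency subthreshold bursts and proximal (SR) suprathreshold
#' pulses, separated by a temporal delay with the SLM layer always leading.
#'
#' The four named protocols are:
#' \describe{
#'   \item{`initial`}{SLM: 10 bursts of 10 pulses at 100 Hz, one burst per
#'     second; SR: 10 single pulses at 1 Hz; delays 0-450 ms.}
#'   \item{`P1` (low frequency)}{SLM: 10 bursts of 5 pulses at 100 Hz at
#'     1 Hz; SR: 10 pulses at 1 Hz; delays 0-350 ms.}
#'   \item{`P2` (theta)}{SLM: 10 bursts of 3 pulses at 100 Hz at 4 Hz;
#'     SR: 10 pulses at 4 Hz; delays 0-160 ms.}
#'   \item{`P3` (theta burst)}{SLM: 10 bursts of 5 pulses at 100 Hz at
#'     5 Hz; SR: 10 pulses at 5 Hz; GABA-A reduced by 70% and GABA-B by
#'     80%; delays 0-160 ms.}
#' }
#' The refined protocols (P1-P3) additionally carry a 2.5 ms lag between
#' excitatory and inhibitory activation and 10% cross-wired inhibitory
#' fractions (SR-driven inhibition onto SLM dendrites, SLM-driven
#' inhibition onto the soma).
#'
#' @param name Protocol name: `"initial"`, `"P1"`, `"P2"` or `"P3"`.
#' @param delay Delay (ms) from each SLM burst onset to the paired SR
#'   pulse; must lie within the protocol's admissible range.
#' @param overrides Named list overriding any protocol field (used for
#'   custom conductance scalings or event counts).
#' @return An object of class `ca1_protocol`.
#' @export
build_protocol <- function(name = c("initial", "P1", "P2", "P3"),
                           delay = 0, overrides = list()) {
  name <- match.arg(name)
  if (!is.numeric(delay) || length(delay) != 1L || delay < 0)
    stop("'delay' must be a non-negative scalar (ms)", call. = FALSE)
  rng <- protocol_delay_range(name)
  if (delay > rng[2])
    stop("delay ", delay, " ms outside the admissible range [", rng[1], ", ",
         rng[2], "] ms for protocol '", name, "'", call. = FALSE)

  spec <- switch(name,
    initial = list(n_events = 10L, event_freq = 1, slm_pulses = 10L,
                   gabaa_mult = 1, gabab_mult = 1, inh_lag = 0,
                   cross_frac = 0, refined = FALSE),
    P1 = list(n_events = 10L, event_freq = 1, slm_pulses = 5L,
              gabaa_mult = 1, gabab_mult = 1, inh_lag = 2.5,
              cross_frac = 0.1, refined = TRUE),
    P2 = list(n_events = 10L, event_freq = 4, slm_pulses = 3L,
              gabaa_mult = 1, gabab_mult = 1, inh_lag = 2.5,
              cross_frac = 0.1, refined = TRUE),
    P3 = list(n_events = 10L, event_freq = 5, slm_pulses = 5L,
              gabaa_mult = 0.3, gabab_mult = 0.2, inh_lag = 2.5,
              cross_frac = 0.1, refined = TRUE)
  )
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]

  period <- 1000 / spec$event_freq
  slm_onsets <- (seq_len(spec$n_events) - 1L) * period
  sr_times <- slm_onsets + delay
  intra_freq <- 100
  burst_span <- (spec$slm_pulses - 1L) * 1000 / intra_freq
  if (burst_span + delay >= period)
    stop("event program overlaps: burst span + delay exceeds the ",
         "inter-event period", call. = FALSE)
  duration <- spec$n_events * period   # 10 s at the 1 Hz event rate

  structure(list(
    name = name, delay = delay, duration = duration,
    slm_onsets = slm_onsets, slm_pulses = spec$slm_pulses,
    slm_intra_freq = intra_freq, sr_times = sr_times,
    gabaa_mult = spec$gabaa_mult, gabab_mult = spec$gabab_mult,
    inh_lag = spec$inh_lag, cross_frac = spec$cross_frac,
    refined = spec$refined
  ), class = "ca1_protocol")
}

protocol_delay_range <- function(name) {
  switch(name,
    initial = c(0, 450), P1 = c(0, 350), P2 = c(0, 160), P3 = c(0, 160),
    stop("unknown protocol '", name, "'", call. = FALSE))
}

#' All SLM pulse times of a protocol
#' @param protocol A `ca1_protocol` object.
#' @return Numeric vector of pulse times (ms).
#' @export
slm_pulse_times <- function(protocol) {
  stopifnot(inherits(protocol, "ca1_protocol"))
  spacing <- 1000 / protocol$slm_intra_freq
  as.numeric(outer((seq_len(protocol$slm_pulses) - 1L) * spacing,
                   protocol$slm_onsets, `+`))
}

#' @export
print.ca1_protocol <- function(x, ...) {
  cat("Stimulation protocol '", x$name, "'\n", sep = "")
  cat("  SLM:", length(x$slm_onsets), "bursts of", x$slm_pulses,
      "pulses @", x$slm_intra_freq, "Hz\n")
  cat("  SR:", length(x$sr_times), "pulses; delay", x$delay,
      "ms; duration", x$duration, "ms\n")
  if (x$gabaa_mult != 1 || x$gabab_mult != 1)
    cat("  inhibition scaling: GABA-A x", x$gabaa_mult,
        ", GABA-B x", x$gabab_mult, "\n")
  invisible(x)
}

#' Temporal delay grids
#'
#' `"full"` is the 34-delay grid used for the firing-frequency curves
#' (0-300 ms in 10 ms steps plus 350, 400 and 450 ms);
#' `"short_0_240_20ms"` is the 13-delay grid used for the ISI-signature
#' dendrogram (0-240 ms in 20 ms steps); `"protocol_range"` covers a given
#' protocol's admissible range in 20 ms steps.
#'
#' @param spec Grid name.
#' @param protocol Protocol name, used only for `"protocol_range"`.
#' @return Ordered numeric vector of delays (ms).
#' @export
delay_grid <- function(spec = c("full", "short_0_240_20ms", "protocol_range"),
                       protocol = "initial") {
  spec <- match.arg(spec)
  switch(spec,
    full = c(seq(0, 300, by = 10), 350, 400, 450),
    short_0_240_20ms = seq(0, 240, by = 20),
    protocol_range = {
      rng <- protocol_delay_range(match.arg(protocol,
                                            c("initial", "P1", "P2", "P3")))
      seq(rng[1], rng[2], by = 20)
    })
}
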