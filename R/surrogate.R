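#' Sigmoidal dendritic subunit response
#'
#' The static nonlinearity of one dendritic subunit: a saturating logistic
#' of the local synaptic drive, anchored so that zero drive yields zero
#' output.  Because the curve is expansive below its half-activation and
#' saturating above, concentrating a fixed amount of drive on few subunits
#' (clustering) yields a larger summed output than spreading it thinly.
#'
#' @param drive Non-negative local synaptic drive (in units of the nominal
#'   per-branch drive of a diffused layout); vectorized.
#' @param half Half-activation drive.
#' @param slope Sigmoid slope parameter.
#' @param smax Saturation level.
#' @return Subunit output in `[0, smax)`, monotone non-decreasing in
#'   `drive`, with `response(0) == 0`.
#' @export
dendritic_subunit_response <- function(drive, half = 1.4, slope = 0.4,
                                       smax = 1) {
  if (any(!is.finite(drive)) || any(drive < 0))
    stop("'drive' must be finite and >= 0", call. = FALSE)
  l <- function(x) 1 / (1 + exp(-(x - half) / slope))
  l0 <- l(0)
  smax * (l(drive) - l0) / (1 - l0)
}

# impulse train on the simulation grid; times outside [0, (n-1)*dt] dropped
impulse_train <- function(times, weights, n, dt) {
  v <- numeric(n)
  if (!length(times)) return(v)
  if (length(weights) == 1L) weights <- rep(weights, length(times))
  idx <- as.integer(round(times / dt)) + 1L
  keep <- idx >= 1L & idx <= n
  idx <- idx[keep]; weights <- weights[keep]
  for (k in seq_along(idx)) v[idx[k]] <- v[idx[k]] + weights[k]
  v
}

# difference-of-exponentials response to an impulse train, unit peak for a
# unit impulse; requires rise < decay
dexp_filter <- function(impulses, dt, rise, decay) {
  stopifnot(rise < decay)
  yd <- stats::filter(impulses, exp(-dt / decay), method = "recursive")
  yr <- stats::filter(impulses, exp(-dt / rise), method = "recursive")
  tp <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  as.numeric(yd - yr) / peak
}

# single-exponential (instant rise) response, unit jump per unit impulse
exp_filter <- function(impulses, dt, decay) {
  as.numeric(stats::filter(impulses, exp(-dt / decay), method = "recursive"))
}

#' GABA-B conductance time course evoked by SLM bursts
#'
#' Each burst evokes a difference-of-exponentials conductance with an onset
#' latency; successive bursts are depressed by the desensitization rate, so
#' the m-th burst contributes `(1 - desens)^(m-1)` of the first.  With the
#' default kinetics (latency 50 ms, rise 100 ms, decay 250 ms) the
#' conductance of a single burst peaks about 200 ms after burst onset,
#' placing the suppression window over delays of roughly 190-350 ms.
#'
#' @param burst_onsets Sorted burst onset times (ms).
#' @param params A [ca1_params()] object (kinetics and desensitization).
#' @param duration Course duration (ms).
#' @param dt Time step (ms); defaults to `params$dt`.
#' @return Numeric vector of the conductance (unit peak per undepressed
#'   burst) on the time grid `seq(0, duration, by = dt)`.
#' @export
gabab_drive <- function(burst_onsets, params = ca1_params(), duration = 1000,
                        dt = params$dt) {
  if (length(burst_onsets) && is.unsorted(burst_onsets))
    stop("'burst_onsets' must be sorted", call. = FALSE)
  n <- as.integer(round(duration / dt)) + 1L
  if (!length(burst_onsets)) return(numeric(n))
  w <- (1 - params$gabab_desens)^(seq_along(burst_onsets) - 1L)
  imp <- impulse_train(burst_onsets + params$gabab_latency, w, n, dt)
  dexp_filter(imp, dt, params$gabab_rise, params$gabab_decay)
}

# layer summaries reused across the three conditions of one trial.
# Sister branches share charge electrotonically: each subunit sees a
# mixture of its own drive and the layer mean (which is 1 by construction
# for every arrangement, since contact totals are conserved).
layer_drives <- function(layout, params) {
  s <- function(d) dendritic_subunit_response(d, params$subunit_half,
                                              params$subunit_slope)
  s_inh <- function(d) dendritic_subunit_response(d, params$inh_half,
                                                  params$inh_slope)
  cpl <- params$dend_coupling
  nom_sr <- sum(layout$sr_exc) / layout$n_sr_branches
  nom_slm <- sum(layout$slm_exc) / layout$n_slm_branches
  d_sr <- (1 - cpl) * layout$sr_exc / nom_sr + cpl
  d_slm <- (1 - cpl) * layout$slm_exc / nom_slm + cpl
  list(
    # SR subunit-sum as a function of the divisive GABA-B shunt factor
    sr_sum = function(shunt) sum(layout$gain_sr * s(d_sr * shunt)),
    # gain of the branches that actually drive the regenerative event
    # (drive-weighted mean): clustered layouts average over few branches,
    # so their plateau amplitudes vary more from trial to trial
    sr_gain = function(shunt) {
      w <- s(d_sr * shunt)
      if (sum(w) == 0) 1 else sum(layout$gain_sr * w) / sum(w)
    },
    sr_ref = layout$n_sr_branches * s(1),
    slm_exc_rec = sum(layout$gain_slm * s(d_slm)) /
      (layout$n_slm_branches * s(1)),
    slm_inh_rec = sum(layout$gain_slm * s_inh(d_slm)) /
      (layout$n_slm_branches * s_inh(1))
  )
}

#' Simulate one trial of the reduced CA1 surrogate
#'
#' Runs the feedforward dendritic stage (subunit sigmoids, SLM priming
#' trace, desensitizing GABA-B conductance, plateau initiation) and
#' integrates the somatic membrane.  `condition = "slm_alone"` and
#' `"sr_alone"` silence the other pathway; with `calibrate = TRUE` (the
#' default for combined runs) both calibration conditions are simulated on
#' the same layout and their outcomes stored in the returned record, as
#' required by the trial filter ([filter_trials()]).
#'
#' Identical `(protocol, layout, params, seed)` always yield identical
#' spike times.
#'
#' @param protocol A [build_protocol()] object.
#' @param layout A [generate_layout()] object.
#' @param params A [ca1_params()] object.
#' @param seed Integer seed for the somatic noise.
#' @param condition `"combined"`, `"slm_alone"` or `"sr_alone"`.
#' @param keep_trace Keep the somatic voltage trace (off by default).
#' @param calibrate Run the two single-pathway calibration conditions and
#'   store their outcomes (`slm_subthreshold`, `sr_alone_rate`).
#' @return An object of class `ca1_trial`: spike times (ms, strictly
#'   increasing), stimulus metadata, calibration flags and optionally the
#'   voltage trace.
#' @export
simulate_trial <- function(protocol, layout, params = ca1_params(), seed,
                           condition = c("combined", "slm_alone", "sr_alone"),
                           keep_trace = FALSE, calibrate = TRUE) {
  stopifnot(inherits(protocol, "ca1_protocol"), inherits(layout, "ca1_layout"),
            inherits(params, "ca1_params"))
  condition <- match.arg(condition)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  spacing <- 1000 / protocol$slm_intra_freq
  if (abs(spacing / params$dt - round(spacing / params$dt)) > 1e-8)
    stop("integration step dt = ", params$dt,
         " ms is incompatible with the ", protocol$slm_intra_freq,
         " Hz intra-burst pulse spacing", call. = FALSE)

  res <- run_condition(protocol, layout, params, seed, condition, keep_trace)
  slm_sub <- NA
  sr_rate <- NA_real_
  if (calibrate && condition == "combined") {
    slm <- run_condition(protocol, layout, params, seed + 1L, "slm_alone",
                         keep_trace = FALSE)
    sr <- run_condition(protocol, layout, params, seed + 2L, "sr_alone",
                        keep_trace = FALSE)
    slm_sub <- length(slm$spikes) == 0L
    sr_rate <- length(sr$spikes) / (protocol$duration / 1000)
  }
  structure(list(
    arrangement = layout$arrangement, delay = protocol$delay,
    protocol = protocol$name, condition = condition, seed = as.integer(seed),
    spikes = res$spikes, trace = if (keep_trace) res$trace else NULL,
    dt = params$dt, duration = protocol$duration,
    slm_onset = protocol$slm_onsets[1], sr_onset = protocol$sr_times[1],
    slm_subthreshold = slm_sub, sr_alone_rate = sr_rate,
    n_plateaus = res$n_plateaus
  ), class = "ca1_trial")
}

run_condition <- function(protocol, layout, params, seed, condition,
                          keep_trace) {
  p <- params
  dt <- p$dt
  n <- as.integer(round(protocol$duration / dt)) + 1L
  drv <- layer_drives(layout, p)

  use_slm <- condition != "sr_alone"
  use_sr <- condition != "slm_alone"

  i_exc <- numeric(n)
  g_inh <- numeric(n)
  prim <- numeric(n)
  fast <- numeric(n)
  gb <- numeric(n)
  n_plateaus <- 0L

  gabaa_sr <- p$g_gabaa_sr * protocol$gabaa_mult
  gabaa_slm <- p$g_gabaa_slm * protocol$gabaa_mult
  att_sr <- (1 + 0.3) / (1 + 0.3 * gabaa_sr)
  att_slm <- (1 + 0.3) / (1 + 0.3 * gabaa_slm)

  if (use_slm) {
    pulses <- slm_pulse_times(protocol)
    # somatic depolarization from the distal layer (strongly attenuated)
    amp_slm <- p$g_ampa_slm * att_slm * drv$slm_exc_rec *
      (1 - p$nmda_epsc_frac + p$nmda_epsc_frac * p$g_nmda_slm)
    i_exc <- i_exc + dexp_filter(impulse_train(pulses, amp_slm, n, dt),
                                 dt, p$slm_rise, p$slm_decay)
    # slow NMDA priming trace that gates plateau initiation; local GABA-A
    # shunting in the SLM attenuates it the same way as the somatic EPSP
    prim_w <- 2 * p$nmda_ampa_ratio_sr * p$g_nmda_slm * att_slm *
      drv$slm_exc_rec / protocol$slm_pulses
    prim <- exp_filter(impulse_train(pulses, prim_w, n, dt), dt,
                       p$priming_tau)
    # fast AMPA-driven dendritic depolarization that gates the R-type
    # trigger pathway (persists under NMDA blockade)
    fast <- exp_filter(impulse_train(pulses, att_slm * drv$slm_exc_rec /
                                       protocol$slm_pulses, n, dt),
                       dt, p$car_gate_tau)
    # desensitizing GABA-B conductance recruited by the SLM bursts
    w_b <- p$g_gabab_slm * protocol$gabab_mult * drv$slm_inh_rec +
      0.2 * p$g_gabab_sr * protocol$gabab_mult
    desens <- (1 - p$gabab_desens)^(seq_along(protocol$slm_onsets) - 1L)
    gb_times <- protocol$slm_onsets + p$gabab_latency + protocol$inh_lag
    gb_w <- w_b * desens
    if (protocol$cross_frac > 0 && use_sr) {
      gb_times <- c(gb_times,
                    protocol$sr_times + p$gabab_latency + protocol$inh_lag)
      gb_w <- c(gb_w, rep(protocol$cross_frac * w_b,
                          length(protocol$sr_times)))
    }
    ord <- order(gb_times)
    gb <- dexp_filter(impulse_train(gb_times[ord], gb_w[ord], n, dt),
                      dt, p$gabab_rise, p$gabab_decay)
    g_inh <- p$g_gabab_soma * gb
  }

  if (use_sr) {
    idx_e <- pmin(as.integer(round(protocol$sr_times / dt)) + 1L, n)
    win <- as.integer(round(p$plateau_window / dt))
    amp_mech <- p$amp_w_base + p$amp_w_nmda * p$g_nmda_sr +
      p$amp_w_car * p$g_car + p$amp_w_carh * p$g_carh + p$amp_w_h * p$g_h
    epsp_scale <- p$g_ampa_sr * att_sr *
      (1 - p$nmda_epsc_frac + p$nmda_epsc_frac * p$g_nmda_sr)

    epsp_amp <- numeric(length(idx_e))
    for (e in seq_along(idx_e)) {
      i0 <- idx_e[e]
      shunt <- 1 / (1 + p$gabab_shunt * gb[i0])
      s_ratio <- drv$sr_sum(shunt) / drv$sr_ref
      epsp_amp[e] <- epsp_scale * s_ratio
      prim_e <- max(prim[i0:min(i0 + win, n)])
      fast_e <- max(fast[i0:min(i0 + win, n)])
      # three trigger pathways: slow NMDA priming, an R-type component
      # gated by fast distal depolarization, and h-current rebound
      # facilitation after GABA-B hyperpolarization
      trig <- s_ratio *
        (p$nmda_ampa_ratio_sr * p$g_nmda_sr * (p$priming_base + prim_e) +
           p$car_trig_w * p$g_car * (1 + p$car_gate * fast_e) +
           p$h_rebound * p$g_h * gb[i0])
      if (trig >= p$plateau_threshold) {
        n_plateaus <- n_plateaus + 1L
        a0 <- p$plateau_gain * trig / (trig + p$plateau_half) * amp_mech *
          drv$sr_gain(shunt)
        i1 <- min(i0 + as.integer(round(p$plateau_duration / dt)), n)
        tt <- (seq.int(i0, i1) - i0) * dt
        i_exc[i0:i1] <- i_exc[i0:i1] + a0 * exp(-tt / p$plateau_adapt)
      }
    }
    i_exc <- i_exc + dexp_filter(impulse_train(protocol$sr_times, epsp_amp,
                                               n, dt),
                                 dt, p$epsp_rise, p$epsp_decay)
  }

  noise <- numeric(0)
  if (p$noise_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed))
    noise <- rnorm(n, 0, p$noise_sd * sqrt(2 * p$tau_m / dt))
  }
  out <- soma_integrate(i_exc, g_inh, dt, p$tau_m, p$v_rest, p$v_thresh,
                        p$v_reset, p$e_inh, p$refractory, noise, keep_trace)
  list(spikes = out$spikes, trace = out$trace, n_plateaus = n_plateaus)
}

#' @export
print.ca1_trial <- function(x, ...) {
  cat("ca1_trial:", x$arrangement, "| protocol", x$protocol,
      "| delay", x$delay, "ms | condition", x$condition, "\n")
  cat("  ", length(x$spikes), "spikes in", x$duration / 1000, "s;",
      x$n_plateaus, "plateau events\n")
  if (!is.na(x$slm_subthreshold))
    cat("  calibration: SLM-alone subthreshold =", x$slm_subthreshold,
        "; SR-alone rate =", round(x$sr_alone_rate, 2), "Hz\n")
  invisible(x)
}
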