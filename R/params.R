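#' Surrogate model parameters
#'
#' Constructs the full parameter set of the reduced CA1 pyramidal-neuron
#' surrogate.  The surrogate is a hybrid of a leaky integrate-and-fire soma,
#' two pools of sigmoidal dendritic subunits (one per input layer), an
#' NMDA/R-type-calcium plateau current that drives somatic bursting, and a
#' slow, desensitizing GABA-B potassium-like conductance recruited by the
#' distal (SLM) layer that drives spike blocking.
#'
#' Conductance-like parameters are dimensionless scale factors: 1 is the
#' calibrated control value, and mechanism blockade multiplies them by
#' `1 - fraction` (see [block_mechanism()]).  Time constants are in ms,
#' voltages in mV.
#'
#' @param v_rest,v_thresh,v_reset Resting, threshold and reset potentials
#'   (mV) of the somatic integrate-and-fire unit.
#' @param tau_m Membrane time constant (ms).
#' @param refractory Absolute refractory period (ms).
#' @param dt Integration step (ms); must be positive and at most 1 ms.
#' @param g_ampa_sr Peak somatic EPSP drive (mV) evoked by one proximal (SR)
#'   stimulation event under the nominal fully diffused layout.  Calibrated
#'   so that SR input alone evokes a single action potential per event.
#' @param g_ampa_slm Peak somatic depolarization drive (mV) per distal (SLM)
#'   pulse; calibrated so a 10-pulse 100 Hz SLM burst alone depolarizes the
#'   soma by about 2 mV.
#' @param g_nmda_sr,g_nmda_slm NMDA conductance scale factors of the
#'   proximal and distal layers.  The SR component sets the plateau-trigger
#'   drive, the SLM component the slow priming trace that makes plateau
#'   initiation delay-dependent.
#' @param g_gabaa_sr,g_gabaa_slm GABA-A conductance scale factors (fast
#'   shunting; dominant in the SR layer).
#' @param g_gabab_sr,g_gabab_slm,g_gabab_soma GABA-B conductance scale
#'   factors.  The SLM term dominates and sets the strength of the slow
#'   dendritic shunt responsible for spike blocking; the somatic term sets
#'   the potassium-like somatic conductance.
#' @param g_car,g_carh,g_h,g_cal,g_can,g_cat Scale factors for the
#'   calcium-current and h-current surrogates that modulate the plateau
#'   amplitude (R-type and dendritic high-threshold R-type contribute, as
#'   does the h-current; L-, N- and T-type do not).
#' @param nmda_ampa_ratio_sr NMDA/AMPA current ratio in the SR layer; the
#'   SLM ratio is twice this value, matching the reported distance
#'   dependence.
#' @param gabab_latency,gabab_rise,gabab_decay Onset latency, rise and decay
#'   time constants (ms) of the GABA-B conductance evoked by one SLM burst.
#'   Defaults place the conductance peak about 200 ms after burst onset so
#'   the suppression window covers 190-350 ms.
#' @param gabab_desens Fractional amplitude depression per successive
#'   100 Hz burst (short-term desensitization).
#' @param gabab_shunt Strength of the divisive dendritic shunt exerted by
#'   the GABA-B conductance on SR subunit drive.
#' @param subunit_half,subunit_slope Half-activation (in units of the
#'   nominal diffused per-branch drive) and slope of the excitatory
#'   dendritic subunit sigmoid.
#' @param inh_half,inh_slope Sigmoid parameters of the interneuron
#'   recruitment stage that converts local SLM drive into GABA-B weight.
#' @param plateau_threshold Plateau-trigger threshold (drive units);
#'   a plateau (and hence a burst) is initiated when the combined
#'   NMDA drive of an SR event exceeds it.
#' @param plateau_gain Peak plateau current (mV drive) at saturating input.
#' @param plateau_half Half-saturation of the plateau amplitude function.
#' @param plateau_duration Plateau duration (ms).
#' @param plateau_adapt Decay time constant (ms) of the plateau current;
#'   sets the slowing of spikes within a burst.
#' @param priming_tau Decay time constant (ms) of the slow SLM priming
#'   trace; sets how fast the bursting regime fades with delay.
#' @param priming_base Delay-independent fraction of the plateau-trigger
#'   drive (allows strongly clustered SR input to burst without priming).
#' @param epsp_rise,epsp_decay Rise/decay time constants (ms) of the
#'   somatic EPSP kernel for proximal events.
#' @param slm_rise,slm_decay Rise/decay time constants (ms) of the somatic
#'   depolarization kernel for distal pulses.
#' @param e_inh Inhibitory (potassium-like) reversal potential (mV).
#' @param noise_sd Stationary standard deviation (mV) of somatic voltage
#'   noise; 0 disables noise.
#' @param branch_sd Log-scale standard deviation of per-branch gain
#'   heterogeneity used when a layout is generated.  Clustered layouts
#'   sample few branches, so this heterogeneity makes their responses more
#'   variable across trials than diffused layouts, which average over the
#'   whole pool.
#' @param dend_coupling Electrotonic coupling between sister branches:
#'   each subunit sees `(1 - c) * own drive + c * layer mean`.  Damps the
#'   granularity of random diffuse contact placement.
#' @param ampa_comp,gabaa_comp Compensation factors: when NMDA (GABA-B) is
#'   blocked by fraction `f`, AMPA (GABA-A) conductances are scaled by
#'   `1 + comp * f` to counteract the lost excitation (inhibition).  See
#'   [calibrate_compensation()].
#' @param nmda_epsc_frac Fraction of the proximal somatic EPSP carried by
#'   the NMDA conductance (the rest is AMPA); determines how much the EPSP
#'   shrinks under NMDA blockade before compensation.
#' @param car_trig_w Weight of the R-type calcium surrogate in the
#'   plateau-trigger drive (NMDA carries the rest); the R-type pathway lets
#'   strong coincident input evoke spike doublets even under NMDA blockade.
#' @param car_gate,car_gate_tau Gain and time constant (ms) of the fast
#'   AMPA-driven distal depolarization that gates the R-type trigger
#'   pathway (a coincidence requirement that survives NMDA blockade).
#' @param h_rebound Weight of the h-current rebound pathway in the plateau
#'   trigger: slow GABA-B hyperpolarization recruits a depolarizing
#'   rebound proportional to the instantaneous GABA-B conductance, which
#'   sustains occasional doublets at long delays while inhibition is
#'   intact.
#' @param plateau_window Window (ms) after an SR event over which the SLM
#'   priming trace is read out when deciding whether a plateau is
#'   initiated; represents the slow rise of the regenerative event.
#' @param amp_w_base,amp_w_nmda,amp_w_car,amp_w_carh,amp_w_h Relative
#'   contributions of the NMDA and voltage-gated surrogates to the plateau
#'   amplitude (they sum to 1 under control conductances).
#'
#' @return An object of class `ca1_params` (a validated named list).
#' @seealso [block_mechanism()], [simulate_trial()], [load_params()]
#' @export
ca1_params <- function(v_rest = -70, v_thresh = -54, v_reset = -65,
                       tau_m = 20, refractory = 5, dt = 0.1,
                       g_ampa_sr = 70, g_ampa_slm = 0.8,
                       g_nmda_sr = 1, g_nmda_slm = 1,
                       g_gabaa_sr = 1, g_gabaa_slm = 1,
                       g_gabab_sr = 0.15, g_gabab_slm = 1, g_gabab_soma = 0.12,
                       g_car = 1, g_carh = 1, g_h = 1,
                       g_cal = 1, g_can = 1, g_cat = 1,
                       nmda_ampa_ratio_sr = 1,
                       gabab_latency = 50, gabab_rise = 100, gabab_decay = 250,
                       gabab_desens = 0.22, gabab_shunt = 0.55,
                       subunit_half = 1.4, subunit_slope = 0.4,
                       inh_half = 1.3, inh_slope = 0.45,
                       plateau_threshold = 0.73, plateau_gain = 76,
                       plateau_half = 1, plateau_duration = 140,
                       plateau_adapt = 60, plateau_window = 40,
                       priming_tau = 90, priming_base = 0.03,
                       nmda_epsc_frac = 0.25, car_trig_w = 0.3,
                       car_gate = 3.4, car_gate_tau = 30, h_rebound = 0.9,
                       dend_coupling = 0.35,
                       amp_w_base = 0.15, amp_w_nmda = 0.25, amp_w_car = 0.12,
                       amp_w_carh = 0.3, amp_w_h = 0.18,
                       epsp_rise = 1.5, epsp_decay = 5,
                       slm_rise = 2, slm_decay = 25,
                       e_inh = -90, noise_sd = 0.15, branch_sd = 0.25,
                       ampa_comp = 0.35, gabaa_comp = 0.6) {
  p <- as.list(environment())
  validate_params(p)
  structure(p, class = "ca1_params")
}

validate_params <- function(p) {
  tc <- c("tau_m", "refractory", "gabab_latency", "gabab_rise", "gabab_decay",
          "plateau_duration", "plateau_adapt", "priming_tau",
          "epsp_rise", "epsp_decay", "slm_rise", "slm_decay")
  for (nm in tc) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive scalar", call. = FALSE)
  }
  if (p$dt <= 0 || p$dt > 1)
    stop("integration step 'dt' must lie in (0, 1] ms", call. = FALSE)
  gc <- grep("^g_", names(p), value = TRUE)
  for (nm in gc) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("conductance scale '", nm, "' must be >= 0", call. = FALSE)
  }
  if (p$plateau_threshold <= 0)
    stop("'plateau_threshold' must be > 0", call. = FALSE)
  if (p$gabab_desens < 0 || p$gabab_desens > 1)
    stop("'gabab_desens' must lie in [0, 1]", call. = FALSE)
  if (p$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.ca1_params <- function(x, ...) {
  cat("Reduced CA1 surrogate parameters\n")
  cat("  soma: rest", x$v_rest, "mV, threshold", x$v_thresh,
      "mV, tau_m", x$tau_m, "ms, dt", x$dt, "ms\n")
  cat("  GABA-B: latency", x$gabab_latency, "rise", x$gabab_rise,
      "decay", x$gabab_decay, "ms, desensitization",
      x$gabab_desens, "per burst\n")
  cat("  plateau: threshold", x$plateau_threshold, "gain", x$plateau_gain,
      "duration", x$plateau_duration, "ms\n")
  cat("  noise sd", x$noise_sd, "mV, branch heterogeneity sd",
      x$branch_sd, "\n")
  invisible(x)
}

#' Mechanism names recognised by [block_mechanism()]
#' @export
ca1_mechanisms <- function() {
  c("GABA_B_SLM", "GABA_B_all", "NMDA_SLM", "NMDA_all",
    "caR_like", "caRH_like", "h_like", "caL_like", "caN_like", "caT_like")
}

#' Block a biophysical mechanism
#'
#' Returns a parameter set in which the named conductance is reduced by
#' `fraction` (90% blockade is the convention used throughout).  When NMDA
#' or GABA-B conductances are blocked, the corresponding AMPA or GABA-A
#' conductances are scaled up by the configured compensation factor so that
#' single-pathway responses stay close to control.
#'
#' @param params A [ca1_params()] object.
#' @param mechanism One of [ca1_mechanisms()].
#' @param fraction Blocked fraction in `[0, 1]`; default 0.9.
#' @param compensate Apply the AMPA/GABA-A compensation (default `TRUE`).
#' @return A modified `ca1_params` object.
#' @export
block_mechanism <- function(params, mechanism, fraction = 0.9,
                            compensate = TRUE) {
  stopifnot(inherits(params, "ca1_params"))
  mechanism <- match.arg(mechanism, ca1_mechanisms())
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must lie in [0, 1]", call. = FALSE)
  keep <- 1 - fraction
  p <- unclass(params)
  comp_a <- 1 + params$ampa_comp * fraction
  comp_g <- 1 + params$gabaa_comp * fraction
  switch(mechanism,
    GABA_B_SLM = {
      p$g_gabab_slm <- p$g_gabab_slm * keep
      p$g_gabab_soma <- p$g_gabab_soma * keep
      if (compensate) p$g_gabaa_slm <- p$g_gabaa_slm * comp_g
    },
    GABA_B_all = {
      p$g_gabab_slm <- p$g_gabab_slm * keep
      p$g_gabab_sr <- p$g_gabab_sr * keep
      p$g_gabab_soma <- p$g_gabab_soma * keep
      if (compensate) {
        p$g_gabaa_slm <- p$g_gabaa_slm * comp_g
        p$g_gabaa_sr <- p$g_gabaa_sr * comp_g
      }
    },
    NMDA_SLM = {
      p$g_nmda_slm <- p$g_nmda_slm * keep
      if (compensate) p$g_ampa_slm <- p$g_ampa_slm * comp_a
    },
    NMDA_all = {
      p$g_nmda_slm <- p$g_nmda_slm * keep
      p$g_nmda_sr <- p$g_nmda_sr * keep
      if (compensate) {
        p$g_ampa_slm <- p$g_ampa_slm * comp_a
        p$g_ampa_sr <- p$g_ampa_sr * comp_a
      }
    },
    caR_like = p$g_car <- p$g_car * keep,
    caRH_like = p$g_carh <- p$g_carh * keep,
    h_like = p$g_h <- p$g_h * keep,
    caL_like = p$g_cal <- p$g_cal * keep,
    caN_like = p$g_can <- p$g_can * keep,
    caT_like = p$g_cat <- p$g_cat * keep
  )
  structure(p, class = "ca1_params")
}

#' Calibrate a blockade compensation factor
#'
#' Searches for the compensation factor that, under blockade of `mechanism`
#' by `fraction`, brings the single-pathway calibration response (SR-alone
#' firing rate for NMDA blockade, SLM-alone peak depolarization for GABA-B
#' blockade) back to within `tol` of the control value.  The search is a
#' coarse seeded grid over `[0, 1.5]`.
#'
#' @inheritParams block_mechanism
#' @param seed Integer seed for the calibration layouts.
#' @param tol Relative tolerance on the single-pathway response.
#' @return The calibrated compensation factor (numeric scalar), with the
#'   achieved relative error as attribute `"rel_error"`.
#' @export
calibrate_compensation <- function(params, mechanism, fraction = 0.9,
                                   seed = 1L, tol = 0.1) {
  stopifnot(inherits(params, "ca1_params"))
  mechanism <- match.arg(mechanism, c("NMDA_all", "NMDA_SLM",
                                      "GABA_B_all", "GABA_B_SLM"))
  nmda <- grepl("^NMDA", mechanism)
  proto <- build_protocol("initial", delay = 0)
  layout <- generate_layout("fully_diffused", seed = seed,
                            branch_sd = params$branch_sd)
  ref_response <- function(p) {
    tr <- simulate_trial(proto, layout, p, seed = seed,
                         condition = if (nmda) "sr_alone" else "slm_alone",
                         calibrate = FALSE, keep_trace = !nmda)
    if (nmda) length(tr$spikes) / (proto$duration / 1000)
    else max(tr$trace) - p$v_rest
  }
  control <- ref_response(params)
  grid <- seq(0, 1.5, by = 0.05)
  errs <- vapply(grid, function(cmp) {
    p <- unclass(params)
    if (nmda) p$ampa_comp <- cmp else p$gabaa_comp <- cmp
    p <- structure(p, class = "ca1_params")
    abs(ref_response(block_mechanism(p, mechanism, fraction)) - control) /
      max(control, 1e-9)
  }, numeric(1))
  best <- grid[which.min(errs)]
  if (min(errs) > tol)
    warning("compensation calibration did not reach tolerance (best rel. error ",
            signif(min(errs), 3), ")")
  structure(best, rel_error = min(errs))
}

#' Read and write surrogate parameters as YAML
#'
#' `load_params()` reads a YAML file with any subset of the [ca1_params()]
#' fields (unspecified fields take their defaults); `save_params()` writes a
#' complete parameter set.  The package ships its default configuration at
#' `default_param_file()`.
#'
#' @param path Path to a YAML file.
#' @return `load_params()` returns a `ca1_params` object.
#' @export
load_params <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(ca1_params)))
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(ca1_params, vals)
}

#' @rdname load_params
#' @param params A `ca1_params` object.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "ca1_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname load_params
#' @export
default_param_file <- function() {
  system.file("extdata", "default-params.yaml", package = "ca1code",
              mustWork = TRUE)
}
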