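# shared simulation helpers; conditions are cached so several test files can
# reuse the same small runs

quiet_params <- function(...) ca1_params(noise_sd = 0, ...)

.sim_cache <- new.env(parent = emptyenv())

sim_condition <- function(arrangement, delay, n = 8, seed0 = 100,
                          params = ca1_params(), protocol = "initial",
                          calibrate = TRUE) {
  key <- paste(arrangement, delay, n, seed0, protocol,
               digest_params(params), calibrate, sep = "|")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  proto <- build_protocol(protocol, delay = delay)
  recs <- lapply(seq_len(n), function(i) {
    lay <- generate_layout(arrangement, seed = seed0 + i,
                           branch_sd = params$branch_sd)
    simulate_trial(proto, lay, params, seed = 5000 + 3L * i,
                   calibrate = calibrate)
  })
  .sim_cache[[key]] <- recs
  recs
}

digest_params <- function(p) paste(signif(unlist(p), 8), collapse = ",")

accepted_ff <- function(recs, duration_s = 10) {
  acc <- filter_trials(recs)
  average_ff(lapply(acc, `[[`, "spikes"), duration_s)
}
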