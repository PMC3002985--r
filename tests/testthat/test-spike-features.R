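test_that("spike detection finds threshold crossings with refractory merge", {
  dt <- 0.1
  flat <- rep(-70, 1000)
  expect_length(detect_spikes(flat, threshold = -54, dt = dt), 0)

  # one synthetic AP waveform
  tr <- rep(-70, 1000)
  tr[501:520] <- c(seq(-70, 20, length.out = 10), seq(20, -70, length.out = 10))
  s <- detect_spikes(tr, threshold = -54, dt = dt)
  expect_length(s, 1)
  expect_equal(s, (which(tr >= -54)[1] - 1) * dt)

  # two crossings 1 ms apart merge into one spike
  tr2 <- rep(-70, 1000)
  tr2[c(301:303, 311:313)] <- 0
  expect_length(detect_spikes(tr2, threshold = -54, dt = dt,
                              merge_window = 2), 1)
  expect_length(detect_spikes(tr2, threshold = -54, dt = dt,
                              merge_window = 0.5), 2)
  expect_error(detect_spikes(c(1, NA, 3)), "finite")
})

test_that("average firing frequency is the mean count over duration", {
  expect_equal(average_ff(list(seq(0, 9000, by = 1000)), 10), 1)
  expect_equal(average_ff(list(1:10 * 10, 1:30 * 10), 10), 2)
  expect_equal(average_ff(list(numeric(0), numeric(0)), 10), 0)
  expect_error(average_ff(list(), 10), "empty")
  expect_error(average_ff(list(1:3), 0), "duration")
  # linearity: doubling every trial's count doubles ff
  trials <- list(c(1, 5, 9), c(2, 4))
  doubled <- lapply(trials, function(s) sort(c(s, s + 0.5)))
  expect_equal(average_ff(doubled, 10), 2 * average_ff(trials, 10))
})

test_that("burst segmentation follows the maximal-run rule", {
  empty <- segment_bursts(numeric(0))
  expect_length(empty$bursts, 0)

  bs <- segment_bursts(c(0, 10, 20, 1000, 1010), max_intra_isi = 50)
  expect_length(bs$bursts, 2)
  expect_equal(bs$intra_isis[[1]], c(10, 10))
  expect_equal(bs$intra_isis[[2]], 10)
  expect_equal(bs$onsets, c(0, 1000))
  expect_equal(bs$n_singletons, 0L)

  # a regular 1 Hz train contains no bursts, only singletons
  reg <- segment_bursts(seq(0, 9000, by = 1000), max_intra_isi = 50)
  expect_length(reg$bursts, 0)
  expect_equal(reg$n_singletons, 10L)

  expect_error(segment_bursts(c(10, 5)), "increasing")
})

test_that("mean burst ISI averages per-trial means over bursting trials", {
  one <- segment_bursts(c(0, 10, 20))
  expect_equal(as.numeric(mean_burst_isi(list(one))), 10)

  t1 <- segment_bursts(c(0, 10, 20))            # mean 10
  t2 <- segment_bursts(c(0, 20, 40))            # mean 20
  expect_equal(as.numeric(mean_burst_isi(list(t1, t2))), 15)

  # non-bursting trial excluded, not averaged in as zero
  t3 <- segment_bursts(seq(0, 5000, by = 1000))
  m <- mean_burst_isi(list(t1, t2, t3))
  expect_equal(as.numeric(m), 15)
  expect_equal(attr(m, "n_bursting"), 2L)

  expect_warning(out <- mean_burst_isi(list(t3)), "undefined")
  expect_true(is.na(out))
})

test_that("duty cycle is burst span over onset-to-onset interval", {
  bs <- segment_bursts(c(0, 15, 30, 1000, 1015, 1030, 2000, 2015, 2030))
  expect_equal(as.numeric(duty_cycle(bs)), 0.03)
  single <- segment_bursts(c(0, 10))
  expect_true(is.na(duty_cycle(single)))
  expect_equal(attr(duty_cycle(single), "n_pairs"), 0L)
})

test_that("time-to-first-spike references subtract correctly", {
  trial <- list(spikes = c(80, 500), slm_onset = 0, sr_onset = 60)
  expect_equal(time_to_first_spike(trial, "SLM_onset"), 80)
  expect_equal(time_to_first_spike(trial, "SR_onset"), 20)
  # spike before SR onset keeps its sign
  early <- list(spikes = 40, slm_onset = 0, sr_onset = 60)
  expect_equal(time_to_first_spike(early, "SR_onset"), -20)
  none <- list(spikes = numeric(0), slm_onset = 0, sr_onset = 60)
  expect_true(is.na(time_to_first_spike(none)))
})

test_that("the ttfs identity ttfs_SLM = ttfs_SR + delay holds exactly", {
  recs <- filter_trials(sim_condition("fully_diffused", 60, n = 6))
  for (r in recs) {
    expect_equal(time_to_first_spike(r, "SLM_onset"),
                 time_to_first_spike(r, "SR_onset") + r$delay)
  }
})

test_that("local variation matches its closed form and Poisson limit", {
  expect_equal(local_variation(rep(7, 50)), 0)
  expect_equal(local_variation(c(1, 2)), 1 / 3)
  set.seed(11)
  expect_equal(local_variation(rexp(20000)), 1, tolerance = 0.1)
  expect_error(local_variation(5), "two")
  expect_error(local_variation(c(1, 0)), "> 0")
})

test_that("the trial filter applies the single-pathway rules", {
  mk <- function(sub, rate) list(spikes = 1, slm_subthreshold = sub,
                                 sr_alone_rate = rate)
  recs <- list(mk(TRUE, 2), mk(FALSE, 2), mk(TRUE, 4), mk(TRUE, 0.5),
               mk(TRUE, 1), mk(TRUE, 3))
  acc <- filter_trials(recs)
  expect_length(acc, 3)                 # 2 Hz, 1 Hz and 3 Hz pass
  expect_equal(attr(acc, "yield"), 0.5)
  expect_error(filter_trials(list(list(spikes = 1))), "calibration")
})
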