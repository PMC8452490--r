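test_that("max-interval burst detection handles the canonical fixtures", {
  st <- spike_train(c(0, .05, .10, .15, .20, 1.0, 2.0), NULL, 1)
  b <- detect_bursts(st, burst_settings(max_isi = 0.1, min_spikes = 5))
  expect_equal(nrow(b), 1)
  expect_equal(b$start, 0)
  expect_equal(b$end, 0.20)
  expect_equal(b$n_spikes, 5L)

  # perfectly periodic 1 Hz train: every ISI exceeds max_isi
  periodic <- spike_train(0:59, NULL, 1)
  expect_equal(nrow(detect_bursts(periodic, burst_settings(0.1, 5))), 0)

  # two runs separated by exactly max_isi merge (inclusive comparison)
  ts <- c(seq(0, 0.08, by = 0.02), seq(0.18, 0.26, by = 0.02))
  b <- detect_bursts(spike_train(ts, NULL, 1), burst_settings(0.1, 5))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 10L)

  expect_equal(nrow(detect_bursts(spike_train(electrode_id = 1),
                                  burst_settings())), 0)
})

test_that("burst detection equals the exhaustive-scan oracle", {
  set.seed(123)
  for (i in 1:300) {
    n <- sample(0:60, 1)
    st <- rand_train(n, duration = 10)
    max_isi <- runif(1, 0.02, 0.5)
    min_spikes <- sample(2:6, 1)
    got <- detect_bursts(st, burst_settings(max_isi, min_spikes))
    want <- oracle_bursts(st$timestamps, max_isi, min_spikes)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_spikes, want$n_spikes)
    }
  }
})

test_that("shrinking max_isi never grows any burst", {
  set.seed(5)
  for (i in 1:50) {
    st <- rand_train(80, duration = 20)
    wide <- detect_bursts(st, burst_settings(0.3, 3))
    narrow <- detect_bursts(st, burst_settings(0.1, 3))
    expect_lte(sum(narrow$n_spikes), sum(wide$n_spikes))
    if (nrow(narrow) && nrow(wide)) {
      expect_lte(max(narrow$n_spikes), max(wide$n_spikes))
    }
  }
})

test_that("channel burst statistics match hand computation", {
  b <- data.frame(electrode_id = 1L, start = c(0, 10), end = c(0.2, 10.5),
                  n_spikes = c(5L, 10L))
  s <- channel_burst_statistics(b, duration = 60)
  expect_equal(s$BR, 2)
  expect_equal(s$BD, 0.35)
  expect_equal(s$BSR, mean(c(25, 20)))
  expect_equal(s$IBI, 9.8)
  expect_true(all(s$defined))

  ten <- data.frame(electrode_id = 1L, start = seq(0, 540, by = 60),
                    end = seq(0.5, 540.5, by = 60), n_spikes = 5L)
  expect_equal(channel_burst_statistics(ten, 600)$BR, 1)

  one <- b[1, ]
  s1 <- channel_burst_statistics(one, 60)
  expect_true(is.na(s1$IBI))
  expect_false(s1$defined[["IBI"]])

  expect_error(channel_burst_statistics(b, 0), "duration")
})

test_that("mean firing rate follows the all-electrode rule", {
  trains <- lapply(1:12, function(k) {
    spike_train(seq(0.5, 599.5, length.out = 600) + k * 1e-6, NULL, k)
  })
  expect_equal(mean_firing_rate(well_recording(trains, 600)), 1.0)

  # 3 active electrodes at 4 Hz, 9 silent: the mean is over all 12 slots
  trains3 <- lapply(1:3, function(k) {
    spike_train(seq(0.1, 599.9, length.out = 2400) + k * 1e-6, NULL, k)
  })
  expect_equal(mean_firing_rate(well_recording(trains3, 600)), 1.0)

  expect_equal(mean_firing_rate(well_recording(duration = 600)), 0)
})

test_that("PRS counts exactly the spikes outside bursts", {
  st <- spike_train(c(0, .05, .10, .15, .20, 1.0, 2.0), NULL, 1)
  well <- well_recording(list(st), duration = 10)
  bursts <- detect_bursts_well(well, burst_settings(0.1, 5))
  prs <- percentage_random_spikes(well, bursts)
  expect_equal(prs$PRS, 100 * 2 / 7, tolerance = 1e-12)

  # all spikes inside bursts
  dense <- spike_train(seq(0, 0.5, by = 0.05), NULL, 1)
  wd <- well_recording(list(dense), duration = 10)
  expect_equal(percentage_random_spikes(
    wd, detect_bursts_well(wd, burst_settings(0.1, 5)))$PRS, 0)

  # no bursts at all
  sparse <- well_recording(list(spike_train(c(1, 3, 5), NULL, 1)),
                           duration = 10)
  expect_equal(percentage_random_spikes(
    sparse, detect_bursts_well(sparse))$PRS, 100)

  empty <- well_recording(duration = 10)
  out <- percentage_random_spikes(empty, detect_bursts_well(empty))
  expect_equal(out$PRS, 0)
  expect_false(out$defined)
})

test_that("burst plus random spikes conserve the total (PRS conservation)", {
  set.seed(99)
  for (i in 1:25) {
    trains <- lapply(1:12, function(k) rand_train(sample(0:200, 1), 30, k))
    well <- well_recording(trains, duration = 30)
    bursts <- detect_bursts_well(well, burst_settings(0.2, 3))
    n_in <- sum(vapply(seq_len(12), function(k) {
      tr <- well$trains[[k]]
      b <- bursts[bursts$electrode_id == k, , drop = FALSE]
      if (!nrow(b)) return(0L)
      sum(vapply(tr$timestamps, function(t) {
        any(t >= b$start & t <= b$end)
      }, logical(1)))
    }, integer(1)))
    prs <- percentage_random_spikes(well, bursts)$PRS
    total <- well_spike_count(well)
    if (total > 0) {
      expect_equal(prs, 100 * (total - n_in) / total, tolerance = 1e-12)
    }
  }
})
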