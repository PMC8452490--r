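test_that("synchronized events across all channels become network bursts", {
  well <- sync_well(onsets = c(10, 20, 30), width = 0.1, channels = 1:12,
                    n_per = 10, duration = 60)
  nbs <- detect_network_bursts(well)
  expect_equal(nrow(nbs), 3)
  expect_equal(nbs$n_channels, rep(12L, 3))
  expect_true(all(abs(nbs$start - c(10, 20, 30)) < 0.1))

  # the same events on only 2 of 12 channels: participation 17% < 25%
  well2 <- sync_well(onsets = c(10, 20, 30), channels = 1:2, duration = 60)
  expect_equal(nrow(detect_network_bursts(well2)), 0)

  expect_equal(nrow(detect_network_bursts(well_recording(duration = 60))), 0)
})

test_that("network-burst detection equals the direct-scan oracle", {
  set.seed(21)
  for (i in 1:40) {
    trains <- lapply(1:12, function(k) rand_train(sample(0:80, 1), 20, k))
    # add a couple of synchronized events so some wells have real NBs
    if (i %% 2 == 0) {
      trains <- lapply(trains, function(tr) {
        extra <- as.vector(outer((0:4) / 100, c(5, 12), "+")) +
          tr$electrode_id / 1000
        spike_train(sort(unique(c(tr$timestamps, extra))), NULL,
                    tr$electrode_id)
      })
    }
    well <- well_recording(trains, duration = 20)
    st <- nb_settings(min_nb_spikes = 5)
    got <- detect_network_bursts(well, st)
    want <- oracle_network_bursts(well, st)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want[, 1])
      expect_equal(got$end, want[, 2])
      expect_equal(got$n_channels, as.integer(want[, 3]))
      expect_equal(got$n_spikes, as.integer(want[, 4]))
    }
  }
})

test_that("raising the threshold never adds network bursts, and bursts never overlap", {
  set.seed(31)
  for (i in 1:10) {
    well <- sync_well(onsets = seq(3, 55, by = 7) + runif(8, 0, 0.5),
                      width = 0.3, channels = 1:10, n_per = 8, duration = 60)
    counts <- vapply(c(2, 4, 8, 16), function(thr) {
      nrow(detect_network_bursts(well, nb_settings(rate_threshold = thr,
                                                   min_nb_spikes = 5)))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
    nbs <- detect_network_bursts(well, nb_settings(min_nb_spikes = 5))
    if (nrow(nbs) > 1) {
      expect_true(all(nbs$start[-1] >= nbs$end[-nrow(nbs)]))
    }
  }
})

test_that("network-burst statistics match hand computation", {
  # perfectly regular: equal onset spacing and equal durations
  nbs <- data.frame(start = c(0, 10, 20, 30), end = c(1, 11, 21, 31),
                    n_channels = 12L, n_spikes = 100L)
  s <- network_burst_statistics(nbs, 600)
  expect_equal(s$CV_NIBI, 0)
  expect_equal(s$NIBI, 9)

  # gaps of 5 and 10 s
  nbs2 <- data.frame(start = c(0, 6, 17), end = c(1, 7, 18),
                     n_channels = 12L, n_spikes = 100L)
  s2 <- network_burst_statistics(nbs2, 60)
  expect_equal(s2$NIBI, 7.5)
  expect_equal(s2$CV_NIBI, sd(c(5, 10)) / 7.5, tolerance = 1e-12)
  expect_equal(round(s2$CV_NIBI, 4), 0.4714)

  nbs19 <- data.frame(start = seq(0, by = 30, length.out = 19),
                      end = seq(1, by = 30, length.out = 19),
                      n_channels = 12L, n_spikes = 100L)
  expect_equal(network_burst_statistics(nbs19, 600)$NBR, 1.9)

  s0 <- network_burst_statistics(nbs19[0, ], 600)
  expect_equal(s0$NBR, 0)
  expect_false(s0$defined[["NBD"]])
  s1 <- network_burst_statistics(nbs19[1, ], 600)
  expect_true(is.na(s1$NIBI))
  expect_false(s1$defined[["NIBI"]])
})

test_that("boxcar network bursts give a flat-top, peak-normalisable shape", {
  well <- sync_well(onsets = seq(5, 55, by = 10), width = 0.5,
                    channels = 1:12, n_per = 50, duration = 60)
  nbs <- detect_network_bursts(well)
  expect_gt(nrow(nbs), 3)
  sh <- network_burst_shape(well, nbs, bin_width = 0.05, window = 1,
                            normalization = "peak")
  expect_equal(max(sh$profile), 1)
  # flat top: all bins inside the boxcar near the peak level
  inside <- sh$profile[sh$t > 0.05 & sh$t < 0.45]
  expect_true(all(inside > 0.9))
  # and near zero after the boxcar ends
  expect_true(all(sh$profile[sh$t > 0.6] < 0.1))

  # single NB: profile equals that burst's own binned rate
  one <- nbs[1, , drop = FALSE]
  sh1 <- network_burst_shape(well, one, bin_width = 0.05, window = 1)
  pooled <- sort(unlist(lapply(well$trains, `[[`, "timestamps")))
  sel <- pooled[pooled >= one$start & pooled < one$start + 1]
  manual <- tabulate(floor((sel - one$start) / 0.05) + 1L, nbins = 20) / 0.05
  expect_equal(sh1$profile, manual)

  expect_error(network_burst_shape(well, nbs[0, ], 0.05, 1), "network bursts")
})

test_that("the mean shape recovers a gamma envelope within 5% RMS", {
  set.seed(77)
  theta <- 0.1
  onsets <- seq(2, 600, by = 3)[1:200]
  spikes_per_nb <- 120
  trains <- lapply(1:12, function(k) {
    ts <- unlist(lapply(onsets, function(o) {
      o + rgamma(spikes_per_nb / 12, shape = 2, scale = theta)
    }))
    spike_train(sort(unique(round(ts * 1e5)) / 1e5), NULL, k)
  })
  well <- well_recording(trains, duration = 605)
  nbs <- data.frame(start = onsets, end = onsets + 1, n_channels = 12L,
                    n_spikes = spikes_per_nb)
  sh <- network_burst_shape(well, nbs, bin_width = 0.02, window = 1)
  analytic <- spikes_per_nb * dgamma(sh$t, shape = 2, scale = theta)
  rms <- sqrt(mean((sh$profile - analytic)^2))
  expect_lt(rms / max(analytic), 0.05)
})

test_that("rise and decay times behave on canonical profiles", {
  mk_shape <- function(profile, bw = 0.01) {
    structure(list(bin_width = bw, window = bw * length(profile),
                   profile = profile,
                   t = (seq_along(profile) - 0.5) * bw,
                   normalization = "none", n_nb = 1L), class = "nb_shape")
  }
  # symmetric triangle, total width 1.0 s, starting from zero
  up <- seq(0, 1, length.out = 51)
  tri <- mk_shape(c(up, rev(up)[-1], rep(0, 20)))
  rd <- rise_decay_times(tri, lo_frac = 1e-6)
  expect_equal(rd$RT, 0.5, tolerance = 0.03)
  expect_equal(rd$DT, 0.5, tolerance = 0.03)
  expect_false(rd$degenerate)

  # right-skewed gamma envelope: decay longer than rise
  t <- seq(0.005, 2, by = 0.01)
  gam <- mk_shape(c(0, dgamma(t, shape = 2, scale = 0.2)))
  rdg <- rise_decay_times(gam, lo_frac = 0.1)
  expect_gt(rdg$DT, rdg$RT)

  # boxcar: degenerate, both times on the order of a bin
  box <- mk_shape(c(rep(1, 30), rep(0, 30)))
  rdb <- rise_decay_times(box, lo_frac = 0.1)
  expect_true(rdb$degenerate)

  # peak at the window edge is flagged undefined
  ramp <- mk_shape(seq(0, 1, length.out = 50))
  rde <- rise_decay_times(ramp)
  expect_true(is.na(rde$RT) && is.na(rde$DT))
  expect_false(any(rde$defined))
})
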