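test_that("identical trains give a unit zero-lag correlation", {
  ts <- seq(0.5, 59.5, by = 0.5)
  a <- spike_train(ts, NULL, 1)
  b <- spike_train(ts, NULL, 2)
  cc <- cross_correlogram(a, b)
  expect_equal(cc$values[cc$lags == 0], 1.0)
})

test_that("a time-shifted copy peaks at the shift lag (sign convention)", {
  ts <- sort(runif(200, 1, 58))
  a <- spike_train(ts, NULL, 1)
  b <- spike_train(ts + 0.05, NULL, 2)
  cc <- cross_correlogram(a, b)
  # b fires after a: the peak sits at positive lag +0.05
  expect_equal(cc$lags[which.max(cc$values)], 0.05)
  # and the transposed pair peaks at -0.05
  cc_t <- cross_correlogram(b, a)
  expect_equal(cc_t$lags[which.max(cc_t$values)], -0.05)
  expect_equal(cc$values, rev(cc_t$values))
})

test_that("correlogram equals brute-force pair counting", {
  set.seed(17)
  for (i in 1:50) {
    a <- rand_train(sample(5:60, 1), 20, 1)
    b <- rand_train(sample(5:60, 1), 20, 2)
    window <- sample(c(0.2, 0.5), 1)
    bin <- sample(c(0.01, 0.05), 1)
    got <- cross_correlogram(a, b, window, bin)
    want <- oracle_xcorr(a$timestamps, b$timestamps, window, bin)
    expect_equal(got$values,
                 want / sqrt(n_spikes(a) * n_spikes(b)))
  }
})

test_that("C_peak dominates C_0 and empty trains flag a zero correlogram", {
  set.seed(23)
  for (i in 1:20) {
    a <- rand_train(50, 30, 1)
    b <- rand_train(50, 30, 2)
    cc <- cross_correlogram(a, b)
    expect_gte(max(cc$values), cc$values[cc$lags == 0])
    expect_true(all(cc$values >= 0))
  }
  cc0 <- cross_correlogram(spike_train(electrode_id = 1),
                           rand_train(10, 30, 2))
  expect_true(cc0$flag_empty)
  expect_true(all(cc0$values == 0))
})

test_that("a well of identical trains is fully connected with unit weight", {
  ts <- seq(0.5, 119.5, by = 0.5)
  well <- well_recording(lapply(1:12, function(k) spike_train(ts, NULL, k)),
                         duration = 120)
  conn <- pairwise_connectivity(well)
  off <- upper.tri(conn$c0_matrix)
  expect_true(all(conn$c0_matrix[off] == 1))
  expect_true(all(conn$cpeak_matrix[off] == 1))
  expect_true(isSymmetric(conn$c0_matrix[1:12, 1:12] + 0,
                          tol = 0, check.attributes = FALSE) ||
                all(conn$c0_matrix == t(conn$c0_matrix), na.rm = TRUE))
  conn <- functional_links(conn, well, n_surrogates = 30, seed = 4)
  expect_equal(conn$n_connections, 66L)
  expect_equal(conn$link_weight, 1)
})

test_that("a silent well yields zero matrices, flagged", {
  conn <- pairwise_connectivity(well_recording(duration = 60))
  expect_true(conn$flag_silent)
  expect_true(all(conn$c0_matrix[upper.tri(conn$c0_matrix)] == 0))
})

test_that("functional links are reproducible and match the alpha null rate", {
  set.seed(55)
  mk_poisson_well <- function(seed) {
    set.seed(seed)
    well_recording(lapply(1:12, function(k) rand_train(240, 120, k)),
                   duration = 120)
  }
  well <- mk_poisson_well(1000)
  conn <- pairwise_connectivity(well)
  l1 <- functional_links(conn, well, n_surrogates = 40, seed = 7)
  l2 <- functional_links(conn, well, n_surrogates = 40, seed = 7)
  expect_identical(l1$links, l2$links)
  expect_identical(l1$threshold, l2$threshold)

  # independent Poisson trains: expected links ~ alpha * 66
  n_links <- vapply(1:6, function(s) {
    w <- mk_poisson_well(2000 + s)
    cn <- pairwise_connectivity(w)
    functional_links(cn, w, n_surrogates = 40, alpha = 0.05,
                     seed = s)$n_connections
  }, integer(1))
  mu <- 0.05 * 66
  # binomial bounds over 6 x 66 pair tests (correlated within a well;
  # allow 3 SDs on the pooled count)
  total <- sum(n_links)
  expect_lt(abs(total - 6 * mu),
            3 * sqrt(6 * 66 * 0.05 * 0.95) + 6)
  expect_warning(functional_links(conn, well, n_surrogates = 10, seed = 1),
                 "surrogates")
})

test_that("stronger participation raises the mean pairwise correlation", {
  mean_cpeak <- function(participation, seed) {
    sim <- simulate_well(
      phenotype_params(nb_rate = 4, participation = participation,
                       intra_nb_rate = 30, channel_burst_rate = 0,
                       background_rate = 0.2),
      duration = 120, seed = seed)
    conn <- pairwise_connectivity(sim$recording)
    mean(conn$cpeak_matrix[upper.tri(conn$cpeak_matrix)])
  }
  hi <- vapply(1:5, function(s) mean_cpeak(1.0, 6000 + s), numeric(1))
  lo <- vapply(1:5, function(s) mean_cpeak(0.3, 7000 + s), numeric(1))
  expect_gt(mean(hi), mean(lo))
  expect_true(all(hi > lo))
})
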