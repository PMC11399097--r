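test_that("identical trains all pass the correlation filter with r = 1", {
  prof <- matrix(rep(exp(-seq(0.08, 1.5, length.out = 170)) * 1e5, 6), 170)
  ts <- train_series(rep(list(prof[, 1:6]), 10), q_grid(), pulse_time_grid(6, 564e3),
                     rep(c(TRUE, FALSE), 5))
  f <- filter_trains(ts)
  expect_equal(f$n_kept, 10)
  expect_true(all(abs(f$report$correlation - 1) < 1e-12))
})

test_that("the 0.99995 filter drops exactly the injected trains", {
  cfg <- generator_config(n_train_pairs = 5, pulses_per_train = 30, seed = 3)
  ts <- simulate_train_series(cfg)
  ts <- inject_instability(ts, ids = c(3, 8), seed = 30)
  f <- filter_trains(ts)  # threshold defaults to 0.99995
  expect_equal(f$n_kept, 8)
  expect_equal(which(!f$report$kept), c(3, 8))
  expect_equal(length(f$kept$profiles), 8)
  expect_length(f$kept$truth$corrupt_ids, 0)

  # everything below threshold is an error, not an empty success
  all_bad <- inject_instability(ts, ids = 1:10, strength = 0.5, seed = 31)
  expect_error(filter_trains(all_bad), "all trains")
})

test_that("filter retains everything for clean data and ~70% at 30% corruption", {
  cfg <- generator_config(n_train_pairs = 20, pulses_per_train = 10, seed = 12)
  f <- filter_trains(simulate_train_series(cfg))
  expect_equal(f$n_kept, 40)

  cfg3 <- generator_config(n_train_pairs = 20, pulses_per_train = 10,
                           corrupt_fraction = 0.3, seed = 13)
  ts3 <- simulate_train_series(cfg3)
  f3 <- filter_trains(ts3)
  expect_equal(f3$n_kept, 40 - length(ts3$truth$corrupt_ids))
  expect_equal(f3$n_kept / 40, 0.7)
})

test_that("normalization makes the window sum one and is scale invariant", {
  q <- seq(0.08, 2.1, length.out = 200)
  s <- exp(-q) * 1e6 + 300
  n1 <- normalize_profile(s, q)
  expect_equal(sum(n1[q >= 0.08 & q <= 2.1]), 1, tolerance = 1e-12)
  expect_equal(normalize_profile(7.3 * s, q), n1)
  # high-q display window variant
  n2 <- normalize_profile(s, q, q_lo = 1.4, q_hi = 1.6)
  expect_equal(sum(n2[q >= 1.4 & q <= 1.6]), 1, tolerance = 1e-12)
  expect_error(normalize_profile(-s, q), "non-positive")
  expect_error(normalize_profile(s, q, q_lo = 3, q_hi = 4), "no q bins")
})

test_that("difference of identical light/dark classes is zero and antisymmetric", {
  ts <- noiseless_series(seed = 7, pairs = 2, pulses = 8)
  # force light identical to dark
  ts0 <- ts
  ts0$profiles[c(1, 3)] <- ts0$profiles[c(2, 4)]
  dS0 <- compute_difference(ts0)
  expect_true(all(dS0$delta_S == 0))

  # label swap flips the sign exactly
  dS <- compute_difference(ts, normalize = FALSE)
  swapped <- ts
  swapped$light_flag <- !swapped$light_flag
  dSsw <- compute_difference(swapped, normalize = FALSE)
  expect_equal(dSsw$delta_S, -dS$delta_S)
  expect_error(compute_difference(
    train_series(ts$profiles[c(1, 3)], ts$q, ts$time_us, c(TRUE, TRUE),
                 check_alternating = FALSE)), "light and one dark")
})

test_that("noiseless difference reproduces yield times the composed kinetics exactly", {
  ts <- noiseless_series(seed = 11, pairs = 3, pulses = 20)
  dS <- compute_difference(ts, normalize = FALSE)
  truth <- ts$truth
  expected <- truth$yield_c * truth$basis_spectra %*% t(truth$concentrations)
  expect_equal(dS$delta_S, unname(expected), tolerance = 1e-9)
  expect_equal(dS$n_light_frames, 3 * 20)
})

test_that("adjacent-pair subtraction suppresses drifting train-level jitter", {
  # the common-mode factor drifts slowly, so adjacent light/dark pairs share
  # nearly the same factor while shuffled (non-adjacent) pairs do not
  cfg <- generator_config(n_train_pairs = 100, pulses_per_train = 4,
                          photons_per_pulse_scale = 1e7,
                          yield_c = 0, jitter_sd = 5e-3, seed = 17)
  ts <- simulate_train_series(cfg)
  li <- which(ts$light_flag); di <- which(!ts$light_flag)
  pair_var <- function(dark_order) {
    var(as.numeric(vapply(seq_along(li), function(k) {
      ts$profiles[[li[k]]] - ts$profiles[[dark_order[k]]]
    }, ts$profiles[[1]])))
  }
  set.seed(1)
  v_adj <- pair_var(di)
  v_shuf <- pair_var(sample(di))
  expect_lt(v_adj, v_shuf)
})

test_that("per-curve normalization removes common-mode factors between distant trains", {
  cfg <- generator_config(n_train_pairs = 30, pulses_per_train = 4,
                          photons_per_pulse_scale = 1e7,
                          yield_c = 0, jitter_sd = 1e-2, seed = 18)
  ts <- simulate_train_series(cfg)
  li <- which(ts$light_flag); di <- rev(which(!ts$light_flag))
  qv <- ts$q$values
  W <- sum(ts$truth$s_dark)
  norm1 <- function(p) apply(p, 2, normalize_profile, q = qv)
  # distant (reversed) pairs: the drifting common-mode factor does not
  # cancel in raw differences, but normalization removes it exactly
  v_raw <- var(as.numeric(vapply(seq_along(li), function(k) {
    ts$profiles[[li[k]]] - ts$profiles[[di[k]]]
  }, ts$profiles[[1]])))
  v_norm <- var(as.numeric(vapply(seq_along(li), function(k) {
    W * (norm1(ts$profiles[[li[k]]]) - norm1(ts$profiles[[di[k]]]))
  }, ts$profiles[[1]])))
  expect_lt(v_norm, v_raw)
})

test_that("an unpaired trailing train is dropped with a message", {
  ts <- noiseless_series(seed = 19, pairs = 3, pulses = 5)
  odd <- train_series(ts$profiles[1:5], ts$q, ts$time_us, ts$light_flag[1:5],
                      check_alternating = FALSE)
  expect_message(compute_difference(odd, pairing = "adjacent"), "unpaired")
})

test_that("concentration-series merging recovers scale/offset and weights correctly", {
  ts <- noiseless_series(seed = 23, pairs = 2, pulses = 12)
  A <- compute_difference(ts, normalize = FALSE)
  # identical inputs: merged = input, a = 1, b = 0
  m0 <- merge_concentrations(A, A)
  expect_equal(m0$delta_S, A$delta_S)
  expect_equal(m0$provenance$scale, 1)
  expect_lt(abs(m0$provenance$offset), 1e-9 * sd(A$delta_S))

  # constructed low-concentration set: recover a0, b0 exactly
  a0 <- 2.5; b0 <- 0.05 * sd(A$delta_S)
  B <- difference_series(A$q, A$time_us, (A$delta_S - b0) / a0,
                         n_light_frames = A$n_light_frames)
  m1 <- merge_concentrations(A, B)
  expect_equal(m1$provenance$scale, a0, tolerance = 1e-9)
  expect_equal(m1$provenance$offset, b0, tolerance = 1e-9)
  expect_equal(m1$delta_S, A$delta_S, tolerance = 1e-9)

  # 3:1 weights give (3A + B')/4
  A3 <- difference_series(A$q, A$time_us, A$delta_S, n_light_frames = 3)
  Bp <- difference_series(A$q, A$time_us, 2 * A$delta_S, n_light_frames = 1)
  m2 <- merge_concentrations(A3, Bp)
  # aligned low set equals A (least squares maps 2A back onto A)
  expect_equal(m2$delta_S, A$delta_S, tolerance = 1e-9)

  bad <- difference_series(q_grid(0.1, 1.4, 170), A$time_us, A$delta_S,
                           n_light_frames = 1)
  expect_error(merge_concentrations(A, bad), "grids must match")
})

test_that("difference noise floor scales as 1/sqrt(retained train pairs)", {
  floor_at <- function(pairs, seed) {
    cfg <- generator_config(n_train_pairs = pairs, pulses_per_train = 6,
                            yield_c = 0, seed = seed)
    dS <- compute_difference(filter_trains(simulate_train_series(cfg))$kept)
    sd(as.numeric(dS$delta_S))
  }
  f1 <- mean(sapply(41:43, function(s) floor_at(12, s)))
  f4 <- mean(sapply(41:43, function(s) floor_at(48, s)))
  expect_lt(abs(f1 / f4 - 2), 0.15 * 2)
})
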