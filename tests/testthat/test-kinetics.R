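test_that("sequential concentrations follow the exponential conversion laws", {
  t <- c(0, 1, 5, 20, 100, 300)
  m2 <- sequential_model(2, 0.3)
  C2 <- concentration_profiles(m2, t)
  expect_equal(C2[, "A"], exp(-0.3 * t))
  expect_equal(C2[, "B"], 1 - exp(-0.3 * t))
  expect_equal(unname(C2[1, ]), c(1, 0))

  m3 <- sequential_model(3, c(0.2, 0.05))
  C3 <- concentration_profiles(m3, t)
  expect_equal(unname(C3[1, ]), c(1, 0, 0))
  kA <- 0.2; kB <- 0.05
  expect_equal(C3[, "B"], kA / (kB - kA) * (exp(-kA * t) - exp(-kB * t)))
  # closed-form argmax of the intermediate population
  tmax <- log(kA / kB) / (kA - kB)
  expect_equal(tmax, 9.24196, tolerance = 1e-5)
  tt <- seq(0, 60, by = 0.001)
  CB <- concentration_profiles(m3, tt)[, "B"]
  expect_equal(tt[which.max(CB)], tmax, tolerance = 1e-3)
  expect_error(concentration_profiles(m3, -1), "non-negative")
  expect_error(sequential_model(3, 0.2), "rate")
  expect_error(sequential_model(4, c(1, 2, 3)), "n_states")
})

test_that("mass is conserved and populations stay in [0, 1] over random rates", {
  set.seed(101)
  for (i in 1:25) {
    rates <- 10^runif(2, -3, 1)
    t <- sort(runif(40, 0, 400))
    C <- concentration_profiles(sequential_model(3, rates), t)
    expect_equal(unname(rowSums(C)), rep(1, 40), tolerance = 1e-9)
    expect_true(all(C >= -1e-12 & C <= 1 + 1e-12))
    # A strictly decreasing, C strictly increasing (away from numerical
    # saturation at 0 and 1)
    live <- C[, "A"] > 1e-12
    expect_true(all(diff(C[live, "A"]) < 0))
    grow <- C[, "C"] < 1 - 1e-12
    expect_true(all(diff(C[grow, "C"]) > 0))
    expect_true(all(diff(C[, "A"]) <= 0) && all(diff(C[, "C"]) >= 0))
  }
})

test_that("near-degenerate rates switch to the confluent limit k t exp(-k t)", {
  kA <- 0.3
  t <- seq(0, 50, length.out = 200)
  limit <- kA * t * exp(-kA * t)
  # generic formula at a tiny rate gap approaches the limit
  gap <- concentration_profiles(sequential_model(3, c(kA, kA * (1 + 1e-6)),
                                                 degenerate_tol = 1e-12), t)
  expect_lt(max(abs(gap[, "B"] - limit)), 1e-6 * max(limit))
  # within tolerance the analytic limit is used exactly
  lim <- concentration_profiles(sequential_model(3, c(kA, kA * (1 + 1e-9))), t)
  expect_equal(lim[, "B"], limit)
})

test_that("basis-spectrum solve matches a normal-equations oracle", {
  set.seed(7)
  nq <- 5; nt <- 8
  C <- concentration_profiles(sequential_model(3, c(0.4, 0.05)),
                              seq(0, 60, length.out = nt))
  BS_true <- matrix(rnorm(nq * 3), nq)
  dS <- BS_true %*% t(C)
  # consistent system: exact recovery
  expect_equal(solve_basis_spectra(dS, C), BS_true, tolerance = 1e-9,
               ignore_attr = TRUE)
  # noisy system: agree with the independent normal-equations solution
  dSn <- dS + matrix(rnorm(nq * nt, sd = 0.1), nq)
  oracle <- t(solve(t(C) %*% C, t(C) %*% t(dSn)))
  expect_equal(solve_basis_spectra(dSn, C), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  # single-state constant concentration: least squares is the time mean
  C1 <- matrix(1, nt, 1)
  expect_equal(as.numeric(solve_basis_spectra(dSn, C1)), rowMeans(dSn),
               tolerance = 1e-12)
  # collinear states are refused
  Cbad <- cbind(C[, 1], C[, 1], C[, 3])
  expect_error(solve_basis_spectra(dS, Cbad), "rank deficient")
})

test_that("variable projection recovers rates on noiseless synthetic data", {
  ts <- noiseless_series(seed = 5, pairs = 1, pulses = 175)
  dS <- compute_difference(ts, normalize = FALSE)
  fit <- fit_kinetics(dS, n_states = 3)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.5, 0.01), tolerance = 1e-4)
  expect_lt(fit$residual_r, 1e-10)
  # reconstruction and residual methods are consistent
  expect_equal(predict(fit) + residuals(fit), dS$delta_S, ignore_attr = TRUE)
})

test_that("fitted kinetic model methods expose rates, summary and simulation", {
  ts <- noiseless_series(seed = 2, pairs = 1, pulses = 40)
  fit <- fit_kinetics(compute_difference(ts, normalize = FALSE), n_states = 3)
  expect_named(coef(fit), c("k_A", "k_B"))
  expect_output(print(fit), "k_A")
  expect_output(summary(fit), "signal power")
  expect_equal(dim(predict(fit, time_us = c(0, 5, 10))), c(170, 3))
})

test_that("variable projection agrees with brute-force joint optimization on a tiny instance", {
  set.seed(33)
  t <- seq(0, 20, length.out = 6)
  kA_true <- 0.25
  C <- concentration_profiles(sequential_model(2, kA_true), t)
  BS_true <- matrix(c(1.5, -0.7, 0.4, 0.9), 2)
  dS <- BS_true %*% t(C) + matrix(rnorm(12, sd = 0.03), 2)
  vp <- fit_kinetics(dS, n_states = 2, time_us = t)
  # brute force: optimize rate and both spectra jointly
  joint <- function(p) {
    Cj <- concentration_profiles(sequential_model(2, exp(p[1])), t)
    sum((dS - matrix(p[2:5], 2) %*% t(Cj))^2)
  }
  bf <- optim(c(log(0.1), 1, -1, 0, 1), joint,
              control = list(reltol = 1e-14, maxit = 20000))
  expect_equal(unname(coef(vp)[1]), exp(bf$par[1]), tolerance = 1e-3)
  expect_equal(vp$residual_r, bf$value, tolerance = 1e-6)
})

test_that("the fit residual is invariant under q-bin permutation", {
  ts <- noiseless_series(seed = 13, pairs = 1, pulses = 30)
  dS <- compute_difference(ts, normalize = FALSE)
  fit <- fit_kinetics(dS, n_states = 2)
  perm <- sample(nrow(dS$delta_S))
  fitp <- fit_kinetics(dS$delta_S[perm, ], n_states = 2, time_us = dS$time_us)
  expect_equal(fitp$residual_r, fit$residual_r, tolerance = 1e-8)
})

test_that("rates are recovered within 10% median error under realistic noise", {
  # inverse-variance (Poisson) weighting via the weight hook
  errs <- sapply(1:20, function(s) {
    ts <- simulate_train_series(generator_config(seed = 200 + s))
    dark <- rowMeans(vapply(ts$profiles[!ts$light_flag], rowMeans,
                            numeric(170)))
    dS <- compute_difference(filter_trains(ts)$kept, normalize = FALSE)
    fit <- fit_kinetics(dS, n_states = 3, weights = 1 / dark)
    mean(abs(coef(fit) - c(0.5, 0.01)) / c(0.5, 0.01))
  })
  expect_lt(median(errs), 0.10)
})

test_that("model comparison selects the larger model only on real improvement", {
  ts <- noiseless_series(seed = 3, pairs = 1, pulses = 60)
  dS <- compute_difference(ts, normalize = FALSE)
  fit2 <- fit_kinetics(dS, n_states = 2)
  fit3 <- fit_kinetics(dS, n_states = 3)
  cmp <- compare_models(fit2, fit3)
  expect_lt(fit3$residual_r, fit2$residual_r)
  expect_equal(cmp$selected, 3)
  expect_length(cmp$slices, 5)

  # tiny improvement retains the smaller model
  fake3 <- fit3; fake3$residual_r <- fit2$residual_r * 0.99
  expect_equal(compare_models(fit2, fake3)$selected, 2)
  # mismatched data are refused
  other <- fit_kinetics(compute_difference(noiseless_series(seed = 4, pairs = 1,
                                                            pulses = 60),
                                           normalize = FALSE), n_states = 3)
  expect_error(compare_models(fit2, other), "hash")
})

test_that("a nested 3-state fit rarely beats 2-state truth by over 5%", {
  wins <- 0
  for (s in 1:8) {
    cfg <- generator_config(n_train_pairs = 30, pulses_per_train = 40,
                            rates = c(k_A = 0.05), seed = 300 + s)
    dS <- compute_difference(simulate_train_series(cfg))
    f2 <- fit_kinetics(dS, n_states = 2)
    f3 <- fit_kinetics(dS, n_states = 3)
    if (compare_models(f2, f3)$improvement > 0.05) wins <- wins + 1
  }
  expect_lte(wins, 1)
})
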