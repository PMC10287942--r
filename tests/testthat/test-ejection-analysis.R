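# Ensemble analysis layer, exercised on fabricated traces (the simulator is
# exercised separately): pathway calls, Wilson intervals, converged fractions,
# energy landscapes, and the persistence-length estimator against an
# independent discrete worm-like-chain sampler.

test_that("pathway classification follows i_exit and flags mid-chain exits", {
  expect_equal(as.character(classify_pathway(fixture_trace(1))), "FIFO")
  expect_false(attr(classify_pathway(fixture_trace(1)), "anomalous"))
  expect_equal(as.character(classify_pathway(fixture_trace(200))), "LIFO")
  mid <- classify_pathway(fixture_trace(100))
  expect_equal(as.character(mid), "FIFO")
  expect_true(attr(mid, "anomalous"))
  expect_error(classify_pathway(fixture_trace(NA_integer_)), "no exit")
})

test_that("P_FIFO uses the Wilson interval and excludes no-exit traces", {
  labs <- c(rep("FIFO", 100), rep("LIFO", 100))
  pf <- p_fifo(labs)
  expect_equal(pf$estimate, 0.5)
  expect_true(pf$lower < 0.5 && pf$upper > 0.5)

  pf0 <- p_fifo(rep("LIFO", 50))
  expect_equal(pf0$estimate, 0)
  expect_equal(pf0$lower, 0)
  expect_gt(pf0$upper, 0)   # one-sided-appropriate upper bound

  traces <- c(lapply(c(1, 1, 200), fixture_trace),
              list(fixture_trace(NA_integer_)))
  pf2 <- p_fifo(traces)
  expect_equal(pf2$n_fifo, 2)
  expect_equal(pf2$n_lifo, 1)
  expect_equal(pf2$n_excluded, 1)
  expect_equal(pf2$estimate, 2 / 3)
  # interval always contains the point estimate
  for (k in c(0, 1, 7, 20)) {
    ci <- wilson_interval(k, 20)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  }
})

test_that("converged fraction averages the final window", {
  tr <- fixture_trace(1, phi = rep(0.75, 500))
  expect_equal(converged_fraction(tr), 0.75)
  tr2 <- fixture_trace(1, phi = c(seq(0, 0.6, length.out = 450), rep(0.6, 50)),
                       converged = FALSE)
  expect_error(converged_fraction(tr2), "did not converge")
  expect_equal(converged_fraction(tr2, require_converged = FALSE), 0.6,
               tolerance = 0.01)
})

test_that("energy-vs-fraction resampling matches a single trace and averages", {
  phi <- seq(0.01, 1, by = 0.01)
  en <- 1000 - 300 * phi
  tr <- fixture_trace(1, phi = phi, energy = en)
  grid <- seq(0.1, 0.9, by = 0.1)
  curve <- energy_vs_fraction(list(tr), grid)
  expect_equal(curve$mean_energy, 1000 - 300 * grid, tolerance = 1e-9)

  # retractions: the running maximum is used for interpolation
  phi_jit <- phi; phi_jit[50] <- phi[49] - 0.005
  trj <- fixture_trace(1, phi = phi_jit, energy = en)
  expect_silent(energy_vs_fraction(list(trj), grid))

  tr2 <- fixture_trace(200, phi = phi, energy = en + 100)
  both <- energy_vs_fraction(list(tr, tr2), grid)
  f <- both[both$pathway == "FIFO", ]
  l <- both[both$pathway == "LIFO", ]
  expect_true(all(l$mean_energy - f$mean_energy == 100))
})

test_that("ensemble summary counts are consistent", {
  traces <- c(lapply(c(1, 1, 200, 200, 200), fixture_trace),
              list(fixture_trace(NA_integer_)))
  s <- ensemble_summary(traces)
  expect_equal(s$n_fifo + s$n_lifo + s$n_failed, s$n_traj)
  expect_equal(s$p_fifo$estimate, 2 / 5)
  expect_equal(s$phi_c_fifo[["n"]], 2)
  row <- ensemble_summary_row(s)
  expect_equal(row$n_traj, 6)
  expect_true(row$p_fifo_lower <= row$p_fifo & row$p_fifo <= row$p_fifo_upper)
})

test_that("persistence-length estimator recovers a known worm-like chain", {
  # independent oracle: discrete WLC with <cos phi> = coth(K) - 1/K, so
  # l_p = -b / log(coth(K) - 1/K)
  for (K in c(5, 10)) {
    frames <- fixture_wlc_frames(60, 80, K, seed = K)
    est <- persistence_length_estimate(frames, s_max = 8)
    lp_true <- -1 / log(1 / tanh(K) - 1 / K)
    expect_false(est$rigid)
    expect_equal(est$lp_sigma, lp_true, tolerance = 0.1)
  }
  # rigid rod: correlations ~1 at all separations -> flagged, infinite
  rod <- replicate(5, cbind(0, 0, seq_len(50)), simplify = FALSE)
  est <- persistence_length_estimate(rod, s_max = 8)
  expect_true(est$rigid)
  expect_equal(est$lp_sigma, Inf)
})
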