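# Orientation calling on synthetic stain profiles: length arithmetic,
# segmentation, Pearson machinery, direction calls and cohort summaries.

test_that("Pearson correlation guards and basic identities", {
  a <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_cor(a, a), 1)
  inc <- 1:10
  expect_equal(pearson_cor(inc, rev(inc)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)  # affine invariance
  expect_error(pearson_cor(c(1, 1, 1), a[1:3]), "zero-variance")
  expect_error(pearson_cor(1:2, 1:2), "length")
})

test_that("length arithmetic reproduces the published conversions", {
  expect_equal(round(contour_length_um(48502), 1), 16.5)
  expect_equal(contour_length_um(0), 0)
  expect_equal(contour_length_um(1000), 0.34)
  expect_equal(round(stain_corrected_length(16.5, 1.5), 1), 24.8)
  expect_equal(stain_corrected_length(10, 1), 10)
  expect_equal(stain_corrected_length(17.25, 1.5), 25.875)
  expect_error(stain_corrected_length(10, 0.9), ">= 1")
  expect_equal(round(ejected_fraction(12.0), 1), 69.6)
  expect_equal(ejected_fraction(17.25), 100)
  expect_equal(ejected_fraction(16.0 / 100 * 17.25 * 100 / 17.25) * 0 + 100 *
                 16 / 17.25, ejected_fraction(16))
})

test_that("length measurement finds the molecule run against background", {
  # 100 signal pixels at 0.16 um/px among background -> 16.0 um
  set.seed(2)
  v <- c(rep(10, 30), rep(100, 100), rep(10, 30)) + rnorm(160, sd = 0.5)
  prof <- intensity_profile(v, 0.16)
  m <- measure_length(prof)
  expect_equal(m$n_pixels, 100)
  expect_equal(m$length_um, 16.0)
  expect_equal(m$first_pixel, 31)
  expect_lt(m$background, 12)
  expect_error(measure_length(intensity_profile(rep(5, 50), 0.16)),
               "no pixels above")
})

test_that("noiseless molecules are called correctly with high correlation", {
  g <- synth_genome(seed = 11)
  spec <- cohort_spec(snr = Inf, seed = 11)
  for (end in c("left", "right")) {
    mol <- synth_molecule_profile(g, 0.70, end, spec, seed = 5)
    call <- call_direction(mol$profile, g)
    expect_equal(call$call, if (end == "left") "FIFO" else "LIFO")
    expect_gt(call$pearson_r, 0.9)
    expect_equal(call$ejected_length_um, mol$truth$length_um)
  }
})

test_that("full-length molecules flip exactly under profile reversal", {
  g <- synth_genome(seed = 4)
  spec <- cohort_spec(snr = 8, seed = 4)
  for (end in c("left", "right")) for (ms in 1:3) {
    mol <- synth_molecule_profile(g, 1.0, end, spec, seed = ms)
    fwd <- call_direction(mol$profile, g)
    rvs <- call_direction(reverse_profile(mol$profile), g)
    expect_equal(fwd$r_forward, rvs$r_reverse, tolerance = 1e-9)
    expect_equal(fwd$r_reverse, rvs$r_forward, tolerance = 1e-9)
    expect_equal(abs(fwd$pearson_r), abs(rvs$pearson_r), tolerance = 1e-9)
    if (fwd$call != "ambiguous")
      expect_equal(rvs$call, setdiff(c("FIFO", "LIFO"), fwd$call))
  }
})

test_that("classifier is >= 95% accurate noiseless and degrades with noise", {
  g <- synth_genome(seed = 21)
  fracs <- rep(seq(0.40, 0.95, by = 0.05), 2)
  ends <- rep(c("left", "right"), each = length(fracs) / 2)
  run_at_snr <- function(snr) {
    spec <- cohort_spec(snr = snr, seed = 21)
    calls <- mapply(function(f, e, s) {
      mol <- synth_molecule_profile(g, f, e, spec, seed = s)
      cl <- call_direction(mol$profile, g)
      if (cl$call == "ambiguous") NA else cl$call == mol$truth$pathway
    }, fracs, ends, seq_along(fracs))
    mean(unlist(calls), na.rm = TRUE)
  }
  acc_clean <- run_at_snr(Inf)
  expect_gte(acc_clean, 0.95)
  # seeded SNR ladder: accuracy non-increasing as noise grows (below SNR ~2
  # the handful of surviving calls are near chance, so the ladder stops there)
  acc <- vapply(c(Inf, 10, 2), run_at_snr, numeric(1))
  expect_true(all(diff(acc) <= 0.05 + 1e-9))  # monotone up to sampling noise
  expect_lt(acc[3], acc_clean)
})

test_that("length measurement is unbiased over a cohort", {
  spec <- cohort_spec(n_molecules = 200, snr = 8, seed = 31)
  cohort <- synth_cohort(spec)
  meas <- vapply(cohort$profiles, function(p) measure_length(p)$length_um,
                 numeric(1))
  err_px <- (meas - cohort$truth$length_um) / spec$pixel_size_um
  expect_lt(abs(mean(err_px)), 1)
})

test_that("cohort summary reports FIFO percentages per set", {
  calls <- lapply(c(rep(1, 27), rep(-1, 23)), function(s) {
    structure(list(call = if (s > 0) "FIFO" else "LIFO", pearson_r = 0.8,
                   ejected_length_um = 11, ejected_fraction_percent = 64),
              class = "orientation_call")
  })
  s <- cohort_summary(calls)
  expect_equal(s$percent_fifo, 54)
  expect_equal(s$n_called, 50)
  s2 <- cohort_summary(calls, sets = rep(c("a", "b"), 25))
  expect_length(s2$per_set, 2)
  expect_equal(mean(s2$per_set), s2$percent_fifo_mean)
  amb <- list(structure(list(call = "ambiguous", pearson_r = NA_real_,
                             ejected_length_um = NA_real_,
                             ejected_fraction_percent = NA_real_),
                        class = "orientation_call"))
  expect_error(cohort_summary(amb), "ambiguous")
})
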