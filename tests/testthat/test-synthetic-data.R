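# Synthetic-data generator: block genomes, molecule profiles, cohorts.

test_that("two-block genomes have the designed composition", {
  g <- synth_genome(48502, 0.53, 0.47, 0.45, seed = 1)
  expect_equal(g$length_bp, 48502)
  gc <- region_gc_fractions(g, 0.45)
  se_l <- sqrt(0.53 * 0.47 / (0.45 * 48502))
  se_r <- sqrt(0.47 * 0.53 / (0.55 * 48502))
  expect_lt(abs(gc[["gamma_left"]] - 0.53), 3 * se_l)
  expect_lt(abs(gc[["gamma_right"]] - 0.47), 3 * se_r)

  # no block structure when the two GC fractions agree
  flat <- synth_genome(20000, 0.5, 0.5, 0.45, seed = 2)
  prof <- at_content_profile(flat, 1000, 1000)
  expect_lt(diff(range(prof$at_percent)), 6 * 100 * sqrt(0.25 / 1000))

  expect_equal(synth_genome(10, seed = 3)$length_bp, 10)
  expect_identical(synth_genome(500, seed = 9)$residues,
                   synth_genome(500, seed = 9)$residues)
  expect_error(synth_genome(0))
})

test_that("molecule profiles carry truth and respect construction arithmetic", {
  g <- synth_genome(seed = 6)
  spec <- cohort_spec(snr = Inf, seed = 6)
  mol <- synth_molecule_profile(g, 0.70, "left", spec, seed = 1)
  expect_s3_class(mol$profile, "intensity_profile")
  expect_equal(mol$truth$pathway, "FIFO")
  # above-threshold length ~ 0.70 x stretched contour, within one pixel
  m <- measure_length(mol$profile)
  expected_um <- contour_length_um(round(0.70 * g$length_bp)) * 1.05
  expect_lt(abs(m$length_um - expected_um), spec$pixel_size_um + 1e-9)

  # complete ejection: left-first and right-first are exact mirror images
  a <- synth_molecule_profile(g, 1.0, "left", spec, seed = 2)
  b <- synth_molecule_profile(g, 1.0, "right", spec, seed = 2)
  na <- a$truth$n_pixels
  expect_equal(a$profile$intensities[seq_len(na)],
               rev(b$profile$intensities[seq_len(na)]), tolerance = 1e-12)

  expect_error(synth_molecule_profile(g, 0, "left", spec), "ejected_fraction")
})

test_that("cohorts are reproducible and label molecules as designed", {
  spec <- cohort_spec(n_molecules = 150, true_p_fifo = 0.5, seed = 8)
  co <- synth_cohort(spec)
  expect_equal(nrow(co$truth), 150)
  p_hat <- mean(co$truth$pathway == "FIFO")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 150))
  expect_true(all(co$truth$ejected_fraction >= spec$ejected_bounds[1] &
                    co$truth$ejected_fraction <= spec$ejected_bounds[2]))

  all_fifo <- synth_cohort(cohort_spec(n_molecules = 20, true_p_fifo = 1,
                                       seed = 9))
  expect_true(all(all_fifo$truth$pathway == "FIFO"))

  again <- synth_cohort(spec)
  expect_identical(co$truth, again$truth)
  expect_identical(co$profiles[[3]]$intensities,
                   again$profiles[[3]]$intensities)
})

test_that("generated lengths convert back to the input ejected fraction", {
  spec <- cohort_spec(n_molecules = 100, snr = 6, seed = 12)
  co <- synth_cohort(spec)
  meas <- vapply(co$profiles, function(p) measure_length(p)$length_um,
                 numeric(1))
  frac_back <- meas / (contour_length_um(spec$length_bp) * spec$stretch_factor)
  bias_pp <- 100 * mean(frac_back - co$truth$ejected_fraction)
  expect_lt(abs(bias_pp), 2)
})
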