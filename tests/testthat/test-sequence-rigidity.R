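# Composition -> rigidity: FASTA reading, AT profiles, terpolymer model,
# region persistence lengths, relative rigidity, bending constants.

test_that("FASTA reading normalises case, takes the first record, rejects junk", {
  p <- fixture_fasta(list(x = "ATGC"))
  g <- read_genome_fasta(p)
  expect_s3_class(g, "genome_sequence")
  expect_equal(g$length_bp, 4L)
  expect_equal(g$residues, "ATGC")

  expect_equal(read_genome_fasta(fixture_fasta(list(lo = "atgc")))$residues,
               "ATGC")
  expect_warning(
    g2 <- read_genome_fasta(fixture_fasta(list(a = "AAAA", b = "CCCC"))),
    "multiple")
  expect_equal(g2$residues, "AAAA")

  expect_error(read_genome_fasta(tempfile()), "not found")
  empty <- tempfile(); writeLines(character(0), empty)
  expect_error(read_genome_fasta(empty))
  expect_error(read_genome_fasta(fixture_fasta(list(x = "ATXG"))), "illegal")
})

test_that("AT profile matches hand counts and handles N exclusion", {
  expect_equal(at_content_profile("ATGC", 4, 4)$at_percent, 50)
  polyA <- strrep("A", 500)
  expect_true(all(at_content_profile(polyA, 100, 50)$at_percent == 100))
  polyG <- strrep("G", 500)
  expect_true(all(at_content_profile(polyG, 100, 50)$at_percent == 0))
  # N excluded from the denominator: ATNN window has 2 informative, 2 AT
  expect_equal(at_content_profile("ATNN", 4, 4)$at_percent, 100)
  expect_error(at_content_profile("NNNN", 4, 4), "all-N")
  expect_error(at_content_profile("ATGC", 10, 1), "window_bp")

  prof <- at_content_profile(strrep("ATGC", 100), 40, 10)
  expect_true(all(diff(prof$positions_bp) > 0))
  expect_true(all(prof$at_percent >= 0 & prof$at_percent <= 100))
  expect_length(prof$at_percent, length(prof$positions_bp))
})

test_that("AT profile of a two-block genome recovers the block means", {
  g <- synth_genome(40000, gc_left = 0.53, gc_right = 0.47,
                    boundary_fraction = 0.45, seed = 5)
  prof <- at_content_profile(g, 1000, 1000)  # non-overlapping windows
  left <- prof$at_percent[prof$positions_bp < 16000]
  right <- prof$at_percent[prof$positions_bp > 20000]
  se <- 100 * sqrt(0.5 * 0.5 / 1000)  # binomial SE per window, worst case
  expect_true(all(abs(left - 47) < 3 * se))
  expect_true(all(abs(right - 53) < 3 * se))
})

test_that("terpolymer persistence-length differences evaluate exactly", {
  # l_p(gamma) = 23 + 23 gamma + 26 gamma^2 + c; c cancels in differences
  expect_equal(terpolymer_lp_difference(0.60, 0.30), 13.92, tolerance = 1e-12)
  expect_equal(round(terpolymer_lp_difference(0.60, 0.30)), 14)
  expect_equal(terpolymer_lp_difference(0.5, 0.5), 0)
  expect_equal(terpolymer_lp_difference(0.53, 0.47), 2.94, tolerance = 1e-9)
  # antisymmetry
  for (g in list(c(0.2, 0.7), c(0, 1), c(0.53, 0.47)))
    expect_equal(terpolymer_lp_difference(g[1], g[2]),
                 -terpolymer_lp_difference(g[2], g[1]))
  # the constant c never enters
  expect_equal(
    terpolymer_lp_difference(0.6, 0.3, terpolymer_model(c = 100)),
    terpolymer_lp_difference(0.6, 0.3, terpolymer_model(c = -5)))
  expect_error(terpolymer_lp_difference(1.2, 0.3), "gamma")
})

test_that("region persistence solve is exact and satisfies both equations", {
  lp <- solve_region_persistence(5.9, 0.45, 0.55, 50)
  expect_equal(round(unname(lp)), c(53, 47))
  expect_equal(lp[["lp_gc_nm"]], 53.245, tolerance = 1e-9)
  expect_equal(lp[["lp_at_nm"]], 47.345, tolerance = 1e-9)
  expect_equal(unname(solve_region_persistence(0, 0.5, 0.5, 50)), c(50, 50))
  expect_equal(unname(solve_region_persistence(14, 0.5, 0.5, 50)), c(57, 43))

  set.seed(1)
  for (i in 1:25) {
    d <- runif(1, 0, 20); w <- runif(1, 0.1, 0.9); m <- runif(1, 30, 70)
    lp <- solve_region_persistence(d, w, 1 - w, m)
    expect_equal(lp[["lp_gc_nm"]] - lp[["lp_at_nm"]], d, tolerance = 1e-9)
    expect_equal(w * lp[["lp_gc_nm"]] + (1 - w) * lp[["lp_at_nm"]], m,
                 tolerance = 1e-9)
  }
  expect_error(solve_region_persistence(5, 0.4, 0.5), "sum to 1")
})

test_that("relative rigidity and bending constants are mutually consistent", {
  expect_equal(round(relative_rigidity(53, 47), 2), 0.13)
  expect_equal(round(relative_rigidity(11.5, 8.5), 2), 0.35)
  expect_equal(relative_rigidity(7, 7), 0)
  expect_error(relative_rigidity(5, 0), "positive")

  expect_equal(round(unname(bending_constants(0.35, 10)), 1), c(11.5, 8.5))
  expect_equal(unname(bending_constants(0, 10)), c(10, 10))
  expect_equal(round(unname(bending_constants(0.13, 10)), 2), c(10.61, 9.39))

  # round trip r -> (K_F, K_L) -> r, and the mean constraint
  for (r in seq(0, 1, by = 0.1)) {
    ks <- bending_constants(r, 10)
    expect_equal(relative_rigidity(ks[["K_F"]], ks[["K_L"]]), r,
                 tolerance = 1e-12)
    expect_equal((ks[["K_F"]] + ks[["K_L"]]) / 2, 10, tolerance = 1e-12)
  }
})

test_that("region_rigidity pipeline exposes both delta-l_p routes", {
  rr <- region_rigidity()
  expect_equal(rr$delta_lp_nm, 5.9)
  expect_equal(round(c(rr$lp_gc_nm, rr$lp_at_nm)), c(53, 47))
  expect_equal(round(relative_rigidity(round(rr$lp_gc_nm), round(rr$lp_at_nm)), 2),
               0.13)
  expect_equal((rr$K_F + rr$K_L) / 2, 10, tolerance = 1e-12)

  rf <- region_rigidity(delta_lp_source = "formula")
  expect_equal(rf$delta_lp_nm, 2.94, tolerance = 1e-9)
  expect_lt(rf$r_relative, rr$r_relative)
})

test_that("region GC fractions recover the generator's block design", {
  g <- synth_genome(30000, gc_left = 0.53, gc_right = 0.47,
                    boundary_fraction = 0.45, seed = 3)
  gc <- region_gc_fractions(g, 0.45)
  expect_equal(gc[["boundary_bp"]], 13500)
  expect_equal(gc[["gamma_left"]], 0.53, tolerance = 0.02)
  expect_equal(gc[["gamma_right"]], 0.47, tolerance = 0.02)
})
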