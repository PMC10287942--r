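# Chain model and capsid geometry: potentials (R reference vs compiled core),
# geometry invariants, initial growth, integrator determinism.

test_that("FENE + WCA bond energy and force match closed forms", {
  # r = sigma: -0.5*30*1.5^2*log(1 - (1/1.5)^2) = 19.8378, WCA adds epsilon
  expect_equal(fene_bond_energy(1), 20.8378, tolerance = 1e-5)
  expect_equal(fene_bond_energy(1) - wca_energy(1), 19.8378, tolerance = 1e-5)
  # at the WCA cutoff only the FENE term remains
  rc <- 2^(1 / 6)
  expect_equal(fene_bond_energy(rc),
               -0.5 * 30 * 1.5^2 * log(1 - (rc / 1.5)^2))
  expect_error(fene_bond_energy(1.5), "diverging")
  expect_error(fene_bond_energy(0), "positive")
  # numerical derivative agrees with the analytic force
  h <- 1e-6
  for (r in c(0.9, 0.97, 1.05, 1.3))
    expect_equal(fene_bond_force(r),
                 -(fene_bond_energy(r + h) - fene_bond_energy(r - h)) / (2 * h),
                 tolerance = 1e-4)
})

test_that("WCA potential is zero at and beyond the cutoff, epsilon at sigma", {
  expect_equal(wca_energy(2^(1 / 6)), 0)
  expect_equal(wca_energy(2), 0)
  expect_equal(wca_energy(1), 1)
  expect_error(wca_energy(0), "positive")
  r <- seq(0.9, 1.3, by = 0.01)
  expect_true(all(diff(wca_energy(r)) <= 0))  # purely repulsive
})

test_that("bending energy is zero for straight, 2K for fold-back", {
  expect_equal(bending_energy(pi, 10), 0, tolerance = 1e-12)
  expect_equal(bending_energy(pi / 2, 10), 10)
  expect_equal(bending_energy(0, 10), 20)
})

test_that("compiled-core potential matches the R reference on random chains", {
  # dual route: sum the R closed forms over a random configuration and
  # compare with the engine's total potential (free chain, no geometry)
  for (seed in 1:3) {
    pos <- fixture_chain(12, seed = seed, kink = 0.5)
    p <- sim_params(n_monomers = 12, K_F = 11.5, K_L = 8.5)
    vel <- matrix(0, 12, 3)
    en <- phageject:::cg_energy(pos, vel, core_params(p), list(active = FALSE))
    bonds <- sqrt(rowSums(diff(pos)^2))
    u_bond <- sum(fene_bond_energy(bonds))
    u_ang <- 0
    for (c in 2:11) {
      b1 <- pos[c, ] - pos[c - 1, ]; b2 <- pos[c + 1, ] - pos[c, ]
      theta <- acos(pmin(1, pmax(-1,
        -sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2)))))
      u_ang <- u_ang + bending_energy(theta, if (c <= 6) 11.5 else 8.5)
    }
    u_pair <- 0
    for (i in 1:10) for (j in (i + 2):12) {
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      u_pair <- u_pair + wca_energy(d)
    }
    expect_equal(en$potential, u_bond + u_ang + u_pair, tolerance = 1e-8)
    expect_equal(en$kinetic, 0)
  }
})

test_that("capsid geometry satisfies the packing-fraction definition", {
  g6 <- build_capsid(0.6, 200)
  expect_equal(g6$interior_radius, 3.467, tolerance = 1e-3)
  g4 <- build_capsid(0.4, 200)
  expect_equal(g4$interior_radius, 3.969, tolerance = 1e-3)
  for (g in list(g6, g4)) {
    phi <- 200 * (pi / 6) / ((4 * pi / 3) * g$interior_radius^3)
    expect_equal(phi, g$packing_fraction, tolerance = 0.01)
    # shell is impermeable to monomers: nearest-neighbour spacing < sigma
    sh <- g$shell
    nn <- vapply(seq_len(nrow(sh)), function(i) {
      d <- sqrt(rowSums((sh[-i, , drop = FALSE] -
                           matrix(sh[i, ], nrow(sh) - 1, 3, byrow = TRUE))^2))
      min(d)
    }, numeric(1))
    expect_lt(max(nn), 1)
    # portal channel narrower than two strands
    expect_lt(2 * g$channel_half_width, 2)
    expect_equal(g$z_out - g$z_base, 10)
  }
  expect_error(build_capsid(0), "packing_fraction")
  expect_error(build_capsid(0.9), "packing_fraction")
})

test_that("initial growth puts 10 monomers in the portal, safe bonds, seeded", {
  p <- sim_params()
  g <- build_capsid(0.6)
  st <- grow_initial_configuration(g, p, seed = 3)
  expect_equal(sum(st$monomer_status == "in_portal"), 10)
  expect_true(all(st$monomer_status[1:10] == "in_portal"))
  expect_true(all(st$monomer_status[11:200] == "outside"))
  b <- sqrt(rowSums(diff(st$positions)^2))
  expect_true(all(b > 0.8 & b < p$R0))
  st2 <- grow_initial_configuration(g, p, seed = 4)
  expect_false(isTRUE(all.equal(st$positions, st2$positions)))
  # same seed reproduces bit-identically
  st3 <- grow_initial_configuration(g, p, seed = 3)
  expect_identical(st$positions, st3$positions)
  expect_identical(st$velocities, st3$velocities)
})

test_that("Langevin stepping is deterministic given the seed", {
  p <- sim_params(n_monomers = 50)
  pos <- cbind(0, 0, 0.97 * seq_len(50))
  vel <- matrix(0, 50, 3)
  r1 <- phageject:::cg_run_phase(pos, vel, core_params(p), list(active = FALSE),
                                 "free", 20, 99, list(sample_every = 5))
  r2 <- phageject:::cg_run_phase(pos, vel, core_params(p), list(active = FALSE),
                                 "free", 20, 99, list(sample_every = 5))
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$velocities, r2$velocities)
  r3 <- phageject:::cg_run_phase(pos, vel, core_params(p), list(active = FALSE),
                                 "free", 20, 100, list(sample_every = 5))
  expect_false(isTRUE(all.equal(r1$positions, r3$positions)))
})

test_that("free-chain bond lengths stay within the FENE limit", {
  run <- simulate_free_chain(n_monomers = 50, K_a = 10, duration_tau = 100,
                             seed = 2, equilibration_tau = 50,
                             sample_every = 2)
  for (fr in run$frames) {
    b <- sqrt(rowSums(diff(fr)^2))
    expect_true(all(b < 1.5))
    expect_true(all(b > 0.7))
  }
})
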