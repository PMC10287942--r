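# Shared fixtures, built in code at test time.

# tiny deterministic genome strings
fixture_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(nm)
    c(paste0(">", nm), records[[nm]]))), path)
  path
}

# a small random open-chain configuration with bonds ~0.97 sigma (no overlaps
# enforced; used for energy cross-checks, not dynamics)
fixture_chain <- function(n, seed = 1, kink = 0.3) {
  set.seed(seed)
  pos <- matrix(0, n, 3)
  dir <- c(0, 0, 1)
  for (i in 2:n) {
    dir <- dir + kink * rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos[i, ] <- pos[i - 1, ] + 0.97 * dir
  }
  pos
}

# independent discrete worm-like-chain sampler: bond directions evolve with
# exactly <cos phi> = coth(K) - 1/K (Boltzmann for U = K (1 - cos phi));
# an oracle for the persistence-length estimator
fixture_wlc_frames <- function(n_frames, n_monomers, K, b = 1, seed = 1) {
  set.seed(seed)
  sample_cos <- function(m) {
    u <- runif(m)
    1 + log(u + (1 - u) * exp(-2 * K)) / K
  }
  lapply(seq_len(n_frames), function(f) {
    pos <- matrix(0, n_monomers, 3)
    dir <- c(0, 0, 1)
    for (i in 2:n_monomers) {
      cphi <- sample_cos(1)
      sphi <- sqrt(max(0, 1 - cphi^2))
      # random perpendicular
      ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * dir) * dir
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      psi <- runif(1, 0, 2 * pi)
      dir <- cphi * dir + sphi * (cos(psi) * e1 + sin(psi) * e2)
      dir <- dir / sqrt(sum(dir^2))
      pos[i, ] <- pos[i - 1, ] + b * dir
    }
    pos
  })
}

# fabricate a minimal ejection_trace for analysis-layer tests
fixture_trace <- function(i_exit, n = 200, phi = NULL, energy = NULL,
                          converged = TRUE, tau_rest = 0) {
  if (is.null(phi)) phi <- pmin(1, seq(0.005, 1.2, by = 0.005))
  if (is.null(energy)) energy <- 1000 - 400 * pmin(phi, 1)
  structure(list(
    i_exit = i_exit, t_exit = 5,
    pathway = if (is.na(i_exit)) "none" else if (i_exit <= n / 2) "FIFO" else "LIFO",
    phi_time = seq_along(phi), phi_e_series = phi, energy_series = energy,
    phi_c = mean(phi[max(1, ceiling(0.9 * length(phi))):length(phi)]),
    converged = converged, time_tau = length(phi), seed = 1,
    n_monomers = n,
    condition = list(packing_fraction = 0.6, K_F = 10, K_L = 10,
                     tau_rest = tau_rest, f_r = 0.35)
  ), class = "ejection_trace")
}

core_params <- function(p) phageject:::as_core_params(p)
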