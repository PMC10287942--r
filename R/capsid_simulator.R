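# Langevin-dynamics engine wrappers: parameters, capsid geometry, potentials
# (reference R implementations mirrored by the compiled core), the
# packaging -> resting -> ejection protocol, and free-chain runs.

#' Simulation parameters in reduced units
#'
#' All quantities are in reduced units: sigma (length), k_BT (energy), m
#' (mass), tau = sqrt(m sigma^2 / k_BT) (time).  Defaults follow the standard
#' Kremer--Grest chain in a capsid: FENE springs `K = 30 k_BT/sigma^2`,
#' `R0 = 1.5 sigma`, bending constants of 10 k_BT on average, a packaging
#' force of 10 k_BT/sigma, a resisting force of 0.35 k_BT/sigma at the portal
#' exit, packaging stalls of 500 tau every 50 packaged monomers, and a time
#' step of 0.005 tau.
#'
#' @param n_monomers chain length (must be even; two equal rigidity halves).
#' @param K FENE spring constant, k_BT/sigma^2.
#' @param R0 FENE maximum extension, sigma.
#' @param epsilon energy unit (k_BT).
#' @param mass monomer mass (reduced).
#' @param dt integration time step, tau.
#' @param friction Langevin damping coefficient, 1/tau.
#' @param temperature reduced temperature.
#' @param K_F,K_L bending constants (k_BT) of the first- and last-packaged
#'   chain halves.
#' @param f_p packaging force on monomers inside the portal, k_BT/sigma.
#' @param f_r resisting force at the portal exit, k_BT/sigma.
#' @param tau_stall duration of each packaging stall, tau.
#' @param stall_every stall after this many monomers are packaged.
#' @param tau_rest resting time between packaging and ejection, tau.
#' @param t_max_eject ejection cutoff, tau.
#' @param t_max_package packaging step budget, tau (excludes stalls).
#' @param packing_fraction capsid packing fraction when fully packaged.
#' @param n_shell number of capsid shell particles.
#' @param sigma_nm physical monomer diameter, nm (bookkeeping only).
#' @return a `sim_params` list (also carries `sigma_reduced = 1`).
#' @export
#' @examples
#' sim_params(K_F = 11.5, K_L = 8.5, tau_rest = 1500)
sim_params <- function(n_monomers = 200, K = 30, R0 = 1.5, epsilon = 1,
                       mass = 1, dt = 0.005, friction = 1, temperature = 1,
                       K_F = 10, K_L = 10, f_p = 10, f_r = 0.35,
                       tau_stall = 500, stall_every = 50, tau_rest = 0,
                       t_max_eject = 5000, t_max_package = 20000,
                       packing_fraction = 0.6, n_shell = 784, sigma_nm = 5) {
  stopifnot(dt > 0, R0 > 1, n_monomers >= 4, n_monomers %% 2 == 0,
            K >= 0, K_F >= 0, K_L >= 0, f_p >= 0, f_r >= 0,
            tau_stall >= 0, tau_rest >= 0, friction >= 0, temperature > 0,
            mass > 0, stall_every >= 1)
  structure(list(
    n_monomers = as.integer(n_monomers), K = K, R0 = R0, epsilon = epsilon,
    sigma_reduced = 1, mass = mass, dt = dt, friction = friction,
    temperature = temperature, K_F = K_F, K_L = K_L, f_p = f_p, f_r = f_r,
    tau_stall = tau_stall, stall_every = as.integer(stall_every),
    tau_rest = tau_rest, t_max_eject = t_max_eject,
    t_max_package = t_max_package, packing_fraction = packing_fraction,
    n_shell = as.integer(n_shell), sigma_nm = sigma_nm
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> n =", x$n_monomers,
      sprintf("| K_F/K_L = %.2f/%.2f k_BT | f_p = %g, f_r = %g k_BT/sigma\n",
              x$K_F, x$K_L, x$f_p, x$f_r),
      sprintf("  dt = %g tau, friction = %g/tau, tau_stall = %g, tau_rest = %g, phi = %g\n",
              x$dt, x$friction, x$tau_stall, x$tau_rest, x$packing_fraction))
  invisible(x)
}

# ------------------------------------------------------------ potentials ---
# Reference R implementations of the pairwise/angular terms; the compiled
# engine implements identical formulas and is cross-checked against these.

#' FENE + WCA bond energy
#'
#' `U_b(r) = -K R0^2/2 ln(1 - (r/R0)^2) + U_WCA(r)`, the Kremer--Grest bond:
#' a finitely extensible attractive spring plus the shifted, purely repulsive
#' WCA term (which is exactly zero at and beyond `2^(1/6) sigma`).
#'
#' @param r inter-monomer distance(s), sigma units; must satisfy `0 < r < R0`.
#' @param K FENE spring constant (k_BT/sigma^2).
#' @param R0 maximum extension (sigma).
#' @param epsilon,sigma WCA energy and length parameters.
#' @return energy in k_BT.
#' @export
#' @examples
#' fene_bond_energy(1)  # 19.838 + 1 = 20.838 k_BT at K = 30, R0 = 1.5
fene_bond_energy <- function(r, K = 30, R0 = 1.5, epsilon = 1, sigma = 1) {
  if (any(r <= 0)) stop("bond length must be positive")
  if (any(r >= R0)) stop("diverging FENE bond: r >= R0")
  -0.5 * K * R0^2 * log(1 - (r / R0)^2) + wca_energy(r, sigma, epsilon)
}

#' FENE + WCA bond force
#'
#' Radial force `-dU_b/dr`; negative values pull the monomers together.
#'
#' @inheritParams fene_bond_energy
#' @return force in k_BT/sigma.
#' @export
fene_bond_force <- function(r, K = 30, R0 = 1.5, epsilon = 1, sigma = 1) {
  if (any(r <= 0)) stop("bond length must be positive")
  if (any(r >= R0)) stop("diverging FENE bond: r >= R0")
  cut <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  wca <- ifelse(r < cut, 24 * epsilon * s6 * (2 * s6 - 1) / r, 0)
  -K * r / (1 - (r / R0)^2) + wca
}

#' Weeks--Chandler--Andersen (WCA) excluded-volume energy
#'
#' `4 eps ((sigma/r)^12 - (sigma/r)^6) + eps` at distances below the
#' `2^(1/6) sigma` cutoff, zero beyond; continuous at the cutoff.
#'
#' @param r distance(s), `> 0`.
#' @param sigma,epsilon length and energy parameters.
#' @return energy in k_BT.
#' @export
#' @examples
#' wca_energy(2^(1/6))  # exactly 0 at the cutoff
#' wca_energy(1)        # exactly epsilon
wca_energy <- function(r, sigma = 1, epsilon = 1) {
  if (any(r <= 0)) stop("distance must be positive")
  cut <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  ifelse(r < cut, 4 * epsilon * s6 * (s6 - 1) + epsilon, 0)
}

#' Bending energy of an interior bond angle
#'
#' `U_a = K_a (1 + cos theta)` with `theta` the interior angle at the centre
#' monomer of a bonded triplet, so a locally straight chain (`theta = pi`)
#' costs zero and a full fold-back (`theta = 0`) costs `2 K_a`.
#'
#' @param theta interior angle(s) in radians.
#' @param K_a bending constant in k_BT.
#' @return energy in k_BT.
#' @export
#' @examples
#' bending_energy(pi, 10)      # 0: straight
#' bending_energy(pi / 2, 10)  # 10: right-angle kink
bending_energy <- function(theta, K_a = 10) {
  K_a * (1 + cos(theta))
}

# --------------------------------------------------------------- geometry --

#' Build the capsid geometry
#'
#' The interior radius solves the packing-fraction definition
#' `phi = n sigma^3 / (8 R_c^3)` (total monomer volume over capsid interior
#' volume).  The shell is `n_shell` fixed WCA particles on a Fibonacci sphere
#' of radius `R_c + sigma/2`; a square portal channel of inner width
#' `1.6 sigma` and length `10 sigma` is attached over a polar opening in the
#' shell, and a removable WCA blockage plane sits across the channel's inner
#' mouth.
#'
#' @param packing_fraction capsid packing fraction when fully packaged, in
#'   `(0, 0.74)`.
#' @param n_monomers number of chain monomers.
#' @param n_shell shell particle count before the portal opening is cut.
#' @return a `capsid_geometry` list (shell coordinates, radii, channel
#'   extent) consumed by the simulator.
#' @export
#' @examples
#' build_capsid(0.6)  # interior radius ~3.467 sigma for 200 monomers
build_capsid <- function(packing_fraction, n_monomers = 200, n_shell = 784) {
  if (packing_fraction <= 0 || packing_fraction >= 0.74)
    stop("packing_fraction must lie in (0, 0.74)")
  if (n_monomers < 1) stop("n_monomers must be positive")
  Rc <- (n_monomers / (8 * packing_fraction))^(1 / 3)
  if (Rc < 2) stop("capsid too small: interior radius < 2 sigma")
  # shell particle centres sit one monomer diameter outside the interior
  # radius, so monomer centres can roam the full interior sphere (WCA contact
  # with the shell at ~R_c); packaging at the stated force then completes
  Rs <- Rc + 1.0
  shell <- cg_fibonacci_sphere(n_shell, Rs)
  # the shell opening must clear the channel bore so the 1.6-sigma channel,
  # not the rim particles, is the constriction; the rim still seals the
  # annular gap around the channel's exterior
  aperture <- 1.45
  lat <- sqrt(shell[, 1]^2 + shell[, 2]^2)
  keep <- !(lat < aperture & shell[, 3] > 0)
  shell <- shell[keep, , drop = FALSE]
  z_base <- sqrt(Rs^2 - aperture^2)
  structure(list(
    active = TRUE, packing_fraction = packing_fraction,
    n_monomers = as.integer(n_monomers), n_shell = as.integer(n_shell),
    n_shell_kept = nrow(shell), interior_radius = Rc, shell_radius = Rs,
    channel_half_width = 0.8, channel_length = 10,
    z_base = z_base, z_out = z_base + 10,
    wall_sigma = 0.5, aperture_radius = aperture, shell = shell
  ), class = "capsid_geometry")
}

#' @export
print.capsid_geometry <- function(x, ...) {
  cat(sprintf(
    "<capsid_geometry> phi = %.2f, R_c = %.3f sigma (%d shell particles kept of %d)\n",
    x$packing_fraction, x$interior_radius, x$n_shell_kept, x$n_shell),
    sprintf("  portal: %.1f x %.1f x %.0f sigma channel at z in [%.2f, %.2f]\n",
            2 * x$channel_half_width, 2 * x$channel_half_width,
            x$channel_length, x$z_base, x$z_out))
  invisible(x)
}

free_geometry <- function() list(active = FALSE)

as_core_params <- function(params) {
  params[c("n_monomers", "K", "R0", "epsilon", "sigma_reduced", "mass", "dt",
           "friction", "temperature", "K_F", "K_L", "f_p", "f_r",
           "tau_stall", "stall_every")]
}

# ------------------------------------------------------------ chain state --

new_chain_state <- function(positions, velocities, params, geometry) {
  st <- list(positions = positions, velocities = velocities,
             params = params, geometry = geometry)
  st$monomer_status <- monomer_status(st)
  st$n_in <- sum(st$monomer_status == "in_capsid")
  class(st) <- "chain_state"
  st
}

#' Classify each monomer's location
#'
#' @param state a `chain_state`.
#' @return character vector: `"outside"`, `"in_portal"` or `"in_capsid"`.
#' @export
monomer_status <- function(state) {
  geom <- state$geometry
  if (!isTRUE(geom$active)) return(rep("outside", nrow(state$positions)))
  codes <- cg_status(state$positions, as_core_params(state$params), geom)
  c("outside", "in_portal", "in_capsid")[codes + 1L]
}

#' @export
print.chain_state <- function(x, ...) {
  tab <- table(factor(x$monomer_status,
                      levels = c("outside", "in_portal", "in_capsid")))
  cat("<chain_state>", nrow(x$positions), "monomers:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Grow an initial configuration
#'
#' Places the first 10 monomers collinearly inside the portal channel and
#' grows the remaining monomers as a self-avoiding random walk outside the
#' capsid (bond length 0.97 sigma, overlap rejection); velocities are drawn
#' from the Maxwell--Boltzmann distribution at the configured temperature.
#'
#' @param geometry a [build_capsid()] geometry.
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return a `chain_state`.
#' @export
grow_initial_configuration <- function(geometry, params, seed) {
  stopifnot(inherits(geometry, "capsid_geometry"), inherits(params, "sim_params"))
  res <- cg_grow_chain(as_core_params(params), geometry, derive_seed(seed, "grow"))
  new_chain_state(res$positions, res$velocities, params, geometry)
}

#' Total conservative energy of a chain state
#'
#' Potential (bonds, bending, excluded volume, shell and wall repulsion) plus
#' kinetic energy, in k_BT.  External protocol forces are non-conservative
#' and carry no potential term.
#'
#' @param state a `chain_state`.
#' @return list with `potential`, `kinetic`, `total`.
#' @export
chain_energy <- function(state) {
  geom <- if (isTRUE(state$geometry$active)) state$geometry else free_geometry()
  cg_energy(state$positions, state$velocities, as_core_params(state$params), geom)
}

# --------------------------------------------------------------- protocol --

#' Run the packaging step
#'
#' Applies the packaging force to every monomer inside the portal channel
#' until all monomers are inside the capsid.  Each time `stall_every`
#' monomers have been packaged, the force is switched off, the monomers in
#' the portal are fixed in place, and the rest of the chain relaxes for
#' `tau_stall`.
#'
#' @param state a `chain_state` from [grow_initial_configuration()].
#' @param geometry the capsid geometry.
#' @param params a [sim_params()].
#' @param seed integer seed for the thermal noise stream.
#' @return the updated `chain_state` with a `packaging` record (`success`,
#'   `n_stalls`, `time_tau`, `n_in` series).
#' @export
run_packaging <- function(state, geometry, params, seed) {
  res <- cg_run_phase(state$positions, state$velocities,
                      as_core_params(params), geometry, "package",
                      params$t_max_package, derive_seed(seed, "package"),
                      list(sample_every = 1))
  out <- new_chain_state(res$positions, res$velocities, params, geometry)
  out$packaging <- list(success = isTRUE(res$success), n_stalls = res$n_stalls,
                        time_tau = res$time_tau, n_in = res$n_in,
                        n_in_series = res$n_in_series,
                        n_in_time = res$n_in_time)
  out
}

#' Run the resting step
#'
#' Plain Langevin dynamics for `tau_rest` with the portal blocked and no
#' external forces, letting the packaged chain relax its conformation.
#'
#' @inheritParams run_packaging
#' @return the updated `chain_state`.
#' @export
run_resting <- function(state, geometry, params, seed) {
  if (params$tau_rest <= 0) {
    state$resting <- list(time_tau = 0)
    return(state)
  }
  res <- cg_run_phase(state$positions, state$velocities,
                      as_core_params(params), geometry, "rest",
                      params$tau_rest, derive_seed(seed, "rest"),
                      list(sample_every = 5))
  out <- new_chain_state(res$positions, res$velocities, params, geometry)
  out$packaging <- state$packaging
  out$resting <- list(time_tau = res$time_tau)
  out
}

#' Run the ejection step
#'
#' Removes the blockage, applies the resisting force to monomers in the
#' outermost `2 sigma` of the channel, and integrates.  `t_max_eject` budgets
#' the wait for the first exit; once ejection has begun, the run continues for
#' a fixed post-onset window (4000 tau) or until the ejection fraction is
#' stationary (two consecutive 500-tau windows differing by < 0.005), so
#' plateau values are compared at matched ejection age regardless of how long
#' an end took to find the portal.  Records the index of the first monomer
#' to cross the channel's outer plane (`i_exit`), the ejection-fraction and
#' total-energy time series (sampled every tau; the ejection fraction counts
#' monomers outside both the capsid and the portal), and the converged
#' fraction `phi_c` (mean ejection fraction over the final 10% of the run).
#'
#' @inheritParams run_packaging
#' @return an `ejection_trace`.
#' @export
run_ejection <- function(state, geometry, params, seed) {
  res <- cg_run_phase(state$positions, state$velocities,
                      as_core_params(params), geometry, "eject",
                      params$t_max_eject, derive_seed(seed, "eject"),
                      list(sample_every = 1, conv_window_tau = 500,
                           conv_tol = 0.005, post_exit_tau = 4000))
  n <- params$n_monomers
  i_exit <- if (res$i_exit > 0) res$i_exit else NA_integer_
  pathway <- if (is.na(i_exit)) "none"
             else if (i_exit <= n / 2) "FIFO" else "LIFO"
  phi <- res$phi_series
  m <- length(phi)
  phi_c <- if (m > 0) mean(phi[max(1, ceiling(0.9 * m)):m]) else NA_real_
  structure(list(
    i_exit = i_exit, t_exit = res$t_exit, pathway = pathway,
    phi_time = res$phi_time, phi_e_series = phi,
    energy_series = res$energy_series,
    phi_c = phi_c, converged = isTRUE(res$converged),
    time_tau = res$time_tau, seed = seed,
    n_monomers = n,
    condition = list(packing_fraction = params$packing_fraction,
                     K_F = params$K_F, K_L = params$K_L,
                     tau_rest = params$tau_rest, f_r = params$f_r),
    packaging = state$packaging, resting = state$resting,
    final_positions = res$positions
  ), class = "ejection_trace")
}

#' @export
print.ejection_trace <- function(x, ...) {
  cat(sprintf(
    "<ejection_trace> pathway %s (i_exit = %s), phi_c = %.3f%s, %.0f tau\n",
    x$pathway, ifelse(is.na(x$i_exit), "none", x$i_exit), x$phi_c,
    if (x$converged) "" else " (not converged)", x$time_tau))
  invisible(x)
}

#' Simulate one full packaging -> resting -> ejection trajectory
#'
#' @param params a [sim_params()]; `packing_fraction`, `K_F`, `K_L`,
#'   `tau_rest` and `f_r` define the condition.
#' @param seed integer master seed for this trajectory; independent streams
#'   are derived per phase.
#' @param geometry optional pre-built [build_capsid()] geometry (rebuilt from
#'   `params` when `NULL`).
#' @return an `ejection_trace`, or a trace with `pathway = "failed"` if
#'   packaging did not complete within the step budget.
#' @export
simulate_trajectory <- function(params, seed, geometry = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(geometry))
    geometry <- build_capsid(params$packing_fraction, params$n_monomers,
                             params$n_shell)
  st <- grow_initial_configuration(geometry, params, seed)
  st <- run_packaging(st, geometry, params, seed)
  if (!isTRUE(st$packaging$success)) {
    return(structure(list(
      i_exit = NA_integer_, pathway = "failed", phi_c = NA_real_,
      converged = FALSE, seed = seed, n_monomers = params$n_monomers,
      condition = list(packing_fraction = params$packing_fraction,
                       K_F = params$K_F, K_L = params$K_L,
                       tau_rest = params$tau_rest, f_r = params$f_r),
      packaging = st$packaging
    ), class = "ejection_trace"))
  }
  st <- run_resting(st, geometry, params, seed)
  run_ejection(st, geometry, params, seed)
}

# ------------------------------------------------------------- free chain --

# discrete worm-like-chain walk: successive bond directions with
# cos(phi) ~ exp(K cos phi) (the Boltzmann weight of U = K (1 - cos phi))
wlc_walk <- function(n, K, b = 0.97) {
  pos <- matrix(0, n, 3)
  dir <- c(0, 0, 1)
  for (i in 2:n) {
    cphi <- if (K > 0) {
      u <- runif(1)
      1 + log(u + (1 - u) * exp(-2 * K)) / K
    } else runif(1, -1, 1)
    sphi <- sqrt(max(0, 1 - cphi^2))
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
}

min_nonbonded_dist2 <- function(pos) {
  d <- as.matrix(dist(pos))
  n <- nrow(pos)
  mask <- abs(row(d) - col(d)) >= 2
  min(d[mask])^2
}

#' Simulate a free chain (no capsid)
#'
#' A straight chain is grown, equilibrated, and then sampled at regular
#' intervals; used to verify the chain model itself (persistence length,
#' equipartition, NVE energy conservation).
#'
#' @param n_monomers chain length.
#' @param K_a bending constant in k_BT applied to the whole chain.
#' @param duration_tau production time in tau.
#' @param seed integer seed.
#' @param equilibration_tau discarded equilibration time in tau.
#' @param sample_every sampling interval in tau.
#' @param thermostat logical; `FALSE` plus `friction = 0` gives NVE
#'   velocity-Verlet dynamics.
#' @param friction Langevin damping, 1/tau.
#' @param record_energy record total/kinetic/potential energy at samples.
#' @param record_frames record monomer coordinates at samples.
#' @param params optional [sim_params()] overriding the defaults.
#' @return list with `frames` (list of n x 3 matrices), energy series,
#'   `bond_length` mean, and the final state.
#' @export
simulate_free_chain <- function(n_monomers = 200, K_a = 10,
                                duration_tau = 1000, seed = 1,
                                equilibration_tau = 0, sample_every = 5,
                                thermostat = TRUE, friction = 1,
                                record_energy = FALSE, record_frames = TRUE,
                                params = NULL) {
  if (is.null(params))
    params <- sim_params(n_monomers = n_monomers, K_F = K_a, K_L = K_a,
                         friction = friction)
  core <- as_core_params(params)
  n <- params$n_monomers
  b0 <- 0.97
  # initial bond angles drawn from the equilibrium distribution of the
  # discrete bending potential (a straight rod takes far longer than any
  # reasonable equilibration window to lose its global orientation memory);
  # rejected and redrawn on excluded-volume clashes
  pos <- local_seed(derive_seed(seed, "init-conformation"), {
    K_init <- (params$K_F + params$K_L) / 2
    repeat {
      p <- wlc_walk(n, K_init, b0)
      d2min <- min_nonbonded_dist2(p)
      if (d2min > 0.81) break
    }
    p
  })
  vel <- local_seed(derive_seed(seed, "velocities"), {
    matrix(rnorm(3 * n, sd = sqrt(params$temperature / params$mass)), n, 3)
  })
  geom <- free_geometry()
  if (equilibration_tau > 0) {
    core_eq <- core
    core_eq$friction <- max(1, core$friction)  # equilibration is always coupled
    eq <- cg_run_phase(pos, vel, core_eq, geom, "free", equilibration_tau,
                       derive_seed(seed, "equilibrate"),
                       list(sample_every = max(sample_every, 5),
                            thermostat = TRUE))
    pos <- eq$positions; vel <- eq$velocities
  }
  res <- cg_run_phase(pos, vel, core, geom, "free", duration_tau,
                      derive_seed(seed, "production"),
                      list(sample_every = sample_every,
                           thermostat = thermostat,
                           record_energy = record_energy,
                           record_frames = record_frames))
  bonds <- diff(res$positions)
  list(frames = if (record_frames) res$frames else list(),
       energy_time = res$energy_time, energy_total = res$energy_total,
       energy_kinetic = res$energy_kinetic,
       energy_potential = res$energy_potential,
       bond_length = mean(sqrt(rowSums(bonds^2))),
       positions = res$positions, velocities = res$velocities,
       params = params)
}
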