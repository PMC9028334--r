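# Synthetic trajectory generators with known ground truth.
#
# The generators emulate the statistical structure of channel MD data:
# point particles undergoing overdamped Langevin dynamics through a
# cylindrical pore under an imposed free-energy profile U(z), plus direct
# generators for collective-coordinate paths, correlated dipole-angle pairs
# and charged-slab systems. Ground truth is returned alongside every dataset
# and is never consumed by the estimators under test.

#' Configuration for the Brownian-dynamics pore generator
#'
#' @param n_particles Number of diffusing particles.
#' @param box Box lengths `c(Lx, Ly, Lz)` in Angstrom; the pore axis is z,
#'   centred laterally at `(Lx/2, Ly/2)`.
#' @param pore_radius Pore radius in Angstrom.
#' @param pore_z_bounds `c(z_lo, z_hi)` of the pore section in Angstrom.
#' @param imposed_profile Tabulated potential: data frame with columns `z`
#'   (Angstrom, covering `pore_z_bounds`) and `U` (kcal/mol), or `NULL` for a
#'   flat profile. The potential acts on z only, for particles inside the
#'   pore radius; it is zero outside the tabulated grid.
#' @param diffusion_coefficient Particle diffusion coefficient in A^2/ns.
#'   Default 230 (bulk water self-diffusion near 310 K).
#' @param dt Integration time step in ns.
#' @param n_frames Number of stored frames.
#' @param save_every Integration steps between stored frames (default 1);
#'   total simulated time is `(n_frames - 1) * save_every * dt`.
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param temperature Kelvin, used for the Boltzmann factor (default 310.15).
#' @param n_channels Number of independent replicate pores (default 1).
#' @return A validated list of class `"PoreSimConfig"`.
#' @export
pore_sim_config <- function(n_particles, box, pore_radius, pore_z_bounds,
                            imposed_profile = NULL,
                            diffusion_coefficient = 230, dt = 5e-4,
                            n_frames = 1000, save_every = 1L, seed = 1L,
                            temperature = 310.15, n_channels = 1L) {
  stopifnot(n_particles >= 1, length(box) == 3, all(box > 0),
            pore_radius > 0, length(pore_z_bounds) == 2,
            diffusion_coefficient > 0, dt > 0, n_frames >= 2,
            save_every >= 1, n_channels >= 1, temperature > 0)
  if (pore_z_bounds[2] <= pore_z_bounds[1]) stop("pore_z_bounds must be ordered (z_lo < z_hi)")
  if (pore_z_bounds[1] < 0 || pore_z_bounds[2] > box[3]) stop("pore section must lie inside the box")
  if (!is.null(imposed_profile)) {
    imposed_profile <- as.data.frame(imposed_profile)
    if (is.null(imposed_profile$z) || is.null(imposed_profile$U))
      stop("imposed_profile needs columns 'z' and 'U'")
    if (min(imposed_profile$z) > pore_z_bounds[1] || max(imposed_profile$z) < pore_z_bounds[2])
      stop("imposed_profile grid must cover pore_z_bounds")
    spacing <- min(diff(sort(imposed_profile$z)))
    beta <- 1 / kT_kcal(temperature)
    gmax <- max(abs(diff(imposed_profile$U)) / diff(imposed_profile$z))
    drift <- beta * diffusion_coefficient * gmax * dt
    if (is.finite(drift) && drift > spacing)
      stop(sprintf(paste0("dt too large for profile curvature: maximum drift per step ",
                          "%.3g A exceeds the profile grid spacing %.3g A; reduce dt ",
                          "below %.3g ns"), drift, spacing, dt * spacing / drift))
  }
  structure(list(n_particles = as.integer(n_particles), box = as.numeric(box),
                 pore_radius = pore_radius, pore_z_bounds = as.numeric(pore_z_bounds),
                 imposed_profile = imposed_profile,
                 diffusion_coefficient = diffusion_coefficient, dt = dt,
                 n_frames = as.integer(n_frames), save_every = as.integer(save_every),
                 seed = as.integer(seed), temperature = temperature,
                 n_channels = as.integer(n_channels)),
            class = "PoreSimConfig")
}

#' Tabulated Gaussian barrier profile
#'
#' Convenience builder for an imposed potential `U(z) = height *
#' exp(-(z - center)^2 / (2 width^2))` on a regular grid.
#'
#' @param height Barrier height, kcal/mol.
#' @param center Barrier position, Angstrom.
#' @param width Gaussian sigma, Angstrom (default 2).
#' @param z_range `c(lo, hi)` grid extent, Angstrom.
#' @param spacing Grid spacing, Angstrom (default 0.25).
#' @return Data frame with columns `z`, `U`.
#' @export
gaussian_barrier_profile <- function(height, center, width = 2,
                                     z_range, spacing = 0.25) {
  z <- seq(z_range[1], z_range[2], by = spacing)
  data.frame(z = z, U = height * exp(-(z - center)^2 / (2 * width^2)))
}

#' Simulate particles diffusing through a cylindrical pore
#'
#' Overdamped Langevin dynamics: per step,
#' `z <- z - beta*D*dU/dz*dt + sqrt(2*D*dt)*xi` (the potential acts on z
#' only, for particles inside the pore radius), with free diffusion in x/y
#' and in the bulk reservoirs. All axes are periodic. A reflective wall at
#' `r = pore_radius` confines particles within the pore z-section to the
#' cylinder (and keeps membrane-region particles out), so the stationary
#' density is Boltzmann in the imposed profile.
#'
#' @param config A [pore_sim_config()].
#' @return A list of class `"PoreSimulation"`:
#'   * `trajectories`: list of `n_channels` independent [trajectory()] objects
#'     (particles named `OW`/`SOL`, one residue per particle);
#'   * `ground_truth`: list with `true_profile`, `true_D` (A^2/ns),
#'     `true_Dn` (NA here; see [generate_collective_series()]),
#'     `true_event_rate` (NA unless analytically known), `temperature`;
#'   * `config`.
#' @export
simulate_pore <- function(config) {
  if (!inherits(config, "PoreSimConfig")) stop("'config' must be a PoreSimConfig")
  cg <- config
  gradf <- NULL
  if (!is.null(cg$imposed_profile)) {
    pr <- cg$imposed_profile[order(cg$imposed_profile$z), ]
    zg <- pr$z
    # centred-difference gradient on the tabulated grid, zero outside it
    g <- c(diff(pr$U[1:2]) / diff(zg[1:2]),
           (pr$U[-(1:2)] - pr$U[1:(length(zg) - 2)]) / (zg[-(1:2)] - zg[1:(length(zg) - 2)]),
           diff(pr$U[(length(zg) - 1):length(zg)]) / diff(zg[(length(zg) - 1):length(zg)]))
    zpad <- c(zg[1] - 1e-6, zg, zg[length(zg)] + 1e-6)
    gpad <- c(0, g, 0)
    gradf <- stats::approxfun(zpad, gpad, rule = 2)
  }
  trajs <- vector("list", cg$n_channels)
  for (ch in seq_len(cg$n_channels)) {
    set.seed(cg$seed + (ch - 1L) * 7919L)
    trajs[[ch]] <- .simulate_one_channel(cg, gradf)
  }
  gt <- list(true_profile = cg$imposed_profile, true_D = cg$diffusion_coefficient,
             true_Dn = NA_real_, true_event_rate = NA_real_,
             temperature = cg$temperature)
  structure(list(trajectories = trajs, ground_truth = gt, config = cg),
            class = "PoreSimulation")
}

.simulate_one_channel <- function(cg, gradf) {
  N <- cg$n_particles
  L <- cg$box; R <- cg$pore_radius
  zlo <- cg$pore_z_bounds[1]; zhi <- cg$pore_z_bounds[2]
  cx <- L[1] / 2; cy <- L[2] / 2
  D <- cg$diffusion_coefficient; dt <- cg$dt
  beta <- 1 / kT_kcal(cg$temperature)
  sd_step <- sqrt(2 * D * dt)
  x <- stats::runif(N, 0, L[1]); y <- stats::runif(N, 0, L[2]); z <- stats::runif(N, 0, L[3])
  nf <- cg$n_frames
  coords <- array(NA_real_, c(nf, N, 3))
  coords[1, , 1] <- x; coords[1, , 2] <- y; coords[1, , 3] <- z
  nsteps <- (nf - 1L) * cg$save_every
  fidx <- 1L
  r2R <- R * R
  for (s in seq_len(nsteps)) {
    dxl <- min_image(x - cx, L[1]); dyl <- min_image(y - cy, L[2])
    r2 <- dxl * dxl + dyl * dyl
    inR <- r2 <= r2R
    in_sec <- z >= zlo & z <= zhi
    fz <- 0
    if (!is.null(gradf)) {
      fz <- numeric(N)
      act <- inR
      if (any(act)) fz[act] <- -gradf(z[act])
    }
    noise <- stats::rnorm(3L * N, 0, sd_step)
    xn <- x + noise[1:N]
    yn <- y + noise[(N + 1L):(2L * N)]
    zn <- z + beta * D * fz * dt + noise[(2L * N + 1L):(3L * N)]
    zn <- zn %% L[3]
    # reflective wall at r = R for particles inside the pore z-section:
    # any attempt to cross the cylinder surface (either direction) while in
    # the section is mirrored radially, preserving detailed balance.
    in_sec_n <- zn >= zlo & zn <= zhi
    dxn <- min_image(xn - cx, L[1]); dyn <- min_image(yn - cy, L[2])
    r2n <- dxn * dxn + dyn * dyn
    crossed <- (in_sec | in_sec_n) & ((r2 <= r2R) != (r2n <= r2R))
    if (any(crossed)) {
      rn <- sqrt(r2n[crossed])
      rmir <- abs(2 * R - rn)
      rmir <- pmin(rmir, 2 * R - 1e-9)       # guard huge steps
      scl <- ifelse(rn > 0, rmir / rn, 1)
      dxn[crossed] <- dxn[crossed] * scl
      dyn[crossed] <- dyn[crossed] * scl
      xn[crossed] <- cx + dxn[crossed]
      yn[crossed] <- cy + dyn[crossed]
    }
    x <- xn %% L[1]; y <- yn %% L[2]; z <- zn
    if (s %% cg$save_every == 0L) {
      fidx <- fidx + 1L
      coords[fidx, , 1] <- x; coords[fidx, , 2] <- y; coords[fidx, , 3] <- z
    }
  }
  atoms <- data.frame(name = rep("OW", N), resname = rep("SOL", N),
                      resid = seq_len(N), chain = rep("W", N),
                      charge = rep(NA_real_, N), radius = rep(NA_real_, N),
                      stringsAsFactors = FALSE)
  trajectory(coords, L, times = (seq_len(nf) - 1) * dt * cg$save_every, atoms = atoms)
}

#' Write a pore simulation to GRO + DCD with a ground-truth sidecar
#'
#' Writes, per channel, `<prefix>_chN.gro` (first frame, topology),
#' `<prefix>_chN.dcd` (all frames) and a single `<prefix>_truth.json`
#' holding the imposed profile and generator parameters.
#'
#' @param sim A `"PoreSimulation"` from [simulate_pore()].
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_pore_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "PoreSimulation"))
  files <- character(0)
  for (ch in seq_along(sim$trajectories)) {
    tr <- sim$trajectories[[ch]]
    g <- sprintf("%s_ch%d.gro", prefix, ch)
    d <- sprintf("%s_ch%d.dcd", prefix, ch)
    write_gro(subset_frames(tr, 1L), g)
    write_dcd(tr, d)
    files <- c(files, g, d)
  }
  j <- sprintf("%s_truth.json", prefix)
  gt <- sim$ground_truth
  gt$config <- sim$config[setdiff(names(sim$config), "imposed_profile")]
  jsonlite::write_json(gt, j, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, j))
}

#' Generate a collective-coordinate Brownian path
#'
#' Direct generator for the dimensionless cumulative coordinate `n(t)` with
#' known diffusion constant: `n` is a Brownian path with
#' `<n(t)^2> = 2 * Dn * t`, the ground truth against which
#' [pf_from_collective()] is validated.
#'
#' @param Dn Collective diffusion constant, 1/ns (`Dn = 0` gives a constant
#'   series).
#' @param n_frames Number of stored points (including `n(0) = 0`).
#' @param dt Time step, ns.
#' @param seed Integer RNG seed.
#' @return A `"CollectiveSeries"`: list with `times` (ns), `n`, and
#'   `true_Dn` attribute-style field.
#' @export
generate_collective_series <- function(Dn, n_frames, dt = 1e-3, seed = 1L) {
  stopifnot(Dn >= 0, n_frames >= 2, dt > 0)
  set.seed(as.integer(seed))
  incr <- if (Dn == 0) rep(0, n_frames - 1L) else
    stats::rnorm(n_frames - 1L, 0, sqrt(2 * Dn * dt))
  structure(list(times = (seq_len(n_frames) - 1) * dt,
                 n = c(0, cumsum(incr)), L = NA_real_, true_Dn = Dn),
            class = "CollectiveSeries")
}

#' Generate a pair of dipole-angle series with controlled correlation
#'
#' Draws a bivariate Gaussian copula with Pearson parameter `rho_target` and
#' maps both margins monotonically onto angles in `[0, 180]` degrees. The
#' sample Spearman correlation converges to `(6/pi) * asin(rho_target / 2)`;
#' `rho_target = 1` gives identical rank order.
#'
#' @param rho_target Copula correlation in `[-1, 1]`.
#' @param n_frames Series length.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `time` (frame index), `angle1`, `angle2`
#'   (degrees), with attribute `rho_target`.
#' @export
generate_dipole_pair <- function(rho_target, n_frames, seed = 1L) {
  stopifnot(abs(rho_target) <= 1, n_frames >= 2)
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n_frames)
  e <- stats::rnorm(n_frames)
  z2 <- rho_target * z1 + sqrt(max(0, 1 - rho_target^2)) * e
  out <- data.frame(time = seq_len(n_frames),
                    angle1 = stats::pnorm(z1) * 180,
                    angle2 = stats::pnorm(z2) * 180)
  attr(out, "rho_target") <- rho_target
  out
}

#' Generate a two-sheet charged slab system
#'
#' Builds a single-frame trajectory of point charges arranged as two
#' opposite uniform sheets of surface charge density `+sigma` and `-sigma`
#' at `z = Lz/2 -+ separation/2`, the analytic fixture for
#' [membrane_potential()]: the potential difference between the plateaus on
#' either side of the pair is `sigma * separation / eps0`.
#'
#' @param sigma Surface charge density, e/A^2 (`sigma = 0` gives zero
#'   density everywhere).
#' @param separation Sheet separation, Angstrom.
#' @param box Box lengths `c(Lx, Ly, Lz)`; both sheets must fit inside.
#' @param n_side Point charges per side of each sheet grid (default 8).
#' @return List of class `"ChargeSlab"`: `trajectory` (one frame,
#'   `2 * n_side^2` charges summing to exactly zero), `sigma`, `separation`,
#'   and `delta_v_mV`, the analytic plateau-to-plateau potential difference
#'   magnitude in mV.
#' @export
generate_charge_slab <- function(sigma, separation, box = c(40, 40, 120),
                                 n_side = 8L) {
  stopifnot(length(box) == 3, all(box > 0), separation > 0, n_side >= 1)
  if (separation >= box[3]) stop("slab separation must fit inside the box z-length")
  zc <- box[3] / 2
  z1 <- zc - separation / 2; z2 <- zc + separation / 2
  gx <- (seq_len(n_side) - 0.5) * box[1] / n_side
  gy <- (seq_len(n_side) - 0.5) * box[2] / n_side
  g <- expand.grid(x = gx, y = gy)
  npt <- nrow(g)
  q <- sigma * box[1] * box[2] / npt
  coords <- array(NA_real_, c(1, 2 * npt, 3))
  coords[1, , 1] <- c(g$x, g$x)
  coords[1, , 2] <- c(g$y, g$y)
  coords[1, , 3] <- c(rep(z1, npt), rep(z2, npt))
  atoms <- data.frame(name = rep("Q", 2 * npt), resname = rep("SLB", 2 * npt),
                      resid = seq_len(2 * npt), chain = rep("S", 2 * npt),
                      charge = c(rep(q, npt), rep(-q, npt)),
                      radius = rep(NA_real_, 2 * npt), stringsAsFactors = FALSE)
  tr <- trajectory(coords, box, times = 0, atoms = atoms)
  structure(list(trajectory = tr, sigma = sigma, separation = separation,
                 delta_v_mV = abs(sigma) * separation * .E_OVER_EPS0_A * 1000),
            class = "ChargeSlab")
}
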