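# Free-energy profiles from water occupancy, barrier extraction, and
# binding free energy -> dissociation constant conversion.

#' Slice-wise water occupancy along the pore axis
#'
#' Divides the cylindrical section into z slices (default 0.5 Angstrom) and
#' computes the time-averaged number density of selected atoms in each
#' slice. The bulk reference density is estimated from all selected atoms
#' outside the cylinder (per unit of the remaining box volume), or can be
#' fixed to a known value downstream.
#'
#' @inheritParams count_crossings
#' @param slice_width Slice thickness in Angstrom (default 0.5).
#' @return `"OccupancyProfile"`: data frame `(z_lo, z_hi, z_mid, mean_count,
#'   density)` with attributes `rho_bulk` (count/A^3), `slice_volume`,
#'   `n_frames`, `geometry`.
#' @export
occupancy_profile <- function(trajectory, selection, geometry, slice_width = 0.5) {
  idx <- selection_indices(selection, trajectory)
  if (length(idx) == 0L) stop("selection is empty")
  nf <- n_frames(trajectory)
  zn <- .pore_zones(trajectory, idx, geometry)
  inside <- zn$zone == 2L
  edges <- seq(geometry$z_lo, geometry$z_hi, by = slice_width)
  if (abs(edges[length(edges)] - geometry$z_hi) > 1e-9)
    edges <- c(edges, geometry$z_hi)
  ns <- length(edges) - 1L
  counts <- numeric(ns)
  zin <- zn$z[inside]
  if (length(zin) > 0) {
    h <- findInterval(zin, edges, rightmost.closed = TRUE)
    h <- h[h >= 1 & h <= ns]
    tb <- tabulate(h, nbins = ns)
    counts <- tb / nf
  }
  widths <- diff(edges)
  slice_vol <- pi * geometry$radius^2 * widths
  vol_box <- mean(trajectory$box[, 1] * trajectory$box[, 2] * trajectory$box[, 3])
  vol_cyl <- pi * geometry$radius^2 * geometry$L
  n_out <- mean(rowSums(!inside))
  rho_bulk <- n_out / (vol_box - vol_cyl)
  out <- data.frame(z_lo = edges[-(ns + 1)], z_hi = edges[-1],
                    z_mid = (edges[-(ns + 1)] + edges[-1]) / 2,
                    mean_count = counts, density = counts / slice_vol)
  attr(out, "rho_bulk") <- rho_bulk
  attr(out, "slice_volume") <- slice_vol
  attr(out, "n_frames") <- nf
  attr(out, "geometry") <- geometry
  class(out) <- c("OccupancyProfile", "data.frame")
  out
}

#' Gibbs free-energy profile from slice densities
#'
#' Converts a slice density profile into free energies via
#' `G(z) = -kT * log(rho(z) / rho_bulk)`. `G` is zero where the density
#' equals the bulk reference; zero-occupancy slices are masked (`defined =
#' FALSE`, `G = NA`), never set to infinity.
#'
#' @param rho An `"OccupancyProfile"` from [occupancy_profile()], or a bare
#'   numeric density vector (then `z` midpoints are taken as `seq_along`).
#' @param rho_bulk Bulk reference density, count/A^3; defaults to the
#'   estimate carried by the occupancy profile. Must be positive.
#' @param temperature Kelvin (default 310.15, the simulation temperature).
#' @return `"FreeEnergyProfile"`: data frame `(z_lo, z_hi, z_mid, G,
#'   defined)` with attributes `temperature` and `rho_bulk`.
#' @export
gibbs_profile <- function(rho, rho_bulk = NULL, temperature = 310.15) {
  if (inherits(rho, "OccupancyProfile")) {
    if (is.null(rho_bulk)) rho_bulk <- attr(rho, "rho_bulk")
    dens <- rho$density
    z_lo <- rho$z_lo; z_hi <- rho$z_hi; z_mid <- rho$z_mid
  } else {
    dens <- as.numeric(rho)
    z_mid <- seq_along(dens)
    z_lo <- z_mid - 0.5; z_hi <- z_mid + 0.5
  }
  if (is.null(rho_bulk) || !is.finite(rho_bulk) || rho_bulk <= 0)
    stop("rho_bulk must be a positive number")
  defined <- dens > 0
  G <- rep(NA_real_, length(dens))
  G[defined] <- -kT_kcal(temperature) * log(dens[defined] / rho_bulk)
  out <- data.frame(z_lo = z_lo, z_hi = z_hi, z_mid = z_mid, G = G,
                    defined = defined)
  attr(out, "temperature") <- temperature
  attr(out, "rho_bulk") <- rho_bulk
  class(out) <- c("FreeEnergyProfile", "data.frame")
  out
}

#' Construct a free-energy profile from known values
#'
#' Builds a `"FreeEnergyProfile"` directly from tabulated free energies, for
#' composing with [apply_dk()] or [barrier()] when the profile comes from an
#' external source.
#'
#' @param z Slice midpoints, Angstrom (regular grid).
#' @param G Free energies, kcal/mol (`NA` marks undefined slices).
#' @param temperature Kelvin.
#' @return A `"FreeEnergyProfile"`.
#' @export
fe_profile <- function(z, G, temperature = 310.15) {
  stopifnot(length(z) == length(G), length(z) >= 1)
  hw <- if (length(z) > 1) min(diff(sort(z))) / 2 else 0.25
  out <- data.frame(z_lo = z - hw, z_hi = z + hw, z_mid = z, G = G,
                    defined = !is.na(G))
  attr(out, "temperature") <- temperature
  attr(out, "rho_bulk") <- NA_real_
  class(out) <- c("FreeEnergyProfile", "data.frame")
  out
}

#' Highest free-energy barrier within a section
#'
#' Maximum of `G` over the defined slices whose midpoint falls in the
#' section, relative to the bulk zero level. Ties are broken toward the
#' smallest z.
#'
#' @param profile A `"FreeEnergyProfile"`.
#' @param section `c(z_lo, z_hi)`; default the full profile support.
#' @return List with `dG_max` (kcal/mol) and `z` (slice midpoint of the
#'   barrier). A fully-masked section is an error.
#' @export
barrier <- function(profile, section = NULL) {
  stopifnot(inherits(profile, "FreeEnergyProfile"))
  if (is.null(section)) section <- c(min(profile$z_lo), max(profile$z_hi))
  sel <- profile$z_mid >= section[1] & profile$z_mid <= section[2] & profile$defined
  if (!any(sel)) stop("no defined slices within the section")
  g <- profile$G[sel]; z <- profile$z_mid[sel]
  i <- which(g == max(g))[1]   # ties -> smallest z (slices are z-ordered)
  list(dG_max = g[i], z = z[i])
}

#' Dissociation constant from binding free energy
#'
#' Converts a ligand binding free energy to a dissociation constant on the
#' 1 M standard state: `KD = exp(dG / (R*T))` in molar, with
#' `R = 1.9872e-3 kcal mol^-1 K^-1`. With this convention a favourable
#' (negative) `dG` gives `KD < 1 M`; `dG = 0` gives exactly 1 M.
#'
#' @param dG Binding free energy (kcal/mol); vectorized.
#' @param temperature Kelvin (default 310.15).
#' @return `KD` in molar.
#' @examples
#' kd_from_dg(-9.22) * 1e9   # ~318 nM
#' @export
kd_from_dg <- function(dG, temperature = 310.15) {
  stopifnot(temperature > 0)
  exp(dG / (.R_KCAL * temperature))
}

#' Read a binding free-energy time series from CSV
#'
#' Expects two columns: time in ns and binding free energy in kcal/mol
#' (header names are free; the first two columns are used).
#'
#' @param path CSV path.
#' @return Data frame with columns `time`, `dG`, ordered by time.
#' @export
read_binding_series <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("binding series CSV needs two columns (time_ns, dG_kcal_mol)")
  out <- data.frame(time = as.numeric(d[[1]]), dG = as.numeric(d[[2]]))
  if (anyNA(out)) stop("binding series contains non-numeric values")
  out[order(out$time), , drop = FALSE]
}

#' Summarize a binding free-energy series as dissociation constants
#'
#' Reports the mean, minimum and maximum of the `dG` series and the
#' corresponding dissociation constants via [kd_from_dg()]. Note that
#' `Kd_mean` is `KD(mean(dG))`, the KD of the average binding free energy,
#' not the average of per-frame KD values.
#'
#' @param series Data frame with columns `time` (ns) and `dG` (kcal/mol),
#'   e.g. from [read_binding_series()].
#' @param temperature Kelvin (default 310.15).
#' @return `"KdSummary"`: list with `dG_mean`, `dG_min`, `dG_max`
#'   (kcal/mol), `Kd_mean`, `Kd_min`, `Kd_max` (molar), `temperature`,
#'   `R` (kcal mol^-1 K^-1), `n`.
#' @export
summarize_binding <- function(series, temperature = 310.15) {
  if (is.null(series$dG) || length(series$dG) == 0)
    stop("series must contain a non-empty 'dG' column")
  if (any(!is.finite(series$dG))) stop("series contains non-finite dG values")
  dg <- series$dG
  structure(list(dG_mean = mean(dg), dG_min = min(dg), dG_max = max(dg),
                 Kd_mean = kd_from_dg(mean(dg), temperature),
                 Kd_min = kd_from_dg(min(dg), temperature),
                 Kd_max = kd_from_dg(max(dg), temperature),
                 temperature = temperature, R = .R_KCAL, n = length(dg)),
            class = "KdSummary")
}

#' @export
print.KdSummary <- function(x, ...) {
  cat(sprintf("KdSummary (n = %d, T = %.2f K)\n", x$n, x$temperature))
  cat(sprintf("  dG [kcal/mol]: mean %.3f, range [%.3f, %.3f]\n",
              x$dG_mean, x$dG_min, x$dG_max))
  cat(sprintf("  KD: mean %.4g nM, range [%.4g, %.4g] nM\n",
              x$Kd_mean * 1e9, x$Kd_min * 1e9, x$Kd_max * 1e9))
  invisible(x)
}
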