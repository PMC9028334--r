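# Water permeation: end-to-end event counting, the collective coordinate
# n(t), and the osmotic permeability coefficient pf with the Dk
# free-energy-barrier correction.

#' Cylindrical pore geometry
#'
#' Axis-aligned cylinder used to define the transmembrane section: lateral
#' centre, radius, and z bounds. The canonical sections are the 30 Angstrom
#' whole-transmembrane cylinder and a 5 Angstrom section around the ar/R
#' constriction.
#'
#' @param center Lateral centre `c(x, y)` in Angstrom.
#' @param radius Cylinder radius, Angstrom.
#' @param z_lo,z_hi Section bounds along z, Angstrom (`z_hi > z_lo`).
#' @return List of class `"PoreGeometry"` with fields `center`, `radius`,
#'   `z_lo`, `z_hi`, `L = z_hi - z_lo`.
#' @export
pore_geometry <- function(center, radius, z_lo, z_hi) {
  stopifnot(length(center) == 2, radius > 0)
  if (z_hi <= z_lo) stop("z_hi must exceed z_lo")
  structure(list(center = as.numeric(center), radius = radius,
                 z_lo = z_lo, z_hi = z_hi, L = z_hi - z_lo),
            class = "PoreGeometry")
}

# Per-frame x particle zone codes w.r.t. a pore geometry:
# 1 = below section, 2 = inside cylinder, 3 = above section,
# 0 = within z-section but laterally outside the radius (membrane region).
.pore_zones <- function(traj, idx, geometry) {
  nf <- n_frames(traj)
  x <- traj$coords[, idx, 1, drop = FALSE]; dim(x) <- c(nf, length(idx))
  y <- traj$coords[, idx, 2, drop = FALSE]; dim(y) <- c(nf, length(idx))
  z <- traj$coords[, idx, 3, drop = FALSE]; dim(z) <- c(nf, length(idx))
  dx <- min_image(x - geometry$center[1], traj$box[, 1])
  dy <- min_image(y - geometry$center[2], traj$box[, 2])
  inR <- dx * dx + dy * dy <= geometry$radius^2
  zone <- matrix(0L, nf, length(idx))
  zone[z < geometry$z_lo] <- 1L
  zone[z > geometry$z_hi] <- 3L
  insec <- zone == 0L
  zone[insec & inR] <- 2L
  list(zone = zone, z = z)
}

#' Count end-to-end permeation events
#'
#' State machine per tracked particle: a permeation event is recorded when a
#' particle enters the cylindrical section through one z-face and exits
#' through the opposite face while staying within the cylinder radius
#' between the two passages. Leaving the cylinder radially (while in the
#' z-section) resets the attempt, as does wrapping across the periodic z
#' boundary (frame-to-frame z jumps larger than half the box are treated as
#' periodic images, never as crossings). Entries through the cylinder wall
#' do not arm an attempt in the default strict mode; with
#' `radial = FALSE` the radius is ignored entirely (slab-crossing rule).
#'
#' @param trajectory A [trajectory()].
#' @param selection Atoms to track: a [select()] result, expression string
#'   or index vector (typically the water oxygens).
#' @param geometry A [pore_geometry()].
#' @param radial Enforce the cylinder radius (default `TRUE`, the strict
#'   end-to-end rule).
#' @return `"PermeationEvents"`: list with
#'   * `events`: data frame `(particle, entry_frame, exit_frame, direction)`
#'     with direction `"+z"`/`"-z"` and `exit_frame > entry_frame`;
#'   * `cumulative`: data frame `(time, count)` of the non-decreasing
#'     cumulative crossing count (by exit time);
#'   * `times`, `total_time` (ns), `geometry`, `n_tracked`.
#' @export
count_crossings <- function(trajectory, selection, geometry, radial = TRUE) {
  idx <- selection_indices(selection, trajectory)
  if (length(idx) == 0L) stop("selection is empty")
  if (geometry$z_lo < 0 || geometry$z_hi > min(trajectory$box[, 3]))
    stop("pore section must lie inside the box")
  nf <- n_frames(trajectory)
  zn <- .pore_zones(trajectory, idx, geometry)
  zone <- zn$zone
  if (!radial) zone[zone == 0L] <- 2L
  Lz <- trajectory$box[, 3]
  # median frame-to-frame rms z step as a dwell-resolution heuristic
  if (nf > 1) {
    dz1 <- min_image(zn$z[-1, , drop = FALSE] - zn$z[-nf, , drop = FALSE],
                     matrix(Lz[-1], nf - 1, length(idx)))
    step_rms <- sqrt(mean(dz1^2))
    if (is.finite(step_rms) && step_rms > geometry$L / 2)
      warning(sprintf(paste0("frame spacing is coarse for this section (rms z step ",
                             "%.2f A vs section length %.1f A): crossings may be ",
                             "undercounted"), step_rms, geometry$L))
  }
  ev_particle <- integer(0); ev_entry <- integer(0); ev_exit <- integer(0)
  ev_dir <- character(0)
  for (p in seq_along(idx)) {
    zp <- zone[, p]
    zzp <- zn$z[, p]
    state <- 0L   # 0 idle, +1 entered from below, -1 entered from above
    entry <- NA_integer_
    for (f in 2:nf) {
      cur <- zp[f]; prev <- zp[f - 1L]
      if (cur == prev && cur != 2L) next
      wrap <- abs(zzp[f] - zzp[f - 1L]) > Lz[f] / 2
      if (cur == 2L) {
        if (state == 0L && !wrap) {
          if (prev == 1L) { state <- 1L; entry <- f }
          else if (prev == 3L) { state <- -1L; entry <- f }
        } else if (wrap) state <- 0L
        # prev == 0 (radial entry) or already armed: no change
      } else if (cur == 0L) {
        state <- 0L                     # radial exit resets the attempt
      } else {                          # reservoir (1 or 3)
        if (!wrap && state == 1L && cur == 3L && prev == 2L) {
          ev_particle <- c(ev_particle, idx[p]); ev_entry <- c(ev_entry, entry)
          ev_exit <- c(ev_exit, f); ev_dir <- c(ev_dir, "+z")
        } else if (!wrap && state == -1L && cur == 1L && prev == 2L) {
          ev_particle <- c(ev_particle, idx[p]); ev_entry <- c(ev_entry, entry)
          ev_exit <- c(ev_exit, f); ev_dir <- c(ev_dir, "-z")
        }
        state <- 0L
      }
    }
  }
  events <- data.frame(particle = ev_particle, entry_frame = ev_entry,
                       exit_frame = ev_exit, direction = ev_dir,
                       stringsAsFactors = FALSE)
  if (nrow(events) > 0) events <- events[order(events$exit_frame), , drop = FALSE]
  cum <- data.frame(time = trajectory$times,
                    count = cumsum(tabulate(events$exit_frame, nbins = nf)))
  structure(list(events = events, cumulative = cum, times = trajectory$times,
                 total_time = trajectory$times[nf] - trajectory$times[1],
                 geometry = geometry, n_tracked = length(idx)),
            class = "PermeationEvents")
}

#' @export
print.PermeationEvents <- function(x, ...) {
  cat(sprintf("PermeationEvents: %d events (%d +z, %d -z) over %.4g ns, %d particles tracked\n",
              nrow(x$events), sum(x$events$direction == "+z"),
              sum(x$events$direction == "-z"), x$total_time, x$n_tracked))
  invisible(x)
}

#' Construct a PermeationEvents object from known event times
#'
#' Used when events come from elsewhere (bookkeeping, tabulated results)
#' rather than from [count_crossings()].
#'
#' @param event_times Event times in ns (at the exit of the pore).
#' @param total_time Trajectory length in ns.
#' @param directions Optional `"+z"`/`"-z"` per event (default all `"+z"`).
#' @return A `"PermeationEvents"` with `events$time` in ns.
#' @export
permeation_events <- function(event_times, total_time, directions = NULL) {
  stopifnot(total_time > 0, all(event_times >= 0), all(event_times <= total_time))
  if (is.null(directions)) directions <- rep("+z", length(event_times))
  if (length(directions) != length(event_times))
    stop("'directions' must have one entry per event")
  o <- order(event_times)
  n <- length(event_times)
  events <- data.frame(particle = rep(NA_integer_, n),
                       entry_frame = rep(NA_integer_, n),
                       exit_frame = rep(NA_integer_, n),
                       direction = directions[o],
                       time = event_times[o], stringsAsFactors = FALSE)
  structure(list(events = events, cumulative = NULL, times = NULL,
                 total_time = total_time, geometry = NULL, n_tracked = NA_integer_),
            class = "PermeationEvents")
}

# event exit times in ns for either flavour of PermeationEvents
.event_times <- function(events) {
  if (!is.null(events$events$time) && !anyNA(events$events$time))
    return(events$events$time)
  if (nrow(events$events) == 0) return(numeric(0))
  events$times[events$events$exit_frame]
}

#' Per-block water crossing counts
#'
#' Splits the trajectory span into contiguous non-overlapping blocks of
#' `block_length` ns anchored at the start and counts permeation events (by
#' exit time) per block; a trailing partial block is dropped with a message.
#'
#' @param events A `"PermeationEvents"`.
#' @param block_length Block length in ns (default 10).
#' @return Data frame `(block, t_lo, t_hi, count)`; `sum(count)` equals the
#'   number of events within the retained span.
#' @export
water_count_per_block <- function(events, block_length = 10) {
  stopifnot(inherits(events, "PermeationEvents"), block_length > 0)
  total <- events$total_time
  nb <- floor(total / block_length + 1e-9)
  if (nb < 1) stop("trajectory shorter than one block")
  if (nb * block_length < total - 1e-9)
    message(sprintf("dropping trailing partial block (%.4g ns)", total - nb * block_length))
  et <- .event_times(events)
  edges <- seq(0, nb * block_length, by = block_length)
  cnt <- if (length(et) == 0) integer(nb) else
    as.integer(table(cut(et[et <= nb * block_length], breaks = edges,
                         right = TRUE, include.lowest = TRUE)))
  data.frame(block = seq_len(nb), t_lo = edges[-(nb + 1)], t_hi = edges[-1],
             count = cnt)
}

#' Collective coordinate n(t) of water through the pore
#'
#' For each consecutive frame pair, sums the minimum-image axial
#' displacements of the particles inside the cylinder in both frames,
#' divided by the section length L; `n(t)` is the cumulative sum with
#' `n(0) = 0`. The diffusion constant of this dimensionless coordinate
#' yields the osmotic permeability (see [pf_from_collective()]).
#'
#' @inheritParams count_crossings
#' @return A `"CollectiveSeries"`: list with `times` (ns), `n`, `L`.
#' @export
collective_coordinate <- function(trajectory, selection, geometry) {
  idx <- selection_indices(selection, trajectory)
  if (length(idx) == 0L) stop("selection is empty")
  nf <- n_frames(trajectory)
  zn <- .pore_zones(trajectory, idx, geometry)
  inside <- zn$zone == 2L
  if (nf < 2) stop("need at least two frames")
  dz <- min_image(zn$z[-1, , drop = FALSE] - zn$z[-nf, , drop = FALSE],
                  matrix(trajectory$box[-1, 3], nf - 1, length(idx)))
  both <- inside[-1, , drop = FALSE] & inside[-nf, , drop = FALSE]
  dn <- rowSums(dz * both) / geometry$L
  structure(list(times = trajectory$times, n = c(0, cumsum(dn)), L = geometry$L,
                 true_Dn = NA_real_),
            class = "CollectiveSeries")
}

# least-squares Dn from the MSD of non-overlapping restart segments
.fit_dn <- function(times, n, n_restarts, fit_fraction) {
  npt <- length(n)
  seg_len <- floor(npt / n_restarts)
  if (seg_len < 5) stop("series too short for the requested number of restarts")
  nlag <- max(2L, floor(fit_fraction * seg_len))
  dt <- mean(diff(times))
  segs <- matrix(n[seq_len(seg_len * n_restarts)], nrow = seg_len)
  disp2 <- (segs[seq_len(nlag + 1L), , drop = FALSE] -
              matrix(segs[1L, ], nlag + 1L, n_restarts, byrow = TRUE))^2
  msd <- rowMeans(disp2)
  tau <- (0:nlag) * dt
  fit <- stats::lm.fit(cbind(1, tau), msd)
  unname(fit$coefficients[2] / 2)
}

#' Osmotic permeability from the collective coordinate
#'
#' Estimates the collective diffusion constant `Dn` as half the slope of
#' `<n(t)^2>` versus `t`, where the mean square displacement is taken over
#' non-overlapping restart segments of the path, and converts it to the
#' single-channel osmotic permeability `pf = v_w * Dn` in cm^3/s.
#'
#' @param series A `"CollectiveSeries"` from [collective_coordinate()] or
#'   [generate_collective_series()].
#' @param v_w Single-water volume in cm^3 (default 2.989e-23, i.e.
#'   18.07 cm^3/mol over Avogadro's number).
#' @param n_restarts Number of non-overlapping restart segments. Default
#'   (`NULL`): one restart per ~200 stored points (at least 10), which keeps
#'   the MSD fit window short where the path is long and the slope variance
#'   correspondingly small.
#' @param fit_fraction MSD fit window as a fraction of the segment length
#'   (default 0.2).
#' @param block_length Optional block length in ns; when given, `Dn` is also
#'   fitted per block and per-block `pf` values are returned in
#'   `block_values`.
#' @return `"PermeabilityResult"`: list with `pf` (cm^3/s), `Dn` (1/ns),
#'   `Dk = 1`, `pf_corrected = pf`, `v_w`, `block_values` (data frame or
#'   `NULL`). A negative fitted slope gives `pf = 0` with a warning.
#' @export
pf_from_collective <- function(series, v_w = .V_WATER_CM3, n_restarts = NULL,
                               fit_fraction = 0.2, block_length = NULL) {
  stopifnot(inherits(series, "CollectiveSeries"), v_w > 0)
  if (is.null(n_restarts)) n_restarts <- max(10L, length(series$n) %/% 200L)
  Dn <- .fit_dn(series$times, series$n, n_restarts, fit_fraction)
  if (Dn < 0) {
    warning("negative fitted MSD slope; pf set to 0")
    Dn <- 0
  }
  pf <- v_w * Dn * 1e9   # 1/ns -> 1/s
  blocks <- NULL
  if (!is.null(block_length)) {
    dtf <- mean(diff(series$times))
    per_block <- max(5L, floor(block_length / dtf))
    nb <- floor(length(series$n) / per_block)
    if (nb >= 1) {
      bv <- vapply(seq_len(nb), function(b) {
        i0 <- (b - 1L) * per_block + 1L
        seg <- series$n[i0:(i0 + per_block - 1L)]
        d <- tryCatch(.fit_dn(series$times[i0:(i0 + per_block - 1L)], seg - seg[1],
                              n_restarts = max(5L, per_block %/% 200L),
                              fit_fraction = fit_fraction),
                      error = function(e) NA_real_)
        max(0, d)
      }, numeric(1))
      blocks <- data.frame(block = seq_len(nb), Dn = bv, pf = v_w * bv * 1e9)
    }
  }
  structure(list(pf = pf, Dn = Dn, Dk = 1, pf_corrected = pf, v_w = v_w,
                 block_values = blocks),
            class = "PermeabilityResult")
}

#' @export
print.PermeabilityResult <- function(x, ...) {
  cat(sprintf("PermeabilityResult: pf = %.4g cm^3/s (Dn = %.4g /ns), Dk = %.4g, pf_corrected = %.4g cm^3/s\n",
              x$pf, x$Dn, x$Dk, x$pf_corrected))
  invisible(x)
}

#' Apply the Dk free-energy-barrier correction to pf
#'
#' Thermal agitation of pore water inflates the collective-diffusion `pf`
#' even when the channel is closed; the `Dk` constant penalizes free-energy
#' barriers along the pore: `Dk = exp(-dG_max / kT)`, where `dG_max` is the
#' highest barrier of the occupancy-derived profile within the pore section
#' relative to the bulk zero level (clamped at 0 so barrier-free channels
#' are untouched), and `pf_corrected = Dk * pf`.
#'
#' @param result A `"PermeabilityResult"`.
#' @param profile A `"FreeEnergyProfile"` (see [gibbs_profile()]) covering
#'   the section.
#' @param section Optional `c(z_lo, z_hi)` restricting the barrier search;
#'   default the full profile. Undefined (zero-occupancy) slices inside the
#'   section are an error.
#' @return The `"PermeabilityResult"` with `Dk` and `pf_corrected` set, plus
#'   `barrier` (kcal/mol) and `barrier_z`.
#' @export
apply_dk <- function(result, profile, section = NULL) {
  stopifnot(inherits(result, "PermeabilityResult"),
            inherits(profile, "FreeEnergyProfile"))
  if (is.null(section)) section <- c(min(profile$z_lo), max(profile$z_hi))
  inside <- profile$z_mid >= section[1] & profile$z_mid <= section[2]
  if (!any(inside)) stop("section lies outside the profile support")
  bad <- inside & !profile$defined
  if (any(bad))
    stop("profile has undefined (zero-occupancy) slices inside the section at z = ",
         paste(sprintf("%.2f", profile$z_mid[bad]), collapse = ", "))
  b <- barrier(profile, section)
  T <- attr(profile, "temperature")
  dk <- exp(-max(0, b$dG_max) / kT_kcal(T))
  result$Dk <- dk
  result$pf_corrected <- dk * result$pf
  result$barrier <- b$dG_max
  result$barrier_z <- b$z
  if (!is.null(result$block_values))
    result$block_values$pf_corrected <- dk * result$block_values$pf
  result
}
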