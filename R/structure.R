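# Geometric and electrostatic observables: hydrogen bonds, minimum
# distances, simplified pore radius profile, radial distribution functions,
# dipole moments and the one-dimensional membrane potential.

# frame coordinates of selected atoms as an n x 3 matrix
.frame_xyz <- function(traj, f, idx) {
  m <- traj$coords[f, idx, , drop = FALSE]
  dim(m) <- c(length(idx), 3)
  m
}

# all minimum-image distances between two coordinate sets (na x nb)
.pair_dists <- function(a, b, box) {
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Geometric hydrogen-bond criterion
#'
#' Donor-acceptor distance and H-donor-acceptor angle cutoffs. Defaults
#' 3.5 Angstrom / 30 degrees, the common geometric criterion of standard MD
#' analysis tools.
#'
#' @param max_da_distance Maximum donor-acceptor distance, Angstrom.
#' @param max_hda_angle Maximum H-D-A angle, degrees.
#' @param max_dh_distance Distance used to attach hydrogens to their donor
#'   heavy atom from the topology (default 1.2 Angstrom).
#' @return List of class `"HBondCriterion"`.
#' @export
hbond_criterion <- function(max_da_distance = 3.5, max_hda_angle = 30,
                            max_dh_distance = 1.2) {
  stopifnot(max_da_distance > 0, max_hda_angle > 0, max_hda_angle < 180,
            max_dh_distance > 0)
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle,
                 max_dh_distance = max_dh_distance),
            class = "HBondCriterion")
}

#' Hydrogen bonds between donor and acceptor groups
#'
#' A bond is counted when the donor-acceptor (minimum-image) distance is at
#' most the cutoff and the H-D-A angle at the donor is at most the angular
#' cutoff. Hydrogens are resolved from the topology: atoms whose name starts
#' with `H`, in the same residue as the donor and within
#' `max_dh_distance` of it in the first frame. Donors without any resolvable
#' hydrogen are excluded with a warning.
#'
#' @param trajectory A [trajectory()].
#' @param donors,acceptors Heavy-atom selections (expression, [select()]
#'   result or indices).
#' @param criterion An [hbond_criterion()].
#' @return List of class `"HBondSeries"`: `counts` data frame `(time,
#'   count)` of distinct donor-acceptor bonded pairs per frame, and `pairs`
#'   data frame `(frame, donor, hydrogen, acceptor, distance, angle)`.
#' @export
hydrogen_bonds <- function(trajectory, donors, acceptors,
                           criterion = hbond_criterion()) {
  di <- selection_indices(donors, trajectory)
  ai <- selection_indices(acceptors, trajectory)
  if (length(di) == 0L || length(ai) == 0L) stop("donor and acceptor selections must be non-empty")
  at <- trajectory$atoms
  h_all <- which(startsWith(as.character(at$name), "H"))
  # attach hydrogens to donors: same residue + within bonding distance (frame 1)
  x1 <- .frame_xyz(trajectory, 1L, seq_len(n_atoms(trajectory)))
  dh_pairs <- list()
  for (d in di) {
    cand <- h_all[at$resid[h_all] == at$resid[d] & at$chain[h_all] == at$chain[d]]
    if (length(cand) > 0) {
      dd <- sqrt(colSums((t(x1[cand, , drop = FALSE]) - x1[d, ])^2))
      cand <- cand[dd <= criterion$max_dh_distance]
    }
    if (length(cand) == 0) next
    dh_pairs[[length(dh_pairs) + 1L]] <- cbind(d, cand)
  }
  if (length(dh_pairs) == 0L) {
    warning("no donor has a resolvable hydrogen; no bonds can be detected")
    return(structure(list(counts = data.frame(time = trajectory$times, count = 0L),
                          pairs = data.frame()), class = "HBondSeries"))
  }
  dropped <- setdiff(di, unique(do.call(rbind, dh_pairs)[, 1]))
  if (length(dropped) > 0)
    warning(length(dropped), " donor(s) without resolvable hydrogen excluded")
  dh <- do.call(rbind, dh_pairs)
  nf <- n_frames(trajectory)
  counts <- integer(nf)
  rows <- list()
  cosmax <- cos(criterion$max_hda_angle * pi / 180)
  for (f in seq_len(nf)) {
    box <- trajectory$box[f, ]
    xd <- .frame_xyz(trajectory, f, dh[, 1])
    xh <- .frame_xyz(trajectory, f, dh[, 2])
    xa <- .frame_xyz(trajectory, f, ai)
    dda <- .pair_dists(xd, xa, box)
    hit <- which(dda <= criterion$max_da_distance, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      keep <- dh[hit[, 1], 1] != ai[hit[, 2]]
      hit <- hit[keep, , drop = FALSE]
    }
    if (nrow(hit) > 0) {
      vh <- min_image(xh[hit[, 1], , drop = FALSE] - xd[hit[, 1], , drop = FALSE],
                      matrix(box, nrow(hit), 3, byrow = TRUE))
      va <- min_image(xa[hit[, 2], , drop = FALSE] - xd[hit[, 1], , drop = FALSE],
                      matrix(box, nrow(hit), 3, byrow = TRUE))
      cosang <- rowSums(vh * va) / (sqrt(rowSums(vh^2)) * sqrt(rowSums(va^2)))
      ok <- cosang >= cosmax
      if (any(ok)) {
        sub <- hit[ok, , drop = FALSE]
        pr <- data.frame(frame = f, donor = dh[sub[, 1], 1],
                         hydrogen = dh[sub[, 1], 2], acceptor = ai[sub[, 2]],
                         distance = dda[sub],
                         angle = acos(pmin(1, cosang[ok])) * 180 / pi)
        rows[[length(rows) + 1L]] <- pr
        counts[f] <- nrow(unique(pr[, c("donor", "acceptor")]))
      }
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else data.frame()
  structure(list(counts = data.frame(time = trajectory$times, count = counts),
                 pairs = pairs),
            class = "HBondSeries")
}

#' Per-frame minimum distance between two groups
#'
#' Exact minimum over all inter-group atom pairs under the minimum-image
#' convention (no cutoff truncation).
#'
#' @param trajectory A [trajectory()].
#' @param groupA,groupB Selections.
#' @return Data frame `(time, distance)` in ns / Angstrom.
#' @export
min_distance <- function(trajectory, groupA, groupB) {
  ia <- selection_indices(groupA, trajectory)
  ib <- selection_indices(groupB, trajectory)
  if (length(ia) == 0L || length(ib) == 0L) stop("both groups must be non-empty")
  nf <- n_frames(trajectory)
  d <- vapply(seq_len(nf), function(f) {
    min(.pair_dists(.frame_xyz(trajectory, f, ia), .frame_xyz(trajectory, f, ib),
                    trajectory$box[f, ]))
  }, numeric(1))
  data.frame(time = trajectory$times, distance = d)
}

#' Simplified pore radius profile
#'
#' Slice-wise inscribed-radius approximation (not the sphere-propagation
#' algorithm of HOLE): for each z slice of the section, the pore radius is
#' the minimum over protein atoms in the slice of (lateral distance to the
#' pore axis minus the atom's van der Waals radius), clamped at zero and
#' averaged over frames. Slices containing no atoms in any frame are
#' masked.
#'
#' @param trajectory A [trajectory()].
#' @param protein Selection of pore-lining atoms; their `radius` metadata
#'   must be present.
#' @param geometry A [pore_geometry()] (its radius is ignored; only the axis
#'   and the z-section are used).
#' @param slice_width Slice thickness, Angstrom (default 1).
#' @return Data frame `(z_lo, z_hi, z_mid, radius, n_frames_defined)`,
#'   `radius = NA` for masked slices, labelled simplified in the
#'   `"method"` attribute.
#' @export
pore_radius_profile <- function(trajectory, protein, geometry, slice_width = 1) {
  idx <- selection_indices(protein, trajectory)
  edges <- seq(geometry$z_lo, geometry$z_hi, by = slice_width)
  if (abs(edges[length(edges)] - geometry$z_hi) > 1e-9) edges <- c(edges, geometry$z_hi)
  ns <- length(edges) - 1L
  if (length(idx) > 0) {
    vdw <- trajectory$atoms$radius[idx]
    if (anyNA(vdw))
      stop("vdW radii missing for ", sum(is.na(vdw)), " selected atoms")
  }
  acc <- numeric(ns); nfr <- integer(ns)
  nf <- n_frames(trajectory)
  for (f in seq_len(nf)) {
    if (length(idx) == 0) break
    xyz <- .frame_xyz(trajectory, f, idx)
    box <- trajectory$box[f, ]
    lat <- sqrt(min_image(xyz[, 1] - geometry$center[1], box[1])^2 +
                  min_image(xyz[, 2] - geometry$center[2], box[2])^2)
    sl <- findInterval(xyz[, 3], edges, rightmost.closed = TRUE)
    ok <- sl >= 1 & sl <= ns
    if (!any(ok)) next
    r <- pmax(0, lat - vdw)
    m <- tapply(r[ok], factor(sl[ok], levels = seq_len(ns)), min)
    got <- !is.na(m)
    acc[got] <- acc[got] + m[got]
    nfr[got] <- nfr[got] + 1L
  }
  radius <- ifelse(nfr > 0, acc / pmax(1L, nfr), NA_real_)
  out <- data.frame(z_lo = edges[-(ns + 1)], z_hi = edges[-1],
                    z_mid = (edges[-(ns + 1)] + edges[-1]) / 2,
                    radius = radius, n_frames_defined = nfr)
  attr(out, "method") <- "simplified slice-wise inscribed radius (not HOLE)"
  out
}

#' Radial distribution function
#'
#' Pair distribution `g(r)` of a target group around a reference group,
#' normalized by the ideal-gas expectation at the target's mean number
#' density over the box, so a uniformly random gas gives `g(r) = 1`.
#' Minimum-image distances; self-pairs (atoms in both groups) are excluded
#' from both the counts and the normalization.
#'
#' @param trajectory A [trajectory()].
#' @param reference,target Selections.
#' @param r_max Maximum radius, Angstrom; must be below half the smallest
#'   box length.
#' @param bin_width Bin width, Angstrom (default 0.1).
#' @return `"RdfResult"`: data frame `(r_lo, r_hi, r_mid, g)` with
#'   attributes `reference_label`, `target_label`, `n_frames`.
#' @export
rdf <- function(trajectory, reference, target, r_max, bin_width = 0.1) {
  ir <- selection_indices(reference, trajectory)
  it <- selection_indices(target, trajectory)
  if (length(ir) == 0L || length(it) == 0L) stop("reference and target must be non-empty")
  if (r_max >= min(trajectory$box) / 2)
    stop(sprintf("r_max (%.2f A) must be below half the smallest box length (%.2f A)",
                 r_max, min(trajectory$box) / 2))
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-9) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  nf <- n_frames(trajectory)
  overlap <- length(intersect(ir, it))
  vol <- mean(trajectory$box[, 1] * trajectory$box[, 2] * trajectory$box[, 3])
  for (f in seq_len(nf)) {
    d <- .pair_dists(.frame_xyz(trajectory, f, ir), .frame_xyz(trajectory, f, it),
                     trajectory$box[f, ])
    if (overlap > 0) d[outer(ir, it, "==")] <- NA
    d <- d[!is.na(d) & d <= r_max & d > 0]
    if (length(d) > 0) counts <- counts + tabulate(findInterval(d, edges,
                                                                rightmost.closed = TRUE),
                                                   nbins = nb)
  }
  n_pairs_per_ref <- length(it) - overlap / length(ir)
  rho <- n_pairs_per_ref / vol
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  g <- counts / (nf * length(ir) * rho * shell)
  out <- data.frame(r_lo = edges[-(nb + 1)], r_hi = edges[-1],
                    r_mid = (edges[-(nb + 1)] + edges[-1]) / 2, g = g)
  attr(out, "reference_label") <- if (inherits(reference, "Selection")) reference$label else as.character(substitute(reference))[1]
  attr(out, "target_label") <- if (inherits(target, "Selection")) target$label else as.character(substitute(target))[1]
  attr(out, "n_frames") <- nf
  class(out) <- c("RdfResult", "data.frame")
  out
}

#' Dipole moment time series
#'
#' Per frame, `mu = sum_i q_i * (r_i - r_cog)` over the selection, with the
#' centre of geometry of the selection as reference point (required for
#' non-neutral selections), reported in Debye together with the angle of
#' the dipole vector with the +z axis.
#'
#' @param trajectory A [trajectory()]; the selected atoms must carry
#'   partial charges.
#' @param selection Selection.
#' @return `"DipoleSeries"`: data frame `(time, mx, my, mz, magnitude,
#'   angle_z)` (Debye / degrees) with attribute `reference = "center of
#'   geometry"`.
#' @export
dipole_moment <- function(trajectory, selection) {
  idx <- selection_indices(selection, trajectory)
  if (length(idx) == 0L) stop("selection is empty")
  q <- trajectory$atoms$charge[idx]
  if (anyNA(q)) {
    miss <- idx[is.na(q)]
    stop("partial charges missing for atoms: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10) else "")
  }
  nf <- n_frames(trajectory)
  out <- data.frame(time = trajectory$times, mx = NA_real_, my = NA_real_,
                    mz = NA_real_, magnitude = NA_real_, angle_z = NA_real_)
  for (f in seq_len(nf)) {
    xyz <- .frame_xyz(trajectory, f, idx)
    cog <- colMeans(xyz)
    mu <- colSums(q * sweep(xyz, 2, cog)) * .EA_TO_DEBYE
    mag <- sqrt(sum(mu^2))
    out$mx[f] <- mu[1]; out$my[f] <- mu[2]; out$mz[f] <- mu[3]
    out$magnitude[f] <- mag
    out$angle_z[f] <- if (mag > 0) acos(pmin(1, pmax(-1, mu[3] / mag))) * 180 / pi else NA_real_
  }
  attr(out, "reference") <- "center of geometry"
  class(out) <- c("DipoleSeries", "data.frame")
  out
}

#' Membrane potential profile along z
#'
#' Bins the partial charges along z (averaged over frames) into a charge
#' density profile and double-integrates the one-dimensional Poisson
#' equation with vacuum permittivity: the field and the potential are fixed
#' to zero at the lower box edge. A non-neutral system triggers a warning
#' with the residual charge.
#'
#' @param trajectory A [trajectory()] whose atoms carry partial charges
#'   (atoms with `NA` charge are an error).
#' @param slice_width Bin width, Angstrom (default 0.5).
#' @param selection Atoms to include (default all).
#' @return `"PotentialProfile"`: data frame `(z, rho, phi_mV)` on bin upper
#'   edges (`z = 0` row included, `phi = 0` there), with attribute
#'   `total_charge` (e).
#' @export
membrane_potential <- function(trajectory, slice_width = 0.5,
                               selection = seq_len(n_atoms(trajectory))) {
  idx <- selection_indices(selection, trajectory)
  q <- trajectory$atoms$charge[idx]
  if (anyNA(q)) stop("partial charges missing for ", sum(is.na(q)), " atoms")
  Lz <- trajectory$box[1, 3]
  edges <- seq(0, Lz, by = slice_width)
  if (abs(edges[length(edges)] - Lz) > 1e-9) edges <- c(edges, Lz)
  nb <- length(edges) - 1L
  nf <- n_frames(trajectory)
  qbin <- numeric(nb)
  for (f in seq_len(nf)) {
    z <- trajectory$coords[f, idx, 3] %% Lz
    b <- findInterval(z, edges, rightmost.closed = TRUE)
    b[b < 1] <- 1L; b[b > nb] <- nb
    qbin <- qbin + vapply(seq_len(nb), function(k) sum(q[b == k]), numeric(1))
  }
  qbin <- qbin / nf
  total <- sum(qbin)
  if (abs(total) > 1e-6)
    warning(sprintf("system is not charge neutral: residual %.4g e", total))
  area <- mean(trajectory$box[, 1] * trajectory$box[, 2])
  dz <- diff(edges)
  rho <- qbin / (area * dz)                       # e / A^3
  E_edge <- c(0, cumsum(rho * dz)) * .E_OVER_EPS0_A   # V/A at bin edges
  E_mid <- (E_edge[-1] + E_edge[-(nb + 1)]) / 2
  phi <- c(0, -cumsum(E_mid * dz)) * 1000         # mV at bin edges
  out <- data.frame(z = edges, rho = c(rho, NA_real_), phi_mV = phi)
  attr(out, "total_charge") <- total
  class(out) <- c("PotentialProfile", "data.frame")
  out
}

#' Angle of an interatomic vector with the z-axis
#'
#' Per-frame angle in `[0, 180]` degrees between the `atom1 -> atom2`
#' minimum-image vector and the +z axis (e.g. backbone C->O orientations of
#' pore-gating loops). Frames where the two atoms coincide are masked.
#'
#' @param trajectory A [trajectory()].
#' @param atom1,atom2 Single-atom selections or indices.
#' @return Data frame `(time, angle)`.
#' @export
bond_vector_angle <- function(trajectory, atom1, atom2) {
  i1 <- selection_indices(atom1, trajectory)
  i2 <- selection_indices(atom2, trajectory)
  if (length(i1) != 1L || length(i2) != 1L) stop("atom1 and atom2 must each select exactly one atom")
  if (i1 == i2) stop("atom1 and atom2 must be distinct")
  v <- trajectory$coords[, i2, , drop = FALSE] - trajectory$coords[, i1, , drop = FALSE]
  dim(v) <- c(n_frames(trajectory), 3)
  for (d in 1:3) v[, d] <- min_image(v[, d], trajectory$box[, d])
  nrm <- sqrt(rowSums(v^2))
  ang <- ifelse(nrm > 0, acos(pmin(1, pmax(-1, v[, 3] / nrm))) * 180 / pi, NA_real_)
  data.frame(time = trajectory$times, angle = ang)
}
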