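#' Construct a trajectory object
#'
#' The in-memory carrier for all analyses: coordinates for `n_frames` frames of
#' `n_atoms` atoms (in Angstrom), per-frame orthorhombic box lengths, frame
#' times in nanoseconds and per-atom metadata.
#'
#' @param coords Numeric array of dimension `c(n_frames, n_atoms, 3)`,
#'   coordinates in Angstrom.
#' @param box Per-frame box lengths in Angstrom: either a length-3 vector
#'   (constant box) or an `n_frames x 3` matrix.
#' @param times Frame times in ns, strictly increasing. Defaults to
#'   `0:(n_frames-1)`.
#' @param atoms Data frame of per-atom metadata with columns `name`,
#'   `resname`, `resid`, `chain` and optionally `charge` (e) and `radius`
#'   (van der Waals, Angstrom). Defaults to generic placeholders.
#' @return An object of class `"Trajectory"`: a list with elements `coords`,
#'   `box`, `times`, `atoms`.
#' @examples
#' tr <- trajectory(array(0, c(2, 3, 3)), box = c(10, 10, 10))
#' n_frames(tr); n_atoms(tr)
#' @export
trajectory <- function(coords, box, times = NULL, atoms = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("'coords' must be an n_frames x n_atoms x 3 array")
  nf <- dim(coords)[1]
  na <- dim(coords)[2]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (is.null(dim(box))) {
    if (length(box) != 3L) stop("'box' must be length 3 or an n_frames x 3 matrix")
    box <- matrix(rep(as.numeric(box), each = nf), nrow = nf)
  }
  box <- as.matrix(box)
  if (nrow(box) != nf || ncol(box) != 3L)
    stop("'box' must have one row of 3 lengths per frame")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  times <- as.numeric(times)
  if (length(times) != nf) stop("'times' must have one value per frame")
  if (nf > 1L && any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (is.null(atoms)) {
    atoms <- data.frame(name = rep("X", na), resname = rep("UNK", na),
                        resid = seq_len(na), chain = rep("A", na),
                        charge = rep(NA_real_, na), radius = rep(NA_real_, na),
                        stringsAsFactors = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) != na) stop("'atoms' must have one row per atom")
  for (col in c("name", "resname", "resid", "chain"))
    if (is.null(atoms[[col]])) stop("atom metadata lacks column '", col, "'")
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (any(atoms$resid < 0, na.rm = TRUE)) stop("residue ids must be >= 0")
  if (any(atoms$radius <= 0, na.rm = TRUE)) stop("vdW radii must be positive")
  structure(list(coords = coords, box = box, times = times, atoms = atoms),
            class = "Trajectory")
}

#' @rdname trajectory
#' @param x A `Trajectory`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname trajectory
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms, %.4g-%.4g ns\n",
              n_frames(x), n_atoms(x), x$times[1], x$times[n_frames(x)]))
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Subset trajectory frames
#'
#' @param x A `Trajectory`.
#' @param frames Integer frame indices to keep (in order).
#' @return A `Trajectory` with the chosen frames.
#' @export
subset_frames <- function(x, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(x))) stop("frame index out of range")
  trajectory(x$coords[frames, , , drop = FALSE], x$box[frames, , drop = FALSE],
             x$times[frames], x$atoms)
}

# Minimum-image displacement component-wise: d wrapped into (-L/2, L/2].
min_image <- function(d, L) d - round(d / L) * L
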