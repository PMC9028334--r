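# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures on disk.

# trajectory from a list of per-frame coordinate matrices (n_atoms x 3)
make_traj <- function(frames, box = c(20, 20, 60), atoms = NULL, times = NULL) {
  nf <- length(frames)
  na <- nrow(frames[[1]])
  co <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) co[f, , ] <- frames[[f]]
  trajectory(co, box, times = times, atoms = atoms)
}

# Hand-built permeation fixture: 3 particles, 50 frames, 4 planted crossing
# attempts (2 up, 2 down, one of the downs aborted by a radial exit
# mid-pore), plus a periodic z-wrap in a reservoir. The hand-executed state
# machine gives exactly 3 events: P1 +z (exit frame 10), P2 +z (exit frame
# 15), P1 -z (exit frame 30).
#
# Geometry: box 20 x 20 x 60, pore center (10,10), radius 4, z in [20, 40].
crossing_fixture <- function() {
  nf <- 50L
  x <- matrix(10, nf, 3); y <- matrix(10, nf, 3); z <- matrix(10, nf, 3)

  # P1: below -> above over frames 2..10 (+z), dwell, above -> below over
  # frames 20..30 (-z), then stays below.
  z[, 1] <- 10
  z[2:10, 1] <- seq(18, 42, length.out = 9)    # crosses z_lo then z_hi
  z[11:19, 1] <- 44
  z[20:30, 1] <- seq(42, 18, length.out = 11)  # back down through the pore
  z[31:50, 1] <- 12

  # P2: below -> above over frames 5..15 (+z), then stays above.
  z[1:4, 2] <- 15
  z[5:15, 2] <- seq(19, 41, length.out = 11)
  z[16:40, 2] <- 45
  # periodic wrap in the upper reservoir: 58 -> 2 across the z boundary
  z[41:45, 2] <- 58
  z[46:50, 2] <- 2

  # P3: above -> below attempt over frames 10..25 but leaves the cylinder
  # radially at mid-pore (frames 16:17), re-enters through the wall, and
  # completes the passage: the radial exit resets the attempt -> no event.
  z[1:9, 3] <- 45
  z[10:25, 3] <- seq(42, 18, length.out = 16)
  z[26:50, 3] <- 15
  x[16:17, 3] <- 16                            # lateral excursion beyond R = 4

  frames <- lapply(seq_len(nf), function(f) cbind(c(x[f, ]), c(y[f, ]), c(z[f, ])))
  list(traj = make_traj(frames, box = c(20, 20, 60)),
       geometry = pore_geometry(c(10, 10), 4, 20, 40),
       expected = data.frame(particle = c(1L, 2L, 1L),
                             exit_frame = c(10L, 15L, 30L),
                             direction = c("+z", "+z", "-z"),
                             stringsAsFactors = FALSE))
}

# uniform ideal-gas trajectory (fresh iid positions each frame)
poisson_gas_traj <- function(n_atoms, n_frames, box, seed) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f)
    cbind(runif(n_atoms, 0, box[1]), runif(n_atoms, 0, box[2]),
          runif(n_atoms, 0, box[3])))
  make_traj(frames, box = box)
}

# brute-force Pearson chi-square statistic (independent oracle)
brute_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  E <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  O <- matrix(c(a, c, b, d), 2)
  sum((O - E)^2 / E)
}
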