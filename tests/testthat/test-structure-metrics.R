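make_hbond_traj <- function(frames) {
  at <- data.frame(name = c("N", "HN", "O1", "O2"),
                   resname = c("DON", "DON", "ACC", "ACC"),
                   resid = c(1, 1, 2, 3), chain = "A")
  make_traj(frames, box = c(30, 30, 30), atoms = at)
}

test_that("hydrogen bonds respect the geometric criterion", {
  # planted 5-frame fixture; hand-enumerated expected counts
  f_bond   <- rbind(c(0, 0, 0), c(0.17, 0, 0.95), c(0, 0, 3.4), c(10, 10, 10))  # D-A 3.4, ~10 deg
  f_far    <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3.6), c(10, 10, 10))        # D-A 3.6: no bond
  f_angle  <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 3.0), c(10, 10, 10))        # angle 90: no bond
  f_two    <- rbind(c(0, 0, 0), c(0.17, 0, 0.95), c(0, 0, 3.2), c(0.8, 0, 3.0)) # both acceptors
  f_none   <- rbind(c(0, 0, 0), c(0, 0, 1), c(15, 15, 15), c(10, 10, 10))
  hb <- hydrogen_bonds(make_hbond_traj(list(f_bond, f_far, f_angle, f_two, f_none)),
                       "name N", "name O1 O2")
  expect_equal(hb$counts$count, c(1L, 0L, 0L, 2L, 0L))
  expect_equal(hb$pairs$acceptor[hb$pairs$frame == 1], 3L)
  # boundary case: exactly at the distance cutoff counts as bonded
  f_edge <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3.5), c(10, 10, 10))
  expect_equal(hydrogen_bonds(make_hbond_traj(list(f_edge)),
                              "name N", "name O1")$counts$count, 1L)
  # donor without hydrogen is excluded with a warning
  at2 <- data.frame(name = c("N", "O1"), resname = c("DON", "ACC"),
                    resid = c(1, 2), chain = "A")
  tr2 <- make_traj(list(rbind(c(0, 0, 0), c(0, 0, 3))), box = c(30, 30, 30),
                   atoms = at2)
  expect_warning(hydrogen_bonds(tr2, "name N", "name O1"), "hydrogen")
})

test_that("minimum distances use the minimum-image convention exactly", {
  co <- array(0, c(1, 2, 3)); co[1, 2, 3] <- 5
  tr <- make_traj(list(co[1, , ]), box = c(100, 100, 100))
  expect_equal(min_distance(tr, 1, 2)$distance, 5)
  # identical groups: zero
  expect_equal(min_distance(tr, c(1, 2), c(1, 2))$distance, 0)
  # across the periodic boundary: z = 1 vs z = 99 in a 100 A box -> 2 A
  co2 <- rbind(c(0, 0, 1), c(0, 0, 99))
  tr2 <- make_traj(list(co2), box = c(100, 100, 100))
  expect_equal(min_distance(tr2, 1, 2)$distance, 2)
  # invariance under rigid translation modulo the box
  co3 <- co2 + 40
  tr3 <- make_traj(list(co3), box = c(100, 100, 100))
  expect_equal(min_distance(tr3, 1, 2)$distance, 2)
})

test_that("simplified pore radius is the slice-wise inscribed radius", {
  # single atom of vdW radius 1.5 at lateral distance 4 -> slice radius 2.5
  at <- data.frame(name = "C", resname = "PRO", resid = 1, chain = "A",
                   charge = 0, radius = 1.5)
  tr <- make_traj(list(matrix(c(14, 10, 25), 1, 3)), box = c(20, 20, 60),
                  atoms = at)
  geom <- pore_geometry(c(10, 10), 4, 20, 30)
  pr <- pore_radius_profile(tr, "all", geom, slice_width = 10)
  expect_equal(pr$radius, 2.5)
  # ring of 8 atoms at lateral 6 with vdW 1.4 -> uniform 4.6
  th <- (0:7) * pi / 4
  ring <- cbind(10 + 6 * cos(th), 10 + 6 * sin(th), 25)
  at8 <- data.frame(name = "C", resname = "PRO", resid = 1:8, chain = "A",
                    charge = 0, radius = 1.4)
  tr8 <- make_traj(list(ring), box = c(20, 20, 60), atoms = at8)
  expect_equal(pore_radius_profile(tr8, "all", geom, slice_width = 10)$radius, 4.6)
  # empty slice is masked; empty selection masks everything
  pr2 <- pore_radius_profile(tr, "all", pore_geometry(c(10, 10), 4, 20, 40),
                             slice_width = 10)
  expect_true(is.na(pr2$radius[2]))
  expect_message(prm <- pore_radius_profile(tr, "resname XXX", geom, 10))
  expect_true(all(is.na(prm$radius)))
})

test_that("rdf normalization: fixed pair, ideal gas and integral audit", {
  # single reference + single target at fixed 5 A: one nonzero bin at 5 A
  co <- rbind(c(15, 15, 15), c(15, 15, 20))
  tr <- make_traj(list(co), box = c(40, 40, 40))
  g <- rdf(tr, 1, 2, r_max = 10, bin_width = 0.5)
  nz <- which(g$g > 0)
  expect_length(nz, 1)
  expect_true(g$r_lo[nz] <= 5 && g$r_hi[nz] >= 5)
  # r_max beyond half the box is rejected
  expect_error(rdf(tr, 1, 2, r_max = 25), "half the smallest box")
  # Poisson gas: g -> 1, and the integral recovers the target count
  trg <- poisson_gas_traj(200, 60, box = c(20, 20, 20), seed = 12)
  gg <- rdf(trg, 1:100, 101:200, r_max = 8, bin_width = 1)
  expect_lt(max(abs(gg$g[gg$r_mid > 2] - 1)), 0.1)
  shell <- 4 / 3 * pi * (gg$r_hi^3 - gg$r_lo^3)
  n_in_sphere <- sum(gg$g * shell) * 100 / 8000
  expect_equal(n_in_sphere, 100 * (4 / 3 * pi * 8^3) / 8000, tolerance = 0.05)
})

test_that("dipole moment converts e*A to Debye and transforms covariantly", {
  at <- data.frame(name = c("A", "B"), resname = "X", resid = 1, chain = "A",
                   charge = c(-1, 1))
  co <- rbind(c(0, 0, 0), c(0, 0, 1))
  tr <- make_traj(list(co), box = c(20, 20, 20), atoms = at)
  dm <- dipole_moment(tr, "all")
  expect_equal(dm$magnitude, 4.803204, tolerance = 1e-6)
  expect_equal(dm$angle_z, 0)
  # rotating 90 degrees about x maps the angle 0 -> 90
  co_rot <- co[, c(1, 3, 2)]; co_rot[, 3] <- -co_rot[, 3]
  dm_rot <- dipole_moment(make_traj(list(co_rot), box = c(20, 20, 20), atoms = at), "all")
  expect_equal(dm_rot$angle_z, 90)
  expect_equal(dm_rot$magnitude, dm$magnitude)
  # net-zero charges at one point: zero dipole
  at0 <- data.frame(name = c("A", "B"), resname = "X", resid = 1, chain = "A",
                    charge = c(-1, 1))
  tr0 <- make_traj(list(rbind(c(3, 3, 3), c(3, 3, 3))), box = c(20, 20, 20), atoms = at0)
  expect_equal(dipole_moment(tr0, "all")$magnitude, 0)
  # missing charges are an error listing atoms
  atna <- data.frame(name = "A", resname = "X", resid = 1, chain = "A",
                     charge = NA_real_)
  expect_error(dipole_moment(make_traj(list(matrix(0, 1, 3)), atoms = atna), "all"),
               "charges missing")
})

test_that("membrane potential integrates Poisson with the stated conventions", {
  # zero charges -> identically zero potential
  at0 <- data.frame(name = "Q", resname = "S", resid = 1:4, chain = "A",
                    charge = 0)
  tr0 <- make_traj(list(matrix(30, 4, 3)), box = c(40, 40, 120), atoms = at0)
  expect_true(all(membrane_potential(tr0)$phi_mV == 0))
  # two-sheet slab: plateau difference equals sigma*d/eps0 within 1%
  slab <- generate_charge_slab(2e-6, separation = 40, box = c(40, 40, 120))
  pot <- membrane_potential(slab$trajectory, slice_width = 0.25)
  dv <- abs(mean(pot$phi_mV[pot$z > 90]) - mean(pot$phi_mV[pot$z < 30]))
  expect_equal(dv, slab$delta_v_mV, tolerance = 0.01)
  # linearity: flipping all charge signs negates the potential
  tr_flip <- slab$trajectory
  tr_flip$atoms$charge <- -tr_flip$atoms$charge
  pot_f <- membrane_potential(tr_flip, slice_width = 0.25)
  expect_equal(pot_f$phi_mV, -pot$phi_mV)
  # non-neutral systems warn with the residual
  tr_nn <- slab$trajectory
  tr_nn$atoms$charge[1] <- tr_nn$atoms$charge[1] + 0.5
  expect_warning(membrane_potential(tr_nn), "not charge neutral")
})

test_that("bond vector angles cover the axis-aligned reference cases", {
  at <- data.frame(name = c("C", "O"), resname = "ALA", resid = 117, chain = "A")
  mk <- function(v) make_traj(list(rbind(c(5, 5, 5), c(5, 5, 5) + v)),
                              box = c(20, 20, 20), atoms = at)
  expect_equal(bond_vector_angle(mk(c(0, 0, 1)), 1, 2)$angle, 0)
  expect_equal(bond_vector_angle(mk(c(1, 0, 0)), 1, 2)$angle, 90)
  expect_equal(bond_vector_angle(mk(c(0, 0, -1)), 1, 2)$angle, 180)
  # coincident atoms: masked frame
  expect_true(is.na(bond_vector_angle(mk(c(0, 0, 0)), 1, 2)$angle))
  expect_error(bond_vector_angle(mk(c(0, 0, 1)), 1, 1), "distinct")
})
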