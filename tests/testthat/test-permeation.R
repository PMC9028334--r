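test_that("hand-built fixture reproduces the hand-executed state machine", {
  fx <- crossing_fixture()
  ev <- count_crossings(fx$traj, "all", fx$geometry)
  expect_equal(nrow(ev$events), 3)
  expect_equal(ev$events$particle, fx$expected$particle)
  expect_equal(ev$events$exit_frame, fx$expected$exit_frame)
  expect_equal(ev$events$direction, fx$expected$direction)
  expect_true(all(ev$events$exit_frame > ev$events$entry_frame))
  expect_true(all(diff(ev$cumulative$count) >= 0))
  # slab rule (radius ignored) also counts the radial-excursion passage
  ev2 <- count_crossings(fx$traj, "all", fx$geometry, radial = FALSE)
  expect_equal(nrow(ev2$events), 4)
})

test_that("simple monotone and oscillating paths count as specified", {
  # monotone -20 -> +20 A through a 30 A cylinder: one +z event
  z <- seq(10, 50, length.out = 21)
  frames <- lapply(z, function(zz) matrix(c(10, 10, zz), 1, 3))
  tr <- make_traj(frames, box = c(20, 20, 60))
  geom <- pore_geometry(c(10, 10), 4, 15, 45)
  ev <- count_crossings(tr, 1, geom)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$direction, "+z")
  # oscillation across z_lo without reaching z_hi: 0 events
  zo <- rep(c(12, 25), 10)
  tro <- make_traj(lapply(zo, function(zz) matrix(c(10, 10, zz), 1, 3)),
                   box = c(20, 20, 60))
  expect_equal(nrow(count_crossings(tro, 1, geom)$events), 0)
})

test_that("counting is invariant to rigid translation and time rebasing", {
  fx <- crossing_fixture()
  ev <- count_crossings(fx$traj, "all", fx$geometry)
  shift <- c(2.5, -1.5, 0)
  co <- fx$traj$coords
  for (d in 1:3) co[, , d] <- co[, , d] + shift[d]
  trs <- trajectory(co, fx$traj$box, fx$traj$times, fx$traj$atoms)
  geoms <- pore_geometry(fx$geometry$center + shift[1:2], fx$geometry$radius,
                         fx$geometry$z_lo, fx$geometry$z_hi)
  evs <- count_crossings(trs, "all", geoms)
  expect_equal(evs$events$exit_frame, ev$events$exit_frame)
  trt <- trajectory(fx$traj$coords, fx$traj$box, fx$traj$times * 2 + 5,
                    fx$traj$atoms)
  evt <- count_crossings(trt, "all", fx$geometry)
  expect_equal(evt$events$direction, ev$events$direction)
})

test_that("block bookkeeping matches direct binning and drops partial blocks", {
  et <- c(0.5, 3.2, 9.99, 10.01, 15, 29.5, 31, 47)
  ev <- permeation_events(et, total_time = 48)
  expect_message(wb <- water_count_per_block(ev, 10), "partial block")
  expect_equal(nrow(wb), 4)
  oracle <- hist(et[et <= 40], breaks = seq(0, 40, 10), plot = FALSE)$counts
  expect_equal(wb$count, oracle)
  expect_equal(sum(wb$count), sum(et <= 40))
  # no events: all-zero table
  wb0 <- water_count_per_block(permeation_events(numeric(0), 50), 10)
  expect_equal(wb0$count, rep(0L, 5))
})

test_that("collective coordinate equals the naive double-loop oracle", {
  set.seed(41)
  nf <- 30; np <- 10
  box <- c(20, 20, 60)
  frames <- lapply(seq_len(nf), function(f)
    cbind(runif(np, 8, 12), runif(np, 8, 12), runif(np, 10, 50)))
  tr <- make_traj(frames, box = box)
  geom <- pore_geometry(c(10, 10), 4, 20, 40)
  cs <- collective_coordinate(tr, "all", geom)
  # naive oracle: per frame pair, recompute membership and summed dz/L
  inside <- function(p) {
    dx <- p[, 1] - 10; dy <- p[, 2] - 10
    dx^2 + dy^2 <= 16 & p[, 3] >= 20 & p[, 3] <= 40
  }
  n_oracle <- 0
  for (f in 2:nf) {
    both <- inside(frames[[f]]) & inside(frames[[f - 1]])
    dz <- frames[[f]][both, 3] - frames[[f - 1]][both, 3]
    dz <- dz - round(dz / box[3]) * box[3]
    n_oracle <- c(n_oracle, sum(dz) / 20)
  }
  expect_equal(cs$n, cumsum(n_oracle))
  # one particle traversing the full section contributes +-1
  z <- seq(19, 41, length.out = 40)
  tr1 <- make_traj(lapply(z, function(zz) matrix(c(10, 10, zz), 1, 3)),
                   box = box)
  cs1 <- collective_coordinate(tr1, 1, geom)
  expect_equal(cs1$n[40], 1, tolerance = 0.1)  # full traversal: total dn = +1
  # static frames: n identically zero
  trs <- make_traj(rep(list(matrix(c(10, 10, 30), 1, 3)), 5), box = box)
  expect_equal(collective_coordinate(trs, 1, geom)$n, rep(0, 5))
})

test_that("pf follows pf = v_w * Dn and degenerate inputs behave", {
  gen <- generate_collective_series(1, 1e5, 1e-3, seed = 2)
  res <- pf_from_collective(gen, v_w = 2.989e-23)
  expect_equal(res$pf, 2.989e-14, tolerance = 0.06)
  # doubling v_w doubles pf
  res2 <- pf_from_collective(gen, v_w = 2 * 2.989e-23)
  expect_equal(res2$pf, 2 * res$pf)
  # constant series: pf = 0
  const <- generate_collective_series(0, 1000, seed = 1)
  expect_equal(pf_from_collective(const)$pf, 0)
  # linear scaling across a 10x Dn sweep (log-log slope 1)
  dns <- c(0.3, 3)
  med <- vapply(dns, function(D) {
    median(vapply(1:8, function(s)
      pf_from_collective(generate_collective_series(D, 2e4, 1e-3, seed = s))$Dn,
      numeric(1)))
  }, numeric(1))
  slope <- diff(log(med)) / diff(log(dns))
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("Dk correction follows the Boltzmann barrier form", {
  gen <- generate_collective_series(1, 2e4, 1e-3, seed = 3)
  res <- pf_from_collective(gen)
  kT <- gas_constant_kcal() * 310.15
  # flat profile leaves pf unchanged
  flat <- fe_profile(seq(15, 45, 0.5), rep(0, 61))
  rflat <- apply_dk(res, flat)
  expect_equal(rflat$Dk, 1)
  expect_equal(rflat$pf_corrected, res$pf)
  # barrier of exactly kT scales pf by 1/e
  one_kt <- fe_profile(seq(15, 45, 0.5), c(rep(0, 30), kT, rep(0, 30)))
  r1 <- apply_dk(res, one_kt)
  expect_equal(r1$Dk, exp(-1))
  expect_equal(r1$pf_corrected, res$pf / exp(1))
  # independent scalar oracle: 3 kcal/mol at 310.15 K
  r3 <- apply_dk(res, fe_profile(seq(15, 45, 0.5), c(rep(0, 30), 3, rep(0, 30))))
  expect_equal(r3$Dk, exp(-3 / 0.61633), tolerance = 1e-4)
  # monotone decreasing in barrier height
  dks <- vapply(seq(0, 5, 0.5), function(h)
    apply_dk(res, fe_profile(seq(15, 45, 0.5), c(rep(0, 30), h, rep(0, 30))))$Dk,
    numeric(1))
  expect_true(all(diff(dks) < 0 | dks[-1] == 1))
  expect_true(all(dks > 0 & dks <= 1))
  # masked slices inside the section are an explicit error
  holed <- fe_profile(seq(15, 45, 0.5), c(rep(0, 30), NA, rep(0, 30)))
  expect_error(apply_dk(res, holed), "undefined")
})
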