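params <- dpd_params()

test_that("conservative pair force follows the linear soft repulsion", {
  # A-A at r = 0.5: magnitude A_ij (1 - r/r_c) = 106.5 * 0.5
  f <- compute_forces(make_pair(0.5), ff_matrix, params, thermostat = FALSE)
  expect_equal(f$conservative[1, ], c(-53.25, 0, 0))
  expect_equal(f$conservative[2, ], c(53.25, 0, 0))
  # beyond the cutoff all pair forces vanish identically
  f2 <- compute_forces(make_pair(1.2), ff_matrix, params)
  for (part in c("conservative", "dissipative", "random"))
    expect_equal(f2[[part]], matrix(0, 2, 3))
  # exactly at the cutoff
  f3 <- compute_forces(make_pair(1.0), ff_matrix, params)
  expect_equal(f3$total, matrix(0, 2, 3))
})

test_that("dissipative force is proportional to the radial relative velocity", {
  # static pair: no drag
  f <- compute_forces(make_pair(0.5), ff_matrix, params)
  expect_equal(f$dissipative, matrix(0, 2, 3))
  # approaching pair at r: F^D = -gamma (1 - r)^2 (e.v_ij) e
  v <- rbind(c(1, 0, 0), c(-1, 0, 0))
  st <- make_pair(0.5, velocities = v)
  fd <- compute_forces(st, ff_matrix, params)$dissipative
  expect_equal(fd[1, 1], -4.5 * 0.25 * 2, tolerance = 1e-12)
  expect_equal(fd[2, 1], +4.5 * 0.25 * 2, tolerance = 1e-12)
  # quadratic switching: same velocities at r = 0.75 give 1/4 the drag
  fd2 <- compute_forces(make_pair(0.75, velocities = v), ff_matrix,
                        params)$dissipative
  expect_equal(fd[1, 1] / fd2[1, 1], 4, tolerance = 1e-12)
})

test_that("random force uses the linear switching function and a shared variate", {
  # same seed => same zeta; magnitudes then scale as w_R = (1 - r)
  fr1 <- compute_forces(make_pair(0.5), ff_matrix, params, seed = 99)$random
  fr2 <- compute_forces(make_pair(0.75), ff_matrix, params, seed = 99)$random
  expect_equal(sqrt(sum(fr1[1, ]^2)) / sqrt(sum(fr2[1, ]^2)), 2,
               tolerance = 1e-12)
  # antisymmetric on the pair (momentum conservation)
  expect_equal(fr1[1, ], -fr1[2, ])
  # dt^(-1/2) scaling
  p2 <- dpd_params(dt = 0.02 * 4)
  fr3 <- compute_forces(make_pair(0.5), ff_matrix, p2, seed = 99)$random
  expect_equal(sqrt(sum(fr1[1, ]^2)) / sqrt(sum(fr3[1, ]^2)), 2,
               tolerance = 1e-12)
})

test_that("overlapping beads get a finite kick of magnitude A_ij", {
  st <- dpd_state(rbind(c(2, 2, 2), c(2, 2, 2)), c("A", "A"), c(6, 6, 6))
  f <- compute_forces(st, ff_matrix, params, seed = 5)
  mag <- sqrt(sum(f$conservative[1, ]^2))
  expect_equal(mag, 106.5, tolerance = 1e-10)
  expect_equal(f$conservative[1, ], -f$conservative[2, ])
})

test_that("harmonic bonds restore the equilibrium length", {
  bond <- rbind(c(1L, 2L))
  # at r_eq: zero force
  f0 <- compute_forces(make_pair(0.45, bonds = bond), ff_matrix, params,
                       thermostat = FALSE)
  expect_equal(f0$bond, matrix(0, 2, 3), tolerance = 1e-12)
  # stretched by 0.10: magnitude kappa * 0.10 = 7.5, attractive
  f1 <- compute_forces(make_pair(0.55, bonds = bond), ff_matrix, params,
                       thermostat = FALSE)
  expect_equal(f1$bond[1, 1], 7.5, tolerance = 1e-10)
  # compressed by 0.10: same magnitude, repulsive (symmetry about r_eq)
  f2 <- compute_forces(make_pair(0.35, bonds = bond), ff_matrix, params,
                       thermostat = FALSE)
  expect_equal(f2$bond[1, 1], -7.5, tolerance = 1e-10)
  expect_equal(f1$bond[1, ], -f1$bond[2, ])
})

test_that("over-stretched bonds trigger the minimum-image hard error", {
  # walled box: x is not minimum-imaged, so the bond length can exceed
  # half the smallest edge
  st <- dpd_state(rbind(c(1, 3, 3), c(5.5, 3, 3)), c("A", "A"), c(10, 6, 6),
                  bonds = rbind(c(1L, 2L)), boundary = "walled_x")
  expect_error(compute_forces(st, ff_matrix, params), "minimum-image")
})

test_that("wall repulsion is quadratic in range and zero beyond", {
  p <- dpd_params()
  mk <- function(x) {
    st <- dpd_state(rbind(c(x, 3, 3), c(5, 3, 3)), c("W", "W"), c(10, 6, 6),
                    boundary = "walled_x")
    compute_forces(st, ff_matrix, p)$wall
  }
  # at z = z_c: edge of the range, zero force
  expect_equal(mk(1.0)[1, ], c(0, 0, 0))
  # at z = z_c / 2: magnitude 2 A_wall (1 - 1/2) / z_c = A_wall
  expect_equal(mk(0.5)[1, 1], 106.5, tolerance = 1e-12)
  # mid-box: zero
  expect_equal(mk(5)[1, ], c(0, 0, 0))
  # near the upper wall the force points inward (-x)
  expect_equal(mk(9.5)[1, 1], -106.5, tolerance = 1e-12)
})

test_that("force-free beads translate uniformly and wrap periodically", {
  st <- dpd_state(rbind(c(1, 1, 1), c(4, 4, 4)), c("W", "W"), c(5, 5, 5),
                  velocities = rbind(c(1, 0, 0), c(0, 2.5, 0)))
  # beads far apart: no interactions; switch thermostat off
  traj <- run_dpd(st, ff_matrix, dpd_params(), steps = 100, seed = 1,
                  thermostat = FALSE)
  expect_equal(traj$state$positions[1, 1], (1 + 0.02 * 100 * 1) %% 5,
               tolerance = 1e-10)
  expect_equal(traj$state$positions[2, 2], (4 + 0.02 * 100 * 2.5) %% 5,
               tolerance = 1e-10)
})

test_that("a bonded dimer without thermostat conserves energy (symplectic check)", {
  # isolate the harmonic bond: negligible soft repulsion
  tiny <- default_interaction_table()
  tiny[] <- 1e-10
  mt <- suppressWarnings(build_interaction_matrix(tiny))
  st <- dpd_state(rbind(c(3, 3, 3), c(3.55, 3, 3)), c("A", "A"), c(6, 6, 6),
                  bonds = rbind(c(1L, 2L)))
  energy <- function(s) {
    r <- sqrt(sum((s$positions[1, ] - s$positions[2, ])^2))
    0.5 * sum(s$velocities^2) + 0.5 * 75 * (r - 0.45)^2
  }
  traj <- run_dpd(st, mt, dpd_params(), steps = 2000, stride = 1,
                  seed = 1, thermostat = FALSE)
  e <- vapply(seq_len(n_snapshots(traj)), function(i)
    energy(get_snapshot(traj, i)), 1.0)
  # velocity-Verlet: energy oscillates within O((w dt)^2) of E but shows no
  # secular drift; phase-averaged halves agree to < 1e-4 per 10^3 steps
  expect_lt(max(abs(e - e[1])) / e[1], 0.02)
  drift <- abs(mean(e[1002:2001]) - mean(e[2:1001])) / mean(e)
  expect_lt(drift, 1e-4)
  # and it oscillates about r_eq rather than collapsing or flying apart
  r_final <- sqrt(sum((traj$state$positions[1, ] -
                         traj$state$positions[2, ])^2))
  expect_gt(r_final, 0.3)
  expect_lt(r_final, 0.7)
})

test_that("total momentum is conserved in a periodic wall-free run", {
  st <- thermalize(make_fluid(L = 5, seed = 3), kT = 1, seed = 4)
  p0 <- total_momentum(st)
  traj <- run_dpd(st, ff_matrix, dpd_params(), steps = 500, seed = 9)
  drift <- apply(abs(traj$momentum - matrix(p0, nrow(traj$momentum), 3,
                                            byrow = TRUE)), 1, max)
  expect_lt(max(drift) / 500, 1e-10)
})

test_that("the thermostat holds kinetic temperature at 1 within 2%", {
  st <- thermalize(make_fluid(L = 7, seed = 5), kT = 1, seed = 6)
  traj <- run_dpd(st, ff_matrix, dpd_params(), steps = 1500, seed = 10)
  t_eq <- mean(tail(traj$temperature, 700))
  expect_equal(t_eq, 1.0, tolerance = 0.02)
})

test_that("identical seeds give bit-identical trajectories", {
  st <- thermalize(make_fluid(L = 5, seed = 1), kT = 1, seed = 2)
  t1 <- run_dpd(st, ff_matrix, dpd_params(), steps = 200, stride = 50, seed = 77)
  t2 <- run_dpd(st, ff_matrix, dpd_params(), steps = 200, stride = 50, seed = 77)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$state$velocities, t2$state$velocities)
  t3 <- run_dpd(st, ff_matrix, dpd_params(), steps = 200, stride = 50, seed = 78)
  expect_false(identical(t1$state$positions, t3$state$positions))
})

test_that("zero-step runs return the initial state only", {
  st <- make_fluid(L = 5)
  traj <- run_dpd(st, ff_matrix, dpd_params(), steps = 0)
  expect_equal(n_snapshots(traj), 1)
  expect_identical(traj$snapshots[[1]], st$positions)
})

test_that("measure_temperature implements equipartition", {
  st <- make_fluid(L = 5)
  st$velocities <- matrix(0, nrow(st$positions), 3)
  expect_equal(measure_temperature(st), 0)
  st2 <- thermalize(st, kT = 1, seed = 11)
  expect_equal(measure_temperature(st2), 1.0, tolerance = 0.05)
  st$frozen[] <- TRUE
  expect_error(measure_temperature(st), "fewer than 2 free beads")
})

test_that("frozen beads never move and keep zero velocity", {
  st <- thermalize(make_fluid(L = 5, seed = 8), kT = 1, seed = 9)
  st$frozen[1:30] <- TRUE
  st$velocities[1:30, ] <- 0
  traj <- run_dpd(st, ff_matrix, dpd_params(), steps = 300, seed = 12)
  expect_identical(traj$state$positions[1:30, ], st$positions[1:30, ])
  expect_identical(traj$state$velocities[1:30, ], matrix(0, 30, 3))
})
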