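test_that("pairwise kernels reproduce their closed forms", {
  two <- function(r) point_system(rbind(c(0, 0, 0), c(r, 0, 0)),
                                  charge = 1, sigma = 0.3, epsilon = 0.5)
  expect_equal(coulomb_energy(two(1), 1, 2), 138.935458, tolerance = 1e-9)
  expect_equal(lj_energy(two(0.3), 1, 2), 0, tolerance = 1e-9)
  expect_equal(lj_energy(two(2^(1/6) * 0.3), 1, 2), -0.5, tolerance = 1e-9)
  zero_q <- two(1); zero_q$atoms$charge[1] <- 0
  expect_equal(coulomb_energy(zero_q, 1, 2), 0)
  expect_error(lj_energy(two(0), 1, 2), "singularity")
  expect_error(coulomb_energy(two(0), 1, 2), "singularity")
})

test_that("energy kernels equal double-loop oracles and are rigid-invariant", {
  set.seed(91)
  n <- 100
  xyz <- matrix(runif(3 * n, 0, 2), ncol = 3)
  sys <- point_system(xyz, charge = runif(n, -0.5, 0.5),
                      sigma = runif(n, 0.25, 0.4),
                      epsilon = runif(n, 0.1, 0.9))
  iA <- 1:50; iB <- 51:100
  lj <- lj_energy(sys, iA, iB)
  cl <- coulomb_energy(sys, iA, iB)
  expect_equal(lj, oracle_lj(xyz, iA, iB, sys$atoms$sigma,
                             sys$atoms$epsilon), tolerance = 1e-10)
  expect_equal(cl, oracle_coulomb(xyz, iA, iB, sys$atoms$charge),
               tolerance = 1e-10)
  xyz2 <- sweep(xyz %*% t(rotation_matrix(c(1, 3, -2), 40)), 2,
                c(5, -2, 1), "+")
  expect_equal(lj_energy(sys, iA, iB, frame = xyz2), lj, tolerance = 1e-9)
  expect_equal(coulomb_energy(sys, iA, iB, frame = xyz2), cl,
               tolerance = 1e-9)
})

born_system <- function(radius = 0.2, q = 1) {
  sys <- point_system(matrix(0, 1, 3), charge = q,
                      sigma = 2 * radius / 2^(1/6), epsilon = 0.1)
  sys
}

test_that("the PB solver reproduces the Born ion and refines monotonically", {
  exact <- -(138.935458 / 2) * (1 - 1 / 78.4) / 0.2
  errs <- vapply(c(0.1, 0.05, 0.025), function(h) {
    g <- solve_pb(born_system(), config = pb_config(h, eps_in = 1,
                                                    eps_out = 78.4))
    abs(g - exact) / abs(exact)
  }, numeric(1))
  expect_lt(errs[2], 0.03)
  expect_true(all(diff(errs) < 0))
  ## zero charge: exactly zero; equal dielectrics: zero
  expect_equal(solve_pb(born_system(q = 0),
                        config = pb_config(0.1, eps_in = 2, eps_out = 78.4)),
               0)
  expect_equal(solve_pb(born_system(),
                        config = pb_config(0.1, eps_in = 4, eps_out = 4)), 0)
})

test_that("PB reaction field is negative and strengthens with eps_out", {
  g20 <- solve_pb(born_system(), config = pb_config(0.1, eps_in = 1,
                                                    eps_out = 20))
  g80 <- solve_pb(born_system(), config = pb_config(0.1, eps_in = 1,
                                                    eps_out = 80))
  expect_lt(g80, 0)
  expect_lt(g20, 0)
  expect_gt(abs(g80), abs(g20))
  ## physiological screening adds a further (small) favourable term
  gsalt <- solve_pb(born_system(), config = pb_config(0.1, eps_in = 1,
                                                      eps_out = 80,
                                                      ionic_strength = 0.154))
  expect_lt(gsalt, g80)
  expect_error(pb_config(margin = 0.2), "configuration error")
  expect_error(pb_config(eps_in = 80, eps_out = 2), "configuration error")
})

test_that("SASA matches sphere closed forms, additivity and burial", {
  f1 <- matrix(0, 1, 3)
  s1 <- sasa(f1, 1, radii = 0.2)
  expect_equal(s1$total, 4 * pi * 0.34^2, tolerance = 0.01)
  ## two far-separated spheres are additive
  f2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(sasa(f2, 1:2, radii = c(0.2, 0.2))$total, 2 * s1$total,
               tolerance = 0.01)
  ## a small sphere inside a large one is fully buried
  f3 <- rbind(c(0, 0, 0), c(0.05, 0, 0))
  expect_equal(sasa(f3, 1:2, radii = c(0.5, 0.05))$area[2], 0)
  expect_error(sasa(f1, 1, radii = -0.1), "parameter error")
  ## monotonicity: adding an atom never increases another atom's area
  set.seed(101)
  cl <- matrix(rnorm(30, sd = 0.3), ncol = 3)
  r <- rep(0.17, 11)
  base <- sasa(cl, 1:10, radii = r)$area
  grown <- sasa(rbind(cl, c(0.1, 0.1, 0.1)), 1:11, radii = r)$area
  expect_true(all(grown[1:10] <= base + 1e-12))
})

test_that("binding free energy vanishes for inert, distant groups", {
  xyz <- rbind(matrix(runif(9, 0, 0.5), ncol = 3),
               matrix(runif(9, 5, 5.5), ncol = 3))
  sys <- point_system(xyz, charge = 0, sigma = 0.3, epsilon = 0)
  traj <- trajectory(sys, list(xyz, xyz, xyz))
  dec <- binding_free_energy(traj, 1:3, 4:6,
                             pb = pb_config(0.1),
                             sasa_cfg = sasa_config(n_sphere_points = 96))
  s <- dec$summary
  expect_equal(s$mean[s$term == "E_vdW"], 0)
  expect_equal(s$mean[s$term == "ddG_pol"], 0)
  expect_equal(s$mean[s$term == "dG_bind"], 0, tolerance = 1e-9)
})

test_that("toy-dimer decomposition equals independently composed terms", {
  set.seed(111)
  xyz <- rbind(matrix(runif(12, 0, 0.6), ncol = 3),
               matrix(runif(9, 0.8, 1.3), ncol = 3))
  sys <- point_system(xyz, charge = c(0.4, -0.3, 0.2, -0.3, 0.5, -0.2, 0.2),
                      sigma = 0.32, epsilon = 0.4)
  traj <- trajectory(sys, list(xyz))
  pbc <- pb_config(0.1)
  sc <- sasa_config(n_sphere_points = 192)
  dec <- binding_free_energy(traj, 1:4, 5:7, pb = pbc, sasa_cfg = sc,
                             frame_window = 1)
  pf <- dec$per_frame
  ## per-term oracles composed by hand
  expect_equal(pf$E_vdW, oracle_lj(xyz, 1:4, 5:7, sys$atoms$sigma,
                                   sys$atoms$epsilon), tolerance = 1e-10)
  expect_equal(pf$E_coul, oracle_coulomb(xyz, 1:4, 5:7, sys$atoms$charge),
               tolerance = 1e-10)
  gp <- vapply(list(1:7, 1:4, 5:7), function(sel)
    solve_pb(sys, sel, config = pbc), numeric(1))
  expect_equal(pf$ddG_pol, gp[1] - gp[2] - gp[3], tolerance = 1e-9)
  radii <- 2^(1/6) * sys$atoms$sigma / 2
  ar <- vapply(list(1:7, 1:4, 5:7), function(sel)
    sasa(xyz, sel, radii, config = sc)$total, numeric(1))
  expect_equal(pf$ddG_nonpol,
               sasa_nonpolar(ar[1], sc) - sasa_nonpolar(ar[2], sc) -
                 sasa_nonpolar(ar[3], sc), tolerance = 1e-9)
  ## thermodynamic-cycle identity holds exactly per frame
  expect_equal(pf$dG_bind,
               pf$E_intra + pf$E_vdW + pf$E_coul + pf$ddG_pol + pf$ddG_nonpol,
               tolerance = 1e-12)
  expect_true(all(pf$E_intra == 0))
  expect_error(binding_free_energy(traj, 1:4, 4:7), "selection error")
})
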