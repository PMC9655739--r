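test_that("cylindrical shells bin single atoms and conserve counts", {
  sys <- point_system(rbind(c(0.55, 0, 0), c(1.23, 0, 3)), box = 6)
  traj <- trajectory(sys, list(coords(sys)))
  cp <- cylindrical_density(traj, 1:2, bin_width = 0.1, shell_length = 4.1)
  expect_equal(cp$counts[cp$bin_edges[-length(cp$bin_edges)] == 0.5], 1)
  ## the second atom sits outside the axial slab and is excluded
  expect_equal(sum(cp$counts), 1)
  ## conservation over a random cloud fully inside the slab
  set.seed(8)
  cloud <- point_system(cbind(matrix(runif(40, -1, 1), ncol = 2),
                              runif(20, -2, 2)), box = 8)
  tr2 <- trajectory(cloud, list(coords(cloud)))
  cp2 <- cylindrical_density(tr2, 1:20, bin_width = 0.1, shell_length = 4.1)
  expect_equal(sum(cp2$counts), 20)
  expect_true(all(cp2$values >= 0))
  ## density definition: counts / shell volume
  vols <- pi * (cp2$bin_edges[-1]^2 -
                  cp2$bin_edges[-length(cp2$bin_edges)]^2) * 4.1
  expect_equal(cp2$values, cp2$counts / vols)
  expect_error(cylindrical_density(tr2, integer(0)), "empty-input")
})

test_that("RDF resolves fixed pair distances and rejects bad ranges", {
  sys <- point_system(rbind(c(0, 0, 0), c(0.32, 0, 0)), box = 4)
  traj <- trajectory(sys, list(coords(sys)))
  r <- rdf(traj, 1, 2, dr = 0.02, r_max = 1)
  nz <- which(r$counts > 0)
  expect_length(nz, 1L)
  expect_equal(r$bin_mid[nz], 0.33, tolerance = 0.011)
  expect_error(rdf(traj, 1, 2, dr = 0.02, r_max = 3), "range error")
  expect_error(rdf(traj, 1, 1, dr = 0.02), "no pairs")
})

test_that("ideal-gas RDF converges to one", {
  ig <- ideal_gas_frames(4, 300, 60, seed = 13)
  r <- rdf(ig, 1:150, 151:300, dr = 0.1, r_max = 2)
  ## Poisson band per bin from the expected pair count
  expected <- r$normalization * 60     # pairs accumulated over all frames
  sig <- sqrt(expected) / expected
  keep <- r$bin_mid > 0.1
  expect_true(all(abs(r$g[keep] - 1) < 3.5 * sig[keep]))
})

test_that("COM-sidewall distance is signed arithmetic on the radial COM", {
  sys <- point_system(rbind(c(1.1915, 0, 0)), mass = 10)
  traj <- trajectory(sys, list(coords(sys)))
  d <- com_sidewall_distance(traj, 1, cnt_radius = 0.3915)
  expect_equal(d$mean, 0.8)
  sys2 <- point_system(rbind(c(0.3915, 0, 0)))
  expect_equal(com_sidewall_distance(trajectory(sys2, list(coords(sys2))),
                                     1, cnt_radius = 0.3915)$mean, 0)
  ## zero-mass selection is an error
  sys3 <- point_system(rbind(c(1, 0, 0)), mass = 0)
  expect_error(com_sidewall_distance(trajectory(sys3, list(coords(sys3))),
                                     1, cnt_radius = 0.39), "invalid-mass")
})

test_that("gyration matches the closed form, the oracle and its identity", {
  f <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0))
  g <- gyration(f, 1:2)
  expect_equal(unname(g), c(0.5, 0.5, 0, 0))
  ## brute-force pair-distance oracle on a random cloud
  set.seed(21)
  p <- matrix(rnorm(300), ncol = 3)
  m <- runif(100, 1, 16)
  g2 <- gyration(p, 1:100, masses = c(m))
  expect_equal(g2[["Rg"]], oracle_rg(p, m), tolerance = 1e-12)
  ## decomposition identity to machine precision
  expect_equal(g2[["Rg"]]^2,
               g2[["Rg_x"]]^2 + g2[["Rg_y"]]^2 + g2[["Rg_z"]]^2,
               tolerance = 1e-14)
  ## rotation invariance of Rg but not Rg_z
  R <- rotation_matrix(c(1, 2, 3), 35)
  g3 <- gyration(p %*% t(R), 1:100, masses = c(m))
  expect_equal(g3[["Rg"]], g2[["Rg"]], tolerance = 1e-12)
  expect_gt(abs(g3[["Rg_z"]] - g2[["Rg_z"]]), 1e-6)
  expect_error(gyration(p, integer(0)), "empty-input")
})

test_that("superposition recovers known transforms and rejects reflections", {
  set.seed(31)
  ref <- matrix(rnorm(150), ncol = 3)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  R <- rotation_matrix(c(0, 0, 1), 90)
  mob <- ref %*% t(R)
  mob <- sweep(mob, 2, c(1, -2, 0.5), "+")
  fit <- superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  moved <- sweep(mob %*% t(fit$rotation), 2, fit$translation, "+")
  expect_equal(moved, ref, tolerance = 1e-9)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "degenerate")
  line <- cbind(1:5, 1:5, 1:5) * 1.0
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("superposed RMSD of a noisy copy matches an independent optimizer", {
  skip_if_not_installed("bio3d")
  set.seed(41)
  ref <- matrix(rnorm(150), ncol = 3)
  mob <- ref %*% t(rotation_matrix(c(1, 1, 0), 25)) +
    matrix(rnorm(150, 0, 0.01), ncol = 3)
  fit <- superpose(mob, ref)
  oracle <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                           mobile = as.numeric(t(mob)),
                           fixed.inds = 1:150, mobile.inds = 1:150)
  rms_oracle <- sqrt(mean(rowSums((matrix(oracle, ncol = 3, byrow = TRUE) -
                                     ref)^2)))
  expect_equal(fit$rmsd, rms_oracle, tolerance = 1e-6)
})

test_that("RMSD series has the stated closed forms", {
  sys <- build_homopeptide(peptide_spec("GLY", 6))
  f0 <- coords(sys)
  sel <- seq_len(nrow(f0))
  ## repeated frames: identically zero
  tr <- trajectory(sys, list(f0, f0, f0))
  expect_equal(rmsd_series(tr, sel)$rmsd, c(0, 0, 0))
  ## pure translation without superposition equals |t|
  t_vec <- c(0.3, -0.4, 1.2)
  tr2 <- trajectory(sys, list(f0, sweep(f0, 2, t_vec, "+")))
  rs <- rmsd_series(tr2, sel, superpose_frames = FALSE)
  expect_equal(rs$rmsd[2], sqrt(sum(t_vec^2)), tolerance = 1e-12)
  ## rigid rotation with superposition is zero
  tr3 <- trajectory(sys, list(f0, f0 %*% t(rotation_matrix(c(1, 0, 2), 70))))
  expect_lt(rmsd_series(tr3, sel)$rmsd[2], 1e-10)
  expect_error(rmsd_series(tr3, sel, reference = 9), "empty-input")
})

test_that("analysis TSV writers are bit-stable and carry headers", {
  ig <- ideal_gas_frames(3, 50, 5, seed = 2)
  cp <- cylindrical_density(ig, 1:50, shell_length = 3)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_analysis_tsv(cp, p1); write_analysis_tsv(cp, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_match(readLines(p1)[1], "^# cylindrical profile")
})
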