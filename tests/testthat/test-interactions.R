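make_triple <- function(d_da, bend_deg = 0) {
  ## donor at origin, hydrogen along +x, acceptor at d_da rotated by bend
  A <- c(d_da * cos(bend_deg * pi / 180), d_da * sin(bend_deg * pi / 180), 0)
  frame <- rbind(c(0, 0, 0), c(0.1, 0, 0), A)
  sys <- point_system(frame, element = "O", group = "PEPTIDE")
  sys$atoms$element <- c("O", "H", "O")
  sys$atoms$parent <- c(NA, 1L, NA)
  list(frame = frame, donors = cbind(1L, 2L), acceptors = 3L, sys = sys)
}

test_that("the distance-angle criterion admits and rejects marginal bonds", {
  tt <- make_triple(0.30)
  rec <- detect_hbonds(tt$frame, tt$donors, acceptors = tt$acceptors)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$d_DA, 0.30)
  expect_equal(rec$angle_dev, 0)
  expect_equal(nrow(detect_hbonds(make_triple(0.36)$frame, tt$donors,
                                  acceptors = 3L)), 0L)
  expect_equal(nrow(detect_hbonds(make_triple(0.30, 31)$frame, tt$donors,
                                  acceptors = 3L)), 0L)
  expect_equal(nrow(detect_hbonds(make_triple(0.30, 29)$frame, tt$donors,
                                  acceptors = 3L)), 1L)
  ## hydrogen with no bonded donor is a topology error
  expect_error(detect_hbonds(tt$frame, cbind(NA_integer_, 2L),
                             acceptors = 3L), "topology error")
})

test_that("grid detection equals the all-pairs oracle on random frames", {
  set.seed(51)
  for (rep in 1:5) {
    n <- 120
    frame <- matrix(runif(3 * n, 0, 2.0), ncol = 3)
    donors <- cbind(seq(1, 40), seq(41, 80))
    ## hydrogens near their donors
    frame[41:80, ] <- frame[1:40, ] + matrix(rnorm(120, 0, 0.05), ncol = 3)
    acceptors <- 81:120
    rec <- detect_hbonds(frame, donors, acceptors = acceptors, method = "grid")
    rec_b <- detect_hbonds(frame, donors, acceptors = acceptors,
                           method = "brute")
    ora <- oracle_hbonds(frame, donors, acceptors)
    expect_equal(hb_triples(rec[, c("donor", "hydrogen", "acceptor")]),
                 hb_triples(ora))
    expect_equal(hb_triples(rec_b[, c("donor", "hydrogen", "acceptor")]),
                 hb_triples(ora))
  }
})

test_that("hydrogen-bond counts are rigid-motion invariant", {
  traj <- generate_hbond_ensemble(30, 0.5, 1, seed = 61)
  f <- traj$frames[[1]]
  top <- hbond_topology(traj$topology)
  n0 <- nrow(detect_hbonds(f, top$donors, acceptors = top$acceptors))
  R <- rotation_matrix(c(2, 1, 5), 57)
  f2 <- sweep(f %*% t(R), 2, c(3, -1, 2), "+")
  expect_equal(nrow(detect_hbonds(f2, top$donors, acceptors = top$acceptors)),
               n0)
})

test_that("category assignment follows donor/acceptor group pairs", {
  sys <- small_grafted_system(residue = "SER", n_res = 6, n_chains = 2)
  traj <- trajectory(sys, list(coords(sys)))
  s <- hbond_summary(traj)
  ## no water in the system: water categories exactly zero
  expect_equal(s$mean[s$category == "peptide-water"], 0)
  expect_equal(s$mean[s$category == "PEO-water"], 0)
  ## synthetic occupancy recovery within the binomial 99% CI
  tm <- generate_hbond_ensemble(50, 0.6, 200, seed = 71)
  sm <- hbond_summary(tm)
  ci99 <- 2.576 * sqrt(0.6 * 0.4 / (50 * 200)) * 50
  expect_lt(abs(sm$mean[sm$category == "peptide-water"] - 30), ci99)
})

test_that("sodium bridges require simultaneous double coordination", {
  ## Na at 0.25 nm from one oxygen of each kind: one bridge
  f <- rbind(c(0, 0, 0), c(0.25, 0, 0), c(-0.25, 0, 0))
  b <- detect_ion_bridges(f, 1, 2, 3)
  expect_equal(b$count, 1L)
  expect_equal(b$triples$o_peo, 2)
  ## 0.25 / 0.40: no bridge
  f2 <- rbind(c(0, 0, 0), c(0.25, 0, 0), c(-0.40, 0, 0))
  expect_equal(detect_ion_bridges(f2, 1, 2, 3)$count, 0L)
  ## random configurations equal a brute-force count
  set.seed(81)
  for (rep in 1:20) {
    f3 <- matrix(runif(3 * 40, 0, 1.2), ncol = 3)
    na <- 1:8; opeo <- 9:24; opep <- 25:40
    brute <- 0
    for (i in na) {
      d_peo <- sqrt(rowSums(sweep(f3[opeo, ], 2, f3[i, ])^2))
      d_pep <- sqrt(rowSums(sweep(f3[opep, ], 2, f3[i, ])^2))
      if (any(d_peo <= 0.32) && any(d_pep <= 0.32)) brute <- brute + 1
    }
    expect_equal(detect_ion_bridges(f3, na, opeo, opep)$count, brute)
  }
})

test_that("backbone torsions follow the IUPAC convention", {
  ## planar quadruples: cis is 0, trans is 180
  expect_equal(torsion_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
               0)
  expect_equal(torsion_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
               180)
  ## an ideal alpha-helix build reads back its own dihedrals within 2 deg
  hel <- build_homopeptide(peptide_spec("GLY", 12, conformation = c(-57, -47)))
  dih <- backbone_dihedrals(coords(hel), hel)
  expect_true(all(abs(dih$phi[2:11] - (-57)) < 2))
  expect_true(all(abs(dih$psi[2:11] - (-47)) < 2))
  ## missing backbone atom is a topology error
  broken <- hel
  broken$atoms <- broken$atoms[broken$atoms$name != "CA" |
                                 broken$atoms$resid != 5, ]
  expect_error(backbone_dihedrals(coords(broken), broken), "topology error")
})

test_that("secondary structure labels ideal helices and extended chains", {
  hel <- build_homopeptide(peptide_spec("GLY", 24, conformation = c(-57, -47)))
  ss <- assign_secondary_structure(coords(hel), hel)
  expect_true(all(ss[3:22] == "H"))
  h310 <- build_homopeptide(peptide_spec("SER", 24, conformation = c(-49, -26)))
  ss3 <- assign_secondary_structure(coords(h310), h310)
  expect_true(all(ss3[3:22] == "G"))
  ext <- build_homopeptide(peptide_spec("VAL", 24))
  sse <- assign_secondary_structure(coords(ext), ext)
  expect_true(all(sse == "C"))
  ## labels partition the residues
  expect_length(ss, 24L)
  expect_equal(sum(table(factor(ss, levels = c("H", "G", "E", "B", "T", "C")))),
               24)
  expect_error(assign_secondary_structure(
    coords(build_homopeptide(peptide_spec("GLY", 4))),
    build_homopeptide(peptide_spec("GLY", 4))), "too-short")
})
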