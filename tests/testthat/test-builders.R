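test_that("diameter formula matches closed form and the nominal rounding", {
  d <- cnt_diameter(cnt_spec(10, 0, 4.1))
  expect_equal(d$exact, 0.246 * 10 / pi, tolerance = 1e-12)
  expect_equal(round(d$exact, 3), 0.783)
  expect_equal(d$nominal, 0.8)
  expect_equal(cnt_diameter(cnt_spec(1, 0, 1, lattice_a = pi))$exact, 1.0)
  expect_equal(cnt_diameter(cnt_spec(5, 5, 1))$exact,
               (0.246 / pi) * sqrt(75), tolerance = 1e-12)
  expect_error(cnt_spec(0, 0), "invalid-spec")
  expect_error(cnt_spec(-3, 0), "invalid-spec")
})

test_that("sidewall area reproduces the nominal-diameter convention", {
  expect_equal(round(sidewall_area(0.8, 4.1), 1), 10.3)
  expect_equal(sidewall_area(0.8, 4.1), pi * 0.8 * 4.1)
  expect_equal(sidewall_area(1 / pi, 1), 1.0)
  expect_equal(sidewall_area(0.783, 4.1), 10.09, tolerance = 1e-3)
  expect_error(sidewall_area(0, 4.1), "invalid-spec")
  expect_error(sidewall_area(0.8, -1), "invalid-spec")
})

test_that("grafting density round-trips chain counts exactly", {
  area <- sidewall_area(0.8, 4.1)
  expect_equal(round(grafting_density(4, area), 3), 0.388)
  expect_equal(round(grafting_density(8, area), 3), 0.776)
  expect_equal(round(grafting_density(16, area), 3), 1.553)
  expect_equal(grafting_density(0, 5), 0)
  expect_error(grafting_density(4, 0), "invalid-spec")
  for (nc in c(1, 4, 8, 16, 37)) for (ar in c(10.304, 2.5, 100)) {
    gs <- graft_spec(nc, 18, area = ar)
    expect_identical(gs$sigma * ar, as.numeric(nc))
  }
})

test_that("built zigzag tube lies exactly on its cylinder", {
  cnt <- build_cnt(cnt_spec(10, 0, 4.1))
  R <- 0.246 * 10 / (2 * pi)
  rho <- sqrt(cnt$atoms$x^2 + cnt$atoms$y^2)
  expect_true(all(abs(rho - R) < 1e-6))
  expect_equal(nrow(cnt$atoms), 4 * 10 * floor(4.1 / (sqrt(3) * 0.246)))
  expect_true(all(cnt$atoms$charge == 0))
  expect_equal(length(unique(cnt$atoms$sigma)), 1L)
  expect_equal(length(unique(cnt$atoms$epsilon)), 1L)
  ## one translational period holds 4n atoms
  one <- build_cnt(cnt_spec(10, 0, sqrt(3) * 0.246 * 1.2))
  expect_equal(nrow(one$atoms), 40L)
  expect_error(build_cnt(cnt_spec(10, 5, 4.1)), "unsupported-chirality")
  ## deterministic, bit-identical
  expect_identical(coords(cnt), coords(build_cnt(cnt_spec(10, 0, 4.1))))
})

test_that("nearest-neighbour arc-corrected carbon distances match graphene", {
  cnt <- build_cnt(cnt_spec(10, 0, 1.1))
  R <- 0.246 * 10 / (2 * pi)
  xyz <- coords(cnt)
  theta <- atan2(xyz[, 2], xyz[, 1])
  nn <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    dth <- theta - theta[i]
    dth <- abs(atan2(sin(dth), cos(dth)))
    d <- sqrt((R * dth)^2 + (xyz[, 3] - xyz[i, 3])^2)
    nn[i] <- min(d[-i])
  }
  expect_true(all(abs(nn - 0.246 / sqrt(3)) / (0.246 / sqrt(3)) < 0.01))
})

test_that("PEO chains have the stated composition and helix extent", {
  p18 <- build_peo_chain(18)
  expect_equal(sum(p18$atoms$element != "H"), 3 * 18 + 1)
  expect_equal(sum(build_peo_chain(1)$atoms$element != "H"), 4L)
  heavy <- which(p18$atoms$element != "H")
  e2e <- sqrt(sum((coords(p18)[heavy[length(heavy)], ] -
                     coords(p18)[heavy[1], ])^2))
  expect_lt(abs(e2e - 18 * 0.28) / (18 * 0.28), 0.10)
  expect_equal(sum(p18$atoms$charge), 0, tolerance = 1e-12)
  expect_error(build_peo_chain(0), "invalid-spec")
})

test_that("grafting patterns are even, deterministic and capacity-limited", {
  cnt <- build_cnt(cnt_spec(10, 0, 4.1))
  area <- sidewall_area(0.8, 4.1)
  ## 4 chains on one ring: all angular separations 90 degrees
  g4 <- graft_chains(cnt, graft_spec(4, 18, area = area), n_rings = 1)
  ang <- sort(g4$meta$graft$anchors[, 1]) * 180 / pi
  expect_equal(diff(ang), rep(90, 3), tolerance = 1e-9)
  ## 8 chains on two rings: 4 per ring, rings symmetric about the midplane
  g8 <- graft_chains(cnt, graft_spec(8, 18, area = area), n_rings = 2)
  zs <- g8$meta$graft$anchors[, 2]
  expect_equal(as.numeric(table(zs)), c(4, 4))
  expect_equal(sum(unique(zs)), 0, tolerance = 1e-9)
  ## 16 chains: deterministic min geodesic beats 1000 random placements
  g16 <- graft_chains(cnt, graft_spec(16, 18, area = area))
  R <- cnt$meta$cnt$radius
  mind <- function(pts) {
    dth <- outer(pts[, 1], pts[, 1], "-")
    dth <- abs(atan2(sin(dth), cos(dth)))
    d <- sqrt((R * dth)^2 + outer(pts[, 2], pts[, 2], "-")^2)
    min(d[upper.tri(d)])
  }
  ours <- mind(g16$meta$graft$anchors)
  set.seed(42)
  rand_best <- max(replicate(1000, {
    mind(cbind(runif(16, 0, 2 * pi),
               runif(16, cnt$meta$cnt$zmin, cnt$meta$cnt$zmax)))
  }))
  expect_gte(ours, rand_best)
  ## determinism and capacity
  expect_identical(coords(g16),
                   coords(graft_chains(cnt, graft_spec(16, 18, area = area))))
  expect_error(graft_chains(cnt, graft_spec(40, 18, area = area)),
               "capacity")
})

test_that("homopeptides match the composition table and are zwitterions", {
  g24 <- build_homopeptide(peptide_spec("GLY", 24))
  expect_equal(nrow(g24$atoms), 24 * 7 + 3)
  v1 <- build_homopeptide(peptide_spec("VAL", 1))
  expect_equal(nrow(v1$atoms), 19L)
  s6 <- build_homopeptide(peptide_spec("SER", 6))
  expect_equal(nrow(s6$atoms), 6 * 11 + 3)
  for (sys in list(g24, v1, s6))
    expect_equal(sum(sys$atoms$charge), 0, tolerance = 1e-9)
  ## termini: three amine protons, one extra carboxylate oxygen
  expect_equal(sum(g24$atoms$name %in% c("H1", "H2", "H3")), 3L)
  expect_equal(sum(g24$atoms$name == "OXT"), 1L)
  expect_error(peptide_spec("TRP"), "invalid-spec")
})

test_that("built peptides carry the requested backbone dihedrals", {
  for (conf in list(c(-135, 135), c(-57, -47), c(-49, -26))) {
    pep <- build_homopeptide(peptide_spec("VAL", 8, conformation = conf))
    dih <- backbone_dihedrals(coords(pep), pep)
    interior <- 2:7
    expect_equal(dih$phi[interior], rep(conf[1], 6), tolerance = 1e-6)
    expect_equal(dih$psi[interior], rep(conf[2], 6), tolerance = 1e-6)
  }
})

test_that("hydropathy lookups return the Kyte-Doolittle scale", {
  expect_equal(lookup_hydropathy("VAL"), 4.2)
  expect_equal(lookup_hydropathy("GLY"), -0.4)
  expect_equal(lookup_hydropathy("SER"), -0.8)
  expect_equal(lookup_hydropathy("ile"), 4.5)
  expect_error(lookup_hydropathy("XXX"), "unknown residue")
})

test_that("peptide placement hits the requested gap window", {
  sys <- small_grafted_system(n_chains = 4)
  psel <- select_atoms(sys, "group PEPTIDE")
  rest <- setdiff(seq_len(nrow(sys$atoms)), psel)
  d <- sqrt(min(nanobrush:::cross_dist2(coords(sys)[psel, ],
                                        coords(sys)[rest, ])))
  expect_gte(d, 0.30)
  expect_lte(d, 0.32)
  ## a box far smaller than the solutes admits no placement
  cnt <- build_cnt(cnt_spec(10, 0, 4.1))
  cnt$box <- 0.5
  expect_error(place_peptide(cnt, build_homopeptide(peptide_spec("GLY", 24)),
                             gap = 0.3), "placement error")
})

test_that("solvation realizes the requested density and exclusion", {
  empty <- molsys(nanobrush:::empty_atoms(0))
  sv <- solvate(empty, solvent_spec(6), seed = 1)
  expect_equal(sv$meta$n_waters, round(33.3 * 216), tolerance = 0.001)
  expect_equal(sv$meta$n_waters / 216, 33.3, tolerance = 0.03)
  ## pristine tube in a 6 nm box: close to the reference count of 7010
  cnt <- build_cnt(cnt_spec(10, 0, 4.1))
  sv2 <- solvate(cnt, solvent_spec(6), seed = 1)
  expect_lt(abs(sv2$meta$n_waters - 7010) / 7010, 0.05)
  ## exclusion radius spanning the box removes everything
  sv3 <- solvate(cnt, solvent_spec(4, exclusion_radius = 4), seed = 1)
  expect_equal(sv3$meta$n_waters, 0L)
  ## determinism
  expect_identical(coords(sv), coords(solvate(empty, solvent_spec(6), seed = 1)))
})

test_that("ion substitution hits the physiological pair count", {
  expect_equal(9.0 / 58.44, 0.154, tolerance = 1e-3)
  ## 7200 waters at 33.3 nm-3 give 20 pairs
  fake <- point_system(matrix(runif(3 * 7200, -4, 4), ncol = 3),
                       group = "WATER", element = "O", box = 9)
  fake$atoms$resid <- seq_len(7200)
  fake$meta <- list(water_number_density = 33.3, n_waters = 7200L)
  si <- add_ions(fake, 9.0, seed = 2)
  expect_equal(si$meta$n_ion_pairs, 20L)
  expect_equal(sum(si$atoms$group == "NA"), 20L)
  expect_equal(sum(si$atoms$group == "CL"), 20L)
  expect_equal(sum(si$atoms$charge), 0)
  ## no salt: unchanged; too little water: composition error
  expect_identical(add_ions(fake, 0), fake)
  tiny <- point_system(matrix(runif(30, -1, 1), ncol = 3),
                       group = "WATER", element = "O", box = 2)
  tiny$meta <- list(water_number_density = 33.3)
  expect_error(add_ions(tiny, 3000), "composition error")
})
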