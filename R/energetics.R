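## MM-PBSA rescoring: gas-phase Lennard-Jones and Coulomb interaction
## terms (no cutoff), finite-difference linearized Poisson-Boltzmann polar
## solvation, Shrake-Rupley SASA nonpolar solvation, and single-trajectory
## frame averaging of the binding free energy.

#' Vacuum Coulomb constant, kJ mol-1 nm e-2
#' @export
COULOMB_F <- 138.935458

GAS_R <- 0.008314462618                  # kJ mol-1 K-1

pair_params <- function(sys, sel_A, sel_B) {
  a <- sys$atoms
  list(sig = sqrt(outer(a$sigma[sel_A], a$sigma[sel_B])),
       eps = sqrt(outer(a$epsilon[sel_A], a$epsilon[sel_B])),
       qq = outer(a$charge[sel_A], a$charge[sel_B]))
}

pair_r2 <- function(frame, sel_A, sel_B) {
  r2 <- cross_dist2(frame[sel_A, , drop = FALSE],
                    frame[sel_B, , drop = FALSE])
  if (any(r2 < 1e-16))
    stop("singularity error: zero interatomic distance between groups")
  r2
}

#' Lennard-Jones interaction energy between two groups
#'
#' Sum over all A-B pairs of 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6) with
#' geometric-mean combination for both sigma and epsilon, no cutoff.
#'
#' @param sys `molsys` supplying sigma/epsilon.
#' @param sel_A,sel_B disjoint atom index vectors.
#' @param frame optional coordinate matrix (default: system coordinates).
#' @return energy in kJ/mol.
#' @export
lj_energy <- function(sys, sel_A, sel_B, frame = NULL) {
  if (is.null(frame)) frame <- coords(sys)
  p <- pair_params(sys, sel_A, sel_B)
  r2 <- pair_r2(frame, sel_A, sel_B)
  sr2 <- p$sig^2 / r2
  sum(4 * p$eps * (sr2^6 - sr2^3))
}

#' Coulomb interaction energy between two groups
#'
#' Sum over all A-B pairs of f q_i q_j / r_ij with
#' f = 138.935458 kJ mol-1 nm e-2, no cutoff.
#'
#' @inheritParams lj_energy
#' @return energy in kJ/mol.
#' @export
coulomb_energy <- function(sys, sel_A, sel_B, frame = NULL) {
  if (is.null(frame)) frame <- coords(sys)
  p <- pair_params(sys, sel_A, sel_B)
  r2 <- pair_r2(frame, sel_A, sel_B)
  COULOMB_F * sum(p$qq / sqrt(r2))
}

#' Poisson-Boltzmann solver configuration
#'
#' @param grid_spacing nm (default 0.05).
#' @param eps_in solute dielectric (default 2).
#' @param eps_out solvent dielectric (default 78.4).
#' @param ionic_strength mol/dm3 (0, or 0.154 for physiological saline).
#' @param temperature K, used in the screening term.
#' @param margin grid margin beyond the solute, nm (>= 1.0).
#' @param radii optional per-atom cavity radii (nm); default is the
#'   Lennard-Jones minimum radius 2^(1/6) sigma / 2.
#' @return object of class `pb_config`.
#' @export
pb_config <- function(grid_spacing = 0.05, eps_in = 2, eps_out = 78.4,
                      ionic_strength = 0, temperature = 298.15,
                      margin = 1.0, radii = NULL) {
  if (eps_in < 1 || eps_out < eps_in)
    stop("configuration error: need eps_out >= eps_in >= 1")
  if (margin < 1.0)
    stop("configuration error: grid margin must be at least 1.0 nm")
  structure(list(grid_spacing = grid_spacing, eps_in = eps_in,
                 eps_out = eps_out, ionic_strength = ionic_strength,
                 temperature = temperature, margin = margin, radii = radii),
            class = "pb_config")
}

## signed distance (dist - radius, minimized over atoms) evaluated at the
## points (x_i, y_j, z_k) of a regular grid, by per-atom local updates
grid_sdf <- function(gx, gy, gz, centers, radii, reach) {
  sdf <- array(Inf, dim = c(length(gx), length(gy), length(gz)))
  h <- if (length(gx) > 1) gx[2] - gx[1] else 1
  for (s in seq_len(nrow(centers))) {
    rad <- radii[s] + reach
    ix <- which(abs(gx - centers[s, 1]) <= rad)
    iy <- which(abs(gy - centers[s, 2]) <= rad)
    iz <- which(abs(gz - centers[s, 3]) <= rad)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - centers[s, 1])^2
    dy2 <- (gy[iy] - centers[s, 2])^2
    dz2 <- (gz[iz] - centers[s, 3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - radii[s]
    sdf[ix, iy, iz] <- pmin(sdf[ix, iy, iz], d)
  }
  sdf
}

## dielectric on faces from the signed distance at face midpoints, with
## harmonic averaging across the molecular boundary
face_eps <- function(sdf_face, h, eps_in, eps_out) {
  fin <- pmin(1, pmax(0, 0.5 - sdf_face / h))
  1 / (fin / eps_in + (1 - fin) / eps_out)
}

solve_grid <- function(gx, gy, gz, charges, centers, config, vacuum,
                       radii, tol = 1e-6) {
  h <- gx[2] - gx[1]
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  eps_out_eff <- if (vacuum) config$eps_in else config$eps_out
  if (vacuum) {
    epsx <- array(config$eps_in, c(nx - 1, ny, nz))
    epsy <- array(config$eps_in, c(nx, ny - 1, nz))
    epsz <- array(config$eps_in, c(nx, ny, nz - 1))
    kap2h2 <- array(0, c(nx, ny, nz))
  } else {
    mx <- (gx[-1] + gx[-nx]) / 2
    my <- (gy[-1] + gy[-ny]) / 2
    mz <- (gz[-1] + gz[-nz]) / 2
    reach <- h
    epsx <- face_eps(grid_sdf(mx, gy, gz, centers, radii, reach), h,
                     config$eps_in, config$eps_out)
    epsy <- face_eps(grid_sdf(gx, my, gz, centers, radii, reach), h,
                     config$eps_in, config$eps_out)
    epsz <- face_eps(grid_sdf(gx, gy, mz, centers, radii, reach), h,
                     config$eps_in, config$eps_out)
    kap2 <- 0
    if (config$ionic_strength > 0) {
      i_nm <- config$ionic_strength * AVOGADRO * 1e-24    # ions per nm3
      kap2 <- 8 * pi * COULOMB_F * i_nm /
        (GAS_R * config$temperature)                      # eps-premultiplied
    }
    node_sdf <- grid_sdf(gx, gy, gz, centers, radii, h)
    kap2h2 <- array(0, c(nx, ny, nz))
    kap2h2[node_sdf > 0] <- kap2 * h^2
  }

  ## trilinear charge assignment
  src <- array(0, c(nx, ny, nz))
  for (s in seq_len(nrow(centers))) {
    if (charges[s] == 0) next
    fx <- (centers[s, 1] - gx[1]) / h; ix <- floor(fx); tx <- fx - ix
    fy <- (centers[s, 2] - gy[1]) / h; iy <- floor(fy); ty <- fy - iy
    fz <- (centers[s, 3] - gz[1]) / h; iz <- floor(fz); tz <- fz - iz
    wx <- c(1 - tx, tx); wy <- c(1 - ty, ty); wz <- c(1 - tz, tz)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      src[ix + 1 + a, iy + 1 + b, iz + 1 + cc] <-
        src[ix + 1 + a, iy + 1 + b, iz + 1 + cc] +
        charges[s] * wx[a + 1] * wy[b + 1] * wz[cc + 1]
  }
  src <- 4 * pi * COULOMB_F * src / h     # src term in the SOR update

  ## Dirichlet boundary from the single-centre Debye-Hueckel potential
  Q <- sum(charges)
  ctr <- if (abs(Q) > 1e-12) colSums(centers * abs(charges)) / sum(abs(charges))
         else colMeans(centers)
  kappa <- if (!vacuum && config$ionic_strength > 0) {
    i_nm <- config$ionic_strength * AVOGADRO * 1e-24
    sqrt(8 * pi * COULOMB_F * i_nm /
           (config$eps_out * GAS_R * config$temperature))
  } else 0
  phi <- array(0, c(nx, ny, nz))
  bc <- function(x, y, z) {
    r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2)
    r[r < h] <- h
    COULOMB_F * Q * exp(-kappa * r) / (eps_out_eff * r)
  }
  phi[1, , ] <- outer(gy, gz, function(y, z) bc(gx[1], y, z))
  phi[nx, , ] <- outer(gy, gz, function(y, z) bc(gx[nx], y, z))
  phi[, 1, ] <- outer(gx, gz, function(x, z) bc(x, gy[1], z))
  phi[, ny, ] <- outer(gx, gz, function(x, z) bc(x, gy[ny], z))
  phi[, , 1] <- outer(gx, gy, function(x, y) bc(x, y, gz[1]))
  phi[, , nz] <- outer(gx, gy, function(x, y) bc(x, y, gz[nz]))

  omega <- 2 / (1 + sin(pi / max(nx, ny, nz)))
  res <- .pb_sor(as.numeric(phi), as.numeric(epsx), as.numeric(epsy),
                 as.numeric(epsz), as.numeric(kap2h2), as.numeric(src),
                 c(nx, ny, nz), omega, tol, 20000L)
  array(res$phi, c(nx, ny, nz))
}

trilinear <- function(phi, gx, gy, gz, pts) {
  h <- gx[2] - gx[1]
  out <- numeric(nrow(pts))
  for (s in seq_len(nrow(pts))) {
    fx <- (pts[s, 1] - gx[1]) / h; ix <- floor(fx); tx <- fx - ix
    fy <- (pts[s, 2] - gy[1]) / h; iy <- floor(fy); ty <- fy - iy
    fz <- (pts[s, 3] - gz[1]) / h; iz <- floor(fz); tz <- fz - iz
    wx <- c(1 - tx, tx); wy <- c(1 - ty, ty); wz <- c(1 - tz, tz)
    v <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      v <- v + phi[ix + 1 + a, iy + 1 + b, iz + 1 + cc] *
        wx[a + 1] * wy[b + 1] * wz[cc + 1]
    out[s] <- v
  }
  out
}

#' Polar solvation energy from the linearized Poisson-Boltzmann equation
#'
#' Finite-difference solution on a regular grid: solute dielectric inside
#' the union of atom spheres, solvent dielectric outside (harmonic
#' averaging across the boundary), Debye screening in the solvent region,
#' Dirichlet boundary from the single-centre Debye-Hueckel potential,
#' successive over-relaxation.  The reaction-field energy is
#' G_pol = 1/2 sum q_i (phi_solvated - phi_reference)(r_i), where the
#' reference solve uses the solute dielectric everywhere, so the grid
#' self-energy cancels.
#'
#' @param sys `molsys` providing charges and LJ radii.
#' @param selection atom indices of the solute.
#' @param config a [pb_config()].
#' @param frame optional coordinate matrix.
#' @return G_pol in kJ/mol.
#' @export
solve_pb <- function(sys, selection = NULL, config = pb_config(),
                     frame = NULL) {
  if (is.null(frame)) frame <- coords(sys)
  if (is.null(selection)) selection <- seq_len(nrow(sys$atoms))
  centers <- frame[selection, , drop = FALSE]
  charges <- sys$atoms$charge[selection]
  radii <- if (!is.null(config$radii)) config$radii
           else 2^(1/6) * sys$atoms$sigma[selection] / 2
  radii[radii <= 0] <- 0.05               # bare-proton floor for the cavity
  if (all(charges == 0)) return(0)
  h <- config$grid_spacing
  lo <- apply(centers, 2, min) - max(radii) - config$margin
  hi <- apply(centers, 2, max) + max(radii) + config$margin
  gx <- seq(lo[1], hi[1] + h, by = h)
  gy <- seq(lo[2], hi[2] + h, by = h)
  gz <- seq(lo[3], hi[3] + h, by = h)
  if (length(gx) < 5 || length(gy) < 5 || length(gz) < 5)
    stop("configuration error: grid does not enclose solute plus margin")
  if (config$eps_out == config$eps_in && config$ionic_strength == 0)
    return(0)
  phi_s <- solve_grid(gx, gy, gz, charges, centers, config, vacuum = FALSE,
                      radii = radii)
  phi_v <- solve_grid(gx, gy, gz, charges, centers, config, vacuum = TRUE,
                      radii = radii)
  dphi <- trilinear(phi_s, gx, gy, gz, centers) -
    trilinear(phi_v, gx, gy, gz, centers)
  0.5 * sum(charges * dphi)
}

#' SASA configuration
#'
#' @param probe_radius nm (default 0.14, a water-sized probe).
#' @param n_sphere_points quadrature points per atom (default 960).
#' @param gamma surface coefficient, kJ mol-1 A-2 (default 0.0227).
#' @param offset constant term, kJ/mol (default 0).
#' @return object of class `sasa_config`.
#' @export
sasa_config <- function(probe_radius = 0.14, n_sphere_points = 960,
                        gamma = 0.0227, offset = 0) {
  if (probe_radius < 0) stop("parameter error: probe_radius must be >= 0")
  if (n_sphere_points < 92)
    stop("parameter error: need at least 92 sphere points")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 gamma = gamma, offset = offset), class = "sasa_config")
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic Fibonacci-lattice quadrature on each atom's expanded
#' sphere of radius r_i + probe; a point is exposed when outside every
#' neighbour's expanded sphere.
#'
#' @param frame n x 3 coordinate matrix (nm).
#' @param selection atom indices.
#' @param radii per-atom radii (full-length vector, nm); negative values
#'   are a parameter error.
#' @param config a [sasa_config()].
#' @return list with `total` (nm2) and per-atom `area`.
#' @export
sasa <- function(frame, selection, radii, config = sasa_config()) {
  if (any(radii[selection] < 0))
    stop("parameter error: negative atom radius")
  p <- frame[selection, , drop = FALSE]
  r <- radii[selection] + config$probe_radius
  n <- length(selection)
  pts <- fibonacci_sphere(config$n_sphere_points)
  area <- numeric(n)
  d2 <- cross_dist2(p, p)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, p[i, ], "+")
    exposed <- rep(TRUE, nrow(surf))
    for (j in nb) {
      if (!any(exposed)) break
      dd <- colSums((t(surf[exposed, , drop = FALSE]) - p[j, ])^2)
      exposed[exposed] <- dd > r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  list(total = sum(area), area = area)
}

#' Nonpolar solvation term from SASA
#' @param area_nm2 surface area in nm2.
#' @param config a [sasa_config()] (gamma in kJ mol-1 A-2).
#' @return gamma * SASA + offset, kJ/mol.
#' @export
sasa_nonpolar <- function(area_nm2, config = sasa_config()) {
  config$gamma * area_nm2 * 100 + config$offset
}

#' Single-trajectory MM-PBSA binding free energy
#'
#' Receptor and ligand coordinates are extracted from each complex frame,
#' so the intramolecular term cancels identically (it is carried as an
#' explicit zero).  Per frame: dE_vdW and dE_coul over receptor-ligand
#' pairs, ddG_pol = G_pol(PC) - G_pol(P) - G_pol(C) from the PB solver,
#' ddG_nonpol analogously from SASA, and
#' dG_bind = dE_vdW + dE_coul + ddG_pol + ddG_nonpol; the entropic
#' term is omitted.  Means and standard deviations are taken over the
#' frame window.
#'
#' @param traj a `trajectory`.
#' @param receptor,ligand disjoint atom index vectors.
#' @param pb a [pb_config()].
#' @param sasa_cfg a [sasa_config()].
#' @param frame_window integer frame indices (default: final third).
#' @return object of class `energy_decomposition`: per-frame data.frame
#'   and a summary with mean +/- sd of every term.
#' @export
binding_free_energy <- function(traj, receptor, ligand,
                                pb = pb_config(), sasa_cfg = sasa_config(),
                                frame_window = NULL) {
  if (length(intersect(receptor, ligand)) > 0)
    stop("selection error: receptor and ligand selections overlap")
  nf <- n_frames(traj)
  if (nf == 0) stop("empty-input error: trajectory has no frames")
  if (is.null(frame_window))
    frame_window <- seq.int(max(1L, floor(2 * nf / 3) + 1L), nf)
  if (length(frame_window) == 0)
    stop("empty-input error: empty frame window")
  sys <- traj$topology
  complex_sel <- sort(c(receptor, ligand))
  radii <- 2^(1/6) * sys$atoms$sigma / 2
  per <- lapply(frame_window, function(fi) {
    f <- traj$frames[[fi]]
    e_vdw <- lj_energy(sys, receptor, ligand, frame = f)
    e_coul <- coulomb_energy(sys, receptor, ligand, frame = f)
    g_pol <- vapply(list(complex_sel, receptor, ligand), function(sel)
      solve_pb(sys, sel, config = pb, frame = f), numeric(1))
    areas <- vapply(list(complex_sel, receptor, ligand), function(sel)
      sasa(f, sel, radii, config = sasa_cfg)$total, numeric(1))
    g_np <- sasa_nonpolar(areas, sasa_cfg)
    data.frame(frame = fi, E_intra = 0, E_vdW = e_vdw, E_coul = e_coul,
               G_pol_complex = g_pol[1], G_pol_receptor = g_pol[2],
               G_pol_ligand = g_pol[3],
               G_nonpol_complex = g_np[1], G_nonpol_receptor = g_np[2],
               G_nonpol_ligand = g_np[3],
               ddG_pol = g_pol[1] - g_pol[2] - g_pol[3],
               ddG_nonpol = g_np[1] - g_np[2] - g_np[3])
  })
  per <- do.call(rbind, per)
  per$dG_g <- per$E_intra + per$E_vdW + per$E_coul
  per$dG_sol <- per$ddG_pol + per$ddG_nonpol
  per$dG_bind <- per$dG_g + per$dG_sol
  terms <- setdiff(names(per), "frame")
  summary <- data.frame(term = terms,
                        mean = vapply(per[terms], mean, numeric(1)),
                        sd = vapply(per[terms], stats::sd, numeric(1)),
                        row.names = NULL)
  structure(list(per_frame = per, summary = summary,
                 frame_window = frame_window), class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("MM-PBSA decomposition over", length(x$frame_window), "frames\n")
  s <- x$summary
  for (t in c("E_vdW", "E_coul", "ddG_pol", "ddG_nonpol", "dG_bind")) {
    r <- s[s$term == t, ]
    cat(sprintf("  %-10s %10.3f +/- %.3f kJ/mol\n", t, r$mean, r$sd))
  }
  invisible(x)
}
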