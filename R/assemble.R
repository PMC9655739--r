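## Assembly of complete simulation systems: rigid placement of a peptide
## next to the grafted layer, lattice solvation, and NaCl substitution.

AVOGADRO <- 6.02214076e23
NACL_MOLAR_MASS <- 58.44                 # g/mol

## the 24 proper rotations of the cube, as a deterministic orientation set
cube_rotations <- function() {
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mats <- list(diag(3))
  gens <- c(lapply(axes, rotation_matrix, angle_deg = 90))
  repeat {
    new <- list()
    for (m in mats) for (g in gens) {
      cand <- round(g %*% m, 10)
      if (!any(vapply(c(mats, new), function(x) all(abs(x - cand) < 1e-8),
                      logical(1))))
        new[[length(new) + 1L]] <- cand
    }
    if (length(new) == 0) break
    mats <- c(mats, new)
  }
  mats
}

#' Place a peptide next to the grafted layer
#'
#' The peptide is rigidly oriented and translated along a radial direction
#' until the minimum distance between any peptide atom and any atom of the
#' existing system lies in [gap, gap + 0.02] nm.  The orientation is chosen
#' greedily over a fixed set of 24 rigid rotations as the one maximizing
#' the number of peptide atoms within `contact_range` of the layer (PEO
#' atoms when present, otherwise the bare sidewall).
#'
#' @param system `molsys` containing CNT (and optionally PEO) groups.
#' @param peptide `molsys` fragment from [build_homopeptide()].
#' @param gap target closest-approach distance, nm (default 0.3).
#' @param contact_range distance defining a "close contact", nm.
#' @return combined `molsys`.
#' @export
place_peptide <- function(system, peptide, gap = 0.3, contact_range = 0.6) {
  if (gap <= 0) stop("invalid-spec: gap must be positive")
  sxyz <- coords(system)
  layer_sel <- if (any(system$atoms$group == "PEO"))
    system$atoms$group == "PEO" else system$atoms$group == "CNT"
  lxyz <- sxyz[layer_sel, , drop = FALSE]
  pxyz0 <- coords(peptide)
  pxyz0 <- sweep(pxyz0, 2, colMeans(pxyz0))       # centre on COM of positions
  radial <- c(1, 0, 0)
  box <- system$box
  rho_hi <- max(sqrt(sxyz[, 1]^2 + sxyz[, 2]^2)) +
    max(sqrt(rowSums(pxyz0^2))) + gap + 1
  if (!is.na(box) && rho_hi > box) rho_hi <- box

  try_orientation <- function(Rm) {
    p <- pxyz0 %*% t(Rm)
    f <- function(rho) {
      q <- sweep(p, 2, rho * radial, "+")
      sqrt(min(cross_dist2(q, sxyz)))
    }
    lo <- 0; hi <- rho_hi
    if (f(hi) < gap) return(NULL)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      d <- f(mid)
      if (d >= gap && d <= gap + 0.02) { lo <- hi <- mid; break }
      if (d < gap) lo <- mid else hi <- mid
    }
    rho <- (lo + hi) / 2
    d <- f(rho)
    if (d < gap || d > gap + 0.02) return(NULL)
    q <- sweep(p, 2, rho * radial, "+")
    contacts <- sum(sqrt(apply(cross_dist2(q, lxyz), 1, min)) <= contact_range)
    list(xyz = q, contacts = contacts, min_dist = d)
  }

  best <- NULL
  for (Rm in cube_rotations()) {
    cand <- try_orientation(Rm)
    if (!is.null(cand) &&
        (is.null(best) || cand$contacts > best$contacts)) best <- cand
  }
  if (is.null(best))
    stop("placement error: no non-overlapping placement at gap ", gap,
         " fits the box")
  merge_systems(system, set_coords(peptide, best$xyz))
}

#' Solvate a system with 3-site water
#'
#' Rigid 3-site water molecules (OH bond 0.09572 nm, HOH angle 104.52
#' degrees) on a jittered cubic lattice at the requested number density;
#' any molecule whose oxygen falls within `exclusion_radius` of a solute
#' heavy atom is deleted.  The box is centred on the origin.
#'
#' @param system `molsys` (may be an empty system for a pure-water box).
#' @param spec a [solvent_spec()].
#' @param seed integer seed for lattice jitter and molecule orientation.
#' @return solvated `molsys` with the box edge set; the number of water
#'   molecules kept is recorded in `$meta$n_waters`.
#' @export
solvate <- function(system, spec, seed = 0) {
  stopifnot(inherits(spec, "solvent_spec"))
  box <- spec$box_edge
  target <- round(spec$water_number_density * box^3)
  nside <- ceiling(target^(1/3))
  sp <- box / nside
  g <- seq_len(nside) - 0.5
  lattice <- as.matrix(expand.grid(x = g, y = g, z = g)) * sp - box / 2
  lattice <- lattice[seq_len(min(target, nrow(lattice))), , drop = FALSE]
  set.seed(seed)
  lattice <- lattice + matrix(runif(length(lattice), -0.2, 0.2) * sp,
                              ncol = 3)

  solute <- system$atoms[system$atoms$element != "H", , drop = FALSE]
  keep <- rep(TRUE, nrow(lattice))
  if (nrow(solute) > 0) {
    sxyz <- as.matrix(solute[, c("x", "y", "z")])
    r2 <- spec$exclusion_radius^2
    chunk <- 20000L
    for (start in seq(1, nrow(lattice), by = chunk)) {
      i <- start:min(start + chunk - 1L, nrow(lattice))
      keep[i] <- apply(cross_dist2(lattice[i, , drop = FALSE], sxyz) >= r2,
                       1, all)
    }
  }
  lattice <- lattice[keep, , drop = FALSE]
  nw <- nrow(lattice)
  if (nw == 0) {
    out <- system
    out$box <- box
    out$meta <- c(system$meta,
                  list(n_waters = 0L,
                       water_number_density = spec$water_number_density))
    return(out)
  }

  ## rigid water geometry in a random orientation per molecule
  b <- 0.09572; half <- deg2rad(104.52) / 2
  h1 <- c(b * sin(half), 0, b * cos(half))
  h2 <- c(-b * sin(half), 0, b * cos(half))
  ang1 <- runif(nw, 0, 360); ang2 <- runif(nw, 0, 360)
  rows <- vector("list", 3 * nw)
  for (i in seq_len(nw)) {
    Rm <- rotation_matrix(c(0, 0, 1), ang1[i]) %*%
      rotation_matrix(c(0, 1, 0), ang2[i])
    o <- lattice[i, ]
    rows[[3 * i - 2]] <- atom_row("O", "OW", "WATER", i, "SOL", o,
                                  -0.834, "O_w")
    rows[[3 * i - 1]] <- atom_row("H", "HW1", "WATER", i, "SOL",
                                  o + as.numeric(Rm %*% h1), 0.417, "H_pol")
    rows[[3 * i]] <- atom_row("H", "HW2", "WATER", i, "SOL",
                              o + as.numeric(Rm %*% h2), 0.417, "H_pol")
  }
  water <- molsys(finalize_atoms(rows))
  ## hydrogens bonded to their own oxygen
  water$atoms$parent <- ifelse(water$atoms$element == "H",
                               3L * (water$atoms$resid - 1L) + 1L,
                               NA_integer_)
  out <- if (nrow(system$atoms) > 0) merge_systems(system, water) else water
  out$box <- box
  out$meta <- c(system$meta,
                list(n_waters = nw,
                     water_number_density = spec$water_number_density))
  out
}

#' Replace waters by Na+ and Cl- at a target mass concentration
#'
#' The number of ion pairs is round(c * N_A * V_water) with the molar
#' concentration c = mass_conc / 58.44 and V_water the volume the waters
#' occupy at the build density; that many water molecules each are replaced
#' (uniformly at random under the seed) by a Na+ and by a Cl- placed at the
#' removed oxygen position, preserving electroneutrality.
#'
#' @param system solvated `molsys`.
#' @param mass_conc NaCl mass concentration, g/dm3 (9.0 = physiological).
#' @param seed integer seed for the replacement draw.
#' @return `molsys` with NA/CL groups; pair count in `$meta$n_ion_pairs`.
#' @export
add_ions <- function(system, mass_conc, seed = 0) {
  if (mass_conc < 0) stop("invalid-spec: mass_conc must be >= 0")
  if (mass_conc == 0) return(system)
  wat <- which(system$atoms$group == "WATER" & system$atoms$element == "O")
  nw <- length(wat)
  if (nw == 0) stop("composition error: system contains no water")
  dens <- system$meta$water_number_density
  if (is.null(dens)) dens <- 33.3
  v_water_nm3 <- nw / dens
  c_molar <- mass_conc / NACL_MOLAR_MASS
  n_pairs <- round(c_molar * AVOGADRO * v_water_nm3 * 1e-24)
  if (2 * n_pairs > nw)
    stop("composition error: fewer waters than required replacements")
  if (n_pairs == 0) return(system)
  set.seed(seed)
  picked <- sample(wat, 2 * n_pairs)
  na_o <- picked[seq_len(n_pairs)]
  cl_o <- picked[n_pairs + seq_len(n_pairs)]

  a <- system$atoms
  wat_res <- a$resid[picked]
  drop <- a$group == "WATER" & a$resid %in% wat_res
  ions <- c(lapply(na_o, function(i)
    atom_row("Na", "NA", "NA", 1L, "NA",
             c(a$x[i], a$y[i], a$z[i]), +1, "Na_ion")),
    lapply(cl_o, function(i)
      atom_row("Cl", "CL", "CL", 1L, "CL",
               c(a$x[i], a$y[i], a$z[i]), -1, "Cl_ion")))
  ions <- finalize_atoms(ions)
  ions$resid <- seq_len(nrow(ions))
  kept <- a[!drop, , drop = FALSE]
  ## re-index while keeping parent references valid
  newid <- integer(nrow(a)); newid[kept$id] <- seq_len(nrow(kept))
  kept$parent <- ifelse(is.na(kept$parent), NA_integer_, newid[kept$parent])
  kept$id <- seq_len(nrow(kept))
  ions$id <- nrow(kept) + seq_len(nrow(ions))
  ions$resid <- max(kept$resid) + ions$resid
  out <- system
  out$atoms <- rbind(kept, ions)
  rownames(out$atoms) <- NULL
  out$meta$n_ion_pairs <- n_pairs
  out$meta$n_waters <- nw - 2 * n_pairs
  out
}
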