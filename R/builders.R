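## System builders: zigzag carbon nanotube from chirality indices, grafted
## poly(ethylene oxide) chains, homopeptides from internal coordinates,
## explicit 3-site water and NaCl.  Units: nm, e, kJ/mol, amu, degrees.

ELEMENT_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                  Na = 22.990, Cl = 35.453)

## Lennard-Jones classes (sigma nm, epsilon kJ/mol); simplified OPLS-like
## defaults, overridable through a per-atom parameter table (read_params).
LJ_CLASS <- list(
  C_aro   = c(0.355,   0.29288),
  C_sp3   = c(0.350,   0.276144),
  C_co    = c(0.375,   0.43932),
  H_ap    = c(0.250,   0.12552),
  H_pol   = c(0.000,   0.00000),
  O_co    = c(0.296,   0.87864),
  O_oh    = c(0.307,   0.71128),
  O_eth   = c(0.290,   0.58576),
  O_w     = c(0.31506, 0.63639),
  N_am    = c(0.325,   0.71128),
  Na_ion  = c(0.2584,  0.41840),
  Cl_ion  = c(0.4401,  0.41840))

atom_row <- function(element, name, group, resid, resname, pos, charge,
                     ljclass, parent = NA_integer_) {
  lj <- LJ_CLASS[[ljclass]]
  data.frame(id = NA_integer_, element = element, name = name, group = group,
             resid = resid, resname = resname,
             x = pos[1], y = pos[2], z = pos[3], charge = charge,
             sigma = lj[1], epsilon = lj[2],
             mass = ELEMENT_MASS[[element]], parent = parent,
             stringsAsFactors = FALSE)
}

finalize_atoms <- function(rows) {
  a <- do.call(rbind, rows)
  a$id <- seq_len(nrow(a))
  rownames(a) <- NULL
  a
}

## ---- specifications --------------------------------------------------------

#' Nanotube build specification
#'
#' @param n,m chirality indices; only zigzag tubes (`m = 0`) can be built,
#'   though the diameter formula accepts any pair.
#' @param length tube length in nm.
#' @param lattice_a graphene lattice constant in nm (default 0.246,
#'   corresponding to a 0.142 nm C-C bond).
#' @return object of class `cnt_spec`.
#' @export
cnt_spec <- function(n = 10, m = 0, length = 4.1, lattice_a = 0.246) {
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("invalid-spec: chirality index n must be a positive integer")
  if (!is.numeric(m) || m < 0 || m != round(m))
    stop("invalid-spec: chirality index m must be a non-negative integer")
  if (length <= 0) stop("invalid-spec: tube length must be positive")
  if (lattice_a <= 0) stop("invalid-spec: lattice constant must be positive")
  structure(list(n = as.integer(n), m = as.integer(m), length = length,
                 lattice_a = lattice_a), class = "cnt_spec")
}

#' Polymer grafting specification
#'
#' @param n_chains number of grafted chains (the reference systems use
#'   4, 8 or 16, but any non-negative count is accepted).
#' @param n_monomers ethylene-oxide monomers per chain (default 18).
#' @param area sidewall area in nm2 used to derive the grafting density.
#' @param terminal end-group label (methoxy).
#' @return object of class `graft_spec` with the derived density `sigma`
#'   (chains per nm2) satisfying `sigma * area == n_chains` exactly.
#' @export
graft_spec <- function(n_chains, n_monomers = 18, area, terminal = "methoxy") {
  if (n_chains < 0 || n_chains != round(n_chains))
    stop("invalid-spec: n_chains must be a non-negative integer")
  if (n_monomers < 1) stop("invalid-spec: n_monomers must be >= 1")
  if (area <= 0) stop("invalid-spec: area must be positive")
  structure(list(n_chains = as.integer(n_chains),
                 n_monomers = as.integer(n_monomers),
                 sigma = n_chains / area, area = area, terminal = terminal),
            class = "graft_spec")
}

#' Homopeptide specification
#'
#' @param residue one of "GLY", "SER", "VAL".
#' @param n_residues chain length (default 24).
#' @param conformation backbone dihedral pair c(phi, psi) in degrees used
#'   for every residue; default extended beta (-135, 135).
#' @return object of class `peptide_spec`.  The N-terminus is always built
#'   protonated (NH3+) and the C-terminus dissociated (COO-).
#' @export
peptide_spec <- function(residue, n_residues = 24,
                         conformation = c(-135, 135)) {
  residue <- toupper(residue)
  if (!residue %in% c("GLY", "SER", "VAL"))
    stop("invalid-spec: residue must be one of GLY, SER, VAL")
  if (n_residues < 1) stop("invalid-spec: n_residues must be >= 1")
  structure(list(residue = residue, n_residues = as.integer(n_residues),
                 n_terminus = "protonated", c_terminus = "dissociated",
                 conformation = conformation), class = "peptide_spec")
}

#' Solvent specification
#'
#' @param box_edge cubic box edge in nm.
#' @param water_number_density molecules per nm3 (default 33.3, bulk water).
#' @param nacl_mass_conc NaCl mass concentration in g/dm3 (0 or 9.0 for the
#'   physiological-saline systems).
#' @param exclusion_radius minimum allowed distance from a water oxygen to
#'   any solute heavy atom, nm.
#' @return object of class `solvent_spec`.
#' @export
solvent_spec <- function(box_edge, water_number_density = 33.3,
                         nacl_mass_conc = 0, exclusion_radius = 0.28) {
  if (box_edge <= 0) stop("invalid-spec: box_edge must be positive")
  if (nacl_mass_conc < 0) stop("invalid-spec: nacl_mass_conc must be >= 0")
  structure(list(box_edge = box_edge,
                 water_number_density = water_number_density,
                 nacl_mass_conc = nacl_mass_conc,
                 exclusion_radius = exclusion_radius), class = "solvent_spec")
}

## ---- setup arithmetic ------------------------------------------------------

#' Nanotube diameter from chirality indices
#'
#' d = (a/pi) * sqrt(n^2 + n m + m^2).  The one-decimal rounded companion
#' value is returned alongside because the published setup numbers
#' (sidewall area, grafting densities) follow from the nominal diameter.
#'
#' @param spec a [cnt_spec()].
#' @return list with `exact` and `nominal` diameters (nm).
#' @export
cnt_diameter <- function(spec) {
  stopifnot(inherits(spec, "cnt_spec"))
  d <- (spec$lattice_a / pi) * sqrt(spec$n^2 + spec$n * spec$m + spec$m^2)
  list(exact = d, nominal = round(d, 1))
}

#' Sidewall area of an open cylinder
#' @param diameter tube diameter, nm.
#' @param length tube length, nm.
#' @return area in nm2 (pi * d * L).
#' @export
sidewall_area <- function(diameter, length) {
  if (diameter <= 0 || length <= 0)
    stop("invalid-spec: diameter and length must be positive")
  pi * diameter * length
}

#' Grafting density
#' @param n_chains number of grafted chains.
#' @param area sidewall area, nm2.
#' @return chains per nm2.
#' @export
grafting_density <- function(n_chains, area) {
  if (n_chains < 0) stop("invalid-spec: n_chains must be >= 0")
  if (area <= 0) stop("invalid-spec: area must be positive")
  n_chains / area
}

#' Kyte-Doolittle hydropathy index
#' @param residue three-letter residue code (case-insensitive).
#' @return dimensionless hydropathy value; positive = hydrophobic.
#' @export
lookup_hydropathy <- function(residue) {
  tab <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
           GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
           LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
           SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)
  key <- toupper(residue)
  if (!key %in% names(tab)) stop("unknown residue: ", residue)
  unname(tab[key])
}

## ---- carbon nanotube -------------------------------------------------------

#' Build a zigzag carbon nanotube
#'
#' Rolls a graphene sheet into an uncapped (n, 0) tube.  Atoms sit exactly
#' on the cylinder of radius d/2; the translational period along the axis
#' is sqrt(3) * a with 4n atoms per period, and as many complete periods as
#' fit in `length` are generated, centred on z = 0.  Carbons are uncharged
#' and flagged immobile (they only take part in non-bonded interactions).
#'
#' @param spec a [cnt_spec()] with m = 0.
#' @return `molsys` fragment with group label "CNT" and tube metadata
#'   (`$meta$cnt`: n, radius, z extent).
#' @export
build_cnt <- function(spec) {
  stopifnot(inherits(spec, "cnt_spec"))
  if (spec$m != 0)
    stop("unsupported-chirality: only zigzag (m = 0) tubes are built")
  a <- spec$lattice_a
  n <- spec$n
  period <- sqrt(3) * a
  if (spec$length <= period)
    stop("invalid-spec: tube length must exceed one translational period")
  n_per <- floor(spec$length / period)
  R <- n * a / (2 * pi)

  ## graphene rows within one period: (x offset in units of a, axial z)
  rows <- rbind(c(0.0, 0),
                c(0.5, a / (2 * sqrt(3))),
                c(0.5, sqrt(3) * a / 2),
                c(0.0, 2 * a / sqrt(3)))
  i <- rep(0:(n - 1), each = 4)
  xoff <- rep(rows[, 1], n)
  zrow <- rep(rows[, 2], n)
  one <- cbind(x = (i + xoff) * a, z = zrow)
  z0 <- rep(seq_len(n_per) - 1, each = nrow(one)) * period
  x <- rep(one[, "x"], n_per)
  z <- rep(one[, "z"], n_per) + z0
  theta <- 2 * pi * x / (n * a)
  z <- z - (max(z) + min(z)) / 2         # centre on the midplane

  pos <- cbind(R * cos(theta), R * sin(theta), z)
  rows_out <- lapply(seq_len(nrow(pos)), function(k)
    atom_row("C", "C", "CNT", 1L, "CNT", pos[k, ], 0, "C_aro"))
  sys <- molsys(finalize_atoms(rows_out))
  sys$meta <- list(cnt = list(n = n, radius = R, lattice_a = a,
                              length = spec$length,
                              zmin = min(z), zmax = max(z),
                              immobile = TRUE))
  sys
}

## ---- poly(ethylene oxide) --------------------------------------------------

#' Build one PEO chain
#'
#' An all-atom (-CH2-CH2-O-)n chain terminated by a methoxy group, laid out
#' on an ideal 7/2 helix (two turns per seven monomers) built along +z with
#' the anchor carbon first.  Per-monomer charges sum to zero.
#'
#' @param n_monomers ethylene-oxide repeat units.
#' @param terminal end-group label; only "methoxy" is supported.
#' @param rise helix rise per monomer, nm (default 0.28, stretched helix).
#' @return `molsys` fragment, group "PEO"; the first atom is the anchor.
#' @export
build_peo_chain <- function(n_monomers, terminal = "methoxy", rise = 0.28) {
  if (n_monomers < 1) stop("invalid-spec: n_monomers must be >= 1")
  if (terminal != "methoxy") stop("invalid-spec: unsupported terminal group")
  r_h <- 0.18                            # helix radius, nm
  dphi <- (4 * pi / 7) / 3               # per heavy atom (7/2 helix)
  dz <- rise / 3
  heavy_pos <- function(k) {
    ang <- k * dphi
    c(r_h * cos(ang), r_h * sin(ang), k * dz)
  }
  outward <- function(k) {
    ang <- k * dphi
    c(cos(ang), sin(ang), 0)
  }
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row
  hb <- 0.109                            # C-H bond, nm
  k <- 0
  for (j in seq_len(n_monomers)) {
    for (cn in c("C1", "C2")) {
      p <- heavy_pos(k); o <- outward(k)
      add(atom_row("C", cn, "PEO", 1L, "PEO", p, 0.14, "C_sp3"))
      ci <- length(rows)
      up <- rotation_matrix(pracma_cross(o, c(0, 0, 1)), 50) %*% o
      dn <- rotation_matrix(pracma_cross(o, c(0, 0, 1)), -50) %*% o
      add(atom_row("H", paste0("H", substr(cn, 2, 2), "1"), "PEO", 1L, "PEO",
                   p + hb * as.numeric(up), 0.03, "H_ap", parent = ci))
      add(atom_row("H", paste0("H", substr(cn, 2, 2), "2"), "PEO", 1L, "PEO",
                   p + hb * as.numeric(dn), 0.03, "H_ap", parent = ci))
      k <- k + 1
    }
    add(atom_row("O", "O", "PEO", 1L, "PEO", heavy_pos(k), -0.40, "O_eth"))
    k <- k + 1
  }
  ## terminal methyl on the last ether oxygen
  p <- heavy_pos(k); o <- outward(k)
  add(atom_row("C", "CT", "PEO", 1L, "PEO", p, -0.09, "C_sp3"))
  ci <- length(rows)
  for (h in 1:3) {
    d <- rotation_matrix(c(0, 0, 1), 120 * (h - 1)) %*% o
    d <- rotation_matrix(pracma_cross(as.numeric(d), c(0, 0, 1)), 35) %*% d
    add(atom_row("H", paste0("HT", h), "PEO", 1L, "PEO",
                 p + hb * as.numeric(d), 0.03, "H_ap", parent = ci))
  }
  ## parent ids refer to positions in `rows`, which equal final ids
  sys <- molsys(finalize_atoms(rows))
  sys$meta <- list(anchor = 1L)
  sys
}

## ---- grafting --------------------------------------------------------------

ring_slot_pattern <- function(n_chains, r, radius, zmin, zmax) {
  k <- n_chains / r
  Lz <- zmax - zmin
  zpos <- zmin + (seq_len(r) - 0.5) * Lz / r
  out <- NULL
  for (j in seq_len(r)) {
    ang <- 2 * pi * (seq_len(k) - 1) / k + (j - 1) * pi / k
    out <- rbind(out, cbind(angle = ang, z = zpos[j]))
  }
  out
}

min_geodesic <- function(pts, radius) {
  if (nrow(pts) < 2) return(Inf)
  dth <- outer(pts[, 1], pts[, 1], "-")
  dth <- abs(atan2(sin(dth), cos(dth)))
  dz <- outer(pts[, 2], pts[, 2], "-")
  d <- sqrt((radius * dth)^2 + dz^2)
  min(d[upper.tri(d)])
}

#' Graft PEO chains onto a nanotube sidewall
#'
#' Anchors are placed on a deterministic rings-by-angular-slots pattern
#' (r rings x k slots, r*k = n_chains, adjacent rings offset by half a
#' slot).  When `n_rings` is not given, the factorization maximizing the
#' minimum anchor-anchor geodesic distance on the cylinder is chosen, which
#' realizes "evenly distributed" as a max-min criterion.  Chains point
#' radially outward; each anchor carbon is bonded (bond record only) to the
#' nearest sidewall carbon.
#'
#' @param cnt `molsys` from [build_cnt()].
#' @param spec a [graft_spec()].
#' @param n_rings optional explicit ring count (must divide n_chains).
#' @param orientation only "radial" is supported.
#' @return combined `molsys` (CNT + PEO groups).
#' @export
graft_chains <- function(cnt, spec, n_rings = NULL, orientation = "radial") {
  stopifnot(inherits(spec, "graft_spec"))
  if (orientation != "radial") stop("invalid-spec: orientation must be radial")
  meta <- cnt$meta$cnt
  if (is.null(meta)) stop("invalid-spec: system lacks nanotube metadata")
  nc <- spec$n_chains
  if (nc == 0) return(cnt)
  capacity <- floor(1.6 * pi * 2 * meta$radius * meta$length)
  if (nc > capacity)
    stop("capacity error: ", nc, " chains exceed the ", capacity,
         " grafting sites of this sidewall")
  if (is.null(n_rings)) {
    divisors <- Filter(function(r) nc %% r == 0, seq_len(nc))
    scores <- vapply(divisors, function(r)
      min_geodesic(ring_slot_pattern(nc, r, meta$radius, meta$zmin, meta$zmax),
                   meta$radius), numeric(1))
    n_rings <- divisors[which.max(scores)]
  } else if (nc %% n_rings != 0) {
    stop("invalid-spec: n_rings must divide n_chains")
  }
  pts <- ring_slot_pattern(nc, n_rings, meta$radius, meta$zmin, meta$zmax)

  cxyz <- coords(cnt)
  parts <- list(cnt)
  anchors <- integer(nc)
  standoff <- 0.15                       # anchor C to sidewall C, nm
  offset_atoms <- nrow(cnt$atoms)
  for (i in seq_len(nc)) {
    ang <- pts[i, 1]; zz <- pts[i, 2]
    radial <- c(cos(ang), sin(ang), 0)
    apos <- c(meta$radius * cos(ang), meta$radius * sin(ang), zz)
    ## nearest sidewall carbon for the bond record
    d2 <- colSums((t(cxyz) - apos)^2)
    anchors[i] <- which.min(d2)
    chain <- build_peo_chain(spec$n_monomers, spec$terminal)
    Rm <- rotation_to(c(0, 0, 1), radial)
    xyz <- coords(chain) %*% t(Rm)
    xyz <- sweep(xyz, 2, xyz[1, ] - (apos + standoff * radial), "-")
    chain <- set_coords(chain, xyz)
    parts[[length(parts) + 1L]] <- chain
  }
  out <- do.call(merge_systems, parts)
  ## bond records: chain anchor atom -> sidewall carbon
  chain_size <- 7L * spec$n_monomers + 4L
  anchor_ids <- offset_atoms + (seq_len(nc) - 1L) * chain_size + 1L
  out$bonds <- rbind(out$bonds, data.frame(i = anchor_ids, j = anchors))
  out$meta <- cnt$meta
  out$meta$graft <- list(n_chains = nc, n_rings = n_rings,
                         sigma = spec$sigma, anchors = pts)
  out
}

## rotation taking unit vector u onto unit vector v
rotation_to <- function(u, v) {
  u <- unit(u); v <- unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    perp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(pracma_cross(u, perp))
    return(rotation_matrix(ax, 180))
  }
  ax <- pracma_cross(u, v)
  rotation_matrix(ax, rad2deg(atan2(vnorm(ax), c_)))
}
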