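GROUP_LEVELS <- c("CNT", "PEO", "PEPTIDE", "WATER", "NA", "CL")

#' Create a molecular system
#'
#' A `molsys` is the package's central container: a per-atom table with
#' positions in nm, point charges in e, Lennard-Jones parameters
#' (sigma in nm, epsilon in kJ/mol), masses in amu, plus a cubic periodic
#' box edge and the designated tube axis (z by convention).
#'
#' @param atoms data.frame with columns `id`, `element`, `name`, `group`,
#'   `resid`, `resname`, `x`, `y`, `z`, `charge`, `sigma`, `epsilon`,
#'   `mass`, `parent` (id of the bonded heavy atom for hydrogens, else NA).
#' @param box cubic box edge length in nm (NA if unset).
#' @param axis unit vector of the nanotube axis; default z.
#' @param bonds optional two-column data.frame of recorded bonds
#'   (anchor bookkeeping; no force evaluation uses it).
#' @return object of class `molsys`.
#' @export
molsys <- function(atoms, box = NA_real_, axis = c(0, 0, 1), bonds = NULL) {
  required <- c("id", "element", "name", "group", "resid", "resname",
                "x", "y", "z", "charge", "sigma", "epsilon", "mass", "parent")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(atoms$group), GROUP_LEVELS)
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(list(atoms = atoms, box = box,
                 axis = axis / sqrt(sum(axis^2)), bonds = bonds),
            class = "molsys")
}

empty_atoms <- function(n = 0) {
  data.frame(id = integer(n), element = character(n), name = character(n),
             group = character(n), resid = integer(n), resname = character(n),
             x = numeric(n), y = numeric(n), z = numeric(n),
             charge = numeric(n), sigma = numeric(n), epsilon = numeric(n),
             mass = numeric(n), parent = rep(NA_integer_, n),
             stringsAsFactors = FALSE)
}

#' @export
print.molsys <- function(x, ...) {
  cat("Molecular system:", nrow(x$atoms), "atoms\n")
  if (nrow(x$atoms) > 0) {
    tab <- table(x$atoms$group)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  box edge:", x$box, "nm; axis:", paste(signif(x$axis, 3), collapse = " "), "\n")
  cat("  total charge:", signif(sum(x$atoms$charge), 6), "e\n")
  invisible(x)
}

#' Coordinates of a system as an n x 3 matrix
#' @param sys a `molsys`.
#' @return numeric matrix with columns x, y, z (nm).
#' @export
coords <- function(sys) {
  as.matrix(sys$atoms[, c("x", "y", "z")])
}

set_coords <- function(sys, xyz) {
  sys$atoms$x <- xyz[, 1]; sys$atoms$y <- xyz[, 2]; sys$atoms$z <- xyz[, 3]
  sys
}

#' Merge molecular systems
#'
#' Concatenates atom tables, re-numbering ids consecutively and remapping
#' hydrogen parent references and bond records.
#'
#' @param ... `molsys` objects; the first one's box and axis are kept.
#' @return combined `molsys`.
#' @export
merge_systems <- function(...) {
  parts <- list(...)
  offset <- 0L
  resoff <- 0L
  atoms <- list(); bonds <- list()
  for (p in parts) {
    a <- p$atoms
    a$id <- a$id + offset
    a$parent <- a$parent + offset
    a$resid <- a$resid + resoff
    if (!is.null(p$bonds) && nrow(p$bonds) > 0)
      bonds[[length(bonds) + 1L]] <- p$bonds + offset
    atoms[[length(atoms) + 1L]] <- a
    offset <- offset + nrow(a)
    if (nrow(a) > 0) resoff <- max(a$resid)
  }
  b <- if (length(bonds) > 0) do.call(rbind, bonds) else NULL
  out <- molsys(do.call(rbind, atoms), box = parts[[1]]$box,
                axis = parts[[1]]$axis, bonds = b)
  meta <- list()
  for (p in parts)
    if (!is.null(p$meta))
      meta <- utils::modifyList(p$meta, meta)    # earlier parts win
  if (length(meta) > 0) out$meta <- meta
  out
}

## ---- small geometry kernel -------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vnorm(v)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (normalized internally).
#' @param angle_deg rotation angle, degrees, right-handed.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- unit(axis); th <- deg2rad(angle_deg)
  c1 <- cos(th); s1 <- sin(th); t1 <- 1 - c1
  x <- u[1]; y <- u[2]; z <- u[3]
  matrix(c(t1 * x * x + c1,     t1 * x * y - s1 * z, t1 * x * z + s1 * y,
           t1 * x * y + s1 * z, t1 * y * y + c1,     t1 * y * z - s1 * x,
           t1 * x * z - s1 * y, t1 * y * z + s1 * x, t1 * z * z + c1),
         nrow = 3, byrow = TRUE)
}

## NeRF internal-coordinate placement: position atom D bonded to C given
## bond length |CD|, angle B-C-D and torsion A-B-C-D.
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  th <- deg2rad(angle_deg); ph <- -deg2rad(dihedral_deg)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Torsion angle of four points
#' @param p1,p2,p3,p4 3-vectors (nm).
#' @return dihedral in degrees, IUPAC sign convention, range (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

## angle at p2 in degrees
bend_angle <- function(p1, p2, p3) {
  v1 <- unit(p1 - p2); v2 <- unit(p3 - p2)
  rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2)))))
}

## all pairwise squared distances between rows of A and rows of B
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

## minimum-image displacement components for a cubic box
min_image <- function(d, box) d - box * round(d / box)
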