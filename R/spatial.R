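## Geometric statistics on trajectories: cylindrical density profiles
## around the tube axis, radial distribution functions, centre-of-mass
## distance from the sidewall, radius of gyration with axial component,
## and least-squares superposition / RMSD series.

#' Time-averaged cylindrical density profile
#'
#' Number density of the selected atoms in concentric cylindrical shells
#' of uniform radial thickness around the z axis, restricted to an axial
#' slab of length `shell_length` centred on the tube midpoint.
#'
#' @param traj a `trajectory`.
#' @param selection integer atom indices (see [select_atoms()]).
#' @param bin_width radial bin width, nm (default 0.1).
#' @param shell_length axial slab length, nm (default 4.1).
#' @param r_max outer radius, nm (default: half the box edge, or the
#'   largest radial distance observed).
#' @return object of class `cyl_profile`: bin edges/centres, raw mean
#'   atoms per shell (`counts`) and number densities per nm3 (`values`),
#'   with the sidewall radius annotated when known.
#' @export
cylindrical_density <- function(traj, selection, bin_width = 0.1,
                                shell_length = 4.1, r_max = NULL) {
  if (n_frames(traj) == 0) stop("empty-input error: trajectory has no frames")
  if (length(selection) == 0) stop("empty-input error: empty selection")
  zmid <- if (!is.null(traj$topology$meta$cnt))
    (traj$topology$meta$cnt$zmin + traj$topology$meta$cnt$zmax) / 2 else 0
  if (is.null(r_max)) {
    r_max <- if (!is.na(traj$topology$box)) traj$topology$box / 2 else {
      max(vapply(traj$frames, function(f) {
        p <- f[selection, , drop = FALSE]
        max(sqrt(p[, 1]^2 + p[, 2]^2))
      }, numeric(1)))
    }
  }
  edges <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(edges) - 1
  acc <- numeric(nb)
  for (f in traj$frames) {
    p <- f[selection, , drop = FALSE]
    inslab <- abs(p[, 3] - zmid) <= shell_length / 2
    rho <- sqrt(p[inslab, 1]^2 + p[inslab, 2]^2)
    acc <- acc + tabulate(findInterval(rho, edges, rightmost.closed = FALSE),
                          nbins = nb)
  }
  counts <- acc / n_frames(traj)
  vols <- pi * (edges[-1]^2 - edges[-length(edges)]^2) * shell_length
  structure(list(bin_edges = edges,
                 bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, values = counts / vols,
                 shell_length = shell_length, bin_width = bin_width,
                 sidewall_radius = traj$topology$meta$cnt$radius,
                 n_frames = n_frames(traj), selection = selection),
            class = "cyl_profile")
}

#' Radial distribution function
#'
#' g(r) between two selections under the minimum-image convention in the
#' cubic box, frame-averaged and normalized so an ideal gas gives 1.
#'
#' @param traj a `trajectory` with a box.
#' @param selection_A,selection_B integer index vectors.  For a self-RDF
#'   pass the same vector; self-pairs are excluded.
#' @param dr bin width, nm.
#' @param r_max maximum distance, nm; must not exceed half the box edge.
#' @return object of class `rdf_result`: bin centres, g(r), raw pair
#'   counts and the normalization used.
#' @export
rdf <- function(traj, selection_A, selection_B, dr = 0.02, r_max = NULL) {
  if (n_frames(traj) == 0) stop("empty-input error: trajectory has no frames")
  box <- traj$topology$box
  if (is.na(box)) stop("range error: RDF requires a periodic box")
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9)
    stop("range error: r_max exceeds half the box edge")
  self_rdf <- identical(sort(selection_A), sort(selection_B))
  nA <- length(selection_A); nB <- length(selection_B)
  n_pairs <- if (self_rdf) nA * (nA - 1) else nA * nB
  if (n_pairs == 0) stop("empty-input error: no pairs in RDF selections")
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1
  acc <- numeric(nb)
  for (f in traj$frames) {
    A <- f[selection_A, , drop = FALSE]
    B <- f[selection_B, , drop = FALSE]
    dx <- min_image(outer(A[, 1], B[, 1], "-"), box)
    dy <- min_image(outer(A[, 2], B[, 2], "-"), box)
    dz <- min_image(outer(A[, 3], B[, 3], "-"), box)
    d <- sqrt(dx^2 + dy^2 + dz^2)
    if (self_rdf) d <- d[row(d) != col(d)]
    d <- d[d < r_max]
    acc <- acc + tabulate(findInterval(d, edges), nbins = nb)
  }
  counts <- acc / n_frames(traj)
  shell_vol <- 4 * pi * ((edges[-1] + edges[-length(edges)]) / 2)^2 * dr
  norm <- n_pairs * shell_vol / box^3
  structure(list(bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 g = counts / norm, counts = counts, normalization = norm,
                 dr = dr, r_max = r_max, n_frames = n_frames(traj)),
            class = "rdf_result")
}

com_radial <- function(frame, selection, masses) {
  m <- masses[selection]
  if (sum(m) <= 0) stop("invalid-mass error: zero total mass in selection")
  com <- colSums(frame[selection, , drop = FALSE] * m) / sum(m)
  sqrt(com[1]^2 + com[2]^2)
}

#' Centre-of-mass distance from the sidewall
#'
#' D(t) = rho_COM(t) - cnt_radius, signed (a negative value would indicate
#' penetration past the wall and is reported, not clipped).
#'
#' @param traj a `trajectory`.
#' @param selection atom indices whose COM is tracked.
#' @param cnt_radius sidewall radius, nm (default: from tube metadata).
#' @return list with per-frame `D`, `mean` and `sd`.
#' @export
com_sidewall_distance <- function(traj, selection, cnt_radius = NULL) {
  if (n_frames(traj) == 0) stop("empty-input error: trajectory has no frames")
  if (length(selection) == 0) stop("empty-input error: empty selection")
  if (is.null(cnt_radius)) cnt_radius <- traj$topology$meta$cnt$radius
  if (is.null(cnt_radius)) stop("invalid-spec: sidewall radius unknown")
  masses <- traj$topology$atoms$mass
  D <- vapply(traj$frames, function(f)
    com_radial(f, selection, masses) - cnt_radius, numeric(1))
  list(D = D, mean = mean(D), sd = stats::sd(D))
}

#' Radius of gyration with per-axis components
#'
#' Rg^2 = sum(m_i |r_i - r_COM|^2) / sum(m_i); the per-coordinate
#' components satisfy Rg^2 = Rg_x^2 + Rg_y^2 + Rg_z^2 exactly.
#'
#' @param frame n x 3 coordinate matrix.
#' @param selection atom indices.
#' @param masses per-atom masses (full-length vector).
#' @param mass_weighted use masses (default) or unit weights.
#' @return named vector (Rg, Rg_x, Rg_y, Rg_z), nm.
#' @export
gyration <- function(frame, selection, masses = NULL, mass_weighted = TRUE) {
  if (length(selection) == 0) stop("empty-input error: empty selection")
  p <- frame[selection, , drop = FALSE]
  m <- if (mass_weighted && !is.null(masses)) masses[selection]
       else rep(1, nrow(p))
  if (sum(m) <= 0) stop("invalid-mass error: zero total mass")
  com <- colSums(p * m) / sum(m)
  d <- sweep(p, 2, com)
  comp2 <- colSums(d^2 * m) / sum(m)
  c(Rg = sqrt(sum(comp2)), Rg_x = sqrt(comp2[[1]]),
    Rg_y = sqrt(comp2[[2]]), Rg_z = sqrt(comp2[[3]]))
}

#' Per-frame conformation descriptors
#'
#' Convenience wrapper producing the published table layout: per-frame and
#' mean +/- sd of D (COM-sidewall distance), Rg and its axis components.
#'
#' @param traj a `trajectory`.
#' @param selection atom indices (all peptide atoms by convention).
#' @param cnt_radius sidewall radius, nm (default from metadata).
#' @return data.frame with columns frame, D, Rg, Rg_x, Rg_y, Rg_z and a
#'   `summary` attribute holding means and sds.
#' @export
conformation_record <- function(traj, selection, cnt_radius = NULL) {
  d <- com_sidewall_distance(traj, selection, cnt_radius)
  masses <- traj$topology$atoms$mass
  g <- t(vapply(traj$frames, gyration, numeric(4),
                selection = selection, masses = masses))
  out <- data.frame(frame = seq_len(n_frames(traj)), D = d$D,
                    Rg = g[, 1], Rg_x = g[, 2], Rg_y = g[, 3], Rg_z = g[, 4])
  attr(out, "summary") <- data.frame(
    quantity = c("D", "Rg", "Rg_x", "Rg_y", "Rg_z"),
    mean = c(d$mean, colMeans(g)),
    sd = c(d$sd, apply(g, 2, stats::sd)))
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation minimizing the (optionally
#' weighted) RMSD between two coordinate sets; reflections are rejected by
#' sign correction of the smallest singular value.
#'
#' @param mobile,reference n x 3 matrices, equal n >= 3.
#' @param weights optional per-atom weights.
#' @return list(rotation, translation, rmsd) such that
#'   `mobile %*% t(rotation) + translation` superposes onto the reference.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (n != nrow(reference) || n < 3)
    stop("degenerate-superposition error: need equal atom counts >= 3")
  w <- if (is.null(weights)) rep(1, n) else weights
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm); Rf <- sweep(reference, 2, cr)
  H <- t(M * w) %*% Rf
  sv <- svd(H)
  if (min(sv$d) < 1e-12 && sv$d[2] < 1e-12)
    stop("degenerate-superposition error: collinear atom set")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  moved <- M %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((moved - Rf)^2)))
  list(rotation = rot, translation = cr - as.numeric(rot %*% cm),
       rmsd = rmsd)
}

rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series
#'
#' Unweighted root-mean-square deviation of the selected atoms from a
#' reference frame, after optional least-squares superposition.  The
#' reported series is unweighted even when superposition weighting is
#' requested, matching the usual definition.
#'
#' @param traj a `trajectory`.
#' @param selection atom indices.
#' @param reference reference frame index (default 1).
#' @param superpose_frames superpose each frame first (default TRUE).
#' @param mass_weighted weight the superposition fit by mass.
#' @return object of class `rmsd_series`: times (ps) and rmsd (nm).
#' @export
rmsd_series <- function(traj, selection, reference = 1L,
                        superpose_frames = TRUE, mass_weighted = FALSE) {
  if (n_frames(traj) == 0) stop("empty-input error: trajectory has no frames")
  if (reference < 1 || reference > n_frames(traj))
    stop("empty-input error: reference frame does not exist")
  ref <- traj$frames[[reference]][selection, , drop = FALSE]
  w <- if (mass_weighted) traj$topology$atoms$mass[selection] else NULL
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    mob <- traj$frames[[i]][selection, , drop = FALSE]
    if (superpose_frames) {
      fit <- superpose(mob, ref, weights = w)
      moved <- mob %*% t(fit$rotation)
      moved <- sweep(moved, 2, fit$translation, "+")
      rmsd_plain(moved, ref)
    } else {
      rmsd_plain(mob, ref)
    }
  }, numeric(1))
  structure(list(times = traj$times, rmsd = vals, reference = reference,
                 superposed = superpose_frames), class = "rmsd_series")
}

#' Write a profile, RDF or RMSD series as TSV with a commented header
#'
#' @param x a `cyl_profile`, `rdf_result` or `rmsd_series`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_analysis_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "cyl_profile")) {
    writeLines(sprintf("# cylindrical profile: bin_width=%g nm shell_length=%g nm frames=%d",
                       x$bin_width, x$shell_length, x$n_frames), con)
    if (!is.null(x$sidewall_radius))
      writeLines(sprintf("# sidewall_radius=%g nm", x$sidewall_radius), con)
    utils::write.table(data.frame(r = x$bin_mid, count = x$counts,
                                  density = x$values),
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "rdf_result")) {
    writeLines(sprintf("# rdf: dr=%g nm r_max=%g nm frames=%d",
                       x$dr, x$r_max, x$n_frames), con)
    utils::write.table(data.frame(r = x$bin_mid, g = x$g, count = x$counts),
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "rmsd_series")) {
    writeLines(sprintf("# rmsd series: reference=%d superposed=%s",
                       x$reference, x$superposed), con)
    utils::write.table(data.frame(time_ps = x$times, rmsd_nm = x$rmsd),
                       con, sep = "\t", row.names = FALSE, quote = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
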