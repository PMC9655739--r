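## Synthetic configuration ensembles with known statistical ground truth.
## These replace molecular-dynamics trajectories so that every estimator in
## the analysis stages can be validated against the generating parameters.

#' Trajectory container
#'
#' Ordered coordinate frames sharing one topology.
#'
#' @param topology a `molsys`.
#' @param frames list of n_atoms x 3 coordinate matrices (nm).
#' @param times frame times in ps (default 10 ps spacing); must be strictly
#'   increasing.
#' @param ground_truth optional generating-model record for synthetic
#'   ensembles.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, times = NULL, ground_truth = NULL) {
  n_atoms <- nrow(topology$atoms)
  for (f in frames)
    if (nrow(f) != n_atoms)
      stop("frame atom count ", nrow(f), " does not match topology ", n_atoms)
  if (is.null(times)) times <- (seq_along(frames) - 1) * 10
  if (length(times) != length(frames))
    stop("times length must equal frame count")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = times,
                 ground_truth = ground_truth), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,",
      nrow(x$topology$atoms), "atoms\n")
  if (!is.null(x$ground_truth)) cat("  (synthetic; ground truth attached)\n")
  invisible(x)
}

#' Number of frames
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Ensemble statistical model
#'
#' Describes the ground truth for a synthetic configuration ensemble: the
#' peptide centre of mass is placed at a radial distance drawn from a
#' normal distribution truncated below at the sidewall radius, with uniform
#' axial/angular position, plus per-atom Gaussian jitter; water (when
#' present) is resampled each frame from an inhomogeneous density
#' bulk * g(rho).
#'
#' @param com_radial_mean rho0, mean radial COM distance from the axis (nm).
#' @param com_radial_sd sigma_rho (nm, >= 0).
#' @param axial_uniform place the COM uniformly along the tube axis.
#' @param internal_jitter_sd per-atom Gaussian jitter sd (nm).
#' @param hbond_occupancy probability per designated donor-acceptor pair.
#' @param water_profile function g(rho) >= 0, dimensionless multiplier on
#'   the bulk density; NULL = leave water untouched.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return object of class `ensemble_model`.
#' @export
ensemble_model <- function(com_radial_mean, com_radial_sd = 0,
                           axial_uniform = TRUE, internal_jitter_sd = 0,
                           hbond_occupancy = NA, water_profile = NULL,
                           n_frames = 100, seed = 0) {
  if (com_radial_sd < 0) stop("invalid-model: com_radial_sd must be >= 0")
  if (!is.na(hbond_occupancy) &&
      (hbond_occupancy < 0 || hbond_occupancy > 1))
    stop("invalid-model: hbond_occupancy must lie in [0, 1]")
  structure(list(com_radial_mean = com_radial_mean,
                 com_radial_sd = com_radial_sd,
                 axial_uniform = axial_uniform,
                 internal_jitter_sd = internal_jitter_sd,
                 hbond_occupancy = hbond_occupancy,
                 water_profile = water_profile,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "ensemble_model")
}

#' Generate a synthetic ensemble for a built system
#'
#' @param system `molsys` containing PEPTIDE and CNT groups.
#' @param model an [ensemble_model()].
#' @return `trajectory` with the model attached as ground truth.
#' @export
generate_ensemble <- function(system, model) {
  stopifnot(inherits(model, "ensemble_model"))
  a <- system$atoms
  pep <- which(a$group == "PEPTIDE")
  if (length(pep) == 0 || !any(a$group == "CNT"))
    stop("invalid-spec: system must contain PEPTIDE and CNT groups")
  radius <- system$meta$cnt$radius
  if (is.null(radius)) radius <- 0
  if (model$com_radial_mean < radius)
    stop("invalid-model: com_radial_mean lies inside the sidewall radius")
  zr <- c(system$meta$cnt$zmin, system$meta$cnt$zmax)
  if (any(is.na(zr)) || is.null(system$meta$cnt)) zr <- c(-0.5, 0.5)
  wat <- which(a$group == "WATER")
  wat_o <- wat[a$element[wat] == "O"]
  box <- system$box

  xyz0 <- coords(system)
  masses <- a$mass[pep]
  pxyz0 <- sweep(xyz0[pep, , drop = FALSE], 2,
                 colSums(xyz0[pep, , drop = FALSE] * masses) / sum(masses))

  gmax <- NULL
  if (!is.null(model$water_profile)) {
    if (is.na(box)) stop("invalid-model: water resampling requires a box")
    rg <- seq(0, box, length.out = 512)
    gmax <- max(vapply(rg, model$water_profile, numeric(1)))
    if (gmax <= 0) stop("invalid-model: water profile is identically zero")
  }

  set.seed(model$seed)
  frames <- vector("list", model$n_frames)
  for (fi in seq_len(model$n_frames)) {
    xyz <- xyz0
    ## rigid peptide placement
    rho <- if (model$com_radial_sd == 0) model$com_radial_mean else {
      repeat {
        r <- rnorm(1, model$com_radial_mean, model$com_radial_sd)
        if (r >= radius) break
      }
      r
    }
    th <- runif(1, 0, 2 * pi)
    zz <- if (model$axial_uniform) runif(1, zr[1], zr[2]) else 0
    com <- c(rho * cos(th), rho * sin(th), zz)
    p <- sweep(pxyz0, 2, com, "+")
    if (model$internal_jitter_sd > 0)
      p <- p + matrix(rnorm(length(p), 0, model$internal_jitter_sd), ncol = 3)
    xyz[pep, ] <- p
    ## water resampling from the inhomogeneous field
    if (!is.null(model$water_profile) && length(wat_o) > 0) {
      for (oi in wat_o) {
        repeat {
          cand <- runif(3, -box / 2, box / 2)
          g <- model$water_profile(sqrt(cand[1]^2 + cand[2]^2))
          if (runif(1) < g / gmax) break
        }
        mol <- which(a$group == "WATER" & a$resid == a$resid[oi])
        shift <- cand - xyz0[oi, ]
        xyz[mol, ] <- sweep(xyz0[mol, , drop = FALSE], 2, shift, "+")
      }
    }
    frames[[fi]] <- xyz
  }
  trajectory(system, frames, ground_truth = model)
}

#' Generate a minimal hydrogen-bond ensemble
#'
#' `n_pairs` donor-hydrogen-acceptor triples on a 1 nm grid; in each frame
#' each pair independently sits inside the geometric criterion (collinear,
#' donor-acceptor distance 0.29 nm) with probability p, otherwise outside
#' it (0.45 nm).  Expected detected count per frame is p * n_pairs.
#'
#' @param n_pairs number of donor-acceptor pairs.
#' @param p occupancy probability in [0, 1].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param acceptor_group group label for the acceptors (default "WATER",
#'   so detected bonds classify as peptide-water).
#' @return `trajectory` with ground truth list(p, n_pairs).
#' @export
generate_hbond_ensemble <- function(n_pairs, p, n_frames, seed = 0,
                                    acceptor_group = "WATER") {
  if (p < 0 || p > 1) stop("invalid-model: p must lie in [0, 1]")
  rows <- list()
  side <- ceiling(sqrt(n_pairs))
  for (i in seq_len(n_pairs)) {
    gx <- ((i - 1) %% side) * 1.0
    gy <- ((i - 1) %/% side) * 1.0
    o <- c(gx, gy, 0)
    rows[[length(rows) + 1L]] <-
      atom_row("O", "OD", "PEPTIDE", i, "DON", o, -0.683, "O_oh")
    iO <- length(rows)
    rows[[length(rows) + 1L]] <-
      atom_row("H", "HD", "PEPTIDE", i, "DON", o + c(0.1, 0, 0), 0.418,
               "H_pol", parent = iO)
    rows[[length(rows) + 1L]] <-
      atom_row("O", "OA", acceptor_group, i, "ACC", o + c(0.29, 0, 0),
               -0.834, "O_w")
  }
  top <- molsys(finalize_atoms(rows))
  xyz0 <- coords(top)
  acc <- seq(3, 3 * n_pairs, by = 3)
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    xyz <- xyz0
    bound <- runif(n_pairs) < p
    xyz[acc, 1] <- xyz[acc, 1] - 0.29 + ifelse(bound, 0.29, 0.45)
    frames[[fi]] <- xyz
  }
  trajectory(top, frames,
             ground_truth = list(p = p, n_pairs = n_pairs))
}

#' Ideal-gas frames (null model for density and RDF estimators)
#'
#' @param box cubic box edge, nm.
#' @param n_atoms number of point atoms (>= 2).
#' @param n_frames number of frames (0 gives an empty trajectory).
#' @param seed integer seed.
#' @return `trajectory` of i.i.d. uniform positions in the centred box.
#' @export
ideal_gas_frames <- function(box, n_atoms, n_frames, seed = 0) {
  if (n_atoms < 2) stop("invalid-spec: n_atoms must be >= 2")
  rows <- lapply(seq_len(n_atoms), function(i)
    atom_row("O", "GAS", "WATER", i, "GAS", c(0, 0, 0), 0, "O_w"))
  top <- molsys(finalize_atoms(rows), box = box)
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames))
    frames[[fi]] <- matrix(runif(3 * n_atoms, -box / 2, box / 2), ncol = 3)
  trajectory(top, frames,
             ground_truth = list(density = n_atoms / box^3))
}
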