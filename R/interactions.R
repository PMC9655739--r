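## Hydrogen-bond detection and classification with the geometric
## distance-angle criterion, sodium-bridge detection, backbone dihedrals,
## and a pattern-based secondary-structure assignment built on backbone
## hydrogen-bond patterns.

#' Geometric hydrogen-bond criterion
#'
#' A bond exists when the donor-acceptor distance is at most
#' `max_da_distance` and the deviation from linearity is at most
#' `max_angle_deviation`.  Two conventions for the angular deviation are
#' offered (they differ at the margins): `"DA-DH"` (default) measures the
#' angle between the D->H and D->A vectors; `"DHA"` measures
#' 180 - angle(D-H...A).
#'
#' @param max_da_distance nm (default 0.35).
#' @param max_angle_deviation degrees (default 30).
#' @param convention "DA-DH" or "DHA".
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 0.35, max_angle_deviation = 30,
                            convention = c("DA-DH", "DHA")) {
  if (max_da_distance <= 0 || max_angle_deviation <= 0)
    stop("invalid-spec: criterion thresholds must be positive")
  structure(list(max_da_distance = max_da_distance,
                 max_angle_deviation = max_angle_deviation,
                 convention = match.arg(convention)),
            class = "hbond_criterion")
}

#' Donor/acceptor chemistry of a system
#'
#' Donors are hydrogens covalently bonded (via the `parent` column, see
#' [derive_parents()]) to N or O; acceptors are all oxygen atoms (carbonyl,
#' carboxylate, hydroxyl, ether, water).  PEO therefore contributes
#' acceptors only; nanotube carbons contribute neither.
#'
#' @param sys a `molsys`.
#' @return list with `donors` (matrix: donor atom, hydrogen atom) and
#'   `acceptors` (atom indices).
#' @export
hbond_topology <- function(sys) {
  a <- sys$atoms
  h <- which(a$element == "H")
  par <- a$parent[h]
  donor_h <- h[!is.na(par) & a$element[pmax(par, 1)] %in% c("N", "O")]
  donors <- cbind(donor = a$parent[donor_h], hydrogen = donor_h)
  acceptors <- which(a$element == "O")
  list(donors = donors, acceptors = acceptors)
}

hbond_angle_dev <- function(D, H, A, convention) {
  if (convention == "DA-DH") {
    v1 <- H - D; v2 <- A - D
    acos(pmin(1, pmax(-1,
      rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))))) *
      180 / pi
  } else {
    v1 <- D - H; v2 <- A - H
    180 - acos(pmin(1, pmax(-1,
      rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))))) *
      180 / pi
  }
}

#' Detect hydrogen bonds in one frame
#'
#' @param frame n x 3 coordinate matrix (nm).
#' @param donors two-column matrix (donor atom index, hydrogen atom index).
#' @param acceptors acceptor atom indices.
#' @param criterion an [hbond_criterion()].
#' @param sys optional `molsys` used to attach group-pair categories.
#' @param method "grid" (cell list, default) or "brute" (all pairs); both
#'   return identical record sets.
#' @return data.frame: donor, hydrogen, acceptor, d_DA (nm), angle_dev
#'   (degrees) and, when `sys` is given, `category`.
#' @export
detect_hbonds <- function(frame, donors, hydrogens = NULL, acceptors,
                          criterion = hbond_criterion(), sys = NULL,
                          method = c("grid", "brute")) {
  method <- match.arg(method)
  if (!is.null(hydrogens)) donors <- cbind(donor = donors, hydrogen = hydrogens)
  if (is.null(dim(donors))) donors <- matrix(donors, ncol = 2)
  if (any(is.na(donors[, 1])))
    stop("topology error: hydrogen without a bonded donor")
  cut <- criterion$max_da_distance
  nd <- nrow(donors)
  if (nd == 0 || length(acceptors) == 0)
    return(empty_hbond_records())
  Dxyz <- frame[donors[, 1], , drop = FALSE]
  Axyz <- frame[acceptors, , drop = FALSE]

  if (method == "brute") {
    d2 <- cross_dist2(Dxyz, Axyz)
    hits <- which(d2 <= cut^2, arr.ind = TRUE)
  } else {
    origin <- apply(rbind(Dxyz, Axyz), 2, min)
    cellA <- floor(sweep(Axyz, 2, origin) / cut)
    keyA <- paste(cellA[, 1], cellA[, 2], cellA[, 3], sep = ",")
    amap <- split(seq_along(acceptors), keyA)
    cellD <- floor(sweep(Dxyz, 2, origin) / cut)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    hits_list <- vector("list", nd)
    for (i in seq_len(nd)) {
      keys <- paste(cellD[i, 1] + offs[, 1], cellD[i, 2] + offs[, 2],
                    cellD[i, 3] + offs[, 3], sep = ",")
      cand <- unlist(amap[keys], use.names = FALSE)
      if (length(cand) == 0) next
      d2 <- colSums((t(Axyz[cand, , drop = FALSE]) - Dxyz[i, ])^2)
      ok <- cand[d2 <= cut^2]
      if (length(ok) > 0)
        hits_list[[i]] <- cbind(row = i, col = ok)
    }
    hits <- do.call(rbind, hits_list)
    if (is.null(hits)) hits <- matrix(integer(0), ncol = 2,
                                      dimnames = list(NULL, c("row", "col")))
  }
  if (nrow(hits) == 0) return(empty_hbond_records())
  di <- hits[, 1]; ai <- hits[, 2]
  keep <- donors[di, 1] != acceptors[ai]
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0) return(empty_hbond_records())
  D <- frame[donors[di, 1], , drop = FALSE]
  H <- frame[donors[di, 2], , drop = FALSE]
  A <- frame[acceptors[ai], , drop = FALSE]
  dev <- hbond_angle_dev(D, H, A, criterion$convention)
  dda <- sqrt(rowSums((A - D)^2))
  ok <- dev <= criterion$max_angle_deviation
  rec <- data.frame(donor = donors[di, 1][ok], hydrogen = donors[di, 2][ok],
                    acceptor = acceptors[ai][ok], d_DA = dda[ok],
                    angle_dev = dev[ok])
  rec <- rec[order(rec$donor, rec$hydrogen, rec$acceptor), , drop = FALSE]
  rownames(rec) <- NULL
  if (!is.null(sys)) rec$category <- hbond_category(sys, rec)
  rec
}

empty_hbond_records <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0),
             acceptor = integer(0), d_DA = numeric(0), angle_dev = numeric(0))
}

HBOND_CATEGORIES <- c("intra-peptide", "peptide-water", "peptide-PEO",
                      "PEO-water", "other")

hbond_category <- function(sys, rec) {
  gd <- sys$atoms$group[rec$donor]
  ga <- sys$atoms$group[rec$acceptor]
  pair <- paste(pmin(gd, ga), pmax(gd, ga))
  out <- rep("other", nrow(rec))
  out[gd == "PEPTIDE" & ga == "PEPTIDE"] <- "intra-peptide"
  out[pair == "PEPTIDE WATER"] <- "peptide-water"
  out[pair == "PEO PEPTIDE"] <- "peptide-PEO"
  out[pair == "PEO WATER"] <- "PEO-water"
  out
}

#' Time-averaged hydrogen-bond counts by category
#'
#' @param traj a `trajectory`.
#' @param criterion an [hbond_criterion()].
#' @param topology optional list from [hbond_topology()] (derived from the
#'   trajectory topology when omitted).
#' @return data.frame with category, mean count per frame and sd.
#' @export
hbond_summary <- function(traj, criterion = hbond_criterion(),
                          topology = NULL) {
  if (n_frames(traj) == 0) stop("empty-input error: trajectory has no frames")
  if (is.null(topology)) topology <- hbond_topology(traj$topology)
  counts <- matrix(0, n_frames(traj), length(HBOND_CATEGORIES),
                   dimnames = list(NULL, HBOND_CATEGORIES))
  for (fi in seq_len(n_frames(traj))) {
    rec <- detect_hbonds(traj$frames[[fi]], topology$donors,
                         acceptors = topology$acceptors,
                         criterion = criterion, sys = traj$topology)
    if (nrow(rec) > 0) {
      tb <- table(factor(rec$category, levels = HBOND_CATEGORIES))
      counts[fi, ] <- as.numeric(tb)
    }
  }
  data.frame(category = HBOND_CATEGORIES,
             mean = colMeans(counts),
             sd = apply(counts, 2, stats::sd),
             row.names = NULL)
}

#' Detect sodium bridges
#'
#' A cation is counted as a bridge when it lies within `cutoff` of at
#' least one PEO oxygen and at least one peptide oxygen simultaneously.
#'
#' @param frame n x 3 coordinate matrix.
#' @param cations cation atom indices.
#' @param o_peo PEO oxygen indices.
#' @param o_pep peptide oxygen indices.
#' @param cutoff coordination cutoff, nm (default 0.32, the typical first
#'   minimum of Na+-O pair distributions).
#' @return list with `count` and a data.frame of (cation, o_peo, o_pep)
#'   triples (nearest partner of each kind per bridging cation).
#' @export
detect_ion_bridges <- function(frame, cations, o_peo, o_pep, cutoff = 0.32) {
  if (cutoff <= 0) stop("invalid-spec: cutoff must be positive")
  if (length(cations) == 0 || length(o_peo) == 0 || length(o_pep) == 0)
    return(list(count = 0L, triples = data.frame(cation = integer(0),
                                                 o_peo = integer(0),
                                                 o_pep = integer(0))))
  C <- frame[cations, , drop = FALSE]
  d2_peo <- cross_dist2(C, frame[o_peo, , drop = FALSE])
  d2_pep <- cross_dist2(C, frame[o_pep, , drop = FALSE])
  near_peo <- d2_peo <= cutoff^2
  near_pep <- d2_pep <= cutoff^2
  is_bridge <- apply(near_peo, 1, any) & apply(near_pep, 1, any)
  idx <- which(is_bridge)
  triples <- data.frame(
    cation = cations[idx],
    o_peo = o_peo[apply(d2_peo[idx, , drop = FALSE], 1, which.min)],
    o_pep = o_pep[apply(d2_pep[idx, , drop = FALSE], 1, which.min)])
  list(count = length(idx), triples = triples)
}

## ---- backbone dihedrals and secondary structure ----------------------------

backbone_index <- function(sys) {
  a <- sys$atoms
  pep <- a$group == "PEPTIDE"
  resids <- sort(unique(a$resid[pep]))
  get1 <- function(rid, nm) {
    i <- which(pep & a$resid == rid & a$name == nm)
    if (length(i) != 1) NA_integer_ else i
  }
  data.frame(resid = resids,
             N = vapply(resids, get1, integer(1), nm = "N"),
             CA = vapply(resids, get1, integer(1), nm = "CA"),
             C = vapply(resids, get1, integer(1), nm = "C"),
             O = vapply(resids, get1, integer(1), nm = "O"),
             H = vapply(resids, get1, integer(1), nm = "H"))
}

#' Backbone dihedral angles
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) = N(i)-CA(i)-C(i)-N(i+1), IUPAC
#' sign convention, range (-180, 180]; NA at chain ends.
#'
#' @param frame n x 3 coordinate matrix.
#' @param sys `molsys` containing a PEPTIDE group.
#' @return data.frame with resid, phi, psi (degrees).
#' @export
backbone_dihedrals <- function(frame, sys) {
  bb <- backbone_index(sys)
  n <- nrow(bb)
  if (any(is.na(bb$N) | is.na(bb$CA) | is.na(bb$C)))
    stop("topology error: missing backbone atom")
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- torsion_angle(frame[bb$C[i - 1], ], frame[bb$N[i], ],
                              frame[bb$CA[i], ], frame[bb$C[i], ])
    if (i < n)
      psi[i] <- torsion_angle(frame[bb$N[i], ], frame[bb$CA[i], ],
                              frame[bb$C[i], ], frame[bb$N[i + 1], ])
  }
  data.frame(resid = bb$resid, phi = phi, psi = psi)
}

#' Pattern-based secondary-structure assignment
#'
#' A stand-in for table-driven assignment programs, built purely on
#' backbone hydrogen-bond patterns from the geometric criterion.  Priority
#' order: two consecutive i->i+4 backbone bonds give alpha-helix (H), two
#' consecutive i->i+3 give 3-10 helix (G), paired nonlocal bridges give
#' beta-sheet (E), a lone bridge gives isolated bridge (B), an unextended
#' i->i+3/4/5 bond gives turn (T), else coil (C).
#'
#' @param frame n x 3 coordinate matrix.
#' @param sys `molsys` with a PEPTIDE group of at least 5 residues.
#' @param criterion an [hbond_criterion()].
#' @return character vector of one-letter labels (H/G/E/B/T/C), one per
#'   residue, named by resid.
#' @export
assign_secondary_structure <- function(frame, sys,
                                       criterion = hbond_criterion()) {
  bb <- backbone_index(sys)
  n <- nrow(bb)
  if (n < 5) stop("too-short error: need at least 5 residues")
  donors <- cbind(donor = bb$N, hydrogen = bb$H)
  donors <- donors[!is.na(donors[, 2]), , drop = FALSE]
  acceptors <- bb$O[!is.na(bb$O)]
  rec <- detect_hbonds(frame, donors, acceptors = acceptors,
                       criterion = criterion)
  res_of <- function(atom) bb$resid[match(atom, bb$N)]
  res_of_O <- function(atom) bb$resid[match(atom, bb$O)]
  dres <- vapply(rec$donor, res_of, numeric(1))
  ares <- vapply(rec$acceptor, res_of_O, numeric(1))
  sep <- dres - ares

  pos <- function(rid) match(rid, bb$resid)
  labels <- rep("C", n)
  turn_at <- function(nturn) {           # acceptor residues with i -> i+n bond
    sort(unique(ares[sep == nturn]))
  }
  mark <- function(idx, lab) {
    idx <- idx[idx >= 1 & idx <= n]
    free <- labels[idx] == "C" | labels[idx] == "T"
    labels[idx[free]] <<- lab
  }
  ## helices: two consecutive n-turns
  for (hel in list(c(4, "H"), c(3, "G"))) {
    nt <- as.integer(hel[1]); lab <- hel[2]
    tpos <- pos(turn_at(nt))
    consec <- tpos[(tpos + 1) %in% tpos]
    for (i in consec) mark((i + 1):(i + nt), lab)
  }
  ## nonlocal bridges
  bridge_res <- sort(unique(c(dres[abs(sep) >= 5], ares[abs(sep) >= 5])))
  bpos <- pos(bridge_res)
  if (length(bpos) > 0) {
    paired <- bpos[(bpos + 1) %in% bpos | (bpos - 1) %in% bpos]
    lone <- setdiff(bpos, paired)
    mark(paired, "E")
    mark(lone, "B")
  }
  ## turns: any n-turn without helix continuation
  for (nt in 3:5) {
    for (i in pos(turn_at(nt))) {
      span <- (i + 1):(i + nt - 1)
      span <- span[span >= 1 & span <= n]
      sel <- span[labels[span] == "C"]
      labels[sel] <- "T"
    }
  }
  names(labels) <- bb$resid
  labels
}
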