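## Shared fixture builders (constructed in code; nothing stored on disk).

## bare point-atom system with explicit per-atom parameters
point_system <- function(xyz, charge = 0, sigma = 0.3, epsilon = 0.5,
                         mass = 12, group = "CNT", element = "C",
                         box = NA_real_) {
  n <- nrow(xyz)
  a <- nanobrush:::empty_atoms(n)
  a$id <- seq_len(n)
  a$element <- rep_len(element, n)
  a$name <- paste0("X", seq_len(n))
  a$group <- rep_len(group, n)
  a$resid <- seq_len(n)
  a$resname <- "XXX"
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  a$charge <- rep_len(charge, n)
  a$sigma <- rep_len(sigma, n)
  a$epsilon <- rep_len(epsilon, n)
  a$mass <- rep_len(mass, n)
  molsys(a, box = box)
}

## small grafted system with a placed peptide, used across modules
small_grafted_system <- function(residue = "GLY", n_res = 24, n_chains = 4) {
  cnt <- build_cnt(cnt_spec(10, 0, 4.1))
  area <- sidewall_area(cnt_diameter(cnt_spec(10, 0, 4.1))$nominal, 4.1)
  sys <- graft_chains(cnt, graft_spec(n_chains, 18, area = area))
  pep <- build_homopeptide(peptide_spec(residue, n_res))
  place_peptide(sys, pep, gap = 0.3)
}

## independent all-pairs hydrogen-bond oracle (plain loops, no package
## geometry helpers)
oracle_hbonds <- function(frame, donors, acceptors, dmax = 0.35, amax = 30) {
  out <- NULL
  for (i in seq_len(nrow(donors))) {
    D <- frame[donors[i, 1], ]; H <- frame[donors[i, 2], ]
    for (acc in acceptors) {
      if (acc == donors[i, 1]) next
      A <- frame[acc, ]
      dda <- sqrt(sum((A - D)^2))
      if (dda > dmax) next
      v1 <- H - D; v2 <- A - D
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang <= amax)
        out <- rbind(out, c(donors[i, 1], donors[i, 2], acc))
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 3)
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

## coerce a record set to a bare numeric triple matrix for set comparison
hb_triples <- function(x) {
  m <- unname(as.matrix(x))
  matrix(as.numeric(m), ncol = 3)
}

## independent double-loop energy oracles
oracle_lj <- function(frame, iA, iB, sigma, epsilon) {
  e <- 0
  for (i in iA) for (j in iB) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    s <- sqrt(sigma[i] * sigma[j]); ep <- sqrt(epsilon[i] * epsilon[j])
    e <- e + 4 * ep * ((s / r)^12 - (s / r)^6)
  }
  e
}

oracle_coulomb <- function(frame, iA, iB, charge) {
  e <- 0
  for (i in iA) for (j in iB)
    e <- e + 138.935458 * charge[i] * charge[j] /
      sqrt(sum((frame[i, ] - frame[j, ])^2))
  e
}

## double-loop radius-of-gyration oracle via the pair-distance identity
oracle_rg <- function(p, m) {
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(p)))
    tot <- tot + m[i] * m[j] * sum((p[i, ] - p[j, ])^2)
  sqrt(tot / (2 * sum(m)^2))
}
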