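## Homopeptide construction from ideal internal coordinates (NeRF chain
## extension).  Bond lengths/angles are standard peptide values; backbone
## dihedrals are set uniformly from the requested (phi, psi) pair.

BB <- list(b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329, b_CO = 0.1231,
           b_NH = 0.101, b_CAHA = 0.109, b_CACB = 0.153, b_CBOG = 0.141,
           b_OH = 0.096, b_CC = 0.153, b_CH = 0.109,
           a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7,
           a_CACO = 120.8, a_CNH = 119.0, a_tet = 109.5)

## per-residue atom counts used as a build-time assertion
RESIDUE_COMPOSITION <- c(GLY = 7L, SER = 11L, VAL = 16L)

#' Build a homopeptide chain
#'
#' All-atom chain at uniform backbone dihedrals with a protonated
#' N-terminus (NH3+) and dissociated C-terminus (COO-), net formal
#' charge zero.  Residue atom counts: Gly 7, Ser 11, Val 16; the
#' N-terminus adds two hydrogens and the C-terminus one oxygen.
#'
#' @param spec a [peptide_spec()].
#' @return `molsys` fragment, group "PEPTIDE".
#' @export
build_homopeptide <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  res <- spec$residue
  nres <- spec$n_residues
  phi <- spec$conformation[1]; psi <- spec$conformation[2]
  rows <- list()
  idx <- 0L
  add <- function(element, name, resid, pos, charge, ljclass, parent = NA_integer_) {
    idx <<- idx + 1L
    rows[[idx]] <<- atom_row(element, name, "PEPTIDE", resid, res, pos,
                             charge, ljclass, parent)
    idx
  }

  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(nres)) {
    first <- i == 1L; last <- i == nres
    if (first) {
      N <- c(0, 0, 0)
      CA <- c(BB$b_NCA, 0, 0)
      C <- place_atom(c(0, 1, 0), N, CA, BB$b_CAC, BB$a_NCAC, phi)
    } else {
      N <- place_atom(prevN, prevCA, prevC, BB$b_CN, BB$a_CACN, psi)
      CA <- place_atom(prevCA, prevC, N, BB$b_NCA, BB$a_CNCA, 180)
      C <- place_atom(prevC, N, CA, BB$b_CAC, BB$a_NCAC, phi)
    }
    ## amide nitrogen + hydrogens
    if (first) {
      iN <- add("N", "N", i, N, -0.19, "N_am")
      for (h in 1:3)
        add("H", paste0("H", h), i,
            place_atom(C, CA, N, BB$b_NH, BB$a_tet, 60 + 120 * (h - 1)),
            0.33, "H_pol", parent = iN)
    } else {
      iN <- add("N", "N", i, N, -0.5, "N_am")
      add("H", "H", i,
          place_atom(prevCA, prevC, N, BB$b_NH, BB$a_CNH, 0),
          0.3, "H_pol", parent = iN)
    }
    ## alpha carbon, alpha hydrogens, side chain
    qCA <- if (res == "GLY") 0.08 else 0.14
    iCA <- add("C", "CA", i, CA, qCA, "C_sp3")
    if (res == "GLY") {
      add("H", "HA1", i, place_atom(C, N, CA, BB$b_CAHA, BB$a_tet, 122),
          0.06, "H_ap", parent = iCA)
      add("H", "HA2", i, place_atom(C, N, CA, BB$b_CAHA, BB$a_tet, -118),
          0.06, "H_ap", parent = iCA)
    } else {
      add("H", "HA", i, place_atom(C, N, CA, BB$b_CAHA, BB$a_tet, -118),
          0.06, "H_ap", parent = iCA)
      CB <- place_atom(C, N, CA, BB$b_CACB, BB$a_tet, 122)
      if (res == "SER") {
        iCB <- add("C", "CB", i, CB, 0.145, "C_sp3")
        OG <- place_atom(N, CA, CB, BB$b_CBOG, 110.5, 180)
        add("H", "HB1", i, place_atom(N, CA, CB, BB$b_CH, 110.5, 60),
            0.06, "H_ap", parent = iCB)
        add("H", "HB2", i, place_atom(N, CA, CB, BB$b_CH, 110.5, -60),
            0.06, "H_ap", parent = iCB)
        iOG <- add("O", "OG", i, OG, -0.683, "O_oh")
        add("H", "HG", i, place_atom(CA, CB, OG, BB$b_OH, 108.5, 180),
            0.418, "H_pol", parent = iOG)
      } else {                            # VAL
        iCB <- add("C", "CB", i, CB, -0.06, "C_sp3")
        add("H", "HB", i, place_atom(N, CA, CB, BB$b_CH, 110.5, 60),
            0.06, "H_ap", parent = iCB)
        for (g in 1:2) {
          CG <- place_atom(N, CA, CB, BB$b_CC, 110.5, if (g == 1) 180 else -60)
          iCG <- add("C", paste0("CG", g), i, CG, -0.18, "C_sp3")
          for (h in 1:3)
            add("H", paste0("HG", g, h), i,
                place_atom(CA, CB, CG, BB$b_CH, 110.5, 60 + 120 * (h - 1)),
                0.06, "H_ap", parent = iCG)
        }
      }
    }
    ## carbonyl / carboxylate
    if (last) {
      add("C", "C", i, C, 0.7, "C_co")
      add("O", "O", i,
          place_atom(N, CA, C, BB$b_CO, 117, psi - 180), -0.85, "O_co")
      add("O", "OXT", i,
          place_atom(N, CA, C, BB$b_CO, 117, psi), -0.85, "O_co")
    } else {
      add("C", "C", i, C, 0.5, "C_co")
      add("O", "O", i,
          place_atom(N, CA, C, BB$b_CO, BB$a_CACO, psi - 180), -0.5, "O_co")
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  atoms <- finalize_atoms(rows)
  expected <- RESIDUE_COMPOSITION[[res]] * nres + 3L
  if (nrow(atoms) != expected)
    stop("internal error: peptide atom count ", nrow(atoms),
         " does not match composition table value ", expected)
  molsys(atoms)
}
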