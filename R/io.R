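## Structure and trajectory I/O (GRO is the canonical internal format; PDB
## for interoperability), the atom-selection mini-language, and the
## per-atom parameter table.  All writers are bit-stable given identical
## input.  Internally atom indices are 0-free (1-based R vectors); file
## output is 1-based as both formats require.

RESNAME_TO_GROUP <- c(CNT = "CNT", PEO = "PEO", SOL = "WATER",
                      "NA" = "NA", CL = "CL")

group_from_resname <- function(resname) {
  g <- RESNAME_TO_GROUP[resname]
  ifelse(is.na(g), "PEPTIDE", g)
}

element_from_name <- function(name) {
  two <- c("NA", "CL")
  first <- toupper(substr(gsub("[0-9]", "", name), 1, 2))
  ifelse(first %in% two, paste0(substr(first, 1, 1),
                                tolower(substr(first, 2, 2))),
         substr(first, 1, 1))
}

## ---- GRO -------------------------------------------------------------------

format_gro_frame <- function(atoms, box, title) {
  n <- nrow(atoms)
  lines <- character(n + 3)
  lines[1] <- title
  lines[2] <- sprintf("%5d", n)
  lines[3:(n + 2)] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              atoms$resid %% 100000L,
                              substr(atoms$resname, 1, 5),
                              substr(atoms$name, 1, 5),
                              atoms$id %% 100000L,
                              atoms$x, atoms$y, atoms$z)
  b <- if (is.na(box)) 0 else box
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f", b, b, b)
  lines
}

#' Write a system (or trajectory) as GRO
#'
#' Fixed-column GROMACS structure format, coordinates in nm, velocity
#' columns omitted.  A trajectory is written as concatenated frames.
#'
#' @param x a `molsys` or `trajectory`.
#' @param path output file.
#' @param title header comment.
#' @return invisibly, the path.
#' @export
write_gro <- function(x, path, title = "nanobrush system") {
  if (inherits(x, "trajectory")) {
    all_lines <- unlist(lapply(seq_along(x$frames), function(i) {
      s <- set_coords(x$topology, x$frames[[i]])
      format_gro_frame(s$atoms, s$box, sprintf("%s t= %.3f", title, x$times[i]))
    }))
    writeLines(all_lines, path)
  } else {
    writeLines(format_gro_frame(x$atoms, x$box, title), path)
  }
  invisible(path)
}

parse_gro_block <- function(lines, start, path) {
  n <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(n)) stop("parse error at line ", start + 1, " of ", path,
                     ": invalid atom count")
  at_lines <- lines[start + 1 + seq_len(n)]
  bad <- which(nchar(at_lines) < 44)
  if (length(bad) > 0)
    stop("parse error at line ", start + 1 + bad[1], " of ", path,
         ": truncated atom record")
  resid <- as.integer(substr(at_lines, 1, 5))
  resname <- trimws(substr(at_lines, 6, 10))
  name <- trimws(substr(at_lines, 11, 15))
  x <- as.numeric(substr(at_lines, 21, 28))
  y <- as.numeric(substr(at_lines, 29, 36))
  z <- as.numeric(substr(at_lines, 37, 44))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("parse error in ", path, ": malformed coordinate field near line ",
         start + 1 + which(is.na(x) | is.na(y) | is.na(z))[1])
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[start + n + 2]),
                                               "\\s+")[[1]]))
  list(resid = resid, resname = resname, name = name, x = x, y = y, z = z,
       box = boxv[1], next_start = start + n + 3)
}

block_to_molsys <- function(b) {
  n <- length(b$x)
  a <- empty_atoms(n)
  a$id <- seq_len(n)
  a$name <- b$name
  a$resname <- b$resname
  a$resid <- b$resid
  a$group <- group_from_resname(b$resname)
  a$element <- element_from_name(b$name)
  a$x <- b$x; a$y <- b$y; a$z <- b$z
  a$mass <- unname(ELEMENT_MASS[a$element])
  a$mass[is.na(a$mass)] <- 12.011
  molsys(a, box = if (length(b$box) && !is.na(b$box) && b$box > 0)
    b$box else NA_real_)
}

#' Read a structure file
#'
#' @param path file path.
#' @param format "GRO" or "PDB" (default: guessed from the extension).
#' @return a `molsys`; positions in nm (PDB Angstrom are divided by 10),
#'   box from the GRO box line or the PDB CRYST1 record, atoms in file
#'   order.  Charges/LJ parameters are zero until assigned with
#'   [apply_params()]; hydrogen-donor pairings can be restored with
#'   [derive_parents()].
#' @export
read_structure <- function(path, format = c("auto", "GRO", "PDB")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "GRO" else "PDB"
  lines <- readLines(path)
  if (format == "GRO") {
    b <- parse_gro_block(lines, 1L, path)
    block_to_molsys(b)
  } else {
    read_pdb_system(lines, path)
  }
}

#' Read a multi-frame trajectory (concatenated GRO or multi-model PDB)
#'
#' @param path file path.
#' @param format "GRO" or "PDB" (guessed from the extension by default).
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "GRO", "PDB")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "GRO" else "PDB"
  lines <- readLines(path)
  if (format == "GRO") {
    start <- 1L
    top <- NULL; frames <- list(); times <- numeric(0)
    while (start <= length(lines) && nzchar(trimws(lines[start]))) {
      b <- parse_gro_block(lines, start, path)
      if (is.null(top)) top <- block_to_molsys(b)
      frames[[length(frames) + 1L]] <- cbind(b$x, b$y, b$z)
      tm <- regmatches(lines[start], regexec("t= *([0-9.eE+-]+)", lines[start]))[[1]]
      times <- c(times, if (length(tm) == 2) as.numeric(tm[2])
                 else (length(frames) - 1) * 10)
      start <- b$next_start
    }
    trajectory(top, frames, times = times)
  } else {
    read_pdb_trajectory(lines, path)
  }
}

## ---- PDB -------------------------------------------------------------------

format_pdb_atoms <- function(atoms) {
  chain <- c(CNT = "T", PEO = "P", PEPTIDE = "A", WATER = "W",
             "NA" = "I", CL = "I")[atoms$group]
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$id %% 100000L,
          substr(atoms$name, 1, 4), substr(atoms$resname, 1, 3),
          chain, atoms$resid %% 10000L,
          atoms$x * 10, atoms$y * 10, atoms$z * 10, 1, 0,
          toupper(atoms$element))
}

#' Write a system (or trajectory) as PDB
#'
#' Coordinates are written in Angstrom; trajectories become multi-model
#' files (MODEL/ENDMDL).
#'
#' @param x a `molsys` or `trajectory`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_pdb <- function(x, path) {
  box_line <- function(box) {
    if (is.na(box)) character(0)
    else sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 box * 10, box * 10, box * 10, 90, 90, 90)
  }
  if (inherits(x, "trajectory")) {
    out <- c(box_line(x$topology$box))
    for (i in seq_along(x$frames)) {
      s <- set_coords(x$topology, x$frames[[i]])
      out <- c(out, sprintf("MODEL     %4d", i),
               format_pdb_atoms(s$atoms), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else {
    writeLines(c(box_line(x$box), format_pdb_atoms(x$atoms), "END"), path)
  }
  invisible(path)
}

parse_pdb_atom_lines <- function(at_lines, path, lineno) {
  short <- which(nchar(at_lines) < 54)
  if (length(short) > 0)
    stop("parse error at line ", lineno[short[1]], " of ", path,
         ": truncated ATOM record")
  name <- trimws(substr(at_lines, 13, 16))
  resname <- trimws(substr(at_lines, 18, 21))
  resid <- as.integer(substr(at_lines, 23, 26))
  x <- as.numeric(substr(at_lines, 31, 38)) / 10
  y <- as.numeric(substr(at_lines, 39, 46)) / 10
  z <- as.numeric(substr(at_lines, 47, 54)) / 10
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("parse error in ", path, ": malformed coordinate at line ",
         lineno[which(is.na(x) | is.na(y) | is.na(z))[1]])
  list(resid = resid, resname = resname, name = name, x = x, y = y, z = z)
}

pdb_box <- function(lines) {
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0) return(NA_real_)
  as.numeric(substr(cr[1], 7, 15)) / 10
}

read_pdb_system <- function(lines, path) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  b <- parse_pdb_atom_lines(lines[sel], path, which(sel))
  b$box <- pdb_box(lines)
  block_to_molsys(b)
}

read_pdb_trajectory <- function(lines, path) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) {
    sys <- read_pdb_system(lines, path)
    return(trajectory(sys, list(coords(sys))))
  }
  if (length(starts) != length(ends))
    stop("parse error in ", path, ": unbalanced MODEL/ENDMDL records")
  top <- NULL; frames <- list()
  for (k in seq_along(starts)) {
    blk <- lines[(starts[k] + 1):(ends[k] - 1)]
    sel <- grepl("^(ATOM  |HETATM)", blk)
    b <- parse_pdb_atom_lines(blk[sel], path, starts[k] + which(sel))
    if (is.null(top)) {
      b$box <- pdb_box(lines)
      top <- block_to_molsys(b)
    }
    frames[[k]] <- cbind(b$x, b$y, b$z)
  }
  trajectory(top, frames)
}

## ---- selections ------------------------------------------------------------

#' Select atoms with a boolean expression
#'
#' Mini-language over per-atom attributes with `and`, `or`, `not` and
#' parentheses.  Primaries: `group LABEL`, `element X`, `name X`,
#' `resid i` or `resid i:j`, `heavy` (excludes hydrogens), `all`.
#'
#' @param sys a `molsys`.
#' @param expression selection string, e.g. `"group PEO and heavy"`.
#' @return sorted, duplicate-free integer vector of atom indices.
#' @export
select_atoms <- function(sys, expression) {
  toks <- strsplit(gsub("([()])", " \\1 ", expression), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) stop("selection-syntax error: empty expression")
  a <- sys$atoms
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }

  parse_primary <- function() {
    t <- advance()
    switch(tolower(t),
      "(" = {
        v <- parse_or()
        if (peek() != ")") stop("selection-syntax error: expected ')'")
        advance(); v
      },
      "not" = !parse_primary(),
      "heavy" = a$element != "H",
      "all" = rep(TRUE, nrow(a)),
      "group" = a$group == advance(),
      "element" = a$element == advance(),
      "name" = a$name == advance(),
      "resid" = {
        r <- advance()
        if (grepl(":", r)) {
          ij <- as.integer(strsplit(r, ":")[[1]])
          a$resid >= ij[1] & a$resid <= ij[2]
        } else a$resid == as.integer(r)
      },
      stop("selection-syntax error: unknown token '", t, "'"))
  }
  parse_and <- function() {
    v <- parse_primary()
    while (tolower(peek()) == "and") { advance(); v <- v & parse_primary() }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (tolower(peek()) == "or") { advance(); v <- v | parse_and() }
    v
  }
  v <- parse_or()
  if (pos <= length(toks))
    stop("selection-syntax error: trailing tokens from '", peek(), "'")
  sort(unique(which(v)))
}

## ---- parameter table -------------------------------------------------------

#' Read a per-atom parameter table
#'
#' Tab-separated columns `name`, `mass`, `charge`, `sigma`, `epsilon`.
#' Duplicate names: the last row wins (a warning reports them).
#'
#' @param path TSV file.
#' @return data.frame keyed by atom name.
#' @export
read_params <- function(path) {
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("schema error: ", conditionMessage(e)))
  need <- c("name", "mass", "charge", "sigma", "epsilon")
  if (nrow(tab) == 0 || !all(need %in% names(tab)))
    stop("schema error: parameter table needs columns ",
         paste(need, collapse = ", "))
  dup <- duplicated(tab$name, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate parameter name(s), last occurrence wins: ",
            paste(unique(tab$name[dup]), collapse = ", "))
    tab <- tab[!dup, , drop = FALSE]
  }
  tab[, need]
}

#' Apply a parameter table to a system
#'
#' @param sys a `molsys`.
#' @param params data.frame from [read_params()].
#' @return the system with mass/charge/sigma/epsilon replaced by table
#'   values; unresolved atom names are reported collectively as an error.
#' @export
apply_params <- function(sys, params) {
  idx <- match(sys$atoms$name, params$name)
  if (anyNA(idx))
    stop("unresolved atom name(s): ",
         paste(unique(sys$atoms$name[is.na(idx)]), collapse = ", "))
  sys$atoms$mass <- params$mass[idx]
  sys$atoms$charge <- params$charge[idx]
  sys$atoms$sigma <- params$sigma[idx]
  sys$atoms$epsilon <- params$epsilon[idx]
  sys
}

#' Infer hydrogen-donor pairings from geometry
#'
#' For structures read from files (where the builder's bookkeeping is
#' absent) each hydrogen is assigned the nearest heavy atom within
#' `cutoff` as its covalently bonded partner; only N-H and O-H pairs act
#' as hydrogen-bond donors downstream.
#'
#' @param sys a `molsys`.
#' @param cutoff maximum covalent-bond distance, nm.
#' @return the system with the `parent` column filled.
#' @export
derive_parents <- function(sys, cutoff = 0.12) {
  a <- sys$atoms
  h <- which(a$element == "H")
  heavy <- which(a$element != "H")
  if (length(h) == 0 || length(heavy) == 0) return(sys)
  xyz <- coords(sys)
  d2 <- cross_dist2(xyz[h, , drop = FALSE], xyz[heavy, , drop = FALSE])
  nearest <- heavy[apply(d2, 1, which.min)]
  dmin <- sqrt(apply(d2, 1, min))
  sys$atoms$parent[h] <- ifelse(dmin <= cutoff, nearest, NA_integer_)
  sys
}
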