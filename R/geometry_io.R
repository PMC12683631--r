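## Elements the covalent-assignment logic knows about.  The model only
## involves water, DMSO, glycerol and methane, but N/P are accepted so that
## foreign atoms degrade to kind "other" instead of a hard failure.
KNOWN_ELEMENTS <- c("H", "C", "N", "O", "P", "S")

## Pairwise covalent cutoffs in Angstrom.  Generous enough for stretched
## O-H bonds (0.968 A) yet far below the shortest hydrogen bond treated by
## the model (1.7 A).  S-C at 1.9 A covers the DMSO sulfur-methyl bond.
COVALENT_CUTOFFS <- list(
  "H|O" = 1.2, "C|H" = 1.3, "O|S" = 1.7,
  "C|C" = 1.7, "C|O" = 1.7, "C|S" = 1.9,
  "H|N" = 1.2, "C|N" = 1.7, "N|O" = 1.7
)

covalent_cutoff <- function(e1, e2) {
  key <- paste(pmin(e1, e2), pmax(e1, e2), sep = "|")
  cut <- rep(0, length(key))
  hit <- key %in% names(COVALENT_CUTOFFS)
  cut[hit] <- unlist(COVALENT_CUTOFFS[key[hit]], use.names = FALSE)
  cut
}

## Canonical Hill-ish formula string, e.g. "C2H6OS".
formula_string <- function(elements) {
  tab <- table(elements)
  nm <- sort(names(tab))
  paste0(vapply(nm, function(e) {
    n <- tab[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}

KIND_BY_FORMULA <- c(
  "H2O"    = "water",
  "C2H6OS" = "dmso",
  "C3H8O3" = "glycerol",
  "CH4"    = "methane"
)

#' Assemble a molecular system from raw atoms
#'
#' Assigns covalent bonds by element-specific interatomic distance cutoffs,
#' partitions atoms into molecules (connected components of the covalent
#' graph), types each molecule by molecular formula (water, DMSO, glycerol,
#' methane, other) and records the role atoms used downstream (water O/H,
#' the DMSO S=O oxygen, glycerol hydroxyl groups, C-H hydrogens).
#'
#' @param atoms data frame with columns `element` (chemical symbol) and
#'   `x`, `y`, `z` (Cartesian coordinates, Angstrom).
#' @param frame_id integer frame label (default 0).
#' @return An object of class `molecular_system`: a list with elements
#'   `atoms` (the input data frame plus a `molecule_id` column), `bonds`
#'   (two-column integer matrix of covalent bonds, 1-based atom indices),
#'   `molecules` (list of molecule units, each with `kind`, `atom_indices`
#'   and `role_atoms`) and `frame_id`.
#' @examples
#' atoms <- data.frame(element = c("O", "H", "H"),
#'                     x = c(0, 0.962, -0.24), y = c(0, 0, 0.93), z = 0)
#' sys <- assign_molecules(atoms)
#' sys$molecules[[1]]$kind
#' @export
assign_molecules <- function(atoms, frame_id = 0L) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  if (n == 0) stop("empty atom list")
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  bad <- !atoms$element %in% KNOWN_ELEMENTS
  if (any(bad))
    stop("unknown element symbol(s): ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("non-finite coordinates")

  ## covalent bonds
  bonds <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    d <- as.matrix(stats::dist(pos))
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    cut <- covalent_cutoff(atoms$element[pairs[, 1]],
                           atoms$element[pairs[, 2]])
    keep <- d[pairs] < cut & cut > 0
    bonds <- cbind(pairs[keep, 1], pairs[keep, 2])
  }

  ## every H must bind exactly one heavy atom
  is_h <- atoms$element == "H"
  h_deg <- tabulate(c(bonds[is_h[bonds[, 1]], 1],
                      bonds[is_h[bonds[, 2]], 2]), nbins = n)
  multi <- which(is_h & h_deg > 1)
  if (length(multi)) {
    i <- multi[1]
    partners <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    stop(sprintf(
      "ambiguous covalent assignment: H atom %d is within covalent cutoff of heavy atoms %s",
      i, paste(sort(partners), collapse = ", ")))
  }

  ## connected components
  comp <- connected_components(n, bonds)
  mol_ids <- sort(unique(comp))
  molecules <- vector("list", length(mol_ids))
  atoms$molecule_id <- comp
  for (m in seq_along(mol_ids)) {
    idx <- which(comp == mol_ids[m])
    atoms$molecule_id[idx] <- m
    molecules[[m]] <- type_molecule(idx, atoms, bonds)
  }

  structure(list(atoms = atoms, bonds = bonds, molecules = molecules,
                 frame_id = as.integer(frame_id)),
            class = "molecular_system")
}

connected_components <- function(n, bonds) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

type_molecule <- function(idx, atoms, bonds) {
  el <- atoms$element[idx]
  f <- formula_string(el)
  kind <- unname(KIND_BY_FORMULA[f])
  if (is.na(kind)) {
    kind <- "other"
    warning(sprintf("molecule with formula %s typed as 'other'", f),
            call. = FALSE)
  }
  sub_bonds <- bonds[bonds[, 1] %in% idx & bonds[, 2] %in% idx, , drop = FALSE]
  bonded_to <- function(i) {
    c(sub_bonds[sub_bonds[, 1] == i, 2], sub_bonds[sub_bonds[, 2] == i, 1])
  }
  role <- list()
  if (kind == "water") {
    role$water_O <- idx[el == "O"]
    hs <- sort(idx[el == "H"])
    role$water_H1 <- hs[1]
    role$water_H2 <- hs[2]
  } else if (kind == "dmso") {
    s <- idx[el == "S"]
    o <- idx[el == "O"]
    role$dmso_S <- s
    role$dmso_O <- o
    role$methyl_H <- sort(idx[el == "H"])
  } else if (kind == "glycerol") {
    os <- idx[el == "O"]
    hs <- idx[el == "H"]
    oh_h <- hs[vapply(hs, function(h) any(bonded_to(h) %in% os), logical(1))]
    role$hydroxyl_O <- sort(os)
    role$hydroxyl_H <- sort(oh_h)
    role$ch_H <- sort(setdiff(hs, oh_h))
  } else if (kind == "methane") {
    role$ch_H <- sort(idx[el == "H"])
  }
  list(kind = kind, atom_indices = sort(idx), role_atoms = role, formula = f)
}

#' @export
print.molecular_system <- function(x, ...) {
  kinds <- vapply(x$molecules, `[[`, character(1), "kind")
  cat(sprintf("molecular_system: %d atoms, %d covalent bonds, frame %d\n",
              nrow(x$atoms), nrow(x$bonds), x$frame_id))
  print(table(kinds))
  invisible(x)
}

#' Read an XYZ file (single- or multi-frame)
#'
#' Parses the plain XYZ dialect: an atom-count line, a comment line, then
#' one `element x y z` line per atom; multi-frame files are concatenated
#' blocks.  Coordinates are taken as Angstrom.
#'
#' @param path path to the XYZ file.
#' @return List of [molecular_system][assign_molecules] objects, one per
#'   frame, with `frame_id` sequential from 0.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  frame_id <- 0L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln])) && ln == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n <= 0)
      stop(sprintf("XYZ parse error at line %d: bad atom count line '%s'",
                   ln, lines[ln]))
    if (ln + 1L + n > length(lines))
      stop(sprintf("XYZ parse error: frame starting at line %d truncated (expected %d atoms)",
                   ln, n))
    rows <- lines[(ln + 2L):(ln + 1L + n)]
    parsed <- lapply(seq_along(rows), function(k) {
      tok <- strsplit(trimws(rows[k]), "[[:space:]]+")[[1]]
      if (length(tok) < 4)
        stop(sprintf("XYZ parse error at line %d: expected 'element x y z'",
                     ln + 1L + k))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz)))
        stop(sprintf("XYZ parse error at line %d: non-numeric coordinate",
                     ln + 1L + k))
      list(el = tok[1], xyz = xyz)
    })
    atoms <- data.frame(
      element = vapply(parsed, `[[`, character(1), "el"),
      x = vapply(parsed, function(p) p$xyz[1], numeric(1)),
      y = vapply(parsed, function(p) p$xyz[2], numeric(1)),
      z = vapply(parsed, function(p) p$xyz[3], numeric(1))
    )
    frames[[length(frames) + 1L]] <- assign_molecules(atoms, frame_id)
    frame_id <- frame_id + 1L
    ln <- ln + 2L + n
    while (ln <= length(lines) && !nzchar(trimws(lines[ln]))) ln <- ln + 1L
  }
  if (!length(frames)) stop("XYZ parse error: no frames found")
  frames
}

#' Write systems to an XYZ file
#'
#' @param systems a `molecular_system` or list of them.
#' @param path output path.
#' @param digits coordinate decimals (default 6).
#' @export
write_xyz <- function(systems, path, digits = 6) {
  if (inherits(systems, "molecular_system")) systems <- list(systems)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%-2s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (sys in systems) {
    writeLines(as.character(nrow(sys$atoms)), con)
    writeLines(sprintf("frame %d", sys$frame_id), con)
    writeLines(sprintf(fmt, sys$atoms$element,
                       sys$atoms$x, sys$atoms$y, sys$atoms$z), con)
  }
  invisible(path)
}

## residue-name hints; formula-based typing always wins.
PDB_RESID_HINTS <- c(HOH = "water", WAT = "water", SOL = "water",
                     DMS = "dmso", GOL = "glycerol")

#' Read a PDB file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()].  Residue names
#' HOH/WAT/SOL, DMS and GOL are used as water/DMSO/glycerol hints, but the
#' final molecule typing is always by covalent connectivity and molecular
#' formula, so mis-named residues are still typed correctly.  Multi-model
#' files (MODEL/ENDMDL) yield one system per model.
#'
#' @param path path to the PDB file.
#' @return List of [molecular_system][assign_molecules] objects, one per
#'   model (length 1 for single-model files).
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  el <- pdb$atom$elesy
  if (is.null(el)) el <- rep("", nrow(pdb$atom))
  el <- toupper(trimws(el))
  guess <- toupper(sub("^[0-9' ]*", "", pdb$atom$elety))
  guess <- substr(gsub("[^A-Z]", "", guess), 1, 1)
  el[!nzchar(el) | is.na(el)] <- guess[!nzchar(el) | is.na(el)]
  bad <- !el %in% KNOWN_ELEMENTS
  if (any(bad))
    stop(sprintf(
      "PDB record(s) %s: missing element field and unrecognizable atom name '%s'",
      paste(which(bad), collapse = ","),
      paste(unique(pdb$atom$elety[bad]), collapse = ",")))

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  systems <- lapply(seq_len(nrow(xyz)), function(f) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    atoms <- data.frame(element = el, x = m[, 1], y = m[, 2], z = m[, 3])
    sys <- assign_molecules(atoms, frame_id = f - 1L)
    check_pdb_hints(sys, pdb$atom$resid)
    sys
  })
  systems
}

check_pdb_hints <- function(sys, resid) {
  hints <- unname(PDB_RESID_HINTS[toupper(trimws(resid))])
  for (mol in sys$molecules) {
    h <- unique(stats::na.omit(hints[mol$atom_indices]))
    if (length(h) == 1 && h != mol$kind)
      message(sprintf(
        "residue name suggests %s but formula typing gives %s (formula wins)",
        h, mol$kind))
  }
  invisible(NULL)
}

#' Read structures from XYZ or PDB
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"xyz"` or `"pdb"`.
#' @return List of `molecular_system` frames.
#' @export
read_structures <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (format == "pdb") read_pdb(path) else read_xyz(path)
}

atom_pos <- function(sys, i) {
  as.numeric(sys$atoms[i, c("x", "y", "z")])
}
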