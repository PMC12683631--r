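## Hydrogen-bond detection and per-water topology classification.
##
## A conventional hydrogen bond is O-H...O with geometric criteria after
## Luzar & Chandler: H...O distance below `r_max` (default 2.5 A, first
## solvation shell) and O-H...O angle above `angle_min` (default 150 deg).
## CH...O contacts (methyl/methine donors) use a distance criterion only.

empty_hbond_table <- function() {
  data.frame(
    donor_mol = integer(0), acceptor_mol = integer(0),
    donor_heavy = integer(0), hydrogen = integer(0),
    acceptor_heavy = integer(0),
    r_hb = numeric(0), angle_dha = numeric(0),
    donor_kind = character(0), acceptor_kind = character(0),
    conventional = logical(0)
  )
}

## Covalent X-H bonds with X of element `donor_element`, as a two-column
## matrix (heavy, H).
donor_xh_pairs <- function(sys, donor_element) {
  b <- sys$bonds
  if (!nrow(b)) return(matrix(integer(0), ncol = 2))
  el <- sys$atoms$element
  out <- rbind(
    b[el[b[, 1]] == donor_element & el[b[, 2]] == "H", , drop = FALSE],
    b[el[b[, 2]] == donor_element & el[b[, 1]] == "H", c(2, 1), drop = FALSE]
  )
  out
}

## Oxygen atoms eligible as acceptors: water O, the DMSO S=O oxygen and
## glycerol hydroxyl oxygens.
acceptor_oxygens <- function(sys) {
  out <- list()
  for (m in seq_along(sys$molecules)) {
    mol <- sys$molecules[[m]]
    o <- switch(mol$kind,
                water = mol$role_atoms$water_O,
                dmso = mol$role_atoms$dmso_O,
                glycerol = mol$role_atoms$hydroxyl_O,
                integer(0))
    if (length(o)) out[[length(out) + 1L]] <- cbind(o, m)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

hbond_rows <- function(sys, donors, acceptors, r_max, angle_min, use_angle,
                       conventional) {
  rows <- list()
  mol_of <- sys$atoms$molecule_id
  kinds <- vapply(sys$molecules, `[[`, character(1), "kind")
  for (k in seq_len(nrow(donors))) {
    d_heavy <- donors[k, 1]
    h <- donors[k, 2]
    ph <- atom_pos(sys, h)
    pd <- atom_pos(sys, d_heavy)
    for (j in seq_len(nrow(acceptors))) {
      a <- acceptors[j, 1]
      if (mol_of[a] == mol_of[h]) next
      pa <- atom_pos(sys, a)
      r <- vdist(ph, pa)
      if (r >= r_max) next
      ang <- vangle(pd, ph, pa)
      if (conventional && use_angle && ang <= angle_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_mol = mol_of[d_heavy], acceptor_mol = acceptors[j, 2],
        donor_heavy = d_heavy, hydrogen = h, acceptor_heavy = a,
        r_hb = r, angle_dha = ang,
        donor_kind = kinds[mol_of[d_heavy]],
        acceptor_kind = kinds[acceptors[j, 2]],
        conventional = conventional
      )
    }
  }
  if (!length(rows)) return(empty_hbond_table())
  out <- do.call(rbind, rows)
  out[order(out$donor_mol, out$hydrogen, out$acceptor_heavy), , drop = FALSE]
}

#' Detect conventional hydrogen bonds
#'
#' Emits one record for every (O-H donor, acceptor O) pair that satisfies
#' the geometric criteria: H...O distance `r_hb < r_max` and, when
#' `use_angle` is `TRUE`, O-H...O angle `angle_dha > angle_min`.
#' Donors are covalent O-H groups (water, glycerol hydroxyls); acceptors
#' are water oxygens, the DMSO S=O oxygen and glycerol hydroxyl oxygens.
#' Intramolecular pairs are excluded.
#'
#' @param sys a [molecular_system][assign_molecules].
#' @param r_max distance criterion, Angstrom (default 2.5).
#' @param angle_min angle criterion, degrees (default 150).
#' @param use_angle apply the angular criterion (default `TRUE`).  The
#'   distance-only variant reproduces a first-shell analysis keyed on the
#'   2.5 A cutoff alone.
#' @return Data frame with one row per bond: `donor_mol`, `acceptor_mol`
#'   (1-based molecule ids), `donor_heavy`, `hydrogen`, `acceptor_heavy`
#'   (1-based atom indices), `r_hb` (A), `angle_dha` (deg), `donor_kind`,
#'   `acceptor_kind`, `conventional = TRUE`.  An empty frame is a valid
#'   result.
#' @examples
#' dimer <- make_dimer()
#' detect_hbonds(dimer)
#' @export
detect_hbonds <- function(sys, r_max = 2.5, angle_min = 150,
                          use_angle = TRUE) {
  stopifnot(inherits(sys, "molecular_system"), r_max > 0)
  donors <- donor_xh_pairs(sys, "O")
  acceptors <- acceptor_oxygens(sys)
  if (!nrow(donors) || !nrow(acceptors)) return(empty_hbond_table())
  hbond_rows(sys, donors, acceptors, r_max, angle_min, use_angle,
             conventional = TRUE)
}

#' Detect CH...O contacts
#'
#' Nonconventional hydrogen bonds with a C-H donor (DMSO methyls, glycerol
#' or methane C-H) and a water oxygen as acceptor, using a distance
#' criterion only (no angular criterion is applied to CH contacts).
#'
#' @param sys a [molecular_system][assign_molecules].
#' @param r_max H...O distance cutoff, Angstrom (default 3.0).
#' @return Data frame in the same layout as [detect_hbonds()], with
#'   `conventional = FALSE`.  The `angle_dha` column records the C-H...O
#'   angle for reference; it is not a criterion.
#' @export
detect_ch_contacts <- function(sys, r_max = 3.0) {
  stopifnot(inherits(sys, "molecular_system"), r_max > 0)
  donors <- donor_xh_pairs(sys, "C")
  wa <- list()
  for (m in seq_along(sys$molecules)) {
    mol <- sys$molecules[[m]]
    if (mol$kind == "water")
      wa[[length(wa) + 1L]] <- cbind(mol$role_atoms$water_O, m)
  }
  if (!nrow(donors) || !length(wa)) return(empty_hbond_table())
  hbond_rows(sys, donors, do.call(rbind, wa), r_max, angle_min = 0,
             use_angle = FALSE, conventional = FALSE)
}

#' Classify the hydrogen-bond environment of each water
#'
#' Builds one profile per water molecule: the conventional bonds it
#' accepts (its O is the acceptor), the conventional bonds it donates
#' (to water, DMSO or glycerol acceptors), and its CH...O contacts.  A
#' water donating fewer than two conventional bonds has at least one free
#' O-H and is flagged `dangling`; donations to DMSO or glycerol acceptors
#' count toward that determination.
#'
#' @param sys a [molecular_system][assign_molecules].
#' @param hbonds conventional bonds from [detect_hbonds()]; computed with
#'   defaults when `NULL`.
#' @param ch_contacts contacts from [detect_ch_contacts()]; computed with
#'   defaults when `NULL`.
#' @return List of `water_profile` objects with fields `water` (molecule
#'   id), `o_atom`, `accepted`, `donated`, `ch_contacts` (bond-table
#'   subsets), `n_accepted`, `n_donated`, `dangling` and `oh_lengths`
#'   (the water's two covalent O-H lengths, A).
#' @examples
#' trimer <- make_multimer(topology_spec(n_accept = 1, n_donate = 1))
#' profile_waters(trimer)[[1]]
#' @export
profile_waters <- function(sys, hbonds = NULL, ch_contacts = NULL) {
  stopifnot(inherits(sys, "molecular_system"))
  if (is.null(hbonds)) hbonds <- detect_hbonds(sys)
  if (is.null(ch_contacts)) ch_contacts <- detect_ch_contacts(sys)
  profiles <- list()
  for (m in seq_along(sys$molecules)) {
    mol <- sys$molecules[[m]]
    if (mol$kind != "water") next
    o <- mol$role_atoms$water_O
    acc <- hbonds[hbonds$acceptor_heavy == o, , drop = FALSE]
    don <- hbonds[hbonds$donor_heavy == o, , drop = FALSE]
    ch <- ch_contacts[ch_contacts$acceptor_heavy == o, , drop = FALSE]
    oh <- c(vdist(atom_pos(sys, o), atom_pos(sys, mol$role_atoms$water_H1)),
            vdist(atom_pos(sys, o), atom_pos(sys, mol$role_atoms$water_H2)))
    p <- list(water = m, o_atom = o, accepted = acc, donated = don,
              ch_contacts = ch, n_accepted = nrow(acc),
              n_donated = nrow(don), dangling = nrow(don) < 2,
              oh_lengths = oh)
    class(p) <- "water_profile"
    profiles[[length(profiles) + 1L]] <- p
  }
  profiles
}

#' @export
print.water_profile <- function(x, ...) {
  cat(sprintf(
    "water %d: %dA %dD%s, %d CH...O contact(s), O-H %.3f/%.3f A\n",
    x$water, x$n_accepted, x$n_donated,
    if (x$dangling) " (dangling O-H)" else "",
    nrow(x$ch_contacts), x$oh_lengths[1], x$oh_lengths[2]))
  invisible(x)
}
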