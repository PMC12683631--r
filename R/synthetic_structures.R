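## Constructive generators for test geometries: single waters, the
## canonical dimer, water n-mers with a prescribed hydrogen-bond topology
## around a central water, DMSO.H2O conformers, a toy glycerol, and
## seeded perturbed pseudo-trajectories.
##
## Every requested geometric parameter (bond length, H-bond distance,
## H-bond angle) is satisfied exactly by construction and can be
## recovered by direct measurement on the output.

atoms_from <- function(elements, pos) {
  data.frame(element = elements, x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Generate a single water molecule
#'
#' Planar water with exact requested internal geometry.  The default
#' 0.962 A O-H length is the free (non-hydrogen-bonded) reference; a
#' donated O-H is conventionally 0.968 A.
#'
#' @param r_oh1,r_oh2 covalent O-H lengths, A.
#' @param hoh_angle H-O-H angle, degrees.
#' @return A [molecular_system][assign_molecules] with one water.
#' @export
make_water <- function(r_oh1 = 0.962, r_oh2 = 0.962, hoh_angle = 104.5) {
  if (r_oh1 <= 0.5 || r_oh1 > 1.5 || r_oh2 <= 0.5 || r_oh2 > 1.5 ||
      hoh_angle <= 0 || hoh_angle >= 180)
    stop("non-physical water geometry requested")
  pos <- rbind(c(0, 0, 0),
               c(r_oh1, 0, 0),
               r_oh2 * c(deg_cos(hoh_angle), deg_sin(hoh_angle), 0))
  assign_molecules(atoms_from(c("O", "H", "H"), pos))
}

## Water H directions on a cone of half-angle `theta` about unit vector
## `v`, separated so that the H-O-H angle equals `hoh`.  Returns a
## 2 x 3 matrix of unit directions.
cone_pair <- function(v, theta, hoh, twist = 0) {
  ct <- deg_cos(theta); st <- deg_sin(theta)
  cdphi <- (deg_cos(hoh) - ct^2) / st^2
  if (abs(cdphi) > 1)
    stop("requested H...O-H and H-O-H angles are incompatible")
  dphi <- acos(cdphi) * 180 / pi
  e1 <- as.numeric(rotation_about(v, twist) %*% orthonormal_to(v))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  phis <- c(dphi / 2, -dphi / 2)
  t(vapply(phis, function(phi)
    ct * v + st * (deg_cos(phi) * e1 + deg_sin(phi) * e2), numeric(3)))
}

## Acceptor water for a donated O-H: H at `h`, donor oxygen at `o_d`.
## The acceptor O is placed at distance r_hb from H with O-H...O angle
## `angle_ohO`; its own hydrogens sit at `angle_hOh` from the incoming H
## direction.  Returns 3 x 3 positions (O, H1, H2).
place_acceptor_water <- function(o_d, h, r_hb, angle_ohO, angle_hOh,
                                 hoh_angle = 104.5, azimuth = 90,
                                 twist = 0, r_oh = 0.962) {
  d0 <- vunit(h - o_d)
  axis <- as.numeric(rotation_about(d0, azimuth) %*% orthonormal_to(d0))
  u <- as.numeric(rotation_about(axis, 180 - angle_ohO) %*% d0)
  o_a <- h + r_hb * u
  v <- -u  # from the acceptor O back toward the donated H
  dirs <- cone_pair(v, angle_hOh, hoh_angle, twist)
  rbind(o_a, o_a + r_oh * dirs[1, ], o_a + r_oh * dirs[2, ])
}

## Donor water delivering an H to the acceptor oxygen `o_c` along unit
## direction `l` at H...O distance r_hb.  Returns 3 x 3 positions
## (O, donated H, second H).
place_donor_water <- function(o_c, l, r_hb, angle_ohO, hoh_angle = 104.5,
                              azimuth = 90, twist = 0,
                              r_oh_donated = 0.968, r_oh_free = 0.962) {
  h <- o_c + r_hb * l
  axis <- as.numeric(rotation_about(l, azimuth) %*% orthonormal_to(l))
  w <- as.numeric(rotation_about(axis, 180 - angle_ohO) %*% l)
  o_d <- h + r_oh_donated * w
  axis2 <- as.numeric(rotation_about(w, twist) %*% orthonormal_to(w))
  dir2 <- as.numeric(rotation_about(axis2, hoh_angle) %*% (-w))
  rbind(o_d, h, o_d + r_oh_free * dir2)
}

#' Generate the canonical water dimer
#'
#' One water donating a single hydrogen bond to another.  The donated
#' O-H is set to 0.968 A; the default geometry is the optimised dimer:
#' H...O distance 1.71 A, O-H...O angle 163.7 deg, H...O-H angle
#' 109.6 deg.  All requested parameters are exact on the output.
#'
#' @param r_hb H...O hydrogen-bond distance, A.
#' @param angle_ohO O-H...O angle at the donated H, degrees.
#' @param angle_hOh H...O-H angle at the acceptor O, degrees.
#' @param hoh_angle internal H-O-H angle of both waters, degrees.
#' @return A [molecular_system][assign_molecules]; molecule 1 is the
#'   donor, molecule 2 the acceptor.
#' @examples
#' detect_hbonds(make_dimer())
#' @export
make_dimer <- function(r_hb = 1.71, angle_ohO = 163.7, angle_hOh = 109.6,
                       hoh_angle = 104.5) {
  if (r_hb <= 1.0 || r_hb > 5)
    stop("non-physical hydrogen-bond distance requested")
  o_d <- c(0, 0, 0)
  h_don <- c(0.968, 0, 0)
  h2 <- 0.962 * c(deg_cos(hoh_angle), deg_sin(hoh_angle), 0)
  acc <- place_acceptor_water(o_d, h_don, r_hb, angle_ohO, angle_hOh,
                              hoh_angle)
  pos <- rbind(o_d, h_don, h2, acc)
  assign_molecules(atoms_from(c("O", "H", "H", "O", "H", "H"), pos))
}

#' Specify the hydrogen-bond topology of a central water
#'
#' @param n_accept number of accepted hydrogen bonds (0-2).
#' @param n_donate number of donated hydrogen bonds (0-2).
#' @param distances H...O distance per bond, A, recycled to
#'   `n_accept + n_donate` (accepted bonds first); each in (1.4, 3.5).
#' @param hb_angle O-H...O angle for every bond, degrees.
#' @param partner_kinds `"water"` or `"glycerol"` per bond, recycled.
#' @return Object of class `topology_spec`.
#' @examples
#' topology_spec(2, 2, distances = 1.70)
#' @export
topology_spec <- function(n_accept, n_donate, distances = 1.71,
                          hb_angle = 163.7, partner_kinds = "water") {
  n_accept <- as.integer(n_accept); n_donate <- as.integer(n_donate)
  stopifnot(n_accept >= 0, n_donate >= 0, n_donate <= 2, n_accept <= 2)
  if (n_accept + n_donate > 4) stop("at most four hydrogen bonds per water")
  n <- n_accept + n_donate
  distances <- rep_len(distances, max(n, 1))[seq_len(n)]
  if (any(distances <= 1.4 | distances >= 3.5))
    stop("hydrogen-bond distances must lie in (1.4, 3.5) A")
  partner_kinds <- rep_len(partner_kinds, max(n, 1))[seq_len(n)]
  stopifnot(all(partner_kinds %in% c("water", "glycerol")))
  structure(list(n_accept = n_accept, n_donate = n_donate,
                 distances = distances, hb_angle = hb_angle,
                 partner_kinds = partner_kinds),
            class = "topology_spec")
}

#' Parse a topology label like `"2A1D"` or `"2A1D@1.75"`
#'
#' @param label string `<n>A<m>D` with an optional `@distance` suffix.
#' @param ... passed to [topology_spec()].
#' @return A `topology_spec`.
#' @export
parse_topology <- function(label, ...) {
  m <- regmatches(label,
    regexec("^([0-9])A([0-9])D(@([0-9.]+))?$", toupper(label)))[[1]]
  if (!length(m)) {
    m <- regmatches(label,
      regexec("^([0-9])A(@([0-9.]+))?$", toupper(label)))[[1]]
    if (length(m))
      m <- c(m[1], m[2], "0", m[3], m[4])
  }
  if (!length(m)) {
    m <- regmatches(label,
      regexec("^([0-9])D(@([0-9.]+))?$", toupper(label)))[[1]]
    if (length(m))
      m <- c(m[1], "0", m[2], m[3], m[4])
  }
  if (!length(m))
    stop("cannot parse topology label '", label, "' (expected e.g. '2A1D@1.75')")
  args <- list(n_accept = as.integer(m[2]), n_donate = as.integer(m[3]), ...)
  if (nzchar(m[5]) && !("distances" %in% names(args)))
    args$distances <- as.numeric(m[5])
  do.call(topology_spec, args)
}

## Toy rigid glycerol (C3H8O3): propane backbone with three hydroxyls,
## one of which (O1/HO1, at the end of the scaffold) is the role hydroxyl
## used for hydrogen bonding; the rest of the molecule extends away from
## it.  Internal geometry is schematic but satisfies all covalent
## cutoffs and the C3H8O3 formula.
glycerol_template <- function() {
  pos <- rbind(
    c(0.000, 0.000, 0.000),     # C1
    c(1.520, 0.000, 0.000),     # C2
    c(3.040, 0.000, 0.000),     # C3
    c(-1.430, 0.000, 0.000),    # O1 (role hydroxyl O)
    c(1.520, 1.430, 0.000),     # O2
    c(3.040, -1.430, 0.000),    # O3
    c(-1.727, 0.913, 0.000),    # HO1 (role hydroxyl H)
    c(1.520, 2.390, 0.000),     # HO2
    c(3.040, -2.390, 0.000),    # HO3
    c(0.000, 0.770, 0.770),     # H on C1
    c(0.000, -0.770, 0.770),    # H on C1
    c(1.520, -0.770, 0.770),    # H on C2
    c(3.040, 0.770, 0.770),     # H on C3
    c(3.040, 0.770, -0.770)     # H on C3
  )
  elements <- c("C", "C", "C", "O", "O", "O",
                "H", "H", "H", "H", "H", "H", "H", "H")
  ## lone-pair direction of the role hydroxyl oxygen: opposite the mean
  ## of its two covalent bond directions
  o1 <- pos[4, ]; c1 <- pos[1, ]; ho1 <- pos[7, ]
  lp <- -vunit(vunit(c1 - o1) + vunit(ho1 - o1))
  list(elements = elements, pos = pos, i_O = 4L, i_H = 7L, lp = lp)
}

rotation_from_to <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- vnorm(ax)
  d <- sum(a * b)
  if (s < 1e-12) {
    if (d > 0) return(diag(3))
    return(rotation_about(orthonormal_to(a), 180))
  }
  rotation_about(ax, atan2(s, d) * 180 / pi)
}

## Rigid-transform the glycerol template so that a chosen template point
## lands on `target` and a chosen template direction lands on `dir`,
## with a free twist (degrees) about `dir`.
place_glycerol <- function(anchor, anchor_dir, target, dir, twist = 0) {
  g <- glycerol_template()
  R <- rotation_about(dir, twist) %*% rotation_from_to(anchor_dir, dir)
  pos <- t(R %*% t(sweep(g$pos, 2, anchor))) +
    matrix(target, nrow(g$pos), 3, byrow = TRUE)
  list(elements = g$elements, pos = pos)
}

## Neighbour placement for make_multimer: one accepted or donated bond.
place_partner <- function(role, kind, o_c, dir_or_h, o_h = NULL, r = NULL,
                          hb_angle = 163.7, azimuth = 90, twist = 0) {
  g <- glycerol_template()
  if (role == "accepted") {
    ## partner donates to the central O along unit direction dir_or_h
    if (kind == "water") {
      p <- place_donor_water(o_c, dir_or_h, r, hb_angle,
                             azimuth = azimuth, twist = twist)
      return(list(elements = c("O", "H", "H"), pos = p))
    }
    h <- o_c + r * dir_or_h
    axis <- as.numeric(rotation_about(dir_or_h, azimuth) %*%
                         orthonormal_to(dir_or_h))
    w <- as.numeric(rotation_about(axis, 180 - hb_angle) %*% dir_or_h)
    return(place_glycerol(g$pos[g$i_H, ], vunit(g$pos[g$i_O, ] - g$pos[g$i_H, ]),
                          h, w, twist))
  }
  ## donated: central O-H (o_c is central O, dir_or_h the H position)
  if (kind == "water") {
    p <- place_acceptor_water(o_c, dir_or_h, r, hb_angle, angle_hOh = 109.6,
                              azimuth = azimuth, twist = twist)
    return(list(elements = c("O", "H", "H"), pos = p))
  }
  d0 <- vunit(dir_or_h - o_c)
  axis <- as.numeric(rotation_about(d0, azimuth) %*% orthonormal_to(d0))
  u <- as.numeric(rotation_about(axis, 180 - hb_angle) %*% d0)
  o_a <- dir_or_h + r * u
  place_glycerol(g$pos[g$i_O, ], g$lp, o_a, -u, twist)
}

#' Build a water n-mer with a prescribed central topology
#'
#' Constructs a central water plus neighbour molecules so that the
#' central water has exactly the requested accepted and donated hydrogen
#' bonds at the requested distances (donated O-H bonds at 0.968 A, free
#' ones at 0.962 A).  Donated bonds leave along the two O-H directions;
#' accepted bonds arrive along the two lone-pair directions.  The
#' placement is verified with the hydrogen-bond detector and re-tried
#' with perturbed azimuths (seeded) until the detected bond set equals
#' the specification; unsatisfiable placements raise an error after
#' bounded retries.
#'
#' @param spec a [topology_spec()].
#' @param seed integer seed for placement retries.
#' @param max_retries bound on placement attempts.
#' @param verify_args list of overrides for the verification detector
#'   (passed to [detect_hbonds()]).
#' @return A [molecular_system][assign_molecules]; molecule 1 is the
#'   central water.
#' @examples
#' sys <- make_multimer(topology_spec(2, 2, distances = 1.70))
#' profile_waters(sys)[[1]]
#' @export
make_multimer <- function(spec, seed = 1L, max_retries = 40L,
                          verify_args = list()) {
  stopifnot(inherits(spec, "topology_spec"))
  half <- 104.5 / 2
  d_h <- rbind(c(deg_cos(half), deg_sin(half), 0),
               c(deg_cos(half), -deg_sin(half), 0))
  lp_half <- 109.5 / 2
  d_lp <- rbind(c(-deg_cos(lp_half), 0, deg_sin(lp_half)),
                c(-deg_cos(lp_half), 0, -deg_sin(lp_half)))
  o_c <- c(0, 0, 0)
  r_oh <- c(if (spec$n_donate >= 1) 0.968 else 0.962,
            if (spec$n_donate >= 2) 0.968 else 0.962)
  h_pos <- rbind(r_oh[1] * d_h[1, ], r_oh[2] * d_h[2, ])

  idx_a <- seq_len(spec$n_accept)
  idx_d <- spec$n_accept + seq_len(spec$n_donate)
  base_az <- c(90, -90)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  for (attempt in seq_len(max_retries)) {
    az_jit <- if (attempt == 1) rep(0, 4) else stats::runif(4, -180, 180)
    tw_jit <- if (attempt == 1) rep(0, 4) else stats::runif(4, -180, 180)
    elements <- c("O", "H", "H")
    pos <- rbind(o_c, h_pos)
    ok <- TRUE
    slot <- 0L
    for (j in seq_len(spec$n_accept)) {
      slot <- slot + 1L
      part <- tryCatch(place_partner(
        "accepted", spec$partner_kinds[idx_a[j]], o_c, d_lp[j, ],
        r = spec$distances[idx_a[j]], hb_angle = spec$hb_angle,
        azimuth = base_az[j] + az_jit[slot], twist = tw_jit[slot]),
        error = function(e) NULL)
      if (is.null(part)) { ok <- FALSE; break }
      elements <- c(elements, part$elements)
      pos <- rbind(pos, part$pos)
    }
    if (ok) for (i in seq_len(spec$n_donate)) {
      slot <- slot + 1L
      part <- tryCatch(place_partner(
        "donated", spec$partner_kinds[idx_d[i]], o_c, h_pos[i, ],
        r = spec$distances[idx_d[i]], hb_angle = spec$hb_angle,
        azimuth = base_az[i] + az_jit[slot], twist = tw_jit[slot]),
        error = function(e) NULL)
      if (is.null(part)) { ok <- FALSE; next }
      elements <- c(elements, part$elements)
      pos <- rbind(pos, part$pos)
    }
    if (!ok) next
    sys <- tryCatch(
      suppressWarnings(assign_molecules(atoms_from(elements, pos))),
      error = function(e) NULL)
    if (is.null(sys)) next
    if (multimer_matches(sys, spec, verify_args)) return(sys)
  }
  stop("could not place neighbours without spurious interactions after ",
       max_retries, " attempts")
}

multimer_matches <- function(sys, spec, verify_args = list()) {
  kinds <- vapply(sys$molecules, `[[`, character(1), "kind")
  if (kinds[1] != "water") return(FALSE)
  expected_kinds <- c("water", spec$partner_kinds)
  if (length(kinds) != length(expected_kinds)) return(FALSE)
  if (!all(sort(kinds[-1]) == sort(spec$partner_kinds))) return(FALSE)
  hb <- do.call(detect_hbonds, c(list(sys), verify_args))
  ch <- detect_ch_contacts(sys)
  if (nrow(ch)) return(FALSE)
  if (nrow(hb) != spec$n_accept + spec$n_donate) return(FALSE)
  prof <- profile_waters(sys, hb, ch)
  central <- prof[[1]]
  if (central$n_accepted != spec$n_accept ||
      central$n_donated != spec$n_donate) return(FALSE)
  got <- sort(c(central$accepted$r_hb, central$donated$r_hb))
  want <- sort(spec$distances)
  length(got) == length(want) && all(abs(got - want) < 1e-6)
}

#' Generate a DMSO-water complex in a named conformation
#'
#' Simplified rigid DMSO.H2O geometries reproducing the interaction
#' patterns of the three reference conformers: Conf1 — water donates to
#' the S=O oxygen and accepts one CH...O contact from each methyl;
#' Conf2 — the donation plus a single CH...O contact; Conf3 — two
#' CH...O contacts only.  The requested H...O distances are exact by
#' construction (the contact C-H is collinear with the water oxygen).
#'
#' @param conf conformer number, 1, 2 or 3.
#' @param r_os O-H...O=S hydrogen-bond distance, A (ignored for Conf3).
#' @param r_ch CH...O contact distance, A.
#' @return A [molecular_system][assign_molecules]; molecule 1 is the
#'   water.
#' @examples
#' nrow(detect_ch_contacts(make_dmso_water(3)))  # 2
#' @export
make_dmso_water <- function(conf = 1, r_os = 1.8, r_ch = 2.4) {
  stopifnot(conf %in% 1:3, r_ch > 1.5, r_os > 1.2)
  o_w <- c(0, 0, 0)
  r_cap <- r_ch + 1.09  # carbon shell so the collinear C-H hits r_ch

  if (conf %in% c(1, 2)) {
    u_d <- c(-1, 0, 0)
    h1 <- 0.968 * u_d
    w <- c(-deg_cos(16.3), -deg_sin(16.3), 0)  # O-H...O angle 163.7
    o_s <- h1 + r_os * w
    s_dir <- as.numeric(rotation_about(c(0, 0, 1), 60) %*% w)
    s <- o_s + 1.50 * s_dir
    h2 <- 0.962 * c(deg_cos(75.5), deg_sin(75.5), 0)  # 104.5 from u_d
    n_toward <- if (conf == 1) 2L else 1L
    carbons <- methyl_carbons(o_w, s, r_cap, n_toward, avoid = o_s)
    elements <- c("O", "H", "H", "O", "S")
    pos <- rbind(o_w, h1, h2, o_s, s)
  } else {
    half <- 104.5 / 2
    h1 <- 0.962 * c(deg_cos(half), deg_sin(half), 0)
    h2 <- 0.962 * c(deg_cos(half), -deg_sin(half), 0)
    s <- c(-4.2, 0, 0)
    o_s <- s + 1.50 * vunit(s)
    carbons <- methyl_carbons(o_w, s, r_cap, 2L, avoid = o_s)
    elements <- c("O", "H", "H", "O", "S")
    pos <- rbind(o_w, h1, h2, o_s, s)
  }
  for (k in seq_along(carbons)) {
    elements <- c(elements, "C", "H", "H", "H")
    pos <- rbind(pos, carbons[[k]])
  }
  assign_molecules(atoms_from(elements, pos))
}

## Methyl groups for the DMSO builder.  `n_toward` carbons sit on the
## sphere |C - water O| = r_cap and |C - S| = 1.81 with one C-H pointing
## collinearly at the water oxygen; remaining carbons are placed on the
## far side of S.  Each methyl's other hydrogens point away from the
## water and from `avoid` (the S=O oxygen).
methyl_carbons <- function(o_w, s, r_cap, n_toward, avoid) {
  d <- vnorm(s - o_w)
  t0 <- (d^2 + r_cap^2 - 1.81^2) / (2 * d)
  rho2 <- r_cap^2 - t0^2
  if (rho2 <= 0)
    stop("requested DMSO distances are geometrically unsatisfiable")
  rho <- sqrt(rho2)
  a <- vunit(s - o_w)
  perp <- avoid - sum(avoid * a) * a
  e1 <- if (vnorm(perp) > 1e-6) -vunit(perp) else orthonormal_to(a)
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  phis <- c(45, -45)
  out <- list()
  for (k in seq_len(n_toward)) {
    cpos <- o_w + t0 * a +
      rho * (deg_cos(phis[k]) * e1 + deg_sin(phis[k]) * e2)
    out[[k]] <- methyl_group(cpos, o_w, s, avoid, toward = TRUE)
  }
  for (k in seq_len(2L - n_toward)) {
    cpos <- s + 1.81 * a  # far side, pointing away from the water
    out[[n_toward + k]] <- methyl_group(cpos, o_w, s, avoid, toward = FALSE)
  }
  out
}

## One methyl: carbon plus three H.  When `toward`, one H is collinear
## C -> water O; the other H's are chosen on a tetrahedral cone to
## maximise clearance from S, the S=O oxygen and the water.
methyl_group <- function(cpos, o_w, s, avoid, toward) {
  rhat <- vunit(cpos - o_w)
  if (toward) {
    h_point <- cpos - 1.09 * rhat
    base <- rhat        # cone axis for the remaining H's
    n_rest <- 2L
  } else {
    h_point <- NULL
    base <- vunit(cpos - s)
    n_rest <- 3L
  }
  p <- orthonormal_to(base)
  q <- c(base[2] * p[3] - base[3] * p[2],
         base[3] * p[1] - base[1] * p[3],
         base[1] * p[2] - base[2] * p[1])
  cand <- lapply(seq(0, 330, by = 30), function(phi)
    cpos + 1.09 * (deg_cos(70.5) * base +
                     deg_sin(70.5) * (deg_cos(phi) * p + deg_sin(phi) * q)))
  clearance <- vapply(cand, function(h)
    min(vdist(h, s), vdist(h, avoid), vdist(h, o_w) * 0.5), numeric(1))
  picks <- order(clearance, decreasing = TRUE)
  sel <- integer(0)
  for (i in picks) {
    if (length(sel) == n_rest) break
    if (all(vapply(sel, function(j)
      vdist(cand[[i]], cand[[j]]) > 1.0, logical(1))))
      sel <- c(sel, i)
  }
  rbind(cpos, h_point, do.call(rbind, cand[sel]))
}

#' Seeded pseudo-trajectory by Gaussian perturbation
#'
#' Displaces every atom by isotropic Gaussian noise of the given
#' amplitude, then re-projects each covalent X-H bond to its original
#' length (rigid bonds), emulating the hydrogen-bond distance and angle
#' fluctuations of an MD trajectory.  Deterministic given the seed.
#'
#' @param sys a [molecular_system][assign_molecules].
#' @param n_frames number of frames to generate.
#' @param amplitude Gaussian displacement amplitude, A.
#' @param seed integer seed.
#' @return List of `molecular_system` frames with sequential `frame_id`.
#' @export
perturb_trajectory <- function(sys, n_frames, amplitude, seed = 1L) {
  stopifnot(inherits(sys, "molecular_system"), n_frames >= 1,
            amplitude >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  pos0 <- as.matrix(sys$atoms[, c("x", "y", "z")])
  is_h <- sys$atoms$element == "H"
  xh <- rbind(
    sys$bonds[is_h[sys$bonds[, 2]] & !is_h[sys$bonds[, 1]], , drop = FALSE],
    sys$bonds[is_h[sys$bonds[, 1]] & !is_h[sys$bonds[, 2]], c(2, 1),
              drop = FALSE])
  r0 <- vapply(seq_len(nrow(xh)), function(k)
    vdist(pos0[xh[k, 1], ], pos0[xh[k, 2], ]), numeric(1))
  lapply(seq_len(n_frames) - 1L, function(f) {
    pos <- pos0 + amplitude * matrix(stats::rnorm(length(pos0)),
                                     nrow(pos0), 3)
    for (k in seq_len(nrow(xh))) {
      x <- pos[xh[k, 1], ]
      pos[xh[k, 2], ] <- x + r0[k] * vunit(pos[xh[k, 2], ] - x)
    }
    atoms <- sys$atoms
    atoms$x <- pos[, 1]; atoms$y <- pos[, 2]; atoms$z <- pos[, 3]
    assign_molecules(atoms[, c("element", "x", "y", "z")], frame_id = f)
  })
}

#' Generate a methane-water complex
#'
#' A methane molecule with one C-H pointing collinearly at the water
#' oxygen at the requested CH...O distance; the model system behind the
#' r^-6 methane term.
#'
#' @param r_ch H...O distance, A.
#' @return A [molecular_system][assign_molecules]; molecule 1 is the
#'   water.
#' @export
make_methane_water <- function(r_ch = 2.6) {
  stopifnot(r_ch > 1.5)
  half <- 104.5 / 2
  o_w <- c(0, 0, 0)
  h1 <- 0.962 * c(deg_cos(half), deg_sin(half), 0)
  h2 <- 0.962 * c(deg_cos(half), -deg_sin(half), 0)
  cpos <- c(-(r_ch + 1.09), 0, 0)
  h_point <- cpos + 1.09 * c(1, 0, 0)
  base <- c(-1, 0, 0)
  dirs <- lapply(c(0, 120, 240), function(phi)
    deg_cos(70.5) * base + deg_sin(70.5) *
      (deg_cos(phi) * c(0, 1, 0) + deg_sin(phi) * c(0, 0, 1)))
  hs <- t(vapply(dirs, function(d) cpos + 1.09 * d, numeric(3)))
  pos <- rbind(o_w, h1, h2, cpos, h_point, hs)
  assign_molecules(atoms_from(c("O", "H", "H", "C", "H", "H", "H", "H"),
                              pos))
}
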