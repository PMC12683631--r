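## Empirical 17O chemical-shift model for water.
##
## All shifts are deshieldings in ppm relative to an isolated water
## molecule unless re-referenced to bulk.  The water-water terms are
## r^-4 power laws in the hydrogen-bond (H...O) distance, with separate
## slopes for the acceptor and donor roles; DMSO S=O and CH...O terms are
## r^-6.  Raw per-bond sums are mapped to cluster-level shifts by linear
## calibrations fitted separately for waters with and without a dangling
## O-H.

#' Model parameter set
#'
#' Returns every fitted constant of the shift model as a named, versioned
#' list.  Distance-function slopes are in ppm A^4 (water-water) or
#' ppm A^6 (DMSO and CH...O); calibration scales are dimensionless and
#' intercepts in ppm.
#'
#' @param variant calibration variant:
#'   * `"default"` — relaxed-geometry dimer slopes (137.08 / 60.98
#'     ppm A^4) with the split dangling / no-dangling calibration
#'     (1.20 / −0.64 and 1.38 / −0.78);
#'   * `"unrelaxed"` — dimer slopes without geometry relaxation
#'     (120 / 40 ppm A^4);
#'   * `"global"` — a single calibration over all sites
#'     (1.43 / −4.05) instead of the split one;
#'   * `"global_blcorr"` — single calibration for bond-length-corrected
#'     predictions (1.05 / 0.08).
#' @param ... named overrides for individual constants.
#' @return Object of class `shift_params`.
#' @examples
#' p <- shift_params()
#' p$slope_acceptor
#' @export
shift_params <- function(variant = c("default", "unrelaxed", "global",
                                     "global_blcorr"), ...) {
  variant <- match.arg(variant)
  p <- list(
    ## water-water dimer power laws (ppm A^4)
    slope_acceptor = 137.08,
    slope_donor = 60.98,
    slope_acceptor_unrelaxed = 120,
    slope_donor_unrelaxed = 40,
    ## cluster calibrations (scale dimensionless, intercept ppm)
    scale_nodangling = 1.38,
    intercept_nodangling = -0.78,
    scale_dangling = 1.20,
    intercept_dangling = -0.64,
    scale_global = 1.43,
    intercept_global = -4.05,
    scale_global_blcorr = 1.05,
    intercept_global_blcorr = 0.08,
    ## bond-length-corrected calibrations (zero intercept)
    scale_nodangling_blcorr = 1.12,
    scale_dangling_blcorr = 0.95,
    ## DMSO / CH...O r^-6 terms (ppm A^6)
    slope_ch_methane = 1694.2,
    scale_conf3 = 1.13,
    scale_conf1 = 0.94,
    slope_so_base = 286.99,
    coeff_so_eq3 = 270.49,
    coeff_ch_eq3 = 1799.10,
    ## glycerol partner scaling (dimensionless)
    scale_glycerol = 0.9,
    ## covalent-bond sensitivity and reference geometry
    dshield_dr = -579.36,   # ppm/A, both O-H bonds moving together
    r_oh_free = 0.962,      # A, non-hydrogen-bonded O-H
    r_oh_hbonded = 0.968,   # A, donated O-H
    ## reference shieldings / offsets
    sigma_isolated = 326.14,  # ppm, isolated molecule reference
    bulk_offset = 36.1,       # ppm, bulk water vs isolated molecule
    ## cluster-level per-bond constants (ppm)
    per_bond_accept = 16.5,
    per_bond_donate = 7.4,
    ppm_per_hbond = 10,
    variant = variant,
    version = "1.0"
  )
  if (variant == "unrelaxed") {
    p$slope_acceptor <- p$slope_acceptor_unrelaxed
    p$slope_donor <- p$slope_donor_unrelaxed
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$dshield_dr < 0, p$slope_acceptor > 0, p$slope_donor > 0)
  structure(p, class = "shift_params")
}

#' @export
print.shift_params <- function(x, ...) {
  cat(sprintf("shift_params v%s (variant '%s')\n", x$version, x$variant))
  cat(sprintf("  acceptor %.2f / donor %.2f ppm A^4; calibration %s\n",
              x$slope_acceptor, x$slope_donor,
              if (x$variant %in% c("global", "global_blcorr"))
                "single" else "split dangling/no-dangling"))
  invisible(x)
}

#' Save / load a parameter set as JSON
#'
#' @param params a [shift_params()] object.
#' @param path JSON file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   a `shift_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "shift_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(shift_params, c(list(variant = p$variant),
                          p[setdiff(names(p), c("variant", "version"))]))
}

check_distance <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("distance must be positive and finite")
  invisible(r)
}

#' Water-water distance terms
#'
#' Per-bond deshielding of a water 17O as a function of the hydrogen-bond
#' (H...O) distance: `slope / r^4`, with the acceptor slope roughly twice
#' the donor slope.  `acceptor_term` applies when the water's oxygen
#' accepts the bond; `donor_term` when one of its hydrogens is donated.
#'
#' @param r_hb H...O distance, Angstrom (vectorised).
#' @param params a [shift_params()] object.
#' @return Deshielding contribution in ppm.
#' @examples
#' acceptor_term(1.7)   # 16.41 ppm
#' donor_term(2.0)      # 3.81 ppm
#' @export
acceptor_term <- function(r_hb, params = shift_params()) {
  check_distance(r_hb)
  params$slope_acceptor / r_hb^4
}

#' @rdname acceptor_term
#' @export
donor_term <- function(r_hb, params = shift_params()) {
  check_distance(r_hb)
  params$slope_donor / r_hb^4
}

#' DMSO interaction terms
#'
#' Deshielding of the water 17O from a DMSO neighbour: an r^-6 term for
#' the donated O-H...O=S bond plus one r^-6 term per CH...O methyl
#' contact (the symmetric two-methyl arrangement doubles the CH term).
#'
#' @param r_os O-H...O=S hydrogen-bond distance (H to S=O oxygen), A;
#'   `NULL` or `NA` if the water does not donate to DMSO.
#' @param r_ch vector of CH...O contact distances (H to water O), A; may
#'   be empty.
#' @param params a [shift_params()] object.
#' @return Total DMSO contribution, ppm.
#' @examples
#' dmso_terms(1.8, c(2.4, 2.4))  # 26.78 ppm
#' @export
dmso_terms <- function(r_os = NULL, r_ch = numeric(0),
                       params = shift_params()) {
  out <- 0
  if (!is.null(r_os) && length(r_os) && !all(is.na(r_os))) {
    r_os <- r_os[!is.na(r_os)]
    check_distance(r_os)
    out <- out + sum(params$coeff_so_eq3 / r_os^6)
  }
  if (length(r_ch)) {
    check_distance(r_ch)
    out <- out + sum(params$coeff_ch_eq3 / r_ch^6)
  }
  out
}

#' Methane CH...O base term
#'
#' The unscaled water-methane deshielding `1694.2 / r^6` derived from the
#' CH4.H2O model, optionally multiplied by the Conf3 scaling (1.13) that
#' maps it onto the DMSO methyl environment.
#'
#' @param r HO...HC distance, Angstrom (vectorised).
#' @param params a [shift_params()] object.
#' @param scaled apply the Conf3 scaling factor (default `FALSE`).
#' @return ppm contribution.
#' @export
methane_base_term <- function(r, params = shift_params(), scaled = FALSE) {
  check_distance(r)
  out <- params$slope_ch_methane / r^6
  if (scaled) out <- out * params$scale_conf3
  out
}

#' Covalent O-H bond-length correction
#'
#' Deshielding from stretched covalent O-H bonds relative to the free
#' bond length (0.962 A): half the simultaneous-stretch derivative
#' (−579.36 ppm/A over both bonds) per bond, i.e.
#' `sum(289.68 * (r_oh − 0.962))`.  Positive for stretched bonds.
#'
#' @param oh_lengths the water's two covalent O-H lengths, A.
#' @param params a [shift_params()] object.
#' @return Correction in ppm.
#' @examples
#' bond_length_correction(c(0.968, 0.962))  # 1.74 ppm
#' @export
bond_length_correction <- function(oh_lengths, params = shift_params()) {
  stopifnot(is.numeric(oh_lengths), all(is.finite(oh_lengths)))
  if (any(oh_lengths < 0.8 | oh_lengths > 1.2))
    warning("O-H length outside [0.8, 1.2] A; hydrogen may be mis-assigned",
            call. = FALSE)
  sum(abs(params$dshield_dr) / 2 * (oh_lengths - params$r_oh_free))
}

#' Additivity estimate from per-bond cluster constants
#'
#' The coarse cluster-level estimate: 16.5 ppm per accepted and 7.4 ppm
#' per donated hydrogen bond, assumed additive.
#'
#' @param n_accept,n_donate hydrogen-bond counts (vectorised).
#' @param params a [shift_params()] object.
#' @return ppm relative to the isolated molecule.
#' @examples
#' additivity_estimate(1, 1)  # 23.9
#' @export
additivity_estimate <- function(n_accept, n_donate,
                                params = shift_params()) {
  stopifnot(all(n_accept >= 0), all(n_donate >= 0))
  params$per_bond_accept * n_accept + params$per_bond_donate * n_donate
}

#' Convert absolute shielding to chemical shift
#'
#' `delta = sigma_ref − sigma`, so a site less shielded than the
#' reference has a positive shift.
#'
#' @param sigma absolute shielding, ppm (vectorised).
#' @param params a [shift_params()] object supplying the default
#'   isolated-molecule reference (326.14 ppm).
#' @param sigma_ref reference shielding override, ppm.
#' @return Chemical shift, ppm.
#' @export
shielding_to_shift <- function(sigma, params = shift_params(),
                               sigma_ref = NULL) {
  if (is.null(sigma_ref)) sigma_ref <- params$sigma_isolated
  sigma_ref - sigma
}

#' Re-reference a shift from the isolated molecule to bulk water
#'
#' Bulk water is 36.1 ppm deshielded from the isolated molecule, so
#' `delta_bulk = delta_isolated − 36.1`.
#'
#' @param delta_isolated shift vs the isolated molecule, ppm.
#' @param params a [shift_params()] object.
#' @return Shift vs bulk water, ppm.
#' @export
rereference_to_bulk <- function(delta_isolated, params = shift_params()) {
  delta_isolated - params$bulk_offset
}

## Per-bond term table for one water profile.  Water-water and glycerol
## bonds enter the calibrated raw sum ("inside" terms); donations to the
## DMSO S=O oxygen and CH...O contacts are independently calibrated
## r^-6 terms added outside the calibration.
profile_terms <- function(profile, params) {
  rows <- list()
  add <- function(label, partner_kind, partner_mol, r, ppm, inside) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, partner_kind = partner_kind,
      partner_mol = partner_mol, distance = r, ppm = ppm, inside = inside)
  }
  acc <- profile$accepted
  for (k in seq_len(nrow(acc))) {
    scale <- if (acc$donor_kind[k] == "glycerol") params$scale_glycerol else 1
    add("accept", acc$donor_kind[k], acc$donor_mol[k], acc$r_hb[k],
        scale * params$slope_acceptor / acc$r_hb[k]^4, TRUE)
  }
  don <- profile$donated
  for (k in seq_len(nrow(don))) {
    if (don$acceptor_kind[k] == "dmso") {
      add("donate_so", "dmso", don$acceptor_mol[k], don$r_hb[k],
          params$coeff_so_eq3 / don$r_hb[k]^6, FALSE)
    } else {
      scale <- if (don$acceptor_kind[k] == "glycerol")
        params$scale_glycerol else 1
      add("donate", don$acceptor_kind[k], don$acceptor_mol[k], don$r_hb[k],
          scale * params$slope_donor / don$r_hb[k]^4, TRUE)
    }
  }
  ch <- profile$ch_contacts
  for (k in seq_len(nrow(ch))) {
    add("ch_contact", ch$donor_kind[k], ch$donor_mol[k], ch$r_hb[k],
        params$coeff_ch_eq3 / ch$r_hb[k]^6, FALSE)
  }
  if (!length(rows))
    return(data.frame(label = character(0), partner_kind = character(0),
                      partner_mol = integer(0), distance = numeric(0),
                      ppm = numeric(0), inside = logical(0)))
  do.call(rbind, rows)
}

#' Raw (uncalibrated) water-water shift sum
#'
#' The bracketed sum of the shift equations: acceptor and donor r^-4
#' terms over the water's conventional hydrogen bonds, with glycerol
#' partners scaled by 0.9.  Donations to the DMSO S=O oxygen and CH...O
#' contacts are excluded here (they carry their own r^-6 terms).
#'
#' @param profile a `water_profile` from [profile_waters()].
#' @param params a [shift_params()] object.
#' @return Raw sum, ppm.
#' @export
raw_water_sum <- function(profile, params = shift_params()) {
  stopifnot(inherits(profile, "water_profile"))
  terms <- profile_terms(profile, params)
  sum(terms$ppm[terms$inside])
}

#' Calibrated 17O shift of one water molecule
#'
#' Evaluates the full empirical model for a water's hydrogen-bond
#' profile.  The raw water/glycerol sum is mapped through the linear
#' calibration selected by the dangling flag (scale 1.38, intercept
#' −0.78 for no-dangling sites; 1.20 / −0.64 for dangling sites), and the
#' independently calibrated DMSO S=O and CH...O r^-6 terms are then added
#' outside the calibration.  With `bond_length_corrected = TRUE` the
#' covalent-stretch correction is added to the raw sum and the
#' zero-intercept slopes (1.12 / 0.95) are used instead.  A water with no
#' bonds of any kind is at the isolated-molecule reference (0 ppm), and a
#' water whose only interactions are DMSO/CH terms receives those terms
#' with no water-water calibration applied.
#'
#' @param profile a `water_profile` from [profile_waters()].
#' @param params a [shift_params()] object.
#' @param bond_length_corrected use the bond-length-corrected variant.
#' @return Object of class `shift_breakdown` with fields `water`,
#'   `delta_isolated_ref`, `delta_bulk_ref` (ppm), `terms` (per-term data
#'   frame), `calibration` (label), `raw_sum`,
#'   `bond_length_correction` and `n_accepted`/`n_donated`/`dangling`.
#' @examples
#' pent <- make_multimer(topology_spec(n_accept = 2, n_donate = 2,
#'                                     distances = 1.70))
#' prof <- profile_waters(pent)
#' central <- prof[[which.max(vapply(prof, function(p)
#'   p$n_accepted + p$n_donated, numeric(1)))]]
#' calibrated_water_shift(central)  # 64.67 ppm
#' @export
calibrated_water_shift <- function(profile, params = shift_params(),
                                   bond_length_corrected = FALSE) {
  stopifnot(inherits(profile, "water_profile"))
  terms <- profile_terms(profile, params)
  raw <- sum(terms$ppm[terms$inside])
  outside <- sum(terms$ppm[!terms$inside])
  n_inside <- sum(terms$inside)
  global <- params$variant %in% c("global", "global_blcorr")
  blc <- 0
  if (n_inside == 0) {
    calibrated <- 0
    label <- "none"
  } else if (bond_length_corrected) {
    blc <- bond_length_correction(profile$oh_lengths, params)
    if (global) {
      calibrated <- params$scale_global_blcorr * (raw + blc) +
        params$intercept_global_blcorr
      label <- "global_blcorr"
    } else if (profile$dangling) {
      calibrated <- params$scale_dangling_blcorr * (raw + blc)
      label <- "dangling_blcorr"
    } else {
      calibrated <- params$scale_nodangling_blcorr * (raw + blc)
      label <- "nodangling_blcorr"
    }
  } else if (global) {
    calibrated <- params$scale_global * raw + params$intercept_global
    label <- "global"
  } else if (profile$dangling) {
    calibrated <- params$scale_dangling * raw + params$intercept_dangling
    label <- "dangling"
  } else {
    calibrated <- params$scale_nodangling * raw + params$intercept_nodangling
    label <- "nodangling"
  }
  delta <- calibrated + outside
  structure(list(
    water = profile$water,
    delta_isolated_ref = delta,
    delta_bulk_ref = delta - params$bulk_offset,
    terms = terms,
    calibration = label,
    raw_sum = raw,
    bond_length_correction = blc,
    n_accepted = profile$n_accepted,
    n_donated = profile$n_donated,
    dangling = profile$dangling
  ), class = "shift_breakdown")
}

#' @export
print.shift_breakdown <- function(x, ...) {
  cat(sprintf(
    "water %d [%dA %dD%s, calibration %s]\n  delta = %.2f ppm (isolated ref) = %.2f ppm (bulk ref)\n",
    x$water, x$n_accepted, x$n_donated,
    if (x$dangling) ", dangling" else "", x$calibration,
    x$delta_isolated_ref, x$delta_bulk_ref))
  if (nrow(x$terms)) {
    cat(sprintf("  %-10s %-9s r=%.3f A  %6.2f ppm%s\n", x$terms$label,
                x$terms$partner_kind, x$terms$distance, x$terms$ppm,
                ifelse(x$terms$inside, "", " (uncalibrated add-on)")),
        sep = "")
  }
  invisible(x)
}

#' Predict shifts for every water in a system
#'
#' Runs hydrogen-bond detection, profiling and the calibrated shift model
#' over one structure.
#'
#' @param sys a [molecular_system][assign_molecules].
#' @param params a [shift_params()] object.
#' @param r_max,angle_min,use_angle hydrogen-bond criteria, see
#'   [detect_hbonds()].
#' @param ch_r_max CH...O cutoff, see [detect_ch_contacts()].
#' @param bond_length_corrected see [calibrated_water_shift()].
#' @return Data frame with one row per water: `frame`, `water`,
#'   `n_accepted`, `n_donated`, `n_ch`, `dangling`, `calibration`,
#'   `raw_sum`, `delta_isolated`, `delta_bulk` (ppm).
#' @export
predict_shifts <- function(sys, params = shift_params(), r_max = 2.5,
                           angle_min = 150, use_angle = TRUE,
                           ch_r_max = 3.0, bond_length_corrected = FALSE) {
  hb <- detect_hbonds(sys, r_max, angle_min, use_angle)
  ch <- detect_ch_contacts(sys, ch_r_max)
  profiles <- profile_waters(sys, hb, ch)
  rows <- lapply(profiles, function(p) {
    b <- calibrated_water_shift(p, params, bond_length_corrected)
    data.frame(frame = sys$frame_id, water = p$water,
               n_accepted = p$n_accepted, n_donated = p$n_donated,
               n_ch = nrow(p$ch_contacts), dangling = p$dangling,
               calibration = b$calibration, raw_sum = b$raw_sum,
               delta_isolated = b$delta_isolated_ref,
               delta_bulk = b$delta_bulk_ref)
  })
  if (!length(rows))
    return(data.frame(frame = integer(0), water = integer(0),
                      n_accepted = integer(0), n_donated = integer(0),
                      n_ch = integer(0), dangling = logical(0),
                      calibration = character(0), raw_sum = numeric(0),
                      delta_isolated = numeric(0), delta_bulk = numeric(0)))
  do.call(rbind, rows)
}
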