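# Independent oracles and random-structure generators used across the
# suite.  These deliberately avoid the package's detector/model code
# paths: covalent O-H pairs are re-derived from raw coordinates and the
# shift equations are evaluated by direct arithmetic.

pos_of <- function(sys, i) as.numeric(sys$atoms[i, c("x", "y", "z")])

dist3 <- function(a, b) sqrt(sum((a - b)^2))

angle3 <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Exhaustive all-pairs hydrogen-bond oracle: every (H, O) pair with the
# H within 1.2 A of exactly one oxygen (its covalent donor) and the
# candidate acceptor O in a different molecule, under the distance and
# optional angle criteria.  Returns a sorted matrix of
# (donor_O, H, acceptor_O) index triples with r and angle.
brute_force_hbonds <- function(sys, r_max = 2.5, angle_min = 150,
                               use_angle = TRUE) {
  el <- sys$atoms$element
  n <- nrow(sys$atoms)
  pos <- as.matrix(sys$atoms[, c("x", "y", "z")])
  mol <- sys$atoms$molecule_id
  out <- NULL
  for (h in which(el == "H")) {
    dists_o <- vapply(which(el == "O"), function(o)
      dist3(pos[h, ], pos[o, ]), numeric(1))
    os <- which(el == "O")
    cov <- os[dists_o < 1.2]
    if (length(cov) != 1) next
    for (a in os) {
      if (a == cov || mol[a] == mol[h]) next
      r <- dist3(pos[h, ], pos[a, ])
      if (r >= r_max) next
      ang <- angle3(pos[cov, ], pos[h, ], pos[a, ])
      if (use_angle && ang <= angle_min) next
      out <- rbind(out, c(cov, h, a, r, ang))
    }
  }
  if (is.null(out)) return(matrix(numeric(0), ncol = 5))
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

# Canonical (donor O, H, acceptor O) triple matrix for set comparison.
canon_triples <- function(x) {
  m <- if (is.data.frame(x))
    as.matrix(x[, c("donor_heavy", "hydrogen", "acceptor_heavy")])
  else x[, 1:3, drop = FALSE]
  m <- matrix(as.numeric(m), ncol = 3)
  unname(m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE])
}

# Random cluster of n waters: O positions drawn in a cube with a minimum
# O-O separation of 2.4 A (so no covalent ambiguity), random rigid
# orientations.  Produces a mix of bonded and non-bonded geometries.
random_water_cluster <- function(n, box = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(box)) box <- max(6, 3.2 * n^(1/3) + 3)
  centres <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    cand <- runif(3, 0, box)
    if (k == 0 || min(sqrt(rowSums(sweep(centres[seq_len(k), , drop = FALSE],
                                         2, cand)^2))) > 2.4) {
      k <- k + 1
      centres[k, ] <- cand
    }
  }
  rand_rot <- function() {
    repeat {
      q <- rnorm(4)
      if (sum(q^2) > 1e-6) break
    }
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  template <- rbind(c(0, 0, 0),
                    c(0.962, 0, 0),
                    0.962 * c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0))
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- template %*% t(rand_rot())
    p <- sweep(p, 2, -centres[i, ])
    data.frame(element = c("O", "H", "H"), x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  assign_molecules(atoms)
}

# Hand-built water_profile (bypasses geometry entirely) for testing the
# shift model against direct formula evaluation.
fake_profile <- function(acc_r = numeric(0), acc_kind = "water",
                         don_r = numeric(0), don_kind = "water",
                         ch_r = numeric(0), ch_kind = "dmso",
                         oh = c(0.962, 0.962)) {
  acc_kind <- rep_len(acc_kind, length(acc_r))
  don_kind <- rep_len(don_kind, length(don_r))
  ch_kind <- rep_len(ch_kind, length(ch_r))
  row <- function(r, dk, ak, conv) {
    if (!length(r)) {
      return(data.frame(donor_mol = integer(0), acceptor_mol = integer(0),
                        donor_heavy = integer(0), hydrogen = integer(0),
                        acceptor_heavy = integer(0), r_hb = numeric(0),
                        angle_dha = numeric(0), donor_kind = character(0),
                        acceptor_kind = character(0),
                        conventional = logical(0)))
    }
    data.frame(donor_mol = seq_along(r) + 1L, acceptor_mol = 1L,
               donor_heavy = 0L, hydrogen = 0L, acceptor_heavy = 0L,
               r_hb = r, angle_dha = 170, donor_kind = dk,
               acceptor_kind = ak, conventional = conv)
  }
  accepted <- row(acc_r, acc_kind, "water", TRUE)
  donated <- row(don_r, "water", don_kind, TRUE)
  ch <- row(ch_r, ch_kind, "water", FALSE)
  # donated rows: this water is the donor
  if (nrow(donated)) {
    donated$donor_mol <- 1L
    donated$acceptor_mol <- seq_len(nrow(donated)) + 10L
    donated$donor_kind <- "water"
  }
  p <- list(water = 1L, o_atom = 1L, accepted = accepted, donated = donated,
            ch_contacts = ch, n_accepted = length(acc_r),
            n_donated = length(don_r), dangling = length(don_r) < 2,
            oh_lengths = oh)
  class(p) <- "water_profile"
  p
}

# Direct arithmetic evaluation of the calibrated shift equations for a
# fake_profile, written independently of the package implementation.
direct_shift <- function(acc_r, acc_kind, don_r, don_kind, ch_r,
                         dangling = length(don_r) < 2,
                         oh = c(0.962, 0.962), blcorr = FALSE) {
  inside <- 0
  outside <- 0
  n_inside <- 0
  for (i in seq_along(acc_r)) {
    s <- if (acc_kind[i] == "glycerol") 0.9 else 1.0
    inside <- inside + s * 137.08 / acc_r[i]^4
    n_inside <- n_inside + 1
  }
  for (i in seq_along(don_r)) {
    if (don_kind[i] == "dmso") {
      outside <- outside + 270.49 / don_r[i]^6
    } else {
      s <- if (don_kind[i] == "glycerol") 0.9 else 1.0
      inside <- inside + s * 60.98 / don_r[i]^4
      n_inside <- n_inside + 1
    }
  }
  for (r in ch_r) outside <- outside + 1799.10 / r^6
  if (n_inside == 0) return(outside)
  if (blcorr) {
    corr <- sum(579.36 / 2 * (oh - 0.962))
    scale <- if (dangling) 0.95 else 1.12
    return(scale * (inside + corr) + outside)
  }
  if (dangling) 1.20 * inside - 0.64 + outside
  else 1.38 * inside - 0.78 + outside
}
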