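test_that("XYZ files parse frame-by-frame with positions in file order", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "one water",
               "O 0.0 0.0 0.0",
               "H 0.962 0.0 0.0",
               "H -0.240974 0.931437 0.0"), f)
  frames <- read_xyz(f)
  expect_length(frames, 1)
  expect_equal(nrow(frames[[1]]$atoms), 3)
  expect_equal(frames[[1]]$atoms$element, c("O", "H", "H"))
  expect_equal(frames[[1]]$frame_id, 0L)

  # two concatenated 6-atom blocks -> 2 frames
  d <- make_dimer()
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(d, d), f2)
  frames2 <- read_xyz(f2)
  expect_length(frames2, 2)
  expect_equal(vapply(frames2, function(s) nrow(s$atoms), numeric(1)),
               c(6, 6))
  expect_equal(vapply(frames2, `[[`, integer(1), "frame_id"), 0:1)
})

test_that("malformed XYZ input raises parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("abc", "comment", "O 0 0 0"), f)
  expect_error(read_xyz(f), "line 1")

  writeLines(c("2", "comment", "O 0 0 0", "H 0.9 x 0"), f)
  expect_error(read_xyz(f), "non-numeric.*line 4|line 4.*non-numeric")

  writeLines(c("4", "comment", "O 0 0 0", "H 0.9 0 0"), f)
  expect_error(read_xyz(f), "truncated")
})

test_that("the canonical dimer file has the trigonometrically derived O-O distance", {
  # law of cosines on the stated geometry: r_OH = 0.968, r_HB = 1.71,
  # O-H...O = 163.7 deg
  oo_expected <- sqrt(0.968^2 + 1.71^2 -
                        2 * 0.968 * 1.71 * cos(163.7 * pi / 180))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(make_dimer(), f)
  sys <- read_xyz(f)[[1]]
  expect_equal(nrow(sys$atoms), 6)
  o_idx <- which(sys$atoms$element == "O")
  oo <- dist3(pos_of(sys, o_idx[1]), pos_of(sys, o_idx[2]))
  expect_equal(oo, oo_expected, tolerance = 1e-5)
})

test_that("write/read round trip preserves positions to 6 decimals", {
  sys <- make_multimer(topology_spec(2, 1, distances = 1.8))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(sys, f)
  back <- read_xyz(f)[[1]]
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(sys$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("covalent assignment types molecules by formula and fills roles", {
  # two waters far apart
  w <- make_water()
  atoms <- rbind(w$atoms[, 1:4],
                 transform(w$atoms[, 1:4], x = x + 10))
  sys <- assign_molecules(atoms)
  expect_length(sys$molecules, 2)
  expect_equal(vapply(sys$molecules, `[[`, character(1), "kind"),
               c("water", "water"))

  # canonical dimer: donated H belongs to the donor O
  d <- make_dimer()
  expect_true(any(d$bonds[, 1] == 1 & d$bonds[, 2] == 2 |
                    d$bonds[, 1] == 2 & d$bonds[, 2] == 1))
  oh <- dist3(pos_of(d, 1), pos_of(d, 2))
  expect_equal(oh, 0.968, tolerance = 1e-9)
  # and not to the acceptor O (atom 4)
  expect_false(any((d$bonds[, 1] == 4 & d$bonds[, 2] == 2) |
                     (d$bonds[, 1] == 2 & d$bonds[, 2] == 4)))

  # methane + water
  mw <- make_methane_water()
  kinds <- sort(vapply(mw$molecules, `[[`, character(1), "kind"))
  expect_equal(kinds, c("methane", "water"))

  # water roles
  wmol <- sys$molecules[[1]]
  expect_equal(sys$atoms$element[wmol$role_atoms$water_O], "O")
  expect_equal(sys$atoms$element[wmol$role_atoms$water_H1], "H")
})

test_that("an H within covalent range of two heavy atoms is flagged", {
  atoms <- data.frame(element = c("O", "H", "O"),
                      x = c(0, 1.0, 2.0), y = 0, z = 0)
  expect_error(assign_molecules(atoms), "ambiguous")
})

test_that("unrecognised formulas degrade to kind 'other' with a warning", {
  atoms <- data.frame(element = c("N", "H", "H", "H"),
                      x = c(0, 1.0, -0.35, -0.35),
                      y = c(0, 0, 0.94, -0.47), z = c(0, 0, 0, 0.82))
  expect_warning(sys <- assign_molecules(atoms), "other")
  expect_equal(sys$molecules[[1]]$kind, "other")
})

test_that("atom permutation changes no molecule kinds or bond set", {
  sys <- make_dmso_water(1)
  set.seed(7)
  perm <- sample(nrow(sys$atoms))
  sys2 <- assign_molecules(sys$atoms[perm, c("element", "x", "y", "z")])
  k1 <- sort(vapply(sys$molecules, `[[`, character(1), "kind"))
  k2 <- sort(vapply(sys2$molecules, `[[`, character(1), "kind"))
  expect_equal(k1, k2)
  # bond sets as unordered pairs of positions (map via perm)
  canon <- function(s, map = seq_len(nrow(s$atoms))) {
    b <- cbind(map[s$bonds[, 1]], map[s$bonds[, 2]])
    b <- t(apply(b, 1, sort))
    b[order(b[, 1], b[, 2]), ]
  }
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  expect_equal(canon(sys), canon(sys2, perm))
  # downstream shifts identical
  expect_equal(sort(predict_shifts(sys)$delta_isolated),
               sort(predict_shifts(sys2)$delta_isolated))
})

test_that("PDB records parse with residue-name hints reconciled by formula", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.962   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1      -0.241   0.931   0.000  1.00  0.00           H",
    "END"), f)
  sys <- read_pdb(f)[[1]]
  expect_length(sys$molecules, 1)
  expect_equal(sys$molecules[[1]]$kind, "water")

  # mis-named residue still typed by formula
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   XYZ A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  XYZ A   1       0.962   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  XYZ A   1      -0.241   0.931   0.000  1.00  0.00           H",
    "END"), f2)
  sys2 <- read_pdb(f2)[[1]]
  expect_equal(sys2$molecules[[1]]$kind, "water")
})

test_that("HETATM DMSO residues are typed from their formula", {
  d <- make_dmso_water(3)
  a <- d$atoms
  recs <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), a$element, ifelse(a$molecule_id == 1, "HOH", "DMS"),
    a$molecule_id, a$x, a$y, a$z, a$element)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(recs, "END"), f)
  sys <- read_pdb(f)[[1]]
  kinds <- sort(vapply(sys$molecules, `[[`, character(1), "kind"))
  expect_equal(kinds, c("dmso", "water"))
})
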