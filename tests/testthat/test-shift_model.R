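p0 <- shift_params()

test_that("acceptor and donor terms follow the r^-4 law", {
  expect_equal(acceptor_term(1.70), 137.08 / 1.7^4, tolerance = 1e-12)
  expect_equal(acceptor_term(2.00), 137.08 / 16, tolerance = 1e-12)
  expect_equal(donor_term(1.70), 60.98 / 1.7^4, tolerance = 1e-12)
  expect_equal(donor_term(2.00), 60.98 / 16, tolerance = 1e-12)
  # the ratio is distance-independent
  r <- seq(1.5, 3.5, by = 0.25)
  expect_equal(acceptor_term(r) / donor_term(r),
               rep(137.08 / 60.98, length(r)))
  expect_error(acceptor_term(0), "positive")
  expect_error(donor_term(-1), "positive")
})

test_that("every distance term is strictly decreasing, convex, and vanishes at large r", {
  r <- seq(1.5, 60, length.out = 400)
  for (f in list(acceptor_term, donor_term,
                 function(r) methane_base_term(r),
                 function(r) vapply(r, function(ri)
                   dmso_terms(r_os = ri), numeric(1)),
                 function(r) vapply(r, function(ri)
                   dmso_terms(r_ch = ri), numeric(1)))) {
    y <- f(r)
    expect_true(all(diff(y) < 0))
    expect_true(all(diff(diff(y)) > 0))  # convex
    expect_lt(f(1e6)[1], 1e-12)
  }
})

test_that("raw water sums add per-bond terms with glycerol scaling", {
  pr <- fake_profile(acc_r = 1.70, don_r = 1.70)
  expect_equal(raw_water_sum(pr), 137.08 / 1.7^4 + 60.98 / 1.7^4,
               tolerance = 1e-12)
  pr2 <- fake_profile(acc_r = c(1.70, 1.70), don_r = c(1.70, 1.70))
  expect_equal(raw_water_sum(pr2), 2 * (137.08 / 1.7^4 + 60.98 / 1.7^4),
               tolerance = 1e-12)
  expect_equal(raw_water_sum(fake_profile()), 0)
  # glycerol partner scaled by 0.9 inside the sum
  prg <- fake_profile(acc_r = 1.8, acc_kind = "glycerol")
  expect_equal(raw_water_sum(prg), 0.9 * 137.08 / 1.8^4, tolerance = 1e-12)
  # a donation to DMSO is excluded from the raw sum
  prd <- fake_profile(don_r = 1.8, don_kind = "dmso")
  expect_equal(raw_water_sum(prd), 0)
})

test_that("raw sums are additive over single-bond sub-profiles", {
  set.seed(5)
  for (k in 1:20) {
    acc <- runif(sample(0:2, 1), 1.6, 2.4)
    don <- runif(sample(0:2, 1), 1.6, 2.4)
    whole <- raw_water_sum(fake_profile(acc_r = acc, don_r = don))
    parts <- sum(vapply(acc, function(r)
      raw_water_sum(fake_profile(acc_r = r)), numeric(1))) +
      sum(vapply(don, function(r)
        raw_water_sum(fake_profile(don_r = r)), numeric(1)))
    expect_equal(whole, parts, tolerance = 1e-12)
  }
})

test_that("calibrated shifts reproduce hand evaluations of the two equations", {
  # no-dangling 2A2D at 1.70 A
  pr <- fake_profile(acc_r = c(1.7, 1.7), don_r = c(1.7, 1.7))
  b <- calibrated_water_shift(pr)
  expect_equal(b$delta_isolated_ref,
               1.38 * (2 * 137.08 / 1.7^4 + 2 * 60.98 / 1.7^4) - 0.78,
               tolerance = 1e-12)
  expect_equal(round(b$delta_isolated_ref, 2), 64.67)
  expect_equal(b$calibration, "nodangling")

  # dangling 1A1D at 1.70 A
  pr2 <- fake_profile(acc_r = 1.7, don_r = 1.7)
  b2 <- calibrated_water_shift(pr2)
  expect_equal(b2$delta_isolated_ref,
               1.20 * (137.08 / 1.7^4 + 60.98 / 1.7^4) - 0.64,
               tolerance = 1e-12)
  expect_equal(round(b2$delta_isolated_ref, 2), 27.82)
  expect_equal(b2$calibration, "dangling")

  # isolated water sits at the reference
  b3 <- calibrated_water_shift(fake_profile())
  expect_equal(b3$delta_isolated_ref, 0)
  expect_equal(b3$calibration, "none")
})

test_that("bulk re-referencing subtracts the 36.1 ppm gas-to-liquid offset", {
  pr <- fake_profile(acc_r = c(1.7, 1.7), don_r = c(1.7, 1.7))
  b <- calibrated_water_shift(pr)
  expect_equal(b$delta_bulk_ref + 36.1, b$delta_isolated_ref)
  expect_equal(rereference_to_bulk(36.1), 0)
  expect_equal(rereference_to_bulk(0), -36.1)
  expect_equal(rereference_to_bulk(rereference_to_bulk(5) + 36.1), 5 - 36.1)
})

test_that("shift breakdowns are invariant to bond ordering", {
  pr <- fake_profile(acc_r = c(1.7, 2.1), don_r = c(1.8, 2.3),
                     ch_r = c(2.5, 2.9))
  pr_rev <- pr
  pr_rev$accepted <- pr$accepted[2:1, ]
  pr_rev$donated <- pr$donated[2:1, ]
  pr_rev$ch_contacts <- pr$ch_contacts[2:1, ]
  expect_equal(calibrated_water_shift(pr)$delta_isolated_ref,
               calibrated_water_shift(pr_rev)$delta_isolated_ref)
})

test_that("raw_sum matches the sum of the inside term entries", {
  pr <- fake_profile(acc_r = c(1.7, 2.0), acc_kind = c("water", "glycerol"),
                     don_r = c(1.8, 2.2), don_kind = c("water", "dmso"),
                     ch_r = 2.6)
  b <- calibrated_water_shift(pr)
  expect_equal(b$raw_sum, sum(b$terms$ppm[b$terms$inside]))
  # the DMSO donation and the CH contact are outside the calibration
  expect_setequal(b$terms$label[!b$terms$inside], c("donate_so", "ch_contact"))
})

test_that("calibrated shifts equal direct formula evaluation on randomized profiles", {
  set.seed(101)
  kinds_a <- c("water", "glycerol")
  kinds_d <- c("water", "glycerol", "dmso")
  for (k in 1:1000) {
    na <- sample(0:2, 1)
    nd <- sample(0:2, 1)
    nc <- sample(0:2, 1)
    acc_r <- runif(na, 1.6, 2.45)
    don_r <- runif(nd, 1.6, 2.45)
    ch_r <- runif(nc, 2.2, 2.95)
    acc_kind <- sample(kinds_a, na, replace = TRUE)
    don_kind <- sample(kinds_d, nd, replace = TRUE)
    oh <- runif(2, 0.960, 0.975)
    blc <- k %% 2 == 0
    pr <- fake_profile(acc_r, acc_kind, don_r, don_kind, ch_r, oh = oh)
    got <- calibrated_water_shift(pr, bond_length_corrected = blc)
    want <- direct_shift(acc_r, acc_kind, don_r, don_kind, ch_r,
                         dangling = nd < 2, oh = oh, blcorr = blc)
    expect_equal(got$delta_isolated_ref, want, tolerance = 1e-10)
  }
})

test_that("the DMSO equation evaluates its r^-6 terms", {
  expect_equal(dmso_terms(1.8, c(2.4, 2.4)),
               270.49 / 1.8^6 + 2 * 1799.10 / 2.4^6, tolerance = 1e-12)
  expect_equal(round(dmso_terms(1.8, c(2.4, 2.4)), 2), 26.78)
  expect_equal(dmso_terms(r_ch = 3.0), 1799.10 / 729, tolerance = 1e-12)
  expect_equal(round(dmso_terms(r_ch = 3.0), 2), 2.47)
  expect_equal(dmso_terms(), 0)
  expect_error(dmso_terms(-0.5), "positive")
})

test_that("the methane term matches its slope and composes to the DMSO CH coefficient", {
  expect_equal(methane_base_term(2.6), 1694.2 / 2.6^6, tolerance = 1e-12)
  expect_equal(round(methane_base_term(2.6), 2), 5.48)
  expect_equal(methane_base_term(2.6, scaled = TRUE),
               1.13 * 1694.2 / 2.6^6, tolerance = 1e-12)
  # 1694.2 * 1.13 * 0.94 ~ 1799.5, within rounding of the printed 1799.10
  composed <- p0$slope_ch_methane * p0$scale_conf3 * p0$scale_conf1
  expect_lt(abs(composed - p0$coeff_ch_eq3), 1)
})

test_that("the bond-length correction uses half the simultaneous-stretch derivative", {
  expect_equal(bond_length_correction(c(0.962, 0.962)), 0)
  expect_equal(bond_length_correction(c(0.968, 0.962)),
               579.36 / 2 * 0.006, tolerance = 1e-9)
  # both bonds at a common stretch recover the full derivative
  expect_equal(bond_length_correction(c(0.972, 0.972)),
               579.36 * 0.010, tolerance = 1e-9)
  expect_warning(bond_length_correction(c(1.5, 0.962)), "mis-assigned")
})

test_that("additivity estimates reproduce the per-bond cluster table", {
  expect_equal(additivity_estimate(1, 1), 23.9)
  expect_equal(additivity_estimate(2, 0), 33.0)
  expect_equal(additivity_estimate(0, 2), 14.8)
  expect_equal(additivity_estimate(2, 1), 40.4)
  expect_equal(additivity_estimate(1, 2), 31.3)
  expect_equal(additivity_estimate(2, 2), 47.8)
  expect_equal(additivity_estimate(0, 0), 0)
})

test_that("shielding converts to shift against the isolated-molecule reference", {
  expect_equal(shielding_to_shift(326.14), 0)
  expect_equal(shielding_to_shift(316.14), 10)
  expect_equal(shielding_to_shift(336.14), -10)
  expect_equal(shielding_to_shift(289.2, sigma_ref = 325.3), 36.1,
               tolerance = 1e-12)
})

test_that("parameter variants swap the intended constants", {
  pu <- shift_params("unrelaxed")
  expect_equal(pu$slope_acceptor, 120)
  expect_equal(pu$slope_donor, 40)
  pg <- shift_params("global")
  pr <- fake_profile(acc_r = 1.7, don_r = 1.7)
  bg <- calibrated_water_shift(pr, pg)
  expect_equal(bg$delta_isolated_ref,
               1.43 * (137.08 / 1.7^4 + 60.98 / 1.7^4) - 4.05,
               tolerance = 1e-12)
  expect_error(shift_params(nonsense = 1), "unknown parameter")
})

test_that("parameter sets survive a JSON round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  p <- shift_params(slope_acceptor = 140)
  write_params(p, f)
  q <- read_params(f)
  expect_s3_class(q, "shift_params")
  expect_equal(q$slope_acceptor, 140)
  expect_equal(q$coeff_ch_eq3, p$coeff_ch_eq3)
})
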