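test_that("two-point correction is exact at the anchors", {
  rec <- make_bulk_fixture(c(s1 = 100), cal_slope = 0.94,
                           cal_intercept = 3.1, noise_sd = 0)
  cal <- two_point_correct(rec)
  std <- dplyr::filter(cal$corrected, kind == "standard")
  expect_equal(std$corrected_delta, std$assigned_delta, tolerance = 1e-9)
  # measured standards equal assigned -> identity map
  cal_id <- two_point_correct(make_bulk_fixture(c(s1 = 5, s2 = -3)))
  expect_equal(cal_id$slope, 1)
  expect_equal(cal_id$intercept, 0)
  smp <- dplyr::filter(cal_id$corrected, kind == "sample")
  expect_equal(smp$corrected_delta, smp$measured_delta)
})

test_that("affine interpolation matches the hand oracle", {
  # anchors measured (-30, +30) for assigned (-26.39, +37.63):
  # slope = 64.02/60, sample measured 0 -> 5.62
  rec <- tibble::tibble(
    sample_id = c("u40a", "u40b", "u41a", "u41b", "x"),
    kind = c(rep("standard", 4), "sample"),
    assigned_delta = c(-26.39, -26.39, 37.63, 37.63, NA),
    measured_delta = c(-30, -30, 30, 30, 0),
    run_position = 1:5, follows_labeled = FALSE)
  cal <- two_point_correct(rec)
  expect_equal(cal$slope, 64.02 / 60)
  x <- dplyr::filter(cal$corrected, kind == "sample")
  expect_equal(x$corrected_delta, 5.62)
  # applying the correction to already-corrected standards is the identity
  rec2 <- cal$corrected
  rec2$measured_delta <- rec2$corrected_delta
  cal2 <- two_point_correct(rec2)
  expect_equal(cal2$slope, 1, tolerance = 1e-12)
  expect_equal(cal2$intercept, 0, tolerance = 1e-9)
})

test_that("carryover screening flags tainted standards and guards the fit", {
  rec <- make_bulk_fixture(c(hot = 25000, cool = 10), noise_sd = 0,
                           carryover_offsets = c(35, 0))
  cal <- two_point_correct(rec, tolerance = 2)
  expect_equal(nrow(cal$flagged), 1)
  expect_true(all(cal$flagged$follows_labeled))
  # flagged standard is excluded: anchors still exact
  std_clean <- dplyr::filter(cal$corrected, kind == "standard",
                             !carryover_flag)
  expect_equal(std_clean$corrected_delta, std_clean$assigned_delta,
               tolerance = 1e-9)
  # flagging the only standard of one anchor leaves a single clean anchor
  rec1 <- tibble::tibble(
    sample_id = c("u40a", "u40b", "hot", "u41post"),
    kind = c("standard", "standard", "sample", "standard"),
    assigned_delta = c(-26.39, -26.39, NA, 37.63),
    measured_delta = c(-26.4, -26.38, 30000, 37.63 + 50),
    run_position = 1:4,
    follows_labeled = c(FALSE, FALSE, FALSE, TRUE))
  expect_error(two_point_correct(rec1, tolerance = 2),
               "calibration error.*u41post")
})

test_that("standard-curve fitting recovers efficiency and inverts exactly", {
  q <- make_qpcr_fixture(c(u1 = 12345, u2 = 42), efficiency = 1,
                         noise_sd = 0)
  curve <- fit_standard_curve(dplyr::filter(q, well_type == "standard"))
  expect_equal(curve$slope, -log2(10), tolerance = 1e-3)
  expect_equal(curve$efficiency, 1, tolerance = 1e-3)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  # quantification round trip exact on the noiseless fixture
  unk <- dplyr::filter(q, well_type == "unknown")
  cq <- tapply(unk$cq, unk$sample_id, mean)
  expect_equal(as.numeric(quantify_copies(curve, cq[c("u1", "u2")])),
               c(12345, 42), tolerance = 1e-9)
  # unknown Cq equal to a standard point's -> that standard's copies
  std3e4 <- dplyr::filter(q, well_type == "standard", copies == 3e4)
  expect_equal(quantify_copies(curve, mean(std3e4$cq)), 3e4,
               tolerance = 1e-9)
  expect_error(fit_standard_curve(tibble::tibble(copies = c(10, 100, 1000),
                                                 cq = c(20, 23, 26))),
               "inverted")
  expect_error(fit_standard_curve(tibble::tibble(copies = c(10, 100),
                                                 cq = c(26, 23))),
               "3 distinct")
})

test_that("relative abundance normalizes per replicate and runs Welch tests", {
  tbl <- tidyr::expand_grid(member = c("HL49", "HL109", "bin04"),
                            condition = c("NO3", "NH4"), replicate = 1:3)
  set.seed(77)
  tbl$copies <- c(1e6, 1.1e6, 0.9e6, 4e6, 4.2e6, 3.9e6,   # HL49 shifts
                  2e6, 2.1e6, 1.9e6, 2e6, 2.2e6, 1.8e6,
                  5e5, 5.5e5, 4.5e5, 5e5, 5.2e5, 4.8e5)
  out <- relative_abundance(tbl)
  sums <- dplyr::summarise(
    dplyr::group_by(out$abundances, condition, replicate),
    s = sum(rel_abundance), .groups = "drop")
  expect_equal(sums$s, rep(1, 6))
  # Welch t equals the textbook formula with Welch-Satterthwaite df
  hl49 <- dplyr::filter(out$abundances, member == "HL49")
  x <- hl49$rel_abundance[hl49$condition == "NO3"]
  y <- hl49$rel_abundance[hl49$condition == "NH4"]
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  df_hand <- (var(x) / 3 + var(y) / 3)^2 /
    ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  got <- dplyr::filter(out$tests, member == "HL49")
  expect_equal(got$statistic_t, t_hand)
  expect_equal(got$df, df_hand)
  # identical conditions -> t = 0, p = 1
  tbl2 <- tidyr::expand_grid(member = c("a", "b"),
                             condition = c("c1", "c2"), replicate = 1:2)
  tbl2$copies <- c(10, 30, 10, 30, 90, 70, 90, 70)
  out2 <- relative_abundance(tbl2)
  expect_equal(out2$tests$statistic_t, c(0, 0))
  expect_equal(out2$tests$p_value, c(1, 1))
  # one member only -> relative abundance 1 everywhere
  one <- relative_abundance(tibble::tibble(
    member = "only", condition = c("c1", "c1", "c2", "c2"),
    replicate = c(1, 2, 1, 2), copies = c(5, 9, 2, 4)))
  expect_true(all(one$abundances$rel_abundance == 1))
  # single replicate per condition -> abundances computed, test skipped
  expect_warning(
    single <- relative_abundance(tibble::tibble(
      member = c("a", "b", "a", "b"),
      condition = c("c1", "c1", "c2", "c2"),
      replicate = 1, copies = c(1, 3, 2, 2))),
    "skipped")
  expect_equal(single$abundances$rel_abundance, c(0.25, 0.75, 0.5, 0.5))
  expect_null(single$tests)
})

test_that("peptide normalization divides by organism totals", {
  counts <- tibble::tibble(
    organism = c("o1", "o1", "o1", "o2"),
    protein = c("p1", "p2", "p3", "q1"),
    sample = "s1", count = c(2, 3, 5, 10))
  out <- normalize_peptides(counts)
  expect_equal(out$normalized$fraction, c(0.2, 0.3, 0.5, 1))
  expect_equal(sum(out$organism_share$share), 1)
  expect_equal(out$organism_share$total, c(10, 10))
  # zero-total organism -> flagged missing, shares still sum to 1
  z <- normalize_peptides(tibble::tibble(
    organism = c("o1", "o2"), protein = c("p", "q"),
    sample = "s1", count = c(0, 7)))
  expect_true(is.na(z$normalized$fraction[1]))
  expect_equal(sum(z$organism_share$share), 1)
  expect_error(normalize_peptides(dplyr::mutate(counts, count = -count)),
               "non-negative")
})
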