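test_that("scene generation honors its geometric contract", {
  # empty scene
  spec0 <- scene_spec(height_px = 64, width_px = 64, n_filaments = 0,
                      n_cocci = 0, seed = 5)
  t0 <- make_scene(spec0)
  expect_true(all(t0$class_map == 0))
  expect_true(all(t0$cell_id_map == 0))
  # single filament -> exactly one connected nonzero component
  spec1 <- scene_spec(height_px = 64, width_px = 64, n_filaments = 1,
                      n_cocci = 0, filament_width_px = 6, seed = 5)
  t1 <- make_scene(spec1)
  expect_equal(max(label_components(t1$class_map > 0)), 1)
  # class_map and cell_id_map agree; atom fractions in [0, 1]
  spec2 <- small_spec(seed = 21)
  t2 <- make_scene(spec2)
  expect_identical(t2$cell_id_map > 0, t2$class_map > 0)
  expect_true(all(t2$x13_map >= 0 & t2$x13_map <= 1))
  expect_true(all(t2$x15_map >= 0 & t2$x15_map <= 1))
  # overlap bookkeeping: attached cocci may overlap, resolved to autotroph
  expect_true(all(t2$cells$n_overlap_px[t2$cells$class == "autotroph"] == 0))
  expect_error(make_scene(scene_spec(height_px = 16, width_px = 16,
                                     n_filaments = 0, n_cocci = 40,
                                     coccus_radius_px = 5, seed = 1)),
               "placement error")
})

test_that("identical seed and spec reproduce the scene and stack bit-exactly", {
  spec <- small_spec(seed = 7)
  t_a <- make_scene(spec); t_b <- make_scene(spec)
  expect_identical(t_a$class_map, t_b$class_map)
  expect_identical(t_a$cell_id_map, t_b$cell_id_map)
  expect_identical(t_a$cells, t_b$cells)
  s_a <- render_ion_counts(t_a, spec); s_b <- render_ion_counts(t_b, spec)
  expect_identical(s_a$counts, s_b$counts)
})

test_that("rendered isotopologue splits follow binomial-pairing algebra", {
  spec <- scene_spec(height_px = 32, width_px = 32, n_filaments = 0,
                     n_cocci = 0, n_planes = 1, seed = 2)
  truth <- make_scene(spec)
  profiles <- default_profiles("NO3_only")
  # x13 = 0 everywhere -> no heavy dicarbon counts at all
  t0 <- truth; t0$x13_map[] <- 0
  s0 <- render_ion_counts(t0, spec, profiles)
  expect_true(all(s0$counts[, , "12C13C", ] == 0))
  # x13 = 0.5 at very high counts -> count ratio -> 2x(1-x)/(1-x)^2 = 2
  t5 <- truth; t5$x13_map[] <- 0.5
  prof_hot <- dplyr::mutate(profiles, rate_C2 = 50000)
  s5 <- render_ion_counts(t5, spec, prof_hot, seed = 8)
  ratio <- sum(s5$counts[, , "12C13C", ]) / sum(s5$counts[, , "12C12C", ])
  expect_equal(ratio, 2, tolerance = 0.01)
  # mass balance is structural: the pair channels are a split of one draw,
  # so totals match the Poisson moment check below by construction
})

test_that("summed counts match Poisson expectations across seeds", {
  spec <- scene_spec(height_px = 24, width_px = 24, n_filaments = 0,
                     n_cocci = 0, n_planes = 6, seed = 1)
  truth <- make_scene(spec)
  profiles <- default_profiles("NO3_only")
  rate_cn <- profiles$rate_CN[profiles$class == "background"]
  means <- vapply(1:10, function(s) {
    st <- render_ion_counts(truth, spec, profiles, seed = s)
    mean(st$counts[, , "12C14N", ] + st$counts[, , "12C15N", ]) * spec$n_planes
  }, double(1))
  expected <- spec$n_planes * rate_cn
  se <- sqrt(expected / (10 * 24 * 24))
  expect_lt(abs(mean(means) - expected), 3 * se)
})

test_that("biomass cyanide signal dominates background by an order of magnitude", {
  for (cond in c("NO3_only", "NH4_amended")) {
    spec <- small_spec(condition = cond, seed = 13)
    truth <- make_scene(spec)
    st <- render_ion_counts(truth, spec)
    cn <- sum_planes(st)$counts[, , "12C14N"]
    expect_gt(mean(cn[truth$class_map > 0]), 10 * mean(cn[truth$class_map == 0]))
  }
})

test_that("default profiles encode the expected condition contrast", {
  refs <- ref_ratios()
  for (cond in c("NO3_only", "NH4_amended")) {
    p <- default_profiles(cond)
    bg <- p[p$class == "background", ]
    au <- p[p$class == "autotroph", ]
    he <- p[p$class == "heterotroph", ]
    expect_true(all(c(au$rate_CN, he$rate_CN) > 10 * bg$rate_CN))
    # autotroph co-enriched in both isotopes under both regimes
    expect_gt(au$x13, bg$x13); expect_gt(au$x15, bg$x15)
  }
  no3 <- default_profiles("NO3_only"); nh4 <- default_profiles("NH4_amended")
  h_no3 <- no3[no3$class == "heterotroph", ]
  h_nh4 <- nh4[nh4$class == "heterotroph", ]
  # NO3-only: heterotroph 13C elevated relative to the NH4 regime;
  # NH4-amended: heterotroph 15N elevated relative to the NO3 regime
  expect_gt(h_no3$x13, h_nh4$x13)
  expect_gt(h_nh4$x15, h_no3$x15)
  # heterotroph deltas reproduce the configured population means
  expect_equal(delta_from_atom_fraction(h_no3$x13, refs$r13), 1328.39,
               tolerance = 1e-9)
  expect_equal(delta_from_atom_fraction(h_nh4$x15, refs$r15), 6351.97,
               tolerance = 1e-9)
})

test_that("neglecting the doubly-heavy dicarbon pair is a bounded approximation", {
  # share of 13C13C among dicarbon pairs is x^2: below 1% up to the
  # moderate-labeling regime, and still small at the hottest default class
  x_grid <- seq(0, 0.02, length.out = 21)
  expect_true(all(x_grid^2 / (x_grid^2 + 2 * x_grid * (1 - x_grid) +
                                (1 - x_grid)^2) < 0.01))
  x_max <- max(default_profiles("NH4_amended")$x13)
  expect_lt(x_max^2, 0.01)
})

test_that("bulk fixtures honor their generative models", {
  # qPCR: 100% efficiency, noise off -> adjacent decades differ by log2(10)
  q <- make_qpcr_fixture(c(a = 1000), efficiency = 1, noise_sd = 0)
  std <- dplyr::distinct(q[q$well_type == "standard", ], copies, cq)
  std <- std[order(std$copies), ]
  expect_equal(unname(diff(std$cq)), rep(-log2(10), 5), tolerance = 1e-12)
  expect_error(make_qpcr_fixture(c(a = -5)), "positive")
  # IRMS: identity calibration, noise off -> measured equals true
  b <- make_bulk_fixture(c(s1 = 10, s2 = 500), cal_slope = 1,
                         cal_intercept = 0, noise_sd = 0)
  expect_equal(b$measured_delta, b$true_delta)
  expect_false(anyDuplicated(b$run_position) > 0)
  # peptides: single-protein organism takes the whole total
  p <- make_peptide_fixture(c(solo = 1), organism_totals = 321,
                            samples = "s1")
  expect_equal(p$count, 321)
})
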