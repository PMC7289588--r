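test_that("log thresholding separates signal levels", {
  set.seed(8)
  img <- matrix(sample(c(10, 10000), 400, replace = TRUE), 20, 20)
  m_otsu <- log_threshold(img, "otsu")
  m_man <- log_threshold(img, "manual", value = log1p(500))
  expect_identical(unclass_bool(m_otsu), img > 500)
  expect_identical(unclass_bool(m_man), img > 500)
  # all-zero image with manual threshold -> empty mask
  expect_true(!any(log_threshold(matrix(0, 5, 5), "manual", value = 1)))
  expect_error(log_threshold(matrix(7, 5, 5), "otsu"), "manual")
  expect_error(log_threshold(matrix(1:4, 2, 2), "manual"), "value")
  expect_warning(log_threshold(img, "manual", 1, channel_name = "12C13C"),
                 "standard segmentation recipe")
})

test_that("automatic threshold matches exhaustive between-class variance search", {
  set.seed(11)
  x <- exp(c(rnorm(400, 2, 0.3), rnorm(400, 6, 0.3)))  # bimodal log histogram
  img <- matrix(x, 20, 40)
  m <- log_threshold(img, "otsu")
  thr <- attr(m, "threshold")
  oracle <- brute_force_otsu(log1p(x))
  # both must separate the modes; equal up to one 256-bin width
  bin_w <- diff(range(log1p(x))) / 256
  expect_lt(abs(thr - oracle), 2 * bin_w)
  expect_true(thr > 2.5 && thr < 5.5)
  expect_identical(unclass_bool(m), matrix(log1p(x) > thr, 20, 40))
})

test_that("mask combination equals per-pixel truth-table evaluation", {
  set.seed(2)
  o <- matrix(runif(64) > 0.5, 8, 8)
  cn <- matrix(runif(64) > 0.5, 8, 8)
  p <- matrix(runif(64) > 0.5, 8, 8)
  ms <- build_masks(o, cn, p)
  expect_identical(ms$autotroph, cn & p)
  expect_identical(ms$heterotroph, cn & !p)
  expect_identical(ms$background, !(cn | o))
  expect_identical(ms$phosphate_high, p & !cn)
  # partition invariants
  expect_false(any(ms$autotroph & ms$heterotroph))
  expect_false(any(ms$background & (ms$autotroph | ms$heterotroph)))
  # degenerate inputs
  ms0 <- build_masks(o, cn, matrix(FALSE, 8, 8))
  expect_false(any(ms0$autotroph))
  expect_identical(ms0$heterotroph, cn)
  ms1 <- build_masks(o, matrix(FALSE, 8, 8), p)
  expect_false(any(ms1$autotroph) || any(ms1$heterotroph))
  expect_error(build_masks(o, cn, p, recipe = list(
    autotroph = "cn & q", heterotroph = "cn", background = "!cn",
    phosphate_high = "p")), "unknown input")
})

test_that("morphological cleanup matches a brute-force oracle and is idempotent", {
  m <- matrix(FALSE, 16, 16)
  m[4:12, 4:6] <- TRUE; m[10:12, 4:12] <- TRUE  # L-shaped object
  m[2, 14] <- TRUE                              # isolated pixel
  cl <- cleanup_mask(m, min_object_px = 5, opening_radius = 1)
  oracle <- brute_force_opening(m, 1)           # L survives, pixel eroded
  expect_identical(cl, oracle)
  expect_false(cl[2, 14])
  # solid square unchanged
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_identical(cleanup_mask(sq, 5, 1), sq)
  # idempotence
  set.seed(6)
  rnd <- matrix(runif(900) > 0.45, 30, 30)
  once <- cleanup_mask(rnd, 8, 1)
  expect_identical(cleanup_mask(once, 8, 1), once)
  # pure size filtering
  expect_false(any(cleanup_mask(m & !m | (row(m) == 2 & col(m) == 14),
                                min_object_px = 5, opening_radius = 0)))
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal touch -> one component
  m[5, 5] <- TRUE                    # separate
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
  expect_equal(max(label_components(matrix(FALSE, 4, 4))), 0)
})

test_that("overlap resolution keeps side-attached cells and drops covered ones", {
  blank <- matrix(FALSE, 12, 12)
  auto <- blank; auto[, 5:8] <- TRUE   # vertical filament band
  # component fully inside the filament -> deleted
  het_in <- blank; het_in[3:4, 6:7] <- TRUE
  # component touching the filament edge, zero overlap -> kept intact
  het_side <- blank; het_side[8:10, 2:4] <- TRUE
  # component with 30% overlap -> kept, overlap reassigned:
  # 10 px, of which cols 5:7 of row 1 fall inside the filament (3 px)
  het_part <- blank; het_part[1, 1:7] <- TRUE; het_part[2, 1:3] <- TRUE
  ms <- structure(list(autotroph = auto,
                       heterotroph = het_in | het_side | het_part,
                       background = !(auto | het_in | het_side | het_part),
                       phosphate_high = blank,
                       recipe = default_mask_recipe(), thresholds = list()),
                  class = "nanosip_masks")
  out <- resolve_overlaps(ms, overlap_fraction_cutoff = 0.5)
  expect_false(any(out$heterotroph & het_in))          # deleted
  expect_identical(out$heterotroph & het_side, het_side)  # kept intact
  kept_part <- out$heterotroph & het_part
  expect_equal(sum(kept_part), 7)                      # 10 px minus 3 overlap
  expect_false(any(kept_part & auto))
  rep <- out$overlap_report
  expect_equal(nrow(rep), 3)
  expect_equal(sort(rep$fraction), c(0, 0.3, 1))
  expect_equal(rep$kept, rep$fraction <= 0.5)
  # masks stay disjoint
  expect_false(any(out$autotroph & out$heterotroph))
})

test_that("per-cell records aggregate counts within components", {
  # two disjoint cocci with uniform counts: cell delta equals pixel delta
  c12 <- matrix(0, 10, 10); c13 <- c12; c14 <- c12; c15 <- c12
  cells_px <- list(cbind(2:3, 2), cbind(7:8, 8))
  for (px in cells_px) {
    c12[px] <- 1000; c13[px] <- 50; c14[px] <- 2000; c15[px] <- 10
  }
  sm <- summed_from(`12C12C` = c12, `12C13C` = c13,
                    `12C14N` = c14, `12C15N` = c15)
  enr <- enrichment_maps(sm, min_counts = 1)
  het <- c12 > 0
  ms <- structure(list(autotroph = matrix(FALSE, 10, 10), heterotroph = het,
                       background = !het,
                       phosphate_high = matrix(FALSE, 10, 10),
                       recipe = default_mask_recipe(), thresholds = list()),
                  class = "nanosip_masks")
  cells <- label_cells(ms, enr)
  expect_equal(nrow(cells), 2)
  expect_true(all(cells$class == "heterotroph"))
  expect_length(intersect(cells$pixels[[1]], cells$pixels[[2]]), 0)
  refs <- ref_ratios()
  d13_exp <- delta_from_ratio(ratio_from_c2_counts(50, 1000), refs$r13)
  expect_equal(cells$delta13C_cell, rep(d13_exp, 2))
  expect_equal(unlist(cells$pixel_delta13C), rep(d13_exp, 4))
  # phosphate-high pixels are excluded from records
  ms2 <- ms; ms2$phosphate_high[2, 2] <- TRUE
  cells2 <- label_cells(ms2, enr)
  expect_equal(sort(cells2$n_px), c(1, 2))
})

test_that("full segmentation recovers the ground-truth scene", {
  spec <- small_spec(seed = 31)
  truth <- make_scene(spec)
  st <- render_ion_counts(truth, spec)
  sm <- sum_planes(st)
  masks <- segment_image(sm)
  expect_gte(jaccard(masks$autotroph, truth$class_map == 1), 0.8)
  expect_gte(jaccard(masks$heterotroph, truth$class_map == 2), 0.8)
  cells <- label_cells(masks, enrichment_maps(sm))
  expect_equal(sum(cells$class == "heterotroph"),
               sum(truth$cells$class == "heterotroph"))
})
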