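test_that("population summaries report mean, sample SD and a conserving histogram", {
  s <- summarize_population(c(1, 2, 3), class = "heterotroph", basis = "pixel")
  expect_equal(s$summary$mean, 2)
  expect_equal(s$summary$sd, 1)
  expect_equal(s$summary$n, 3)
  # degenerate single value: SD reported 0 with a flag
  s1 <- summarize_population(42, basis = "cell")
  expect_equal(s1$summary$sd, 0)
  expect_true(s1$summary$single_value)
  # histogram conservation on random input
  set.seed(19)
  v <- rnorm(500, 100, 30)
  sr <- summarize_population(v, bins = 37)
  expect_equal(sum(sr$histogram$count), 500)
  expect_error(summarize_population(c(NA, NaN), class = "autotroph",
                                    basis = "cell"),
               "empty population.*cell.*autotroph")
})

test_that("rank-sum p values match exact enumeration", {
  rt <- compare_populations(c(1, 2, 3), c(4, 5, 6))
  # enumeration oracle: all choose(6, 3) = 20 assignments of ranks
  ranks <- 1:6
  combos <- combn(6, 3)
  u_stats <- apply(combos, 2, function(ix) sum(ranks[ix]) - 6)
  u_obs <- 0  # a entirely below b
  p_exact <- mean(abs(u_stats - 4.5) >= abs(u_obs - 4.5))
  expect_equal(p_exact, 0.1)
  expect_equal(rt$statistic_W, 0)
  expect_equal(rt$p_value, 0.1)
  expect_true(rt$exact)
})

test_that("rank test is symmetric and handles degenerate pairing", {
  set.seed(5)
  a <- rnorm(8); b <- rnorm(10, 1)
  r_ab <- compare_populations(a, b)
  r_ba <- compare_populations(b, a)
  expect_equal(r_ab$statistic_W + r_ba$statistic_W, 8 * 10)
  expect_equal(r_ab$p_value, r_ba$p_value)
  # paired with all zero differences -> p = 1 convention
  d <- compare_populations(a, a, variant = "signed_rank")
  expect_equal(d$p_value, 1)
  expect_equal(d$statistic_W, 0)
  expect_error(compare_populations(a, b, variant = "signed_rank"),
               "rank_sum")
  expect_match(format_p(1e-5), "< 1e-3")
  expect_match(format_p(0.04), "0.04")
})

test_that("rank test holds its nominal type-I error under the null", {
  set.seed(101)
  rejections <- vapply(1:1000, function(i) {
    a <- rnorm(30); b <- rnorm(30)
    compare_populations(a, b)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("confidence ellipse follows the chi-square scaling of the covariance", {
  # four points with exact identity sample covariance -> circle of radius
  # sqrt(qchisq(0.95, 2)) = 2.4477
  a <- sqrt(3 / 2)
  pts <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  e <- ellipse_95(pts)
  expect_equal(unname(e$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-10)
  expect_equal(sqrt(qchisq(0.95, 2)), 2.4477, tolerance = 1e-4)
  # rotation equivariance and scale homogeneity
  set.seed(7)
  base <- cbind(rnorm(200, sd = 3), rnorm(200, sd = 1))
  e0 <- ellipse_95(base)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  e_rot <- ellipse_95(base %*% t(rot))
  ang_diff <- (e_rot$angle - e0$angle - th) %% pi
  expect_lt(min(ang_diff, pi - ang_diff), 1e-8)
  e_scaled <- ellipse_95(2 * base)
  expect_equal(e_scaled$semi_axes, 2 * e0$semi_axes)
  expect_error(ellipse_95(cbind(1:5, 2 * (1:5))), "collinear")
  expect_error(ellipse_95(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("ellipse membership test agrees with its boundary", {
  set.seed(12)
  pts <- cbind(rnorm(500), rnorm(500))
  e <- ellipse_95(pts)
  bd <- ellipse_boundary(e, n = 64)
  d2 <- stats::mahalanobis(as.matrix(bd), e$center, e$cov)
  expect_equal(d2, rep(qchisq(0.95, 2), 64), tolerance = 1e-8)
})

test_that("replicate signatures average per bin", {
  h1 <- summarize_population(c(1, 1, 2), bins = 4, range = c(0, 4))$histogram
  h2 <- h1; h2$count <- c(0, 2, 0, 0)
  h1$count <- c(0, 0, 0, 0)
  sig <- replicate_signature(list(h1, h2))
  expect_equal(sig$mean_count[2], 1)
  expect_equal(sig$sd_count[2], sqrt(2))
  # identical replicates -> SD zero; mean of copies equals the original
  sig3 <- replicate_signature(list(h2, h2, h2))
  expect_true(all(sig3$sd_count == 0))
  expect_equal(sig3$mean_count, as.double(h2$count))
  bad <- h2; bad$bin_low <- bad$bin_low + 1
  expect_error(replicate_signature(list(h1, bad)), "mismatched bins")
})

test_that("pixel and cell means agree for homogeneous equal-sized cells", {
  c12 <- matrix(0, 12, 12); c13 <- c12; c14 <- c12; c15 <- c12
  specs <- list(list(px = cbind(2:4, 2), h = 40),
                list(px = cbind(8:10, 9), h = 90))
  for (s in specs) {
    c12[s$px] <- 1000; c13[s$px] <- s$h; c14[s$px] <- 1500; c15[s$px] <- 6
  }
  enr <- enrichment_maps(summed_from(`12C12C` = c12, `12C13C` = c13,
                                     `12C14N` = c14, `12C15N` = c15),
                         min_counts = 1)
  het <- c12 > 0
  ms <- structure(list(autotroph = matrix(FALSE, 12, 12), heterotroph = het,
                       background = !het,
                       phosphate_high = matrix(FALSE, 12, 12),
                       recipe = default_mask_recipe(), thresholds = list()),
                  class = "nanosip_masks")
  cells <- label_cells(ms, enr)
  expect_equal(mean(cells$delta13C_cell),
               mean(unlist(cells$pixel_delta13C)))
})
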