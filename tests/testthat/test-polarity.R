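test_that("shape normalization whitens boundaries to isotropic moments", {
  cc <- circle_cell(120, r = 5)
  U <- shape_normalize(cc$boundary)
  M <- crossprod(U) / nrow(U)
  expect_lt(abs(M[1, 2]), 1e-9)
  ev <- eigen(M, symmetric = TRUE)$values
  expect_equal(ev[1] / ev[2], 1, tolerance = 1e-6)
  ## 2:1 ellipse whitens back to eigenvalue ratio 1
  ec <- stretched_cell(120, r = 5, s = 2)
  ev2 <- eigen(crossprod(shape_normalize(ec$boundary)) / 120,
               symmetric = TRUE)$values
  expect_equal(ev2[1] / ev2[2], 1, tolerance = 1e-6)
  ## random convex polygon: recomputed tensor proportional to identity
  set.seed(11)
  th <- sort(runif(40, 0, 2 * pi))
  poly <- cbind(x = (2 + runif(1)) * cos(th), y = (1 + runif(1)) * sin(th))
  M3 <- crossprod(shape_normalize(poly)) / nrow(poly)
  expect_equal(M3 / M3[1, 1], diag(2), tolerance = 1e-9)
  expect_error(shape_normalize(cbind(1:10, 2 * (1:10))), "rank-deficient")
})

test_that("PCA polarity recovers painted intensity axes on circles", {
  cc <- circle_cell(240)
  ## uniform intensity: symmetric, magnitude ~ 0
  expect_lt(pca_polarity(cc, rep(1, 240))$magnitude, 1e-6)
  ## cosine pattern at 30 degrees: matches the grid-search oracle and truth
  I <- 1 + 0.5 * cos(2 * (cc$phi_deg - 30) * pi / 180)
  p <- pca_polarity(cc, I)
  expect_lt(axial_diff_test(p$angle, 30), 1)
  oracle <- grid_polarity_oracle(shape_normalize(cc$boundary), I / mean(I))
  expect_lt(axial_diff_test(p$angle, oracle), 0.2)
  ## two bright antipodal arcs at 90/270 force the 90-degree axis
  I2 <- 0.01 + as.numeric(abs(sin(cc$phi_deg * pi / 180)) > 0.95)
  expect_lt(axial_diff_test(pca_polarity(cc, I2)$angle, 90), 0.5)
  ## input validation
  expect_error(pca_polarity(cc, rep(0, 240)), "zero")
  small <- list(id = 1, boundary = cc$boundary[1:5, ])
  expect_error(pca_polarity(small, rep(1, 5)), "8 boundary")
})

test_that("polarity is rotation-equivariant with the SOP axis", {
  cc <- circle_cell(240)
  I <- 1 + 0.4 * cos(2 * (cc$phi_deg - 70) * pi / 180)
  p0 <- pca_polarity(cc, I, reference_axis(0))
  for (delta in c(15, 90, 133)) {
    rot <- delta * pi / 180
    R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
    cc2 <- cc; cc2$boundary <- cc$boundary %*% t(R)  # screen-CCW rotation
    p1 <- pca_polarity(cc2, I, reference_axis(delta))
    expect_lt(axial_diff_test(p1$angle, p0$angle), 1e-6)
    expect_equal(p1$magnitude, p0$magnitude, tolerance = 1e-9)
  }
})

test_that("magnitude rises monotonically with contrast, robust to stretching", {
  cc <- circle_cell(240)
  ms <- seq(0, 0.9, by = 0.1)
  mags <- vapply(ms, function(m) {
    I <- 1 + m * cos(2 * (cc$phi_deg - 40) * pi / 180)
    pca_polarity(cc, I)$magnitude
  }, 0)
  expect_lt(mags[1], 1e-8)
  expect_true(all(diff(mags) > 0))
  ## 2:1 stretch along an axis uncorrelated with the pattern:
  ## magnitude shifts < 10%, angle < 5 degrees (PCA eccentricity robustness)
  sc <- stretched_cell(240, s = 2, axis_deg = 110)
  I <- 1 + 0.5 * cos(2 * (cc$phi_deg - 40) * pi / 180)
  p0 <- pca_polarity(cc, I)
  p1 <- pca_polarity(list(id = 1, boundary = sc$boundary), I)
  expect_lt(abs(p1$magnitude - p0$magnitude) / p0$magnitude, 0.10)
  expect_lt(axial_diff_test(p1$angle, p0$angle), 5)
})

test_that("coarse graining averages blocks as nematic tensors", {
  ts <- make_tissue(120, seed = 8)
  pol <- data.frame(cell_id = as.integer(names(ts$cells)),
                    angle_deg = 20, magnitude = 0.4,
                    interior = TRUE)
  cg <- coarse_grain(pol, ts, block_cells = 3)
  expect_true(all(abs(cg$mean_angle - 20) < 1e-9))
  expect_true(all(abs(cg$mean_magnitude - 0.4) < 1e-9))
  expect_equal(sum(cg$n_cells), 120)
  ## equal mix of 0 and 90 cancels within every block
  pol2 <- pol
  pol2$angle_deg <- rep(c(0, 90), length.out = nrow(pol))
  pol2$magnitude <- 0.5
  cg2 <- coarse_grain(pol2, ts, block_cells = 100)  # one block
  expect_equal(nrow(cg2), 1)
  expect_lt(cg2$mean_magnitude, 0.03)
  ## random mixture equals the double-angle vector-sum oracle per block
  set.seed(2)
  pol3 <- pol
  pol3$angle_deg <- runif(nrow(pol), 0, 180)
  pol3$magnitude <- runif(nrow(pol))
  cg3 <- coarse_grain(pol3, ts, block_cells = 100)
  t2 <- 2 * pol3$angle_deg * pi / 180
  expect_equal(cg3$mean_magnitude,
               sqrt(mean(pol3$magnitude * cos(t2))^2 +
                      mean(pol3$magnitude * sin(t2))^2),
               tolerance = 1e-12)
})

test_that("weighted circular histograms bin and conserve weight", {
  h <- weighted_angle_histogram(12, 0.4)
  expect_equal(h$bin_weights[2], 0.4)
  expect_equal(sum(h$bin_weights), 0.4)
  h0 <- weighted_angle_histogram(numeric(0))
  expect_equal(h0$bin_weights, rep(0, 18))
  expect_equal(h0$n_items, 0)
  expect_error(weighted_angle_histogram(180, 1), "\\[0, 180\\)")
  ## 1000 random items match a direct accumulation loop, and conserve mass
  set.seed(4)
  a <- runif(1000, 0, 180); w <- runif(1000)
  h1 <- weighted_angle_histogram(a, w)
  manual <- numeric(18)
  for (i in 1:1000) {
    b <- floor(a[i] / 10) + 1
    manual[b] <- manual[b] + w[i]
  }
  expect_equal(h1$bin_weights, manual)
  expect_equal(sum(h1$bin_weights), sum(w))
  ## magnitude_mean divides by count; empty bins are 0
  h2 <- weighted_angle_histogram(c(12, 14), c(0.2, 0.6),
                                 mode = "magnitude_mean")
  expect_equal(h2$bin_weights[2], 0.4)
  expect_equal(h2$bin_weights[1], 0)
})

test_that("PD-enriched junction intensity yields AP-oriented cell polarity", {
  ts <- make_tissue(200, seed = 3)
  g <- build_junction_graph(ts, compute_bands = TRUE)
  pp <- paint_polarity(ts, g, enrichment_axis = 0, contrast = 0.5, seed = 3)
  pol <- tissue_polarity(ts, pp$image)
  med <- median(pol$angle_deg[pol$interior], na.rm = TRUE)
  expect_gte(med, 85)
  expect_lte(med, 95)
  ## doubling the base intensity leaves the polarity output unchanged
  pp2 <- paint_polarity(ts, g, enrichment_axis = 0, contrast = 0.5,
                        base = 200, seed = 3)
  pol2 <- tissue_polarity(ts, pp2$image)
  expect_equal(pol2$angle_deg, pol$angle_deg, tolerance = 1e-9)
  expect_equal(pol2$magnitude, pol$magnitude, tolerance = 1e-9)
})
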