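test_that("circularity matches closed forms to machine precision", {
  r <- 5.3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  a <- 2.7
  expect_equal(circularity(a^2, 4 * a), pi / 4, tolerance = 1e-12)
  # scale invariance: A -> 4A, L -> 2L
  expect_equal(circularity(4 * 7, 2 * 9), circularity(7, 9), tolerance = 1e-12)
  expect_error(circularity(0, 1), "positive")
  expect_error(circularity(1, -2), "positive")
})

test_that("mask-based circularity is flagged approximate and behaves sanely", {
  n <- 101
  xi <- matrix(seq_len(n), n, n)
  disc <- (xi - 51)^2 + (t(xi) - 51)^2 <= 40^2
  res <- mask_circularity(binary_image(disc, pixel_size = 2,
                                       phase_label = "cell"))
  expect_equal(res$area_nm2, sum(disc) * 4)
  # the city-block boundary of a disc is 8r vs the true 2*pi*r, so the
  # estimate is biased low by ~(pi/4)^2 = 0.617
  expect_gt(res$circularity, 0.55)
  expect_lt(res$circularity, 0.70)
  expect_error(mask_circularity(binary_image(matrix(FALSE, 4, 4),
                                             phase_label = "cell")),
               "foreground")
})

test_that("granulometry recovers constructed disc and stripe sizes", {
  discs <- make_synthetic_pores("discs", feature_nm = 20, pixel_size = 2,
                                size_px = 128)
  g <- granulometry_size(discs)
  expect_lt(abs(g$mean_size - 20), 2)  # within one pixel
  expect_equal(g$mean_size, mean(g$sizes))
  expect_equal(g$n, length(g$sizes))
  expect_gte(g$sem, 0)

  stripes <- make_synthetic_pores("stripes", feature_nm = 20, pixel_size = 2,
                                  size_px = 128)
  gs <- granulometry_size(stripes)
  expect_lt(abs(gs$mean_size - 20), 2)
})

test_that("inverting the mask swaps pore and ligament measurements", {
  stripes <- make_synthetic_pores("stripes", feature_nm = 20, pixel_size = 2,
                                  size_px = 128)
  inv <- invert_phase(stripes)
  expect_identical(inv$pixels, !stripes$pixels)
  expect_identical(inv$phase_label, "ligament")
  # equal-width stripes: the dual phase has the same local width
  expect_equal(granulometry_size(inv)$mean_size,
               granulometry_size(stripes)$mean_size, tolerance = 1e-12)
})

test_that("single-phase images cannot be sized", {
  expect_error(granulometry_size(binary_image(matrix(TRUE, 8, 8))),
               "both phases")
  expect_error(granulometry_size(binary_image(matrix(FALSE, 8, 8))),
               "both phases")
})

test_that("synthetic pore patterns are deterministic and resolution-checked", {
  v1 <- make_synthetic_pores("voronoi", 20, 2, seed = 9, size_px = 96)
  v2 <- make_synthetic_pores("voronoi", 20, 2, seed = 9, size_px = 96)
  v3 <- make_synthetic_pores("voronoi", 20, 2, seed = 10, size_px = 96)
  expect_identical(v1$pixels, v2$pixels)
  expect_false(identical(v1$pixels, v3$pixels))
  expect_error(make_synthetic_pores("discs", 3, 2), "resolved")
})

test_that("pore-ligament fit reproduces a hand-computed least squares", {
  tab <- npg_size_table()
  fit <- fit_pore_ligament(tab$pore_nm, tab$ligament_nm)
  g <- glance(fit)
  # closed-form OLS on the five printed means, computed independently:
  # slope = Sxy/Sxx, intercept = ybar - slope xbar
  x <- tab$pore_nm
  y <- tab$ligament_nm
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  expect_equal(g$slope, slope, tolerance = 1e-6)
  expect_equal(g$intercept, intercept, tolerance = 1e-6)
  expect_equal(g$r_squared, r2, tolerance = 1e-6)
  # frozen values of that closed form
  expect_equal(g$slope, 1.08221834, tolerance = 1e-6)
  expect_equal(g$intercept, 9.51070843, tolerance = 1e-6)
  expect_equal(g$r_squared, 0.99574970, tolerance = 1e-6)
  expect_lt(g$p_value, 1e-3)
  expect_equal(g$n, 5)
})

test_that("pore-ligament fit handles degenerate inputs", {
  perfect <- suppressWarnings(glance(fit_pore_ligament(1:4, 2 * (1:4) + 3)))
  expect_equal(perfect$r_squared, 1)
  expect_error(fit_pore_ligament(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_pore_ligament(c(2, 2, 2), c(1, 2, 3)), "variance")
  expect_error(fit_pore_ligament(1:4, 1:5), "equal length")
})

test_that("granulometry on the phase-separated field agrees with its spectral length", {
  f <- generate_npg_field(seed = 2, target_length_nm = 20, size_px = 128)
  len <- characteristic_length(f)
  pores <- binary_image(f$concentration < 0.5, pixel_size = f$pixel_size,
                        phase_label = "pore")
  ligaments <- invert_phase(pores)
  # the two metrics differ by definition; they agree within 25%
  expect_lt(abs(granulometry_size(pores)$mean_size - len) / len, 0.25)
  expect_lt(abs(granulometry_size(ligaments)$mean_size - len) / len, 0.25)
})

test_that("binary masks round-trip through PNG", {
  img <- make_synthetic_pores("discs", feature_nm = 20, pixel_size = 2,
                              size_px = 64)
  path <- tempfile(fileext = ".png")
  write_mask_png(img, path)
  back <- read_mask_png(path, pixel_size = 2)
  expect_identical(back$pixels, img$pixels)
  unlink(path)
})
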