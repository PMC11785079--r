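test_that("NSD catalog has the documented structure", {
  cat28 <- nsd_catalog
  expect_equal(nrow(cat28), 28)
  expect_equal(nrow(catalog_exemplars(cat28)), 112)
  expect_equal(sort(unique(catalog_exemplars(cat28)$phase)),
               c(0, 1.57, 3.14, 4.71))
  expect_true(all(cat28$omega_r[cat28$shape == "pinwheel"] == 0))
  expect_true(all(cat28$omega_a[cat28$shape == "annulus"] == 0))
  sp <- cat28[cat28$shape %in% c("forward_spiral", "reverse_spiral"), ]
  expect_true(all(abs(sp$omega_r) == abs(sp$omega_a)))
  expect_true(all(cat28$base_frequency > 0))
})

test_that("base frequencies match across shapes only approximately", {
  cat28 <- nsd_catalog
  ann <- sort(cat28$base_frequency[cat28$shape == "annulus"])
  spi <- sort(cat28$base_frequency[cat28$shape == "forward_spiral"])
  expect_equal(ann, c(6, 11, 20, 37, 69, 128))
  expect_equal(spi, c(4, 7, 14, 26, 49, 91) * sqrt(2))
  # nearly matched (within ~12%) but never exactly equal: the integer
  # constraint on angular frequency forces slight discrepancies
  expect_true(all(abs(ann / spi - 1) < 0.12))
  expect_true(all(ann != spi))
})

test_that("custom catalogs validate their frequency vectors", {
  expect_error(make_catalog("custom",
                            data.frame(omega_r = 0, omega_a = 0)),
               "both zero")
  expect_error(make_catalog("custom",
                            data.frame(omega_r = 1, omega_a = 2.5)),
               "integer")
  cc <- make_catalog("custom", data.frame(omega_r = c(0, 5, 5),
                                          omega_a = c(-5, 0, 5)))
  expect_equal(cc$shape, c("pinwheel", "annulus", "reverse_spiral"))
})

test_that("degenerate frequency vectors render to constant images", {
  g1 <- render_grating(0, 0, phase = 0, n_px = 64, extent_deg = 8.4)
  expect_true(all(g1$pixels == 1))  # mask radius 0: nothing masked
  g2 <- render_grating(0, 0, phase = pi / 2, n_px = 64, extent_deg = 8.4)
  expect_true(all(abs(g2$pixels) < 1e-12))
})

test_that("rendered intensities are bounded and the center is masked", {
  for (i in c(1, 7, 13, 19, 25)) {  # one class of each shape
    g <- render_grating(nsd_catalog$omega_r[i], nsd_catalog$omega_a[i],
                        n_px = 128, extent_deg = 8.4)
    expect_true(all(abs(g$pixels) <= 1))
    expect_true(g$mask_radius_deg > 0)
    c0 <- 64:65
    expect_true(all(g$pixels[c0, c0] == 0))
  }
})

test_that("local spatial frequency follows base/(2*pi*r)", {
  ls <- local_stimulus(1, 0, omega_r = 6, omega_a = 0)
  expect_equal(ls$sf_cpd, 6 / (2 * pi), tolerance = 1e-12)
  expect_equal(ls$period_dpc * ls$sf_cpd, 1, tolerance = 1e-12)
  # doubling eccentricity exactly halves the local frequency
  a <- local_stimulus(1.3, 0.7, 14, -34)
  b <- local_stimulus(2.6, 0.7, 14, -34)
  expect_equal(b$sf_cpd, a$sf_cpd / 2, tolerance = 1e-12)
  expect_error(local_stimulus(0, 0, 6, 0), "r_deg")
})

test_that("local orientation follows the stated convention per shape", {
  th <- 0.9
  expect_equal(local_stimulus(2, th, 6, 0)$ori_rad, th %% pi)
  expect_equal(local_stimulus(2, th, 0, -6)$ori_rad, (th + pi / 2) %% pi)
  expect_equal(local_stimulus(2, th, 0, 6)$ori_rad, (th + pi / 2) %% pi)
  expect_equal(local_stimulus(2, th, 5, -5)$ori_rad, (th - pi / 4) %% pi)
  expect_equal(local_stimulus(2, th, 5, 5)$ori_rad, (th + pi / 4) %% pi)
  expect_true(all(local_stimulus(1:5, 6, 14, 34)$ori_rad >= 0))
  expect_true(all(local_stimulus(1:5, 6, 14, 34)$ori_rad < pi))
})

test_that("mask radius scales inversely with cutoff and orders by base frequency", {
  expect_equal(mask_radius(6, 0, 20), 2 * mask_radius(6, 0, 40))
  rads <- mask_radius(nsd_catalog$omega_r, nsd_catalog$omega_a, 10)
  expect_equal(which.max(rads),
               which.max(nsd_catalog$base_frequency))  # base 91*sqrt(2) largest
  expect_equal(which.min(rads),
               which.min(nsd_catalog$base_frequency))  # base 4*sqrt(2) smallest
  # ratio of extreme mask radii = ratio of extreme base frequencies,
  # (91*sqrt(2)) / (4*sqrt(2)) = 91/4
  expect_equal(max(rads) / min(rads), 91 / 4, tolerance = 1e-12)
})

test_that("measured phase gradients of an annulus match the analytic field", {
  # finite-difference oracle on the rendered image; independently confirms
  # both the 1/(2*pi) cycles-per-degree convention and the orientation field
  g <- render_grating(6, 0, n_px = 512, extent_deg = 8.4)
  r <- seq(max(0.5, 2 * g$mask_radius_deg), 0.9 * 4.2, length.out = 8)
  th <- seq(0, 2 * pi - 0.3, length.out = 7)
  grid <- expand.grid(r = r, th = th)
  meas <- measure_local_frequency(6, 0, grid$r, grid$th,
                                  n_px = 512, extent_deg = 8.4)
  pred <- local_stimulus(grid$r, grid$th, 6, 0)
  expect_true(all(abs(meas$sf_cpd_measured / pred$sf_cpd - 1) < 0.02))
  dori <- abs(meas$ori_rad_measured - pred$ori_rad) %% pi
  dori <- pmin(dori, pi - dori)
  expect_true(all(dori < 2 * pi / 180))
})

test_that("measured local frequency is independent of pixel resolution", {
  m256 <- measure_local_frequency(20, 0, c(1.5, 2.5, 3.5), c(0.4, 2, 4),
                                  n_px = 256, extent_deg = 8.4)
  m512 <- measure_local_frequency(20, 0, c(1.5, 2.5, 3.5), c(0.4, 2, 4),
                                  n_px = 512, extent_deg = 8.4)
  expect_true(all(abs(m256$sf_cpd_measured / m512$sf_cpd_measured - 1) < 0.01))
})

test_that("a stimulus set round-trips through PNG + sidecar CSV", {
  dir <- withr::local_tempdir()
  cc <- make_catalog("custom", data.frame(omega_r = c(6, 0),
                                          omega_a = c(0, -6)),
                     phases = c(0, pi / 2))
  side <- write_stimulus_set(cc, dir, n_px = 64, extent_deg = 8.4)
  expect_equal(nrow(side), 4)
  expect_true(all(file.exists(file.path(dir, side$filename))))
  img <- png::readPNG(file.path(dir, side$filename[1]))
  g <- render_grating(6, 0, 0, n_px = 64, extent_deg = 8.4)
  expect_equal(img * 2 - 1, g$pixels, tolerance = 1 / 127)
})
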