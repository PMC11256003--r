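test_that("noiseless closed forms hold at well centers", {
  tpl <- default_template()
  # no attenuation, no blur, no noise: every well center sits at bg + A0
  cfg <- synthetic_config(image_shape = c(160, 220), background_level = 100,
                          peak_amplitude = 1000, attenuation_mu = 0,
                          blur_sigma0 = 0, blur_slope = 0,
                          poisson_gain = 0, read_noise_sigma = 0, seed = 1)
  tpl_px <- apply_transform(tpl, frame_transform(tpl, cfg$image_shape))
  r <- render_phantom(tpl_px, cfg)
  centers <- round(tpl_px$well_centers)
  vals <- r$image$values[cbind(centers[, 2] + 1, centers[, 1] + 1)]
  expect_equal(vals, rep(1100, 9))

  # attenuation 1/mm at depth 3 mm: bg + A0 * exp(-3)
  cfg2 <- synthetic_config(image_shape = c(160, 220), background_level = 100,
                           peak_amplitude = 1000, attenuation_mu = 1,
                           blur_sigma0 = 0, blur_slope = 0,
                           poisson_gain = 0, read_noise_sigma = 0, seed = 1)
  r2 <- render_phantom(tpl_px, cfg2)
  v9 <- r2$ground_truth$noiseless[centers[9, 2] + 1, centers[9, 1] + 1]
  expect_equal(v9, 100 + 1000 * exp(-3), tolerance = 1e-12)
})

test_that("shot noise matches Poisson statistics on a flat background", {
  # law-of-large-numbers check: gain 1, flat level 100, ~1e5 pixels
  cfg <- synthetic_config(image_shape = c(320, 440), background_level = 100,
                          peak_amplitude = 1, attenuation_mu = 0,
                          blur_sigma0 = 0, blur_slope = 0, poisson_gain = 1,
                          read_noise_sigma = 0, seed = 11)
  tpl <- default_template()
  tpl_px <- apply_transform(tpl, frame_transform(tpl, cfg$image_shape))
  r <- render_phantom(tpl_px, cfg)
  # background pixels only: far from any well or annulus
  in_roi <- logical(length(r$image$values))
  ws <- structure(list(centers = tpl_px$well_centers,
                       radius = tpl_px$well_radius,
                       depths_mm = tpl_px$depths_mm,
                       b2_center = tpl_px$b2_center,
                       b2_radius = tpl_px$b2_radius), class = "well_set")
  m <- build_masks(ws, dim(r$image$values))
  in_roi[unlist(c(m$well_masks, m$b1_masks, list(m$b2_mask)))] <- TRUE
  bg <- r$image$values[!in_roi]
  expect_gt(length(bg), 1e5)
  expect_true(var(bg) > 95 && var(bg) < 105)
  expect_true(mean(bg) > 99 && mean(bg) < 101)
})

test_that("rendering is deterministic and respects quantization", {
  r1 <- tiny_render(seed = 5)
  r2 <- tiny_render(seed = 5)
  expect_identical(r1$image$values, r2$image$values)
  r3 <- tiny_render(seed = 6)
  expect_false(identical(r1$image$values, r3$image$values))
  v <- r1$image$values
  expect_true(all(v == floor(v)))
  expect_true(all(v >= 0 & v <= 65535))
  v8 <- tiny_render(seed = 5, bit_depth = 8L, background_level = 20,
                    peak_amplitude = 180)$image$values
  expect_true(all(v8 >= 0 & v8 <= 255))
})

test_that("ground-truth well means strictly decrease with depth", {
  r <- tiny_render(noise = FALSE, attenuation_mu = 1)
  expect_true(all(diff(r$ground_truth$well_means) < 0))
})

test_that("renderer rejects bad geometry and bad configs", {
  tpl <- default_template()
  cfg <- synthetic_config(image_shape = c(160, 220))
  # design-unit template (radius 1 at origin) is not in pixel space
  expect_error(render_phantom(tpl, cfg), "geometry error")
  expect_error(synthetic_config(bit_depth = 12), "bit_depth")
  expect_error(synthetic_config(peak_amplitude = 0), "peak_amplitude")
})

test_that("system presets mirror the six-camera suite", {
  p <- system_presets()
  expect_length(p, 6L)
  expect_named(p, c("Mob", "NIRF I", "NIRF II", "Solaris", "RawFl", "Hybrid"))
  expect_equal(p[["Mob"]]$bit_depth, 8L)
  for (nm in setdiff(names(p), "Mob")) expect_equal(p[[nm]]$bit_depth, 16L)
  expect_equal(attr(p, "resolution_scale"), 4)
  # native formats scaled down by the recorded factor
  expect_equal(p[["Hybrid"]]$image_shape, c(128L, 128L))
  expect_equal(p[["Mob"]]$image_shape, c(612L, 816L))
})

test_that("ground-truth sidecar echoes template and config", {
  r <- tiny_render(seed = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_phantom(r[c("image", "ground_truth")], path)
  side <- jsonlite::read_json(sub("\\.tif$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(side$seed, 3L)
  expect_equal(side$well_means, r$ground_truth$well_means, tolerance = 1e-12)
  expect_equal(side$template$depths_mm, r$template$depths_mm)
})
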