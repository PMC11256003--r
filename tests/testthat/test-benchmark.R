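test_that("smape matches its closed forms and the direct-summation oracle", {
  expect_equal(smape(rep(6, 9), 6), 0)
  expect_equal(smape(rep(3, 5), 1), 0.5)      # |3Y-Y| / (3Y+Y)
  expect_equal(smape(0, 1), 1)
  expect_identical(smape(c(-Inf, NaN, NA), 1), 1)  # sentinels enter as 0
  expect_error(smape(numeric(0), 1), "empty-input")
  expect_error(smape(1:3, 0), "reference")

  set.seed(77)
  for (i in 1:50) {
    x <- rnorm(9, mean = runif(1, -5, 20), sd = 5)
    if (i %% 5 == 0) x[sample(9, 2)] <- -Inf
    y <- runif(1, 0.1, 10)
    expect_equal(smape(x, y), smape_oracle(x, y), tolerance = 1e-12)
    expect_gte(smape(x, y), 0); expect_lte(smape(x, y), 1)
  }
})

test_that("bm_score averages the two sMAPEs", {
  expect_equal(bm_score(0.2, 0.4), 0.3)
  expect_equal(bm_score(0, 0), 0)
  expect_equal(bm_score(1, 1), 1)
  expect_error(bm_score(1.2, 0), "smape_snr")
})

reference_table <- function(system = "ref") {
  # metric table where every metric sits exactly at its reference
  v <- metric_variants()
  rows <- do.call(rbind, lapply(1:9, function(w) {
    val <- ifelse(v$family == "CM", 0.33, ifelse(v$family == "CW", 1, 6))
    data.frame(system = system, well = w, depth_mm = w, variant = v$variant,
               family = v$family, background = v$background, scale = v$scale,
               value = val, sentinel = FALSE)
  }))
  class(rows) <- c("metric_table", "data.frame")
  attr(rows, "provenance") <- list(system = system)
  rows
}

test_that("bm_map is 7 x 4 and vanishes at the references", {
  res <- bm_map(reference_table())
  expect_equal(dim(res$bm), c(7L, 4L))
  expect_equal(rownames(res$bm),
               c("SNR1", "SNR2b1", "SNR2b2", "SNR3b1", "SNR3b2",
                 "SNR4b1", "SNR4b2"))
  expect_equal(colnames(res$bm), c("CMb1", "CMb2", "CWb1", "CWb2"))
  expect_true(all(abs(res$bm) <= 1e-12))
  expect_true(all(res$n_wells == 9L))
  expect_true(all(res$smape >= 0 & res$smape <= 1))
})

test_that("doubling intensities leaves scale-invariant BM cells unchanged", {
  # noise on: a noise-free background has zero std and SNR4 is undefined
  r <- tiny_render(seed = 13)
  ws <- segment_wells(r$image, r$template)
  m <- build_masks(ws, dim(r$image$values))
  img2 <- intensity_image(2 * r$image$values, 16L, dark_corrected = TRUE)
  tb1 <- compute_metric_table(r$image, m, ws, "s")
  tb2 <- compute_metric_table(img2, m, ws, "s")
  bm1 <- bm_map(tb1); bm2 <- bm_map(tb2)
  inv_rows <- c("SNR3b1", "SNR3b2", "SNR4b1", "SNR4b2")
  expect_equal(bm2$bm[inv_rows, ], bm1$bm[inv_rows, ], tolerance = 1e-9)
  # while the photon-scaled variants move
  expect_false(isTRUE(all.equal(bm2$bm["SNR1", ], bm1$bm["SNR1", ],
                                tolerance = 1e-6)))
})

test_that("rank_systems ranks each cell, higher BM = higher rank", {
  mk <- function(id, offset) {
    res <- bm_map(reference_table(id))
    res$bm[] <- res$bm + offset
    res$system <- id
    res
  }
  r <- rank_systems(list(mk("A", 0.1), mk("B", 0.5), mk("C", 0.3)))
  expect_equal(unname(r$ranks[1, 1, ]), c(1L, 3L, 2L))
  # every cell holds a permutation of 1..K
  for (i in 1:7) for (j in 1:4) {
    expect_setequal(r$ranks[i, j, ], 1:3)
  }
  # inverted convention
  r2 <- rank_systems(list(mk("A", 0.1), mk("B", 0.5), mk("C", 0.3)),
                     higher_is_better = FALSE)
  expect_equal(unname(r2$ranks[1, 1, ]), c(3L, 1L, 2L))
  # ties broken lexicographically and flagged
  r3 <- rank_systems(list(mk("B", 0.2), mk("A", 0.2)))
  expect_true(all(r3$ties))
  expect_equal(unname(r3$ranks[1, 1, c("A", "B")]), c(1L, 2L))
  expect_error(rank_systems(list(mk("A", 0))), "at least 2")
  expect_error(rank_systems(list(mk("A", 0), mk("A", 0.1))), "duplicate")
})

test_that("injected sensitivity ordering is recovered in the SNR4b2/CWb2 cell", {
  # six synthetic systems, identical geometry/noise, strictly descending
  # peak amplitude: the brightest should earn the highest BM rank
  tpl <- default_template()
  amps <- c(24000, 14000, 8000, 4500, 2500, 1400)
  results <- lapply(seq_along(amps), function(k) {
    cfg <- synthetic_config(image_shape = c(140, 200),
                            peak_amplitude = amps[k], attenuation_mu = 1,
                            read_noise_sigma = 10, seed = 100 + k)
    tpl_px <- apply_transform(tpl, frame_transform(tpl, cfg$image_shape))
    r <- render_phantom(tpl_px, cfg)
    ws <- segment_wells(r$image, tpl)
    m <- build_masks(ws, dim(r$image$values))
    bm_map(compute_metric_table(r$image, m, ws, sprintf("sys%d", k)))
  })
  ranks <- rank_systems(results)
  cell <- ranks$ranks["SNR4b2", "CWb2", ]
  expect_equal(unname(cell), c(6L, 5L, 4L, 3L, 2L, 1L))
})

test_that("bm_map is permutation-equivariant in wells", {
  tb <- reference_table()
  tb$value[tb$variant == "SNR4b2"] <- seq(2, 18, by = 2)
  set.seed(8)
  perm <- sample(9)
  tb2 <- do.call(rbind, lapply(split(tb, tb$variant), function(d) {
    d$value <- d$value[perm]   # relabel the wells
    d
  }))
  class(tb2) <- c("metric_table", "data.frame")
  res1 <- bm_map(tb)
  res2 <- bm_map(tb2)
  expect_equal(res1$bm, res2$bm, tolerance = 1e-12)
})
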