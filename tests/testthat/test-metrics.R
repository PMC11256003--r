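test_that("dB conversion uses the amplitude (20 log10) convention", {
  expect_equal(to_db(2), 20 * log10(2), tolerance = 1e-12)  # 6.0206 dB
  expect_equal(to_db(1), 0)
  expect_equal(to_db(10), 20)
  expect_identical(to_db(0), -Inf)
  expect_error(to_db(-1), "domain error")
})

test_that("SNR formulas reproduce their closed forms", {
  # SNR1 = sqrt(n)
  expect_equal(snr1(rs(100)), 20)
  expect_equal(snr1(rs(1)), 0)
  expect_identical(snr1(rs(0)), -Inf)
  expect_error(snr1(rs(-5)), "domain error")

  # SNR2 default S / sqrt(S + N); alternate S / (S + N)
  expect_equal(snr2(rs(100), rs(44)), 20 * log10(100 / 12), tolerance = 1e-12)
  expect_equal(snr2(rs(100), rs(44), interpretation = "ratio"),
               20 * log10(100 / 144), tolerance = 1e-12)
  expect_identical(snr2(rs(0), rs(5)), -Inf)
  expect_identical(snr2(rs(0), rs(0)), -Inf)

  # SNR3 = (S - N) / sd(S)
  expect_equal(snr3(rs(300, std = 50), rs(100)), 20 * log10(4),
               tolerance = 1e-12)
  expect_identical(snr3(rs(100, std = 50), rs(100)), -Inf)
  expect_identical(snr3(rs(50, std = 10), rs(100)), -Inf) # negative linear
  expect_error(snr3(rs(300, std = 0), rs(100)), "undefined-noise")

  # SNR4 = (S - N) / sd(N)
  expect_equal(snr4(rs(300), rs(100, std = 50)), 20 * log10(4),
               tolerance = 1e-12)
  expect_identical(snr4(rs(100), rs(100, std = 50)), -Inf)
  expect_error(snr4(rs(300), rs(100, std = 0)), "undefined-noise")
})

test_that("contrast formulas reproduce their closed forms", {
  expect_equal(michelson(rs(0, max = 2), rs(0, min = 1)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(michelson(rs(0, max = 5), rs(0, min = 5)), 0)
  expect_equal(michelson(rs(0, max = 7), rs(0, min = 0)), 1)
  expect_true(is.nan(michelson(rs(0, max = 0), rs(0, min = 0))))

  expect_equal(weber(rs(0, max = 2), rs(0, min = 1)), 1)
  expect_equal(weber(rs(0, max = 5), rs(0, min = 5)), 0)
  expect_error(weber(rs(0, max = 5), rs(0, min = 0)), "undefined-background")
})

test_that("twofold detection-limit configuration hits all three references", {
  # signal excess exactly twice the background noise, and max intensity
  # exactly twice the minimum background intensity
  sig <- rs(300, std = 50, max = 200)
  bg <- rs(200, std = 50, min = 100)
  expect_equal(snr4(sig, bg), 20 * log10(2), tolerance = 1e-12)  # 6.02 dB
  expect_equal(michelson(sig, bg), 1 / 3, tolerance = 1e-12)
  expect_equal(weber(sig, bg), 1, tolerance = 1e-12)
})

test_that("metric scaling laws hold under intensity scaling", {
  set.seed(31)
  for (i in 1:20) {
    S <- runif(1, 50, 500); N <- runif(1, 10, S)
    sS <- runif(1, 1, 30); sN <- runif(1, 1, 30)
    imax <- S + runif(1, 0, 100); imin <- runif(1, 1, N)
    k <- runif(1, 0.5, 20)
    sig <- rs(S, std = sS, max = imax); bg <- rs(N, std = sN, min = imin)
    sig_k <- rs(k * S, std = k * sS, max = k * imax)
    bg_k <- rs(k * N, std = k * sN, min = k * imin)
    # snr3, snr4, CM, CW invariant under image * k
    expect_equal(snr3(sig_k, bg_k), snr3(sig, bg), tolerance = 1e-9)
    expect_equal(snr4(sig_k, bg_k), snr4(sig, bg), tolerance = 1e-9)
    expect_equal(michelson(sig_k, bg_k), michelson(sig, bg),
                 tolerance = 1e-12)
    expect_equal(weber(sig_k, bg_k), weber(sig, bg), tolerance = 1e-9)
    # snr1, snr2 scale as sqrt(k): +10 log10 k in dB
    expect_equal(snr1(sig_k), snr1(sig) + 10 * log10(k), tolerance = 1e-9)
    expect_equal(snr2(sig_k, bg_k), snr2(sig, bg) + 10 * log10(k),
                 tolerance = 1e-9)
    # CM in [0, 1] for nonnegative intensities; CW = 2 CM / (1 - CM)
    cm <- michelson(sig, bg)
    expect_gte(cm, 0); expect_lte(cm, 1)
    if (cm < 1) {
      expect_equal(weber(sig, bg), 2 * cm / (1 - cm), tolerance = 1e-9)
    }
  }
})

test_that("metric_variants enumerates 7 SNR + 4 contrast variants", {
  v <- metric_variants()
  expect_equal(nrow(v), 11L)
  expect_equal(sum(v$scale == "dB"), 7L)
  expect_equal(sum(v$scale == "unitless"), 4L)
  expect_equal(v$variant[v$family == "SNR1"], "SNR1")
  expect_setequal(v$variant[v$family == "CM"], c("CMb1", "CMb2"))
  expect_true(all(v$background[v$family != "SNR1"] %in% c("b1", "b2")))
})

test_that("compute_metric_table fills 9 wells x 11 variants", {
  r <- tiny_render(seed = 9)
  ws <- segment_wells(r$image, r$template)
  m <- build_masks(ws, dim(r$image$values))
  tb <- compute_metric_table(r$image, m, ws, "sysA")
  expect_s3_class(tb, "metric_table")
  expect_equal(nrow(tb), 99L)
  expect_equal(as.integer(table(tb$well)), rep(11L, 9))
  expect_false(any(is.na(tb$value) & !tb$sentinel))
  prov <- attr(tb, "provenance")
  expect_equal(prov$snr2_interpretation, "shot")
  expect_equal(prov$std_convention, "population")
  expect_false(prov$dark_corrected)
  # SNR4b2 decreases with depth on a bright, clean phantom
  snr4b2 <- tb$value[tb$variant == "SNR4b2"]
  expect_true(all(diff(snr4b2) < 0))
})
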