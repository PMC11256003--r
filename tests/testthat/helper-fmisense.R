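# Shared fixtures, built in code at test time.

# region_stats with prescribed moments, for closed-form formula tests
rs <- function(mean, std = 1, min = mean, max = mean, count = 100L) {
  structure(list(mean = mean, std = std, min = min, max = max,
                 count = as.integer(count), saturated_count = 0L,
                 std_convention = "population"),
            class = "region_stats")
}

# small rendered phantom with ground truth; noise off by default for
# deterministic geometry tests
tiny_render <- function(seed = 1L, shape = c(160L, 220L), noise = TRUE,
                        attenuation_mu = 1.0, blur_sigma0 = 0.8,
                        blur_slope = 1.0, bit_depth = 16L,
                        background_level = 500, peak_amplitude = 20000) {
  cfg <- synthetic_config(
    image_shape = shape, bit_depth = bit_depth,
    background_level = background_level, peak_amplitude = peak_amplitude,
    attenuation_mu = attenuation_mu, blur_sigma0 = blur_sigma0,
    blur_slope = blur_slope,
    poisson_gain = if (noise) 1 else 0,
    read_noise_sigma = if (noise) 5 else 0,
    seed = seed)
  tpl <- default_template()
  tpl_px <- apply_transform(tpl, frame_transform(tpl, cfg$image_shape))
  c(render_phantom(tpl_px, cfg),
    list(template = tpl, template_px = tpl_px, config = cfg))
}

# independent exhaustive Otsu oracle: direct between-class variance search
# over all 256 candidate splits of the binned histogram
otsu_oracle <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  bin <- pmin(floor((v - lo) / (hi - lo) * nbins), nbins - 1L)
  counts <- tabulate(bin + 1L, nbins)
  mids <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  best_t <- NA; best_v <- -Inf
  for (t in seq_len(nbins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:t] * mids[1:t]) / n0
    m1 <- sum(counts[(t + 1):nbins] * mids[(t + 1):nbins]) / n1
    w0 <- n0 / sum(counts); w1 <- 1 - w0
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best_v + 1e-12) { best_v <- sb; best_t <- t }
  }
  lo + best_t / nbins * (hi - lo)
}

# direct-summation sMAPE oracle (explicit loop, no vectorized shortcuts)
smape_oracle <- function(values, reference) {
  total <- 0
  for (x in values) {
    if (!is.finite(x)) x <- 0
    den <- abs(x) + abs(reference)
    if (den > 0) total <- total + abs(x - reference) / den
  }
  total / length(values)
}
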