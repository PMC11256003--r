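#' Convert a linear ratio to decibels
#'
#' Uses the amplitude convention `20 * log10(ratio)` for every SNR variant,
#' fixed by the detection-limit pairing of "signal twofold the noise" with a
#' 6 dB reference (`20 * log10(2) = 6.02`). A zero ratio maps to the
#' non-detect sentinel `-Inf`.
#'
#' @param ratio nonnegative linear ratio.
#' @return Value in dB; `-Inf` for ratio 0.
#' @export
to_db <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop("domain error: ratio must be finite and >= 0", call. = FALSE)
  }
  ifelse(ratio == 0, -Inf, 20 * log10(ratio))
}

# dB for a linear SNR that may legitimately be <= 0 (background brighter
# than signal): non-positive values become the non-detect sentinel.
db_or_sentinel <- function(linear) {
  if (!is.finite(linear) || linear <= 0) -Inf else 20 * log10(linear)
}

#' SNR variant 1: shot-noise-limited photon SNR
#'
#' `sqrt(n)` with `n` the photon count on the detector, proxied by the
#' (dark-corrected) mean well intensity in counts — no gain calibration is
#' attempted, and the proxy is recorded in the metric-table provenance.
#'
#' @param signal [region_stats()] of the well disk.
#' @return SNR in dB; `-Inf` sentinel for a zero mean.
#' @export
snr1 <- function(signal) {
  n <- signal$mean
  if (n < 0) stop("domain error: negative mean intensity", call. = FALSE)
  db_or_sentinel(sqrt(n))
}

#' SNR variant 2: signal over signal-plus-background
#'
#' Default interpretation `S / sqrt(S + N)` (shot-noise-limited signal plus
#' background); the alternate plain ratio `S / (S + N)` is selectable. The
#' active interpretation is stamped into the metric-table provenance.
#'
#' @param signal,background [region_stats()] of the well and of a background
#'   region (b1 annulus or b2 disk).
#' @param interpretation `"shot"` (default, with the radical) or `"ratio"`.
#' @return SNR in dB; `-Inf` sentinel when S = 0 or S + N = 0.
#' @export
snr2 <- function(signal, background, interpretation = c("shot", "ratio")) {
  interpretation <- match.arg(interpretation)
  S <- signal$mean; N <- background$mean
  if (S < 0 || N < 0) stop("domain error: negative mean intensity",
                           call. = FALSE)
  if (S + N == 0) return(-Inf)
  lin <- if (interpretation == "shot") S / sqrt(S + N) else S / (S + N)
  db_or_sentinel(lin)
}

#' SNR variant 3: background-subtracted mean over signal standard deviation
#'
#' `(mean(S) - mean(N)) / sd(S)`. Negative linear values (background
#' brighter than signal) map to the non-detect sentinel in dB.
#'
#' @inheritParams snr2
#' @return SNR in dB; `-Inf` sentinel for non-positive linear SNR.
#' @export
snr3 <- function(signal, background) {
  if (signal$std <= 0) {
    stop("undefined-noise error: signal standard deviation is zero",
         call. = FALSE)
  }
  db_or_sentinel((signal$mean - background$mean) / signal$std)
}

#' SNR variant 4: background-subtracted mean over background standard
#' deviation
#'
#' `(mean(S) - mean(N)) / sd(N)`: the detection-limit form, equal to 6.02 dB
#' exactly when the signal excess is twofold the background noise.
#'
#' @inheritParams snr2
#' @return SNR in dB; `-Inf` sentinel for non-positive linear SNR.
#' @export
snr4 <- function(signal, background) {
  if (background$std <= 0) {
    stop("undefined-noise error: background standard deviation is zero",
         call. = FALSE)
  }
  db_or_sentinel((signal$mean - background$mean) / background$std)
}

#' Michelson contrast
#'
#' `(Imax - Imin) / (Imax + Imin)` with `Imax` the maximum well pixel
#' intensity and `Imin` the minimum background pixel intensity.
#'
#' @inheritParams snr2
#' @return Unitless contrast; `NaN` sentinel when `Imax + Imin = 0`.
#' @export
michelson <- function(signal, background) {
  imax <- signal$max; imin <- background$min
  if (imax < 0 || imin < 0) stop("domain error: negative intensity",
                                 call. = FALSE)
  if (imax + imin == 0) return(NaN)
  (imax - imin) / (imax + imin)
}

#' Weber contrast
#'
#' `(Is - Ib) / Ib` with `Is` the maximum well pixel intensity and `Ib` the
#' minimum background pixel intensity.
#'
#' @inheritParams snr2
#' @return Unitless contrast.
#' @export
weber <- function(signal, background) {
  is_ <- signal$max; ib <- background$min
  if (ib <= 0) {
    stop("undefined-background error: minimum background intensity is zero",
         call. = FALSE)
  }
  (is_ - ib) / ib
}

#' Enumerate the eleven metric variants
#'
#' Seven SNR variants (SNR1; SNR2, SNR3, SNR4 each under b1 and b2) and four
#' contrast variants (Michelson and Weber each under b1 and b2).
#'
#' @return Data frame with columns `variant`, `family`, `background`,
#'   `scale` (`"dB"` or `"unitless"`).
#' @export
metric_variants <- function() {
  v <- rbind(
    data.frame(family = "SNR1", background = "none"),
    expand.grid(family = c("SNR2", "SNR3", "SNR4", "CM", "CW"),
                background = c("b1", "b2"), stringsAsFactors = FALSE)
  )
  v <- v[order(match(v$family, c("SNR1", "SNR2", "SNR3", "SNR4", "CM", "CW")),
               v$background), ]
  v$variant <- ifelse(v$background == "none", v$family,
                      paste0(v$family, v$background))
  v$scale <- ifelse(v$family %in% c("CM", "CW"), "unitless", "dB")
  rownames(v) <- NULL
  v[, c("variant", "family", "background", "scale")]
}

#' Compute the full per-well metric table
#'
#' Evaluates, for each of the nine wells, all eleven metric variants:
#' SNR1; SNR2, SNR3, SNR4 each against that well's own b1 annulus and
#' against the shared b2 disk; Michelson and Weber contrast against b1 and
#' b2. Non-finite results are flagged (`sentinel = TRUE`), never silently
#' dropped.
#'
#' @param image an [intensity_image()].
#' @param masks a [build_masks()] result.
#' @param wells the `well_set` the masks were built from (provides depths).
#' @param system_id identifier stamped on every row.
#' @param snr2_interpretation `"shot"` or `"ratio"`, see [snr2()].
#' @param std `"population"` or `"sample"`, see [region_stats()].
#' @return A data frame of class `metric_table` with columns `system`,
#'   `well`, `depth_mm`, `variant`, `family`, `background`, `scale`,
#'   `value`, `sentinel`, and a `provenance` attribute recording every
#'   analysis setting.
#' @export
compute_metric_table <- function(image, masks, wells, system_id = "system",
                                 snr2_interpretation = c("shot", "ratio"),
                                 std = c("population", "sample")) {
  snr2_interpretation <- match.arg(snr2_interpretation)
  std <- match.arg(std)
  stopifnot(inherits(masks, "roi_mask_set"), inherits(wells, "well_set"))
  b2 <- region_stats(image, masks$b2_mask, std = std)
  variants <- metric_variants()
  rows <- vector("list", 9L * nrow(variants))
  k <- 0L
  for (i in seq_len(9)) {
    sig <- region_stats(image, masks$well_masks[[i]], std = std)
    b1 <- region_stats(image, masks$b1_masks[[i]], std = std)
    for (j in seq_len(nrow(variants))) {
      fam <- variants$family[j]
      bg <- switch(variants$background[j], none = NULL, b1 = b1, b2 = b2)
      val <- tryCatch(
        switch(fam,
               SNR1 = snr1(sig),
               SNR2 = snr2(sig, bg, interpretation = snr2_interpretation),
               SNR3 = snr3(sig, bg),
               SNR4 = snr4(sig, bg),
               CM   = michelson(sig, bg),
               CW   = weber(sig, bg)),
        error = function(e) {
          stop(sprintf("well %d, variant %s: %s", i, variants$variant[j],
                       conditionMessage(e)), call. = FALSE)
        })
      k <- k + 1L
      rows[[k]] <- data.frame(
        system = system_id, well = i, depth_mm = wells$depths_mm[i],
        variant = variants$variant[j], family = fam,
        background = variants$background[j], scale = variants$scale[j],
        value = val, sentinel = !is.finite(val))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", "data.frame")
  attr(out, "provenance") <- list(
    system = system_id,
    dark_corrected = image$dark_corrected,
    std_convention = std,
    snr2_interpretation = snr2_interpretation,
    snr1_photon_proxy = "mean well intensity in counts (no gain calibration)",
    overlap_policy = masks$overlap_policy,
    b1_factor = masks$b1_factor,
    db_convention = "20*log10",
    saturated_pixels = sum(vapply(
      c(masks$well_masks, masks$b1_masks, list(masks$b2_mask)),
      function(m) sum(image$values[m] >= image$saturation_value),
      numeric(1)))
  )
  out
}

#' Write a metric table as tidy CSV
#'
#' @param table a [compute_metric_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
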