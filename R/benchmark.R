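#' Detection-limit reference values
#'
#' References derive from assuming normal signal statistics: a measurement
#' has 95% confidence when the signal is twofold the noise level, which
#' fixes 6 dB for SNR, 1/3 for Michelson contrast and 1 for Weber contrast.
#'
#' @param snr_ref SNR reference in dB.
#' @param cm_ref Michelson contrast reference.
#' @param cw_ref Weber contrast reference.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(snr_ref = 6, cm_ref = 0.33, cw_ref = 1) {
  if (any(c(snr_ref, cm_ref, cw_ref) <= 0)) {
    stop("reference values must be strictly positive", call. = FALSE)
  }
  structure(list(snr_ref = snr_ref, cm_ref = cm_ref, cw_ref = cw_ref),
            class = "reference_set")
}

#' Symmetric mean absolute percentage error
#'
#' `smape = (1/n) * sum |X_i - Y| / (|X_i| + |Y|)`, bounded in [0, 1].
#' Non-finite measurements (non-detect sentinels) are replaced by 0, the
#' pessimistic worst case; any 0/0 term is defined as 0.
#'
#' @param values per-well metric values X_1..X_n.
#' @param reference scalar reference value Y (> 0).
#' @return sMAPE in [0, 1].
#' @export
smape <- function(values, reference) {
  if (length(values) == 0L) stop("empty-input error", call. = FALSE)
  if (!is.finite(reference) || reference <= 0) {
    stop("reference must be finite and > 0", call. = FALSE)
  }
  x <- ifelse(is.finite(values), values, 0)
  num <- abs(x - reference)
  den <- abs(x) + abs(reference)
  terms <- ifelse(den == 0, 0, num / den)
  mean(terms)
}

#' Benchmarking score for one (SNR, contrast) combination
#'
#' `BM = (smape_snr + smape_contrast) / N` with `N = 2` metrics combined,
#' i.e. the mean of the two sMAPEs; bounded in [0, 1].
#'
#' @param smape_snr,smape_contrast sMAPE values in [0, 1].
#' @return BM score in [0, 1].
#' @export
bm_score <- function(smape_snr, smape_contrast) {
  stopifnot(smape_snr >= 0, smape_snr <= 1,
            smape_contrast >= 0, smape_contrast <= 1)
  (smape_snr + smape_contrast) / 2
}

#' BM score map for one system
#'
#' Computes the per-variant sMAPE of each metric against its detection-limit
#' reference (SNR variants compared on the dB scale against `snr_ref`,
#' Michelson against `cm_ref`, Weber against `cw_ref`), then combines every
#' SNR variant with every contrast variant into the 7 x 4 BM map.
#'
#' @param table a [compute_metric_table()] result.
#' @param refs a [reference_set()].
#' @return An object of class `bm_result`: `system`, `smape` (named vector
#'   over the 11 variants), `bm` (7 x 4 matrix, rows = SNR variants,
#'   columns = contrast variants), `n_wells` (named vector of the number of
#'   wells entering each variant's sMAPE), `provenance`.
#' @export
bm_map <- function(table, refs = reference_set()) {
  stopifnot(inherits(table, "metric_table"), inherits(refs, "reference_set"))
  variants <- metric_variants()
  sm <- numeric(nrow(variants))
  nw <- integer(nrow(variants))
  names(sm) <- names(nw) <- variants$variant
  for (j in seq_len(nrow(variants))) {
    rows <- table[table$variant == variants$variant[j], ]
    ref <- switch(variants$family[j],
                  CM = refs$cm_ref, CW = refs$cw_ref, refs$snr_ref)
    sm[j] <- smape(rows$value, ref)
    nw[j] <- nrow(rows)
  }
  snr_vars <- variants$variant[!variants$family %in% c("CM", "CW")]
  c_vars <- variants$variant[variants$family %in% c("CM", "CW")]
  bm <- outer(sm[snr_vars], sm[c_vars], bm_score)
  dimnames(bm) <- list(snr_vars, c_vars)
  structure(
    list(system = table$system[1], smape = sm, bm = bm, n_wells = nw,
         references = refs, provenance = attr(table, "provenance")),
    class = "bm_result"
  )
}

#' @export
print.bm_result <- function(x, ...) {
  cat("<bm_result> system", x$system, "\n")
  print(round(x$bm, 3))
  invisible(x)
}

#' Rank systems within each BM map cell
#'
#' Within each of the 28 (SNR variant, contrast variant) cells, systems are
#' ranked by BM score. Under the default `higher_is_better = TRUE`
#' convention the system with the highest BM score receives rank K (best)
#' and the lowest receives rank 1 (worst). Ties are broken by lexicographic
#' system id (the lexicographically earlier system takes the lower rank) and
#' flagged.
#'
#' @param results list of [bm_map()] results with identical map layouts.
#' @param higher_is_better if `FALSE`, the ranking is inverted (lowest BM
#'   score is best).
#' @return An object of class `rank_table`: `ranks` (7 x 4 x K array),
#'   `systems`, `ties` (7 x 4 logical), `higher_is_better`.
#' @export
rank_systems <- function(results, higher_is_better = TRUE) {
  if (length(results) < 2L) {
    stop("need at least 2 systems to rank", call. = FALSE)
  }
  layouts <- lapply(results, function(r) dimnames(r$bm))
  if (!all(vapply(layouts[-1], identical, logical(1), layouts[[1]]))) {
    stop("layout error: BM maps have different layouts", call. = FALSE)
  }
  systems <- vapply(results, function(r) r$system, character(1))
  if (anyDuplicated(systems)) {
    stop("layout error: duplicate system ids", call. = FALSE)
  }
  K <- length(results)
  dn <- dimnames(results[[1]]$bm)
  ranks <- array(NA_integer_, dim = c(dim(results[[1]]$bm), K),
                 dimnames = c(dn, list(systems)))
  ties <- matrix(FALSE, nrow(ranks), ncol(ranks), dimnames = dn)
  for (i in seq_len(nrow(ranks))) {
    for (j in seq_len(ncol(ranks))) {
      scores <- vapply(results, function(r) r$bm[i, j], numeric(1))
      ties[i, j] <- anyDuplicated(scores) > 0L
      key <- if (higher_is_better) scores else -scores
      # order by score ascending, ties by system id ascending -> worst first
      ord <- order(key, systems)
      ranks[i, j, ord] <- seq_len(K)
    }
  }
  structure(list(ranks = ranks, systems = systems, ties = ties,
                 higher_is_better = higher_is_better),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat("<rank_table>", length(x$systems), "systems (rank",
      length(x$systems), "= best):\n")
  for (s in x$systems) {
    cat(" ", s, ": median rank", stats::median(x$ranks[, , s]), "\n")
  }
  invisible(x)
}

#' Write a BM map (and optional heatmap) to disk
#'
#' @param result a [bm_map()] result.
#' @param path output CSV path (rows = SNR variants, columns = contrast
#'   variants).
#' @param heatmap_path optional PNG heatmap path.
#' @return `path`, invisibly.
#' @export
write_bm_map <- function(result, path, heatmap_path = NULL) {
  utils::write.csv(as.data.frame(result$bm), path, row.names = TRUE)
  if (!is.null(heatmap_path)) {
    grDevices::png(heatmap_path, width = 480, height = 640)
    on.exit(grDevices::dev.off())
    graphics::image(
      t(result$bm[nrow(result$bm):1, ]), axes = FALSE,
      col = grDevices::hcl.colors(64, "viridis"),
      main = paste("BM scores:", result$system), zlim = c(0, 1))
    graphics::axis(1, at = seq(0, 1, length.out = ncol(result$bm)),
                   labels = colnames(result$bm), las = 2)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(result$bm)),
                   labels = rev(rownames(result$bm)), las = 1)
  }
  invisible(path)
}

#' Write a rank table as CSV
#'
#' One row per (SNR variant, contrast variant) cell, one column per system.
#'
#' @param ranks a [rank_systems()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(ranks, path) {
  dn <- dimnames(ranks$ranks)
  grid <- expand.grid(snr = dn[[1]], contrast = dn[[2]],
                      stringsAsFactors = FALSE)
  for (s in ranks$systems) {
    grid[[s]] <- mapply(function(i, j) ranks$ranks[i, j, s],
                        match(grid$snr, dn[[1]]), match(grid$contrast, dn[[2]]))
  }
  grid$tie <- mapply(function(i, j) ranks$ties[i, j],
                     match(grid$snr, dn[[1]]), match(grid$contrast, dn[[2]]))
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
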