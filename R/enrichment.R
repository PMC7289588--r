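#' Per-pixel isotope enrichment maps from a summed ion image
#'
#' Converts the two isotopologue pairs of a summed ion image into per-pixel
#' 13C/12C and 15N/14N atom ratios and per-mil delta values against the
#' reference ratios. The ratio is taken pixel-wise on the plane-summed
#' counts (ratio of sums, never a mean of per-plane ratios). Pixels whose
#' denominator isotopologue (12C12C- for carbon, 12C14N- for nitrogen) has
#' fewer than `min_counts` summed counts are marked invalid and excluded
#' from all downstream statistics; this keeps the Poisson standard error of
#' a single-pixel delta bounded.
#'
#' @param summed A `nanosip_summed` image containing channels `12C12C`,
#'   `12C13C`, `12C14N`, `12C15N`.
#' @param refs Reference ratios, see [ref_ratios()].
#' @param min_counts Minimum summed denominator counts for a pixel to be
#'   valid (default 100).
#' @param c2_correction Dicarbon pairing correction passed to
#'   [ratio_from_c2_counts()]: `"half"` (default) or `"none"`.
#' @return An object of class `nanosip_enrich`: matrices `delta13C`,
#'   `delta15N`, `r13`, `r15` (invalid pixels `NA`), logical `valid13`,
#'   `valid15`, `valid` (= both), the four isotopologue count matrices, and
#'   the parameters used.
#' @export
enrichment_maps <- function(summed, refs = ref_ratios(), min_counts = 100,
                            c2_correction = c("half", "none")) {
  stopifnot(inherits(summed, "nanosip_summed"), min_counts >= 0)
  c2_correction <- match.arg(c2_correction)
  need <- c("12C12C", "12C13C", "12C14N", "12C15N")
  miss <- setdiff(need, summed$channel_names)
  if (length(miss))
    stop("summed image lacks channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  c12 <- channel(summed, "12C12C"); c13 <- channel(summed, "12C13C")
  n14 <- channel(summed, "12C14N"); n15 <- channel(summed, "12C15N")

  valid13 <- c12 >= max(min_counts, 1)
  valid15 <- n14 >= max(min_counts, 1)
  r13 <- ratio_from_c2_counts(c13, c12, c2_correction)
  r15 <- ratio_from_cn_counts(n15, n14)
  r13[!valid13] <- NA_real_
  r15[!valid15] <- NA_real_
  delta13C <- delta_from_ratio(r13, refs$r13)
  delta15N <- delta_from_ratio(r15, refs$r15)

  structure(list(
    delta13C = delta13C, delta15N = delta15N, r13 = r13, r15 = r15,
    valid13 = valid13, valid15 = valid15, valid = valid13 & valid15,
    counts = list(`12C12C` = c12, `12C13C` = c13,
                  `12C14N` = n14, `12C15N` = n15),
    refs = refs, min_counts = min_counts, c2_correction = c2_correction,
    provenance = summed$provenance),
    class = "nanosip_enrich")
}

#' @export
print.nanosip_enrich <- function(x, ...) {
  cat(sprintf("Enrichment maps %d x %d px (min_counts = %d, C2 correction: %s)\n",
              nrow(x$delta13C), ncol(x$delta13C), x$min_counts,
              x$c2_correction))
  cat(sprintf("  valid pixels: %d of %d\n", sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Write enrichment maps as a float TIFF with JSON sidecar
#'
#' Channels `delta13C`, `delta15N` and `valid` are written as three pages;
#' invalid pixels carry the sentinel recorded in the sidecar.
#'
#' @param maps A `nanosip_enrich`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(maps, path) {
  stopifnot(inherits(maps, "nanosip_enrich"))
  lo <- -1000
  rng <- range(c(maps$delta13C, maps$delta15N), na.rm = TRUE)
  hi <- max(rng[2], lo + 1)
  enc <- function(m) {
    m[is.na(m)] <- lo
    (pmin(pmax(m, lo), hi) - lo) / (hi - lo)
  }
  tiff::writeTIFF(list(enc(maps$delta13C), enc(maps$delta15N),
                       maps$valid * 1), path,
                  bits.per.sample = 32L, compression = "deflate")
  jsonlite::write_json(
    list(format = "nanosip_enrich", channels = c("delta13C", "delta15N", "valid"),
         delta_low = lo, delta_high = hi, invalid_sentinel = lo,
         min_counts = maps$min_counts, c2_correction = maps$c2_correction,
         r13_standard = maps$refs$r13, r15_standard = maps$refs$r15),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tidy per-pixel enrichment table
#'
#' One row per valid pixel with both deltas, ready for dplyr/ggplot2 work.
#'
#' @param x A `nanosip_enrich`.
#' @param ... Unused.
#' @return A tibble: `row`, `col`, `delta13C`, `delta15N`, `valid13`,
#'   `valid15`.
#' @export
tidy.nanosip_enrich <- function(x, ...) {
  idx <- which(x$valid13 | x$valid15)
  tibble::tibble(
    row = ((idx - 1L) %% nrow(x$delta13C)) + 1L,
    col = ((idx - 1L) %/% nrow(x$delta13C)) + 1L,
    delta13C = x$delta13C[idx], delta15N = x$delta15N[idx],
    valid13 = x$valid13[idx], valid15 = x$valid15[idx])
}
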