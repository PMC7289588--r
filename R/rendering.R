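#' Rendering specification for delta and count images
#'
#' Controls how a delta (or count) image is mapped to colors: intensity
#' bounds (fixed in per mil, or percentile-based winsorization), the
#' colormap, and the width of the perceptual edge fade toward the black
#' background.
#'
#' @param bounds_mode `"percentile"` (winsorize at `percentiles` of the
#'   valid pixels, the default) or `"fixed"` (clamp to `fixed_bounds`).
#' @param fixed_bounds Length-2 numeric `(low, high)`, required for
#'   `"fixed"` mode (e.g. `c(-200, 9000)` for a delta13C display).
#' @param percentiles Length-2 percentiles in \[0, 100\] for
#'   `"percentile"` mode (default `c(5, 95)`).
#' @param fade_band_px Width in pixels of the lightness fade next to
#'   background (default 2).
#' @param colormap_name Colormap (default `"cividis"`).
#' @param background_color Background color (default black).
#' @return An object of class `nanosip_render_spec`.
#' @export
render_spec <- function(bounds_mode = c("percentile", "fixed"),
                        fixed_bounds = NULL, percentiles = c(5, 95),
                        fade_band_px = 2, colormap_name = "cividis",
                        background_color = "black") {
  bounds_mode <- match.arg(bounds_mode)
  if (bounds_mode == "fixed") {
    if (is.null(fixed_bounds) || length(fixed_bounds) != 2 ||
        fixed_bounds[1] >= fixed_bounds[2])
      stop("fixed mode requires fixed_bounds = c(low, high) with low < high",
           call. = FALSE)
  } else {
    stopifnot(length(percentiles) == 2, percentiles[1] < percentiles[2],
              percentiles[1] >= 0, percentiles[2] <= 100)
  }
  stopifnot(fade_band_px >= 0)
  structure(list(bounds_mode = bounds_mode, fixed_bounds = fixed_bounds,
                 percentiles = percentiles, fade_band_px = fade_band_px,
                 colormap_name = colormap_name,
                 background_color = background_color),
            class = "nanosip_render_spec")
}

#' Clip and normalize an image to the unit interval
#'
#' Percentile mode winsorizes at the stated percentiles of the valid pixels
#' (values beyond them are set to the percentile value) and then min-max
#' scales; fixed mode clamps to the fixed bounds and scales. Percentiles use
#' linear interpolation (`stats::quantile` type 7). A constant image maps to
#' all zeros. Pixel order among unclipped values is preserved.
#'
#' @param image Numeric matrix; `NA` pixels are ignored for bounds and
#'   return `NA`.
#' @param spec A [render_spec()].
#' @param valid Optional logical matrix restricting which pixels define
#'   percentile bounds.
#' @return List: `unit` (matrix in \[0,1\]), `bounds` (realized low/high).
#' @export
clip_normalize <- function(image, spec = render_spec(), valid = NULL) {
  stopifnot(is.matrix(image))
  v <- image
  if (!is.null(valid)) v[!valid] <- NA
  vals <- v[is.finite(v)]
  if (!length(vals))
    stop("render error: no finite pixels to scale", call. = FALSE)
  if (spec$bounds_mode == "fixed") {
    bounds <- spec$fixed_bounds
  } else {
    bounds <- unname(stats::quantile(vals, spec$percentiles / 100,
                                     type = 7, names = FALSE))
  }
  clipped <- pmin(pmax(image, bounds[1]), bounds[2])
  rng <- bounds[2] - bounds[1]
  unit <- if (rng <= 0) {
    z <- image; z[] <- 0; z[is.na(image)] <- NA; z
  } else (clipped - bounds[1]) / rng
  list(unit = unit, bounds = bounds)
}

#' Map a unit-interval image through a colormap
#'
#' @param unit Matrix in \[0, 1\] (NAs allowed).
#' @param colormap_name Currently `"cividis"` (perceptually uniform,
#'   color-vision-deficiency-friendly) or any `grDevices::hcl.colors`
#'   palette name.
#' @param n Number of colormap levels.
#' @return `[h, w, 3]` array of sRGB values in \[0, 1\]; `NA` pixels map to
#'   black.
#' @export
apply_colormap <- function(unit, colormap_name = "cividis", n = 256L) {
  pal_name <- if (tolower(colormap_name) == "cividis") "Cividis"
              else colormap_name
  pal <- grDevices::hcl.colors(n, pal_name)
  rgb <- t(grDevices::col2rgb(pal)) / 255
  idx <- pmin(pmax(floor(unit * (n - 1)) + 1L, 1L), n)
  h <- nrow(unit); w <- ncol(unit)
  out <- array(0, c(h, w, 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[ok] <- rgb[idx[ok], ch]
    out[, , ch] <- plane
  }
  out
}

#' Fade foreground pixels near the background toward black
#'
#' Computes the Euclidean distance of every foreground pixel to the nearest
#' background pixel; pixels within `fade_band_px` have their perceptual
#' lightness (J' in CAM02-UCS) scaled by `d / (fade_band_px + 1)`, leaving
#' hue and colorfulness coordinates untouched, and are converted back to
#' sRGB. Background pixels are painted black. Pixels beyond the band are
#' bit-identical before and after; no pixel is ever brightened.
#'
#' @param rgb `[h, w, 3]` sRGB array in \[0, 1\].
#' @param background_mask Logical matrix, `TRUE` at background.
#' @param fade_band_px Band width in pixels (default 2; 0 disables fading).
#' @return `[h, w, 3]` sRGB array.
#' @export
fade_edges <- function(rgb, background_mask, fade_band_px = 2) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3,
            identical(dim(rgb)[1:2], dim(background_mask)),
            fade_band_px >= 0)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  out <- rgb
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[background_mask] <- 0
    out[, , ch] <- plane
  }
  if (fade_band_px == 0 || !any(background_mask) || all(background_mask))
    return(out)
  fg <- matrix(1, h, w)
  fg[background_mask] <- 0
  d <- as.matrix(EBImage::distmap(fg, metric = "euclidean"))
  band <- which(!background_mask & d <= fade_band_px)
  if (!length(band)) return(out)
  cols <- cbind(out[, , 1][band], out[, , 2][band], out[, , 3][band])
  ucs <- srgb_to_cam02ucs(cols)
  ucs[, 1] <- ucs[, 1] * d[band] / (fade_band_px + 1)
  faded <- cam02ucs_to_srgb(ucs)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[band] <- faded[, ch]
    out[, , ch] <- plane
  }
  out
}

#' Render a delta image to a PNG file
#'
#' The full deterministic rendering contract: clip/normalize the chosen
#' delta map (invalid pixels and `background_mask` count as background),
#' apply the colormap, fade the 2-pixel boundary band toward black, paint
#' background black, and write a PNG plus a provenance JSON with the
#' realized bounds. Identical inputs produce byte-identical PNGs.
#'
#' @param enrich A `nanosip_enrich`.
#' @param which `"delta13C"` or `"delta15N"`.
#' @param background_mask Logical background matrix (e.g. from
#'   segmentation); invalid enrichment pixels are always treated as
#'   background.
#' @param spec A [render_spec()].
#' @param path Output PNG path; provenance JSON goes to
#'   `paste0(path, ".json")`.
#' @return Invisibly, the realized bounds `c(low, high)`.
#' @export
render_delta_png <- function(enrich, which = c("delta13C", "delta15N"),
                             background_mask = NULL, spec = render_spec(),
                             path) {
  which <- match.arg(which)
  stopifnot(inherits(enrich, "nanosip_enrich"))
  img <- enrich[[which]]
  validity <- if (which == "delta13C") enrich$valid13 else enrich$valid15
  bg <- !validity
  if (!is.null(background_mask)) bg <- bg | background_mask
  if (all(bg)) stop("render error: image is entirely background", call. = FALSE)
  cn <- clip_normalize(img, spec, valid = !bg)
  rgb <- apply_colormap(cn$unit, spec$colormap_name)
  rgb <- fade_edges(rgb, bg, spec$fade_band_px)
  png::writePNG(rgb, path)
  jsonlite::write_json(
    list(image = which, bounds_mode = spec$bounds_mode,
         realized_bounds = cn$bounds, percentiles = spec$percentiles,
         fade_band_px = spec$fade_band_px,
         colormap = spec$colormap_name,
         percentile_definition = "linear interpolation (type 7)",
         fade_distance = "euclidean"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(cn$bounds)
}
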