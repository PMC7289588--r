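#' Threshold the log of a count image
#'
#' The first Fig-S6-style segmentation step: take `log1p` of a raw count
#' image and threshold it to separate high from low signal. The automatic
#' method maximizes between-class variance over 256 candidate thresholds on
#' the log histogram (Otsu's criterion); `"manual"` uses a caller-supplied
#' threshold on the `log1p` scale.
#'
#' @param image Numeric count matrix (one channel of a summed image).
#' @param method `"otsu"` or `"manual"`.
#' @param value Manual threshold on the `log1p(counts)` scale (required for
#'   `method = "manual"`).
#' @param channel_name Optional channel label recorded in the result. The
#'   standard recipe uses `16O`, `12C14N` and `31P`; other channels are
#'   accepted with a warning.
#' @return A logical mask (`log1p(counts) > threshold`) with attributes
#'   `threshold` and `method`.
#' @export
log_threshold <- function(image, method = c("otsu", "manual"), value = NULL,
                          channel_name = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.null(channel_name) &&
      !channel_name %in% c("16O", "12C14N", "31P"))
    warning("channel ", channel_name,
            " is not part of the standard segmentation recipe")
  lg <- log1p(image)
  if (method == "manual") {
    if (is.null(value))
      stop("manual thresholding requires `value`", call. = FALSE)
    thr <- value
  } else {
    if (diff(range(lg)) < .Machine$double.eps^0.5)
      stop("degenerate threshold: image is constant on the log scale; ",
           "use method = \"manual\"", call. = FALSE)
    thr <- otsu_threshold(lg, n_bins = 256L)
  }
  structure(lg > thr, threshold = thr, method = method,
            channel_name = channel_name)
}

# Between-class-variance-maximizing threshold on a 256-bin histogram.
# Returns a value strictly between the two classes (bin upper edge).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  w2 <- 1 - w1
  bcv <- (mu_t * w1 - mu1)^2 / (w1 * w2)
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  edges[k + 1L]
}

#' Combine thresholded channel masks into class masks
#'
#' Evaluates a boolean recipe over the three thresholded channel masks
#' (`o` = 16O, `cn` = 12C14N, `p` = 31P) to produce the class masks. The
#' default recipe treats the cyanide mask as biomass, splits biomass into
#' autotrophs (phosphate-high, reflecting cyanobacterial polyphosphate) and
#' heterotrophs (phosphate-low), and calls everything outside both the
#' cyanide and oxygen masks background. The recipe is recorded verbatim for
#' provenance and can be overridden.
#'
#' @param o_mask,cn_mask,p_mask Logical masks of identical shape.
#' @param recipe Named list of boolean expressions (as strings) over the
#'   names `o`, `cn`, `p` with entries `autotroph`, `heterotroph`,
#'   `background`, `phosphate_high`.
#' @return An object of class `nanosip_masks`: the four logical masks plus
#'   the recipe and any threshold attributes found on the inputs.
#' @export
build_masks <- function(o_mask, cn_mask, p_mask,
                        recipe = default_mask_recipe()) {
  stopifnot(is.logical(o_mask), is.logical(cn_mask), is.logical(p_mask),
            identical(dim(o_mask), dim(cn_mask)),
            identical(dim(o_mask), dim(p_mask)))
  need <- c("autotroph", "heterotroph", "background", "phosphate_high")
  if (!all(need %in% names(recipe)))
    stop("recipe must define: ", paste(need, collapse = ", "), call. = FALSE)
  env <- list(o = unclass_mask(o_mask), cn = unclass_mask(cn_mask),
              p = unclass_mask(p_mask))
  ev <- function(expr_str) {
    e <- parse(text = expr_str)[[1]]
    bad <- setdiff(all.vars(e), names(env))
    if (length(bad))
      stop("recipe references unknown input(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    out <- eval(e, env)
    stopifnot(is.logical(out))
    out
  }
  masks <- lapply(recipe[need], ev)
  structure(c(masks, list(
    recipe = recipe,
    thresholds = list(o = attr(o_mask, "threshold"),
                      cn = attr(cn_mask, "threshold"),
                      p = attr(p_mask, "threshold")))),
    class = "nanosip_masks")
}

#' Default boolean mask recipe
#' @return Named list of recipe expressions (strings over `o`, `cn`, `p`).
#' @export
default_mask_recipe <- function() {
  list(autotroph = "cn & p",
       heterotroph = "cn & !p",
       background = "!(cn | o)",
       phosphate_high = "p & !cn")
}

unclass_mask <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' @export
print.nanosip_masks <- function(x, ...) {
  cat("Segmentation masks:\n")
  for (nm in c("background", "autotroph", "heterotroph", "phosphate_high"))
    cat(sprintf("  %-15s %6d px\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening with a disc structuring element of the given radius,
#' followed by removal of 8-connected components smaller than
#' `min_object_px`. Idempotent for fixed parameters.
#'
#' @param mask Logical matrix.
#' @param min_object_px Minimum component size kept (0 keeps all).
#' @param opening_radius Disc radius for the opening (0 skips it).
#' @return Cleaned logical mask.
#' @export
cleanup_mask <- function(mask, min_object_px = 10, opening_radius = 1) {
  stopifnot(is.logical(mask), min_object_px >= 0, opening_radius >= 0)
  m <- unclass_mask(mask)
  if (opening_radius > 0) {
    # square (Chebyshev-ball) element, consistent with 8-connectivity;
    # preserves axis-aligned rectangles, erodes isolated pixels
    k <- 2L * as.integer(opening_radius) + 1L
    m <- as.matrix(EBImage::opening(m * 1, matrix(1, k, k))) > 0.5
  }
  if (min_object_px > 0) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

#' 8-connected component labeling
#'
#' Labels connected foreground components using 8-connectivity (diagonal
#' neighbours connect).
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels, 0 for background. Labels are
#'   ordered by first (column-major) foreground pixel.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, h, w)
  if (!length(idx)) return(out)
  pos <- integer(h * w)
  pos[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edges <- integer(0)
  # neighbours at +row, +col, +col-row, +col+row (undirected dedup)
  for (d in list(c(1L, 0L), c(0L, 1L), c(-1L, 1L), c(1L, 1L))) {
    nr <- rr + d[1]; nc <- cc + d[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    hit <- pos[nidx] > 0L
    if (any(hit))
      edges <- c(edges, rbind(pos[idx[ok]][hit], pos[nidx][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel in order of first appearance (column-major scan)
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  out[idx] <- relab[memb]
  out
}

#' Resolve heterotroph components overlapping the autotroph mask
#'
#' Heterotroph cells sitting on top of filaments are excluded from analysis,
#' while cells merely attached to a filament side are kept: each 8-connected
#' heterotroph component whose fractional pixel overlap with the autotroph
#' mask exceeds `overlap_fraction_cutoff` is deleted; kept components have
#' their overlapping pixels reassigned to the autotroph mask.
#'
#' @param masks A `nanosip_masks`.
#' @param overlap_fraction_cutoff Deletion cutoff in (0, 1\]; default 0.5.
#' @return The updated `nanosip_masks`, with an `overlap_report` tibble
#'   attached (`component`, `n_px`, `n_overlap`, `fraction`, `kept`).
#' @export
resolve_overlaps <- function(masks, overlap_fraction_cutoff = 0.5) {
  stopifnot(inherits(masks, "nanosip_masks"),
            overlap_fraction_cutoff > 0, overlap_fraction_cutoff <= 1)
  lab <- label_components(masks$heterotroph)
  n_comp <- max(lab)
  het <- masks$heterotroph
  auto <- masks$autotroph
  rep_rows <- list()
  for (k in seq_len(n_comp)) {
    comp <- lab == k
    n_px <- sum(comp)
    n_ov <- sum(comp & auto)
    frac <- n_ov / n_px
    kept <- frac <= overlap_fraction_cutoff
    if (!kept) {
      het[comp] <- FALSE
    } else if (n_ov > 0) {
      het[comp & auto] <- FALSE   # overlap pixels stay autotroph
    }
    rep_rows[[k]] <- tibble::tibble(component = k, n_px = n_px,
                                    n_overlap = n_ov, fraction = frac,
                                    kept = kept)
  }
  masks$heterotroph <- het
  masks$overlap_report <- if (length(rep_rows)) dplyr::bind_rows(rep_rows)
    else tibble::tibble(component = integer(), n_px = integer(),
                        n_overlap = integer(), fraction = double(),
                        kept = logical())
  masks
}

#' Extract per-cell records from class masks and enrichment maps
#'
#' Labels 8-connected components per class and computes per-cell delta
#' values from the summed isotopologue counts over each cell's valid pixels
#' (a ratio of summed counts, not a mean of pixel deltas). Pixels in the
#' `phosphate_high` region are excluded from every record. Cells whose
#' valid denominator counts are zero are flagged (`excluded = TRUE`) and
#' carry `NA` deltas.
#'
#' @param masks A `nanosip_masks` (after any overlap resolution).
#' @param enrich A `nanosip_enrich` sharing the mask shape.
#' @return A tibble with one row per cell: `cell_id`, `class`, `n_px`,
#'   `n_valid13`, `n_valid15`, summed isotopologue counts, `delta13C_cell`,
#'   `delta15N_cell`, `excluded`, and list-columns `pixels` (linear indices),
#'   `pixel_delta13C`, `pixel_delta15N`.
#' @export
label_cells <- function(masks, enrich) {
  stopifnot(inherits(masks, "nanosip_masks"), inherits(enrich, "nanosip_enrich"),
            identical(dim(masks$autotroph), dim(enrich$delta13C)))
  cts <- enrich$counts
  refs <- enrich$refs
  out <- list()
  next_id <- 0L
  for (cls in c("autotroph", "heterotroph")) {
    m <- masks[[cls]] & !masks$phosphate_high
    lab <- label_components(m)
    for (k in seq_len(max(lab))) {
      next_id <- next_id + 1L
      px <- which(lab == k)
      v13 <- px[enrich$valid13[px]]
      v15 <- px[enrich$valid15[px]]
      s12 <- sum(cts$`12C12C`[v13]); s13 <- sum(cts$`12C13C`[v13])
      s14 <- sum(cts$`12C14N`[v15]); s15 <- sum(cts$`12C15N`[v15])
      d13 <- if (s12 > 0)
        delta_from_ratio(ratio_from_c2_counts(s13, s12, enrich$c2_correction),
                         refs$r13) else NA_real_
      d15 <- if (s14 > 0)
        delta_from_ratio(ratio_from_cn_counts(s15, s14), refs$r15)
        else NA_real_
      out[[next_id]] <- tibble::tibble(
        cell_id = next_id, class = cls, n_px = length(px),
        n_valid13 = length(v13), n_valid15 = length(v15),
        c12C12C = s12, c12C13C = s13, c12C14N = s14, c12C15N = s15,
        delta13C_cell = d13, delta15N_cell = d15,
        excluded = s12 == 0 || s14 == 0,
        pixels = list(px),
        pixel_delta13C = list(enrich$delta13C[v13]),
        pixel_delta15N = list(enrich$delta15N[v15]))
    }
  }
  if (!length(out))
    return(tibble::tibble(cell_id = integer(), class = character(),
                          n_px = integer(), n_valid13 = integer(),
                          n_valid15 = integer(), c12C12C = double(),
                          c12C13C = double(), c12C14N = double(),
                          c12C15N = double(), delta13C_cell = double(),
                          delta15N_cell = double(), excluded = logical(),
                          pixels = list(), pixel_delta13C = list(),
                          pixel_delta15N = list()))
  dplyr::bind_rows(out)
}

#' One-call segmentation of a summed image
#'
#' Convenience wrapper running the standard recipe: log-threshold the 16O,
#' 12C14N and 31P channels, combine them with `recipe`, clean both class
#' masks, and resolve heterotroph/autotroph overlaps.
#'
#' @param summed A `nanosip_summed` image.
#' @param recipe Boolean recipe, see [build_masks()].
#' @param thresholds Optional named list of manual `log1p`-scale thresholds
#'   for any of `o`, `cn`, `p`; channels not named use Otsu.
#' @param min_object_px,opening_radius Cleanup parameters, see
#'   [cleanup_mask()].
#' @param overlap_fraction_cutoff See [resolve_overlaps()].
#' @return A `nanosip_masks`.
#' @export
segment_image <- function(summed, recipe = default_mask_recipe(),
                          thresholds = list(),
                          min_object_px = 10, opening_radius = 1,
                          overlap_fraction_cutoff = 0.5) {
  thr_mask <- function(ch, key) {
    img <- channel(summed, ch)
    if (!is.null(thresholds[[key]]))
      log_threshold(img, "manual", thresholds[[key]], channel_name = ch)
    else log_threshold(img, "otsu", channel_name = ch)
  }
  masks <- build_masks(thr_mask("16O", "o"), thr_mask("12C14N", "cn"),
                       thr_mask("31P", "p"), recipe)
  masks$autotroph <- cleanup_mask(masks$autotroph, min_object_px,
                                  opening_radius)
  masks$heterotroph <- cleanup_mask(masks$heterotroph, min_object_px,
                                    opening_radius)
  resolve_overlaps(masks, overlap_fraction_cutoff)
}

#' Jaccard overlap between two masks
#' @param a,b Logical matrices of identical shape.
#' @return Intersection over union (1 if both empty).
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
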