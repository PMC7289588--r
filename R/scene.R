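#' Synthetic biofilm scene specification
#'
#' Describes the geometry and acquisition parameters of a synthetic
#' phototrophic-biofilm scene: cyanobacterial filaments (autotrophs) drawn as
#' constant-width tubes along smooth random curves spanning the field, and
#' coccoid heterotrophs placed partly side-attached to the filaments and
#' partly distal. Defaults mirror the standard acquisition geometry this
#' package models: a 40 um field imaged at 256 x 256 pixels over 13 planes.
#'
#' @param height_px,width_px Canvas size in pixels (>= 16).
#' @param pixel_size_um Pixel edge in micrometres.
#' @param n_planes Number of acquisition planes (>= 1).
#' @param n_filaments,n_cocci Object counts (>= 0).
#' @param filament_width_px Filament tube width in pixels.
#' @param coccus_radius_px Coccus disc radius in pixels.
#' @param attach_fraction Fraction of cocci placed touching a filament side;
#'   the rest are placed distal (not touching any filament).
#' @param n_granules_per_filament Number of high-phosphate granule discs
#'   placed inside each filament.
#' @param granule_radius_px Granule disc radius in pixels.
#' @param condition Labeling regime, `"NO3_only"` or `"NH4_amended"`;
#'   selects the default class enrichment profiles.
#' @param seed Integer seed; identical spec + seed reproduces the scene
#'   bit-exactly.
#' @return An object of class `nanosip_scene_spec` (a named list).
#' @export
scene_spec <- function(height_px = 256, width_px = 256,
                       pixel_size_um = 40 / 256, n_planes = 13,
                       n_filaments = 2, n_cocci = 30,
                       filament_width_px = 12, coccus_radius_px = 4,
                       attach_fraction = 0.5,
                       n_granules_per_filament = 3, granule_radius_px = 2.5,
                       condition = c("NO3_only", "NH4_amended"),
                       seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(height_px >= 16, width_px >= 16, n_planes >= 1,
            n_filaments >= 0, n_cocci >= 0,
            filament_width_px > 0, coccus_radius_px > 0,
            attach_fraction >= 0, attach_fraction <= 1,
            pixel_size_um > 0)
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    pixel_size_um = pixel_size_um, n_planes = as.integer(n_planes),
    n_filaments = as.integer(n_filaments), n_cocci = as.integer(n_cocci),
    filament_width_px = filament_width_px,
    coccus_radius_px = coccus_radius_px,
    attach_fraction = attach_fraction,
    n_granules_per_filament = as.integer(n_granules_per_filament),
    granule_radius_px = granule_radius_px,
    condition = condition, seed = as.integer(seed)),
    class = "nanosip_scene_spec")
}

#' Default per-class enrichment and count-rate profiles
#'
#' One row per scene class (background, autotroph, heterotroph) giving the
#' 13C and 15N atom fractions and the expected secondary-ion count rates per
#' pixel per plane for each detected channel group. Heterotroph atom
#' fractions are chosen so the implied population deltas match the published
#' Fig-3-style values for each labeling regime (NO3-only heterotrophs:
#' delta13C 1328.39 permil, delta15N 1814.13 permil; NH4-amended:
#' delta13C 121.38 permil, delta15N 6351.97 permil). Autotroph deltas are
#' not published and are package defaults chosen to satisfy the qualitative
#' pattern (autotrophs co-enriched in both isotopes under both regimes, more
#' strongly under NH4 amendment). Count rates are synthetic defaults; no
#' instrument rates are published.
#'
#' @param condition `"NO3_only"` or `"NH4_amended"`.
#' @param refs Reference ratios used to convert deltas to atom fractions.
#' @return A tibble with columns `class`, `x13`, `x15`, `rate_16O`,
#'   `rate_C2`, `rate_CN`, `rate_31P`.
#' @export
default_profiles <- function(condition = c("NO3_only", "NH4_amended"),
                             refs = ref_ratios()) {
  condition <- match.arg(condition)
  d <- switch(condition,
    NO3_only    = list(het = c(1328.39, 1814.13), auto = c(3000, 9000)),
    NH4_amended = list(het = c(121.38, 6351.97),  auto = c(5500, 16000)))
  tibble::tibble(
    class = c("background", "autotroph", "heterotroph"),
    x13 = atom_fraction_from_delta(c(0, d$auto[1], d$het[1]), refs$r13),
    x15 = atom_fraction_from_delta(c(0, d$auto[2], d$het[2]), refs$r15),
    rate_16O = c(5, 40, 30),
    rate_C2  = c(0.5, 80, 60),
    rate_CN  = c(1, 200, 150),
    rate_31P = c(0.05, 15, 0.3))
}

# Deterministic sub-seed per (seed, operation) so adding one draw stream
# does not perturb the others.
op_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 10007 + h * 97) %% 2147483647)
}

#' Generate a ground-truth biofilm scene
#'
#' Places filaments, granules and cocci on the canvas and returns per-pixel
#' ground truth. Pixels where a coccus overlaps a filament are resolved in
#' favour of the autotroph class in `class_map`, but the overlap is recorded
#' per cell so downstream overlap-exclusion logic can be validated.
#'
#' @param spec A [scene_spec()].
#' @param profiles Class profile tibble as from [default_profiles()]; must
#'   cover classes background, autotroph and heterotroph.
#' @return An object of class `nanosip_truth`: list with integer
#'   `class_map` (0 background, 1 autotroph, 2 heterotroph), `x13_map`,
#'   `x15_map`, `cell_id_map` (0 = background), logical `granule_map`, and a
#'   `cells` tibble (`cell_id`, `class`, `n_px`, `n_overlap_px`, `attached`).
#' @export
make_scene <- function(spec, profiles = default_profiles(spec$condition)) {
  stopifnot(inherits(spec, "nanosip_scene_spec"))
  need <- c("background", "autotroph", "heterotroph")
  if (!all(need %in% profiles$class))
    stop("profiles must cover classes: ", paste(need, collapse = ", "),
         call. = FALSE)
  h <- spec$height_px; w <- spec$width_px
  class_map <- matrix(0L, h, w)
  cell_id_map <- matrix(0L, h, w)
  granule_map <- matrix(FALSE, h, w)
  cells <- list()

  half_w <- spec$filament_width_px / 2
  r <- spec$coccus_radius_px
  if (spec$n_filaments > 0 &&
      (2 * half_w >= min(h, w) || 2 * half_w >= h))
    stop("placement error: filament too wide for the canvas", call. = FALSE)
  if (spec$n_cocci > 0 && (2 * r + 2 >= min(h, w)))
    stop("placement error: coccus too large for the canvas", call. = FALSE)

  # filaments: smooth spline centerlines spanning the field left-to-right
  set.seed(op_seed(spec$seed, "filaments"))
  centerlines <- list()
  for (i in seq_len(spec$n_filaments)) {
    nx <- 6
    cx <- seq(-4, w + 4, length.out = nx)
    band <- c(0.15, 0.85) * h
    cy <- stats::runif(1, band[1], band[2]) +
      cumsum(stats::rnorm(nx, 0, h / 14))
    cy <- pmin(pmax(cy, half_w + 1), h - half_w - 1)
    s <- stats::spline(cx, cy, n = 6L * w)
    keep <- s$x >= 1 & s$x <= w & s$y >= 1 & s$y <= h
    centerlines[[i]] <- cbind(row = s$y[keep], col = s$x[keep])
    cl <- matrix(1L, h, w)
    cl[cbind(pmin(pmax(round(s$y[keep]), 1), h),
             pmin(pmax(round(s$x[keep]), 1), w))] <- 0L
    d <- as.matrix(EBImage::distmap(cl, metric = "euclidean"))
    tube <- d <= half_w
    newpx <- tube & class_map == 0L
    class_map[tube] <- 1L
    cell_id_map[newpx] <- i
    cells[[i]] <- tibble::tibble(cell_id = i, class = "autotroph",
                                 n_px = sum(newpx), n_overlap_px = 0L,
                                 attached = NA)
  }

  # phosphate granules inside filaments
  set.seed(op_seed(spec$seed, "granules"))
  for (i in seq_len(spec$n_filaments)) {
    pts <- centerlines[[i]]
    if (nrow(pts) == 0L) next
    idx <- sample.int(nrow(pts), min(spec$n_granules_per_filament, nrow(pts)))
    for (j in idx) {
      disc <- disc_pixels(pts[j, "row"], pts[j, "col"],
                          spec$granule_radius_px, h, w)
      granule_map[disc] <- TRUE
    }
  }
  granule_map <- granule_map & class_map == 1L

  # cocci: some side-attached to filaments, the rest distal
  set.seed(op_seed(spec$seed, "cocci"))
  n_attached <- if (spec$n_filaments > 0)
    round(spec$attach_fraction * spec$n_cocci) else 0L
  auto_dist <- if (spec$n_filaments > 0) {
    m <- matrix(1L, h, w); m[class_map == 1L] <- 0L
    as.matrix(EBImage::distmap(m, metric = "euclidean"))
  } else matrix(Inf, h, w)
  centers <- matrix(numeric(0), 0, 2)
  place_ok <- function(cy, cx) {
    if (cy < r + 1 || cy > h - r || cx < r + 1 || cx > w - r) return(FALSE)
    if (nrow(centers) == 0) return(TRUE)
    all((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2 > (2 * r + 2)^2)
  }
  all_pts <- do.call(rbind, centerlines)
  for (k in seq_len(spec$n_cocci)) {
    attached_k <- k <= n_attached
    placed <- FALSE
    for (try in seq_len(2000)) {
      if (attached_k) {
        j <- sample.int(nrow(all_pts), 1)
        # local tangent from a neighbouring centerline point
        j2 <- min(j + 5L, nrow(all_pts))
        tv <- all_pts[j2, ] - all_pts[max(j - 5L, 1L), ]
        nv <- c(-tv[2], tv[1]) / sqrt(sum(tv^2) + 1e-12)
        side <- sample(c(-1, 1), 1)
        off <- half_w + r
        cy <- all_pts[j, "row"] + side * nv[1] * off
        cx <- all_pts[j, "col"] + side * nv[2] * off
      } else {
        cy <- stats::runif(1, r + 1, h - r)
        cx <- stats::runif(1, r + 1, w - r)
        if (auto_dist[round(cy), round(cx)] <= r + 3) next
      }
      if (!place_ok(cy, cx)) next
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("placement error: could not place coccus %d", k),
           call. = FALSE)
    centers <- rbind(centers, c(cy, cx))
    disc <- disc_pixels(cy, cx, r, h, w)
    id <- spec$n_filaments + k
    overlap <- class_map[disc] == 1L
    newpx <- disc[!overlap & class_map[disc] == 0L, , drop = FALSE]
    class_map[newpx] <- 2L
    cell_id_map[newpx] <- id
    cells[[id]] <- tibble::tibble(cell_id = id, class = "heterotroph",
                                  n_px = nrow(newpx),
                                  n_overlap_px = sum(overlap),
                                  attached = attached_k)
  }

  prof <- function(cls, col) profiles[[col]][profiles$class == cls]
  x13_map <- matrix(prof("background", "x13"), h, w)
  x15_map <- matrix(prof("background", "x15"), h, w)
  for (cls in c(autotroph = 1L, heterotroph = 2L)) {
    nm <- names(which(c(autotroph = 1L, heterotroph = 2L) == cls))
    x13_map[class_map == cls] <- prof(nm, "x13")
    x15_map[class_map == cls] <- prof(nm, "x15")
  }

  structure(list(
    class_map = class_map, x13_map = x13_map, x15_map = x15_map,
    cell_id_map = cell_id_map, granule_map = granule_map,
    cells = if (length(cells)) dplyr::bind_rows(cells) else
      tibble::tibble(cell_id = integer(), class = character(),
                     n_px = integer(), n_overlap_px = integer(),
                     attached = logical()),
    spec = spec),
    class = "nanosip_truth")
}

disc_pixels <- function(cy, cx, radius, h, w) {
  rr <- max(1, floor(cy - radius)):min(h, ceiling(cy + radius))
  cc <- max(1, floor(cx - radius)):min(w, ceiling(cx + radius))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= radius^2
  cbind(g$row[keep], g$col[keep])
}

#' @export
print.nanosip_truth <- function(x, ...) {
  cat(sprintf("Ground-truth scene %d x %d px: %d autotroph, %d heterotroph cells\n",
              nrow(x$class_map), ncol(x$class_map),
              sum(x$cells$class == "autotroph"),
              sum(x$cells$class == "heterotroph")))
  invisible(x)
}

#' Render a ground-truth scene into a noisy ion-count stack
#'
#' Draws per-pixel, per-plane Poisson counts for each channel group at the
#' class rates, then splits the dicarbon total into 12C12C-/12C13C- by
#' binomial pairing of carbon atoms (13C13C- neglected, second order in the
#' atom fraction) and the cyanide total into 12C14N-/12C15N- by the nitrogen
#' atom fraction. The 31P- rate is elevated inside granule subregions.
#'
#' @param truth A `nanosip_truth` from [make_scene()].
#' @param spec The [scene_spec()] used to build `truth`.
#' @param profiles Class profile tibble (atom fractions are taken from the
#'   truth maps; rates from here).
#' @param granule_rate_31P Expected 31P- counts per pixel per plane inside
#'   granules.
#' @param seed Seed for the rendering noise stream; defaults to the scene
#'   seed.
#' @return A `nanosip_stack` with the six standard channels.
#' @export
render_ion_counts <- function(truth, spec, profiles = default_profiles(spec$condition),
                              granule_rate_31P = 60, seed = spec$seed) {
  stopifnot(inherits(truth, "nanosip_truth"))
  if (any(truth$x13_map < 0 | truth$x13_map > 1) ||
      any(truth$x15_map < 0 | truth$x15_map > 1))
    stop("atom-fraction maps must lie in [0, 1]", call. = FALSE)
  h <- nrow(truth$class_map); w <- ncol(truth$class_map)
  n <- h * w
  cls <- truth$class_map + 1L  # 1 bg, 2 auto, 3 het
  ord <- match(c("background", "autotroph", "heterotroph"), profiles$class)
  rate <- function(col) matrix(profiles[[col]][ord][cls], h, w)
  r16O <- rate("rate_16O"); rC2 <- rate("rate_C2")
  rCN <- rate("rate_CN");   r31P <- rate("rate_31P")
  r31P[truth$granule_map] <- granule_rate_31P
  x13 <- truth$x13_map; x15 <- truth$x15_map
  p13 <- 2 * x13 / (1 + x13)  # P(12C13C | C2 pair detected), 13C13C neglected

  counts <- array(0, c(h, w, 6L, spec$n_planes))
  set.seed(op_seed(seed, "render"))
  for (p in seq_len(spec$n_planes)) {
    c2_tot <- stats::rpois(n, rC2)
    c13 <- stats::rbinom(n, c2_tot, as.vector(p13))
    cn_tot <- stats::rpois(n, rCN)
    c15 <- stats::rbinom(n, cn_tot, as.vector(x15))
    counts[, , 1L, p] <- stats::rpois(n, r16O)
    counts[, , 2L, p] <- c2_tot - c13
    counts[, , 3L, p] <- c13
    counts[, , 4L, p] <- cn_tot - c15
    counts[, , 5L, p] <- c15
    counts[, , 6L, p] <- stats::rpois(n, r31P)
  }
  ion_stack(counts, NANOSIP_CHANNELS,
            pixel_size_um = spec$pixel_size_um,
            dwell_time_ms = 2,
            acquisition_tag = sprintf("synthetic:%s:seed%d",
                                      spec$condition, seed))
}

# Bulk-assay fixtures ----------------------------------------------------

#' Synthetic bulk-IRMS run fixture
#'
#' Builds an instrument-run table of standards and samples with a known
#' affine measurement distortion, optional Gaussian noise, and optional
#' carryover offsets injected into standards that follow labeled samples —
#' the inputs the two-point calibration expects.
#'
#' @param true_deltas Named or unnamed numeric vector of true sample deltas
#'   (permil).
#' @param cal_slope,cal_intercept Affine measurement distortion:
#'   `measured = cal_slope * true + cal_intercept (+ noise)`.
#' @param noise_sd Gaussian measurement noise SD (permil).
#' @param n_clean_per_anchor Leading clean standards per anchor.
#' @param carryover_offsets Numeric offsets (permil) added to the
#'   `follows_labeled` standard after each sample; recycled to the number of
#'   samples. Zero means no carryover.
#' @param anchors Named vector of assigned anchor deltas; defaults to the
#'   USGS 40 / USGS 41 assigned delta13C values.
#' @param seed Integer seed.
#' @return A tibble of IRMS records: `sample_id`, `kind`, `assigned_delta`,
#'   `true_delta`, `measured_delta`, `run_position`, `follows_labeled`.
#' @export
make_bulk_fixture <- function(true_deltas, cal_slope = 1, cal_intercept = 0,
                              noise_sd = 0, n_clean_per_anchor = 2,
                              carryover_offsets = 0,
                              anchors = c(usgs40 = -26.39, usgs41 = 37.63),
                              seed = 1L) {
  stopifnot(length(anchors) == 2, cal_slope != 0)
  set.seed(op_seed(seed, "bulk"))
  ids <- names(true_deltas)
  if (is.null(ids)) ids <- sprintf("sample%02d", seq_along(true_deltas))
  distort <- function(d) cal_slope * d + cal_intercept +
    stats::rnorm(length(d), 0, noise_sd)
  rows <- list()
  pos <- 0L
  for (a in seq_along(anchors)) for (k in seq_len(n_clean_per_anchor)) {
    pos <- pos + 1L
    rows[[pos]] <- tibble::tibble(
      sample_id = sprintf("%s_pre%d", names(anchors)[a], k),
      kind = "standard", assigned_delta = unname(anchors[a]),
      true_delta = unname(anchors[a]),
      measured_delta = distort(unname(anchors[a])),
      run_position = pos, follows_labeled = FALSE)
  }
  off <- rep_len(carryover_offsets, length(true_deltas))
  for (i in seq_along(true_deltas)) {
    pos <- pos + 1L
    rows[[pos]] <- tibble::tibble(
      sample_id = ids[i], kind = "sample", assigned_delta = NA_real_,
      true_delta = unname(true_deltas[i]),
      measured_delta = distort(unname(true_deltas[i])),
      run_position = pos, follows_labeled = FALSE)
    a <- 1L + (i %% 2L)
    pos <- pos + 1L
    rows[[pos]] <- tibble::tibble(
      sample_id = sprintf("%s_post%d", names(anchors)[a], i),
      kind = "standard", assigned_delta = unname(anchors[a]),
      true_delta = unname(anchors[a]),
      measured_delta = distort(unname(anchors[a])) + off[i],
      run_position = pos, follows_labeled = TRUE)
  }
  dplyr::bind_rows(rows)
}

#' Synthetic qPCR plate fixture
#'
#' Standard curve at the six canonical levels (3e1 .. 3e6 copies, in
#' triplicate) plus unknowns, generated from the amplification-efficiency
#' model `Cq = intercept - log10(copies) / log10(1 + efficiency)`.
#'
#' @param true_copies Named numeric vector of unknown template copies (> 0).
#' @param efficiency Amplification efficiency in (0.5, 1.1].
#' @param intercept Cq at 1 copy.
#' @param noise_sd Gaussian Cq noise SD.
#' @param n_rep Technical replicates per well group.
#' @param seed Integer seed.
#' @return A tibble: `well_type`, `sample_id`, `copies`, `replicate`, `cq`.
#' @export
make_qpcr_fixture <- function(true_copies, efficiency = 1, intercept = 38,
                              noise_sd = 0, n_rep = 3, seed = 1L) {
  if (any(true_copies <= 0))
    stop("template copies must be positive", call. = FALSE)
  stopifnot(efficiency > 0.5, efficiency <= 1.1)
  set.seed(op_seed(seed, "qpcr"))
  slope <- -1 / log10(1 + efficiency)
  cq_of <- function(copies, m) intercept + slope * log10(copies) +
    stats::rnorm(m, 0, noise_sd)
  std_levels <- 3 * 10^(6:1)
  std <- tidyr::expand_grid(copies = std_levels, replicate = seq_len(n_rep))
  std <- dplyr::mutate(std,
    well_type = "standard",
    sample_id = sprintf("std_%g", .data$copies),
    cq = cq_of(.data$copies, dplyr::n()) )
  ids <- names(true_copies)
  if (is.null(ids)) ids <- sprintf("unk%02d", seq_along(true_copies))
  unk <- tidyr::expand_grid(i = seq_along(true_copies),
                            replicate = seq_len(n_rep))
  unk <- dplyr::mutate(unk,
    well_type = "unknown", sample_id = ids[.data$i],
    copies = NA_real_,
    cq = cq_of(true_copies[.data$i], dplyr::n()))
  dplyr::bind_rows(
    dplyr::select(std, "well_type", "sample_id", "copies", "replicate", "cq"),
    dplyr::select(unk, "well_type", "sample_id", "copies", "replicate", "cq"))
}

#' Synthetic peptide-count fixture
#'
#' Multinomial peptide counts per organism: each organism's total observed
#' peptides are spread over its proteins with random (but seeded) weights,
#' per sample.
#'
#' @param organism_sizes Named integer vector: proteins per organism.
#' @param organism_totals Total peptide counts per organism (recycled).
#' @param samples Character vector of sample names.
#' @param seed Integer seed.
#' @return A tibble: `organism`, `protein`, `sample`, `count`.
#' @export
make_peptide_fixture <- function(organism_sizes,
                                 organism_totals = 1000,
                                 samples = c("NO3_only", "NH4_amended"),
                                 seed = 1L) {
  stopifnot(length(organism_sizes) >= 1, all(organism_sizes >= 1))
  if (is.null(names(organism_sizes)))
    names(organism_sizes) <- sprintf("org%02d", seq_along(organism_sizes))
  totals <- rep_len(organism_totals, length(organism_sizes))
  set.seed(op_seed(seed, "peptides"))
  out <- list()
  for (i in seq_along(organism_sizes)) {
    k <- organism_sizes[[i]]
    wts <- stats::rexp(k) + 0.05
    for (s in samples) {
      cts <- as.vector(stats::rmultinom(1, totals[i], wts))
      out[[length(out) + 1L]] <- tibble::tibble(
        organism = names(organism_sizes)[i],
        protein = sprintf("%s_p%03d", names(organism_sizes)[i], seq_len(k)),
        sample = s, count = cts)
    }
  }
  dplyr::bind_rows(out)
}
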