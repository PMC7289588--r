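#' Two-point delta calibration with carryover screening
#'
#' Calibrates measured bulk delta values against two standards of known
#' assigned delta (by default the USGS 40 / USGS 41 glutamic acid anchors
#' for delta13C). Standards that directly follow a labeled sample are
#' screened for carryover: if such a standard's measured value deviates
#' from the mean of the clean (non-following) standards of the same anchor
#' by more than `tolerance`, it is flagged and excluded from the fit (but
#' reported, never silently dropped). The remaining standards define an
#' affine map from measured to assigned delta through the two anchor means;
#' the map reproduces the anchor means exactly and is applied to every
#' record.
#'
#' @param records Tibble of IRMS records with columns `sample_id`, `kind`
#'   (`"sample"`/`"standard"`), `assigned_delta` (per mil, `NA` for
#'   samples), `measured_delta`, `run_position`, `follows_labeled`; see
#'   [make_bulk_fixture()].
#' @param tolerance Carryover tolerance in per mil (default 2).
#' @return An object of class `nanosip_calibration`: list with `corrected`
#'   (the records plus `corrected_delta` and `carryover_flag`), `slope`,
#'   `intercept` (assigned = intercept + slope * measured), `anchors`
#'   (per-anchor tibble), and `flagged` (flagged standards).
#' @export
two_point_correct <- function(records, tolerance = 2) {
  need <- c("sample_id", "kind", "assigned_delta", "measured_delta",
            "run_position", "follows_labeled")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records$run_position))
    stop("run_position must be unique within a run", call. = FALSE)
  records <- records[setdiff(names(records),
                             c("corrected_delta", "carryover_flag"))]
  std <- dplyr::filter(records, .data$kind == "standard")
  if (any(is.na(std$assigned_delta)))
    stop("standards must carry assigned_delta", call. = FALSE)
  anchors <- sort(unique(std$assigned_delta))
  if (length(anchors) != 2)
    stop("two-point correction needs exactly 2 distinct assigned ",
         "standard deltas, found ", length(anchors), call. = FALSE)

  std$carryover_flag <- FALSE
  for (a in anchors) {
    grp <- which(std$assigned_delta == a)
    clean_base <- grp[!std$follows_labeled[grp]]
    for (i in grp[std$follows_labeled[grp]]) {
      others <- setdiff(if (length(clean_base)) clean_base else grp, i)
      # lone post-label standards fall back to the assigned value itself
      baseline <- if (length(others)) mean(std$measured_delta[others]) else a
      if (abs(std$measured_delta[i] - baseline) > tolerance)
        std$carryover_flag[i] <- TRUE
    }
  }
  flagged <- dplyr::filter(std, .data$carryover_flag)
  clean <- dplyr::filter(std, !.data$carryover_flag)
  anchor_tbl <- dplyr::summarise(
    dplyr::group_by(clean, assigned = .data$assigned_delta),
    measured_mean = mean(.data$measured_delta), n = dplyr::n(),
    .groups = "drop")
  if (nrow(anchor_tbl) < 2)
    stop("calibration error: fewer than 2 clean anchors remain; flagged: ",
         paste(flagged$sample_id, collapse = ", "), call. = FALSE)
  m <- anchor_tbl$measured_mean; a <- anchor_tbl$assigned
  if (abs(diff(m)) < .Machine$double.eps^0.5)
    stop("calibration error: anchor measured means coincide", call. = FALSE)
  slope <- diff(a) / diff(m)
  intercept <- a[1] - slope * m[1]

  corrected <- dplyr::left_join(
    records,
    dplyr::select(std, "run_position", "carryover_flag"),
    by = "run_position")
  corrected$carryover_flag[is.na(corrected$carryover_flag)] <- FALSE
  corrected$corrected_delta <- intercept + slope * corrected$measured_delta
  structure(list(corrected = tibble::as_tibble(corrected),
                 slope = slope, intercept = intercept,
                 anchors = anchor_tbl, flagged = flagged,
                 tolerance = tolerance),
            class = "nanosip_calibration")
}

#' @export
print.nanosip_calibration <- function(x, ...) {
  cat(sprintf("Two-point delta calibration: corrected = %.5f + %.5f * measured\n",
              x$intercept, x$slope))
  cat(sprintf("  anchors (assigned): %s; %d standard(s) flagged for carryover\n",
              paste(sprintf("%+.2f", x$anchors$assigned), collapse = ", "),
              nrow(x$flagged)))
  invisible(x)
}

#' @export
tidy.nanosip_calibration <- function(x, ...) x$corrected

#' @export
glance.nanosip_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n_standards = sum(x$corrected$kind == "standard"),
                 n_flagged = nrow(x$flagged), tolerance = x$tolerance)
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq against log10(copies) over the standard
#' dilution series (technical replicates are averaged per copy level before
#' fitting). Amplification efficiency follows from the slope as
#' `10^(-1/slope) - 1`; a perfect doubling per cycle gives slope
#' -log2(10) = -3.3219 and efficiency 1.
#'
#' @param points Tibble with columns `copies` (> 0) and `cq`.
#' @return An object of class `nanosip_stdcurve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `points` (level means used).
#' @export
fit_standard_curve <- function(points) {
  stopifnot(all(c("copies", "cq") %in% names(points)))
  if (any(points$copies <= 0))
    stop("standard copies must be positive", call. = FALSE)
  if (any(!is.finite(points$cq)))
    stop("Cq values must be finite", call. = FALSE)
  lev <- dplyr::summarise(dplyr::group_by(points, copies = .data$copies),
                          cq = mean(.data$cq), n = dplyr::n(),
                          .groups = "drop")
  if (nrow(lev) < 3)
    stop("need at least 3 distinct copy levels", call. = FALSE)
  fit <- stats::lm(cq ~ log10(copies), data = lev)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("fit error: non-negative slope; Cq should fall with template ",
         "copies (inputs inverted?)", call. = FALSE)
  r_squared <- 1 - sum(stats::residuals(fit)^2) /
    sum((lev$cq - mean(lev$cq))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r_squared,
                 points = lev),
            class = "nanosip_stdcurve")
}

#' @export
print.nanosip_stdcurve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Cq = %.4f %+.4f log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  efficiency %.1f%%, R^2 = %.5f, %d levels\n",
              100 * x$efficiency, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.nanosip_stdcurve <- function(x, ...) x$points

#' @export
glance.nanosip_stdcurve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 efficiency = x$efficiency, r_squared = x$r_squared,
                 n_levels = nrow(x$points))
}

#' Absolute quantification from a standard curve
#'
#' Inverts the fitted curve: `copies = 10^((cq - intercept) / slope)`.
#'
#' @param curve A `nanosip_stdcurve`.
#' @param cq Numeric Cq values.
#' @return Estimated template copies (always positive).
#' @export
quantify_copies <- function(curve, cq) {
  stopifnot(inherits(curve, "nanosip_stdcurve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Relative abundances and Welch tests from genome-copy counts
#'
#' Normalizes genome copies to relative abundances within each replicate
#' (columns sum to 1) and, when both conditions have at least two
#' replicates, runs Welch's unequal-variance t test per community member
#' across the two conditions.
#'
#' @param copies Tibble with columns `member`, `condition`, `replicate`,
#'   `copies`.
#' @return An object of class `nanosip_abundance`: list with `abundances`
#'   (input plus `rel_abundance`) and `tests` (tibble: `member`,
#'   `statistic_t`, `df`, `p_value`), `NULL` with a warning when either
#'   condition has a single replicate.
#' @export
relative_abundance <- function(copies) {
  need <- c("member", "condition", "replicate", "copies")
  miss <- setdiff(need, names(copies))
  if (length(miss))
    stop("copies table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(copies$copies < 0)) stop("copies must be non-negative", call. = FALSE)
  ab <- dplyr::mutate(
    dplyr::group_by(copies, .data$condition, .data$replicate),
    rel_abundance = .data$copies / sum(.data$copies))
  ab <- dplyr::ungroup(ab)
  conds <- unique(copies$condition)
  tests <- NULL
  if (length(conds) == 2) {
    n_rep <- dplyr::summarise(dplyr::group_by(ab, .data$condition),
                              n = dplyr::n_distinct(.data$replicate),
                              .groups = "drop")
    if (all(n_rep$n >= 2)) {
      tests <- dplyr::group_modify(
        dplyr::group_by(ab, member = .data$member), function(d, g) {
          x <- d$rel_abundance[d$condition == conds[1]]
          y <- d$rel_abundance[d$condition == conds[2]]
          if (stats::var(x) + stats::var(y) == 0)
            return(tibble::tibble(statistic_t = 0, df = NA_real_,
                                  p_value = 1))
          tt <- stats::t.test(x, y, var.equal = FALSE)
          tibble::tibble(statistic_t = unname(tt$statistic),
                         df = unname(tt$parameter),
                         p_value = tt$p.value)
        })
      tests <- dplyr::ungroup(tests)
    } else {
      warning("a condition has fewer than 2 replicates; Welch tests skipped")
    }
  } else if (length(conds) > 2) {
    warning("more than two conditions; Welch tests skipped")
  }
  structure(list(abundances = ab, tests = tests),
            class = "nanosip_abundance")
}

#' @export
print.nanosip_abundance <- function(x, ...) {
  cat(sprintf("Relative abundances: %d members, %d records\n",
              dplyr::n_distinct(x$abundances$member), nrow(x$abundances)))
  if (!is.null(x$tests))
    cat(sprintf("  Welch tests: %d members, %d with p < 0.01\n",
                nrow(x$tests), sum(x$tests$p_value < 0.01)))
  invisible(x)
}

#' Normalize peptide counts within organisms
#'
#' Divides each protein's peptide count by the total peptide count of the
#' organism it originates from (per sample), removing organism-abundance
#' differences from protein-level comparisons, and reports each organism's
#' share of the community-wide counts per sample.
#'
#' @param counts Tibble with columns `organism`, `protein`, `sample`,
#'   `count` (non-negative integers).
#' @return An object of class `nanosip_peptides`: list with `normalized`
#'   (input plus `fraction`, `NA` when an organism total is zero) and
#'   `organism_share` (tibble: `organism`, `sample`, `total`, `share`).
#' @export
normalize_peptides <- function(counts) {
  need <- c("organism", "protein", "sample", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(counts$count < 0) ||
      any(abs(counts$count - round(counts$count)) > 1e-9))
    stop("peptide counts must be non-negative integers", call. = FALSE)
  norm <- dplyr::mutate(
    dplyr::group_by(counts, .data$organism, .data$sample),
    .tot = sum(.data$count))
  norm <- dplyr::ungroup(norm)
  norm$fraction <- ifelse(norm$.tot > 0, norm$count / norm$.tot, NA_real_)
  norm$.tot <- NULL
  share <- dplyr::summarise(
    dplyr::group_by(counts, .data$organism, .data$sample),
    total = sum(.data$count), .groups = "drop_last")
  share <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(share, .data$sample),
    share = .data$total / sum(.data$total)))
  structure(list(normalized = norm, organism_share = share),
            class = "nanosip_peptides")
}

#' @export
print.nanosip_peptides <- function(x, ...) {
  cat(sprintf("Peptide normalization: %d organisms, %d proteins, %d samples\n",
              dplyr::n_distinct(x$normalized$organism),
              dplyr::n_distinct(x$normalized$protein),
              dplyr::n_distinct(x$normalized$sample)))
  invisible(x)
}
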