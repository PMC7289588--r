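#' Isotopic reference ratios
#'
#' Bundle of the international reference isotope ratios used to express
#' enrichment in delta notation: VPDB (Vienna Pee Dee Belemnite) for
#' \eqn{^{13}C/^{12}C} and AIR (atmospheric N2) for \eqn{^{15}N/^{14}N}.
#'
#' @param r13 Reference 13C/12C atom ratio. Default is the VPDB value.
#' @param r15 Reference 15N/14N atom ratio. Default is the AIR value.
#'
#' @return An object of class `nanosip_refs`: a list with elements `r13`,
#'   `r15` and `permil_scale` (fixed at 1000).
#' @examples
#' refs <- ref_ratios()
#' delta_from_ratio(2 * refs$r13, refs$r13) # 1000 permil
#' @export
ref_ratios <- function(r13 = 0.0112372, r15 = 0.003676) {
  stopifnot(is.numeric(r13), length(r13) == 1L, r13 > 0,
            is.numeric(r15), length(r15) == 1L, r15 > 0)
  structure(list(r13 = r13, r15 = r15, permil_scale = 1000),
            class = "nanosip_refs")
}

#' @export
print.nanosip_refs <- function(x, ...) {
  cat("Reference isotope ratios\n")
  cat(sprintf("  13C/12C (VPDB-style): %.7f\n", x$r13))
  cat(sprintf("  15N/14N (AIR-style):  %.6f\n", x$r15))
  invisible(x)
}

#' 13C/12C atom ratio from C2- isotopologue counts
#'
#' Converts counts of the two dicarbon secondary-ion isotopologues into the
#' 13C/12C atom ratio. Under random (binomial) pairing of carbon atoms with
#' atom fraction x, the expected count ratio 12C13C/12C12C is
#' \eqn{2x(1-x)/(1-x)^2 = 2x/(1-x)}, i.e. twice the atom ratio, so the
#' default correction halves the count ratio (the 13C13C isotopologue is
#' neglected; its share is second order in x). `c2_correction = "none"`
#' returns the raw count ratio instead.
#'
#' @param heavy Counts of 12C13C- (vector, matrix or array).
#' @param light Counts of 12C12C- (same shape).
#' @param c2_correction `"half"` (default, binomial-pairing correction) or
#'   `"none"` (raw count ratio).
#' @return Atom ratios with the shape of the inputs; `NA` where `light == 0`.
#' @export
ratio_from_c2_counts <- function(heavy, light, c2_correction = c("half", "none")) {
  c2_correction <- match.arg(c2_correction)
  check_counts(heavy, "heavy")
  check_counts(light, "light")
  stopifnot(length(heavy) == length(light))
  r <- ifelse(light > 0, heavy / light, NA_real_)
  if (c2_correction == "half") r <- r / 2
  keep_shape(r, heavy)
}

#' 15N/14N atom ratio from CN- isotopologue counts
#'
#' The CN- ion carries a single nitrogen atom, so the 12C15N-/12C14N- count
#' ratio estimates the 15N/14N atom ratio directly, with no pairing factor.
#'
#' @param heavy Counts of 12C15N-.
#' @param light Counts of 12C14N- (same shape).
#' @return Atom ratios; `NA` where `light == 0`.
#' @export
ratio_from_cn_counts <- function(heavy, light) {
  check_counts(heavy, "heavy")
  check_counts(light, "light")
  stopifnot(length(heavy) == length(light))
  keep_shape(ifelse(light > 0, heavy / light, NA_real_), heavy)
}

#' Delta notation from an isotope ratio
#'
#' \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000} per mil.
#'
#' @param r_sample Measured isotope ratio(s); non-negative (`NA` allowed and
#'   propagated).
#' @param r_standard Reference ratio, a single positive number.
#' @return Delta values in per mil, same shape as `r_sample`.
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  stopifnot(is.numeric(r_standard), length(r_standard) == 1L, r_standard > 0)
  if (any(r_sample < 0, na.rm = TRUE))
    stop("`r_sample` must be non-negative", call. = FALSE)
  keep_shape((r_sample / r_standard - 1) * 1000, r_sample)
}

#' Heavy-isotope atom fraction from a delta value
#'
#' Inverts delta notation to the atom fraction x = R/(1+R) with
#' R = R_standard (1 + delta/1000). Round-trips with [delta_from_ratio()]
#' to within 1e-12 relative error.
#'
#' @param delta Delta values in per mil; must be >= -1000.
#' @param r_standard Reference ratio.
#' @return Atom fractions in \[0, 1\].
#' @export
atom_fraction_from_delta <- function(delta, r_standard) {
  stopifnot(is.numeric(r_standard), length(r_standard) == 1L, r_standard > 0)
  if (any(delta < -1000, na.rm = TRUE))
    stop("delta values below -1000 permil are not physical", call. = FALSE)
  r <- r_standard * (1 + delta / 1000)
  keep_shape(r / (1 + r), delta)
}

#' Delta value implied by a heavy-isotope atom fraction
#'
#' The forward companion of [atom_fraction_from_delta()]: converts an atom
#' fraction x to R = x/(1-x) and then to per-mil delta.
#'
#' @param x Atom fractions in \[0, 1).
#' @param r_standard Reference ratio.
#' @return Delta values in per mil.
#' @export
delta_from_atom_fraction <- function(x, r_standard) {
  if (any(x < 0 | x >= 1, na.rm = TRUE))
    stop("atom fractions must lie in [0, 1)", call. = FALSE)
  delta_from_ratio(x / (1 - x), r_standard)
}

# internal ---------------------------------------------------------------

check_counts <- function(x, name) {
  if (!is.numeric(x) || any(x < 0, na.rm = TRUE) ||
      any(abs(x - round(x)) > 1e-9, na.rm = TRUE))
    stop(sprintf("`%s` must contain non-negative integer counts", name),
         call. = FALSE)
  invisible(x)
}

keep_shape <- function(out, like) {
  if (!is.null(dim(like))) dim(out) <- dim(like)
  out
}
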