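# CIECAM02 appearance model and the CAM02-UCS uniform colorspace.
# Forward and inverse paths are exact inverses of each other; the forward
# model reproduces the standard CIECAM02 worked examples (see tests).
# Used only for the perceptual-lightness edge fade in rendering.

MCAT02 <- matrix(c(0.7328, 0.4296, -0.1624,
                   -0.7036, 1.6975, 0.0061,
                   0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)
MHPE <- matrix(c(0.38971, 0.68898, -0.07868,
                 -0.22981, 1.18340, 0.04641,
                 0, 0, 1), 3, 3, byrow = TRUE)
MSRGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

# Viewing conditions: sRGB-style average surround, D65 white, dim ambient.
cam02_conditions <- function(XYZ_w = c(95.047, 100, 108.883),
                             L_A = (64 / pi) / 5, Y_b = 20,
                             surround = c(F = 1, c = 0.69, N_c = 1)) {
  F <- surround[["F"]]; c_s <- surround[["c"]]; N_c <- surround[["N_c"]]
  RGB_w <- as.vector(MCAT02 %*% XYZ_w)
  D <- pmin(pmax(F * (1 - (1 / 3.6) * exp((-L_A - 42) / 92)), 0), 1)
  Y_w <- XYZ_w[2]
  D_RGB <- D * Y_w / RGB_w + 1 - D
  k <- 1 / (5 * L_A + 1)
  F_L <- 0.2 * k^4 * (5 * L_A) + 0.1 * (1 - k^4)^2 * (5 * L_A)^(1 / 3)
  n <- Y_b / Y_w
  z <- 1.48 + sqrt(n)
  N_bb <- 0.725 * (1 / n)^0.2
  RGB_wc <- D_RGB * RGB_w
  RGBp_w <- as.vector(MHPE %*% solve(MCAT02) %*% RGB_wc)
  RGBpa_w <- cam02_adapt(RGBp_w, F_L)
  A_w <- (2 * RGBpa_w[1] + RGBpa_w[2] + RGBpa_w[3] / 20 - 0.305) * N_bb
  list(XYZ_w = XYZ_w, L_A = L_A, Y_b = Y_b, F = F, c = c_s, N_c = N_c,
       D_RGB = D_RGB, F_L = F_L, n = n, z = z, N_bb = N_bb, N_cb = N_bb,
       A_w = A_w)
}

cam02_adapt <- function(x, F_L) {
  t <- (F_L * abs(x) / 100)^0.42
  sign(x) * 400 * t / (27.13 + t) + 0.1
}

cam02_adapt_inv <- function(xa, F_L) {
  u <- xa - 0.1
  sign(u) * (100 / F_L) * (27.13 * abs(u) / (400 - abs(u)))^(1 / 0.42)
}

# XYZ rows (0-100 scale) -> matrix with columns J, C, h (h in degrees)
ciecam02_forward <- function(XYZ, vc) {
  XYZ <- matrix(XYZ, ncol = 3)
  RGB <- XYZ %*% t(MCAT02)
  RGB_c <- sweep(RGB, 2, vc$D_RGB, `*`)
  RGBp <- RGB_c %*% t(MHPE %*% solve(MCAT02))
  RGBpa <- cam02_adapt(RGBp, vc$F_L)
  a <- RGBpa[, 1] - 12 * RGBpa[, 2] / 11 + RGBpa[, 3] / 11
  b <- (RGBpa[, 1] + RGBpa[, 2] - 2 * RGBpa[, 3]) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  e_t <- (cos(h * pi / 180 + 2) + 3.8) / 4
  A <- (2 * RGBpa[, 1] + RGBpa[, 2] + RGBpa[, 3] / 20 - 0.305) * vc$N_bb
  J <- 100 * pmax(A / vc$A_w, 0)^(vc$c * vc$z)
  t_num <- (50000 / 13) * vc$N_c * vc$N_cb * e_t * sqrt(a^2 + b^2)
  t_den <- RGBpa[, 1] + RGBpa[, 2] + 21 / 20 * RGBpa[, 3]
  t <- t_num / t_den
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^vc$n)^0.73
  cbind(J = J, C = C, h = h)
}

# (J, C, h) rows -> XYZ rows (0-100)
ciecam02_inverse <- function(JCh, vc) {
  JCh <- matrix(JCh, ncol = 3)
  J <- JCh[, 1]; C <- JCh[, 2]; h <- JCh[, 3]
  t <- (C / (sqrt(pmax(J, 1e-12) / 100) * (1.64 - 0.29^vc$n)^0.73))^(1 / 0.9)
  e_t <- (cos(h * pi / 180 + 2) + 3.8) / 4
  A <- vc$A_w * (J / 100)^(1 / (vc$c * vc$z))
  p1 <- (50000 / 13) * vc$N_c * vc$N_cb * e_t / t
  p2 <- A / vc$N_bb + 0.305
  hr <- h * pi / 180
  a <- b <- numeric(length(J))
  zero_t <- !is.finite(p1) | t <= 1e-12
  sin_dom <- abs(sin(hr)) >= abs(cos(hr)) & !zero_t
  i <- sin_dom
  if (any(i)) {
    p4 <- p1[i] / sin(hr[i])
    b[i] <- p2[i] * (2 + 21 / 20) * (460 / 1403) /
      (p4 + (2 + 21 / 20) * (220 / 1403) * (cos(hr[i]) / sin(hr[i])) -
         (27 / 1403) + (21 / 20) * (6300 / 1403))
    a[i] <- b[i] * cos(hr[i]) / sin(hr[i])
  }
  i <- !sin_dom & !zero_t
  if (any(i)) {
    p5 <- p1[i] / cos(hr[i])
    a[i] <- p2[i] * (2 + 21 / 20) * (460 / 1403) /
      (p5 + (2 + 21 / 20) * (220 / 1403) -
         ((27 / 1403) - (21 / 20) * (6300 / 1403)) * (sin(hr[i]) / cos(hr[i])))
    b[i] <- a[i] * sin(hr[i]) / cos(hr[i])
  }
  RGBpa <- cbind((460 * p2 + 451 * a + 288 * b) / 1403,
                 (460 * p2 - 891 * a - 261 * b) / 1403,
                 (460 * p2 - 220 * a - 6300 * b) / 1403)
  RGBp <- cam02_adapt_inv(RGBpa, vc$F_L)
  RGB_c <- RGBp %*% t(MCAT02 %*% solve(MHPE))
  RGB <- sweep(RGB_c, 2, vc$D_RGB, `/`)
  RGB %*% t(solve(MCAT02))
}

srgb_linearize <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

srgb_delinearize <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

srgb_to_xyz100 <- function(rgb) {
  matrix(srgb_linearize(rgb), ncol = 3) %*% t(MSRGB2XYZ) * 100
}

xyz100_to_srgb <- function(xyz) {
  lin <- matrix(xyz, ncol = 3) %*% t(solve(MSRGB2XYZ)) / 100
  matrix(srgb_delinearize(pmin(pmax(lin, 0), 1)), ncol = 3)
}

#' Convert sRGB colors to CAM02-UCS coordinates
#'
#' CAM02-UCS is the uniform colorspace built on the CIECAM02 appearance
#' model: lightness J' and opponent chroma coordinates a', b'. Viewing
#' conditions are the customary sRGB set (D65 white, average surround,
#' background luminance factor 20).
#'
#' @param rgb n x 3 matrix of sRGB components in \[0, 1\].
#' @return n x 3 matrix with columns `Jp`, `ap`, `bp`.
#' @export
srgb_to_cam02ucs <- function(rgb) {
  vc <- cam02_conditions()
  JCh <- ciecam02_forward(srgb_to_xyz100(rgb), vc)
  J <- JCh[, 1]; M <- JCh[, 2] * vc$F_L^0.25; h <- JCh[, 3] * pi / 180
  Jp <- 1.7 * J / (1 + 0.007 * J)
  Mp <- log(1 + 0.0228 * M) / 0.0228
  cbind(Jp = Jp, ap = Mp * cos(h), bp = Mp * sin(h))
}

#' Convert CAM02-UCS coordinates back to sRGB
#'
#' Inverse of [srgb_to_cam02ucs()]. Out-of-gamut results are clipped to
#' \[0, 1\].
#'
#' @param ucs n x 3 matrix with columns `Jp`, `ap`, `bp`.
#' @return n x 3 matrix of sRGB components in \[0, 1\].
#' @export
cam02ucs_to_srgb <- function(ucs) {
  vc <- cam02_conditions()
  ucs <- matrix(ucs, ncol = 3)
  Jp <- ucs[, 1]
  Mp <- sqrt(ucs[, 2]^2 + ucs[, 3]^2)
  h <- (atan2(ucs[, 3], ucs[, 2]) * 180 / pi) %% 360
  J <- pmax(Jp, 0) / (1.7 - 0.007 * pmax(Jp, 0))
  M <- (exp(0.0228 * Mp) - 1) / 0.0228
  C <- M / vc$F_L^0.25
  xyz <- ciecam02_inverse(cbind(J, C, h), vc)
  pmin(pmax(xyz100_to_srgb(xyz), 0), 1)
}
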