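# Shared fixture builders; everything is generated in code at test time.

# A small, fast scene for module-level tests.
small_spec <- function(condition = "NO3_only", seed = 3, ...) {
  args <- list(height_px = 96, width_px = 96, n_planes = 8,
               n_filaments = 1, n_cocci = 8, filament_width_px = 10,
               coccus_radius_px = 4, condition = condition, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scene_spec, args)
}

# A uniform single-class stack with known isotopologue rates.
uniform_stack <- function(x13 = 0.01, x15 = 0.004, rate_c2 = 100,
                          rate_cn = 200, n_planes = 10, side = 24,
                          seed = 42) {
  set.seed(seed)
  n <- side * side
  p13 <- 2 * x13 / (1 + x13)
  counts <- array(0, c(side, side, 6, n_planes))
  for (p in seq_len(n_planes)) {
    c2 <- rpois(n, rate_c2); c13 <- rbinom(n, c2, p13)
    cn <- rpois(n, rate_cn); c15 <- rbinom(n, cn, x15)
    counts[, , 1, p] <- rpois(n, 50)
    counts[, , 2, p] <- c2 - c13
    counts[, , 3, p] <- c13
    counts[, , 4, p] <- cn - c15
    counts[, , 5, p] <- c15
    counts[, , 6, p] <- rpois(n, 5)
  }
  ion_stack(counts, NANOSIP_CHANNELS)
}

# Build a nanosip_summed object directly from channel matrices.
summed_from <- function(...) {
  chans <- list(...)
  h <- nrow(chans[[1]]); w <- ncol(chans[[1]])
  counts <- array(0, c(h, w, length(chans)))
  for (i in seq_along(chans)) counts[, , i] <- chans[[i]]
  dimnames(counts) <- list(NULL, NULL, names(chans))
  structure(list(counts = counts, channel_names = names(chans),
                 pixel_size_um = 0.15,
                 provenance = list(acquisition_tag = "fixture", planes = 1L)),
            class = "nanosip_summed")
}

# Strip threshold/method attributes from a mask for identity comparison.
unclass_bool <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# Brute-force between-class variance over candidate thresholds (independent
# of the histogram-based implementation).
brute_force_otsu <- function(x, n_candidates = 256) {
  cand <- seq(min(x), max(x), length.out = n_candidates)
  bcv <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    w1 <- length(lo) / length(x); w2 <- 1 - w1
    w1 * w2 * (mean(lo) - mean(hi))^2
  }, double(1))
  cand[which.max(bcv)]
}

# Brute-force binary opening: erosion then dilation with an explicit
# structuring-element loop (square element, matching the implementation's
# 8-connectivity convention).
brute_force_opening <- function(mask, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  h <- nrow(mask); w <- ncol(mask)
  hit_all <- function(m, r, c) {
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
      if (rr < 1 || rr > h || cc < 1 || cc > w || !m[rr, cc]) return(FALSE)
    }
    TRUE
  }
  er <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) er[r, c] <- hit_all(mask, r, c)
  di <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) {
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && er[rr, cc]) {
        di[r, c] <- TRUE
        break
      }
    }
  }
  di
}
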