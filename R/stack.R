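#' Known NanoSIMS channel names
#'
#' The six secondary-ion species detected simultaneously in the acquisition
#' this package models.
#' @export
NANOSIP_CHANNELS <- c("16O", "12C12C", "12C13C", "12C14N", "12C15N", "31P")

#' Multi-plane, multi-channel ion-count image stack
#'
#' The central raster container: an integer array of secondary-ion counts
#' indexed `[row, col, channel, plane]`, with channel names drawn from
#' [NANOSIP_CHANNELS] plus acquisition metadata. Rows are image y increasing
#' downward; indices are 1-based in R.
#'
#' @param counts 4-d array `[row, col, channel, plane]` of non-negative
#'   integer counts. A 3-d array is treated as a single plane.
#' @param channel_names Character vector naming `dim(counts)[3]` channels;
#'   must be unique and members of [NANOSIP_CHANNELS].
#' @param pixel_size_um Physical pixel edge in micrometres.
#' @param dwell_time_ms Dwell time per pixel in milliseconds.
#' @param acquisition_tag Free-text provenance tag.
#' @return An object of class `nanosip_stack`.
#' @export
ion_stack <- function(counts, channel_names, pixel_size_um = 40 / 256,
                      dwell_time_ms = 2, acquisition_tag = "") {
  if (length(dim(counts)) == 3L) dim(counts) <- c(dim(counts), 1L)
  if (length(dim(counts)) != 4L)
    stop("`counts` must be a [row, col, channel, plane] array", call. = FALSE)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    stop("ion counts must be non-negative integers", call. = FALSE)
  if (length(channel_names) != dim(counts)[3L])
    stop("`channel_names` must match the channel dimension", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique", call. = FALSE)
  unknown <- setdiff(channel_names, NANOSIP_CHANNELS)
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stopifnot(pixel_size_um > 0, dwell_time_ms > 0)
  storage.mode(counts) <- "double"   # holds exact integers < 2^53
  dimnames(counts) <- list(NULL, NULL, channel_names, NULL)
  structure(
    list(counts = counts, channel_names = channel_names,
         pixel_size_um = pixel_size_um, dwell_time_ms = dwell_time_ms,
         acquisition_tag = acquisition_tag),
    class = "nanosip_stack")
}

#' @export
print.nanosip_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Ion-count stack: %d x %d px, %d channels, %d plane(s)\n",
              d[1], d[2], d[3], d[4]))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("  pixel %.3f um, dwell %.1f ms  %s\n",
              x$pixel_size_um, x$dwell_time_ms, x$acquisition_tag))
  invisible(x)
}

#' Number of planes in a stack
#' @param stack A `nanosip_stack`.
#' @return Integer plane count.
#' @export
n_planes <- function(stack) dim(stack$counts)[4L]

#' Write an ion-count stack to multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered plane-major (plane 1 channels 1..k, plane 2 ...).
#' TIFF samples live in \[0, 1\], so counts are stored divided by the global
#' maximum count, which is recorded (with all other metadata) in a JSON
#' sidecar at `paste0(path, ".json")`. The write -> read round trip is
#' bit-identical.
#'
#' @param stack A `nanosip_stack`.
#' @param path Output TIFF path (sidecar written alongside).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "nanosip_stack"))
  d <- dim(stack$counts)
  scale <- max(1, max(stack$counts))
  pages <- vector("list", d[3L] * d[4L])
  i <- 0L
  for (p in seq_len(d[4L])) for (ch in seq_len(d[3L])) {
    i <- i + 1L
    pages[[i]] <- stack$counts[, , ch, p, drop = TRUE] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(
    format = "nanosip_stack", version = 1L,
    rows = d[1L], cols = d[2L],
    channel_names = stack$channel_names, n_planes = d[4L],
    count_scale = scale,
    pixel_size_um = stack$pixel_size_um,
    dwell_time_ms = stack$dwell_time_ms,
    acquisition_tag = stack$acquisition_tag)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ion-count stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar `paste0(path, ".json")` must exist.
#' @return A `nanosip_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$format, "nanosip_stack"))
    stop("not a nanosip stack file: ", path, call. = FALSE)
  missing_ch <- setdiff(NANOSIP_CHANNELS, meta$channel_names)
  if (length(missing_ch))
    stop("format error: stack file lacks channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  k <- length(meta$channel_names)
  if (length(pages) != k * meta$n_planes)
    stop("page count does not match metadata (ragged planes?)", call. = FALSE)
  dims <- vapply(pages, function(m) dim(m)[1:2], integer(2))
  if (any(dims[1, ] != meta$rows) || any(dims[2, ] != meta$cols))
    stop("planes have inconsistent dimensions", call. = FALSE)
  counts <- array(0, c(meta$rows, meta$cols, k, meta$n_planes))
  i <- 0L
  for (p in seq_len(meta$n_planes)) for (ch in seq_len(k)) {
    i <- i + 1L
    counts[, , ch, p] <- round(pages[[i]] * meta$count_scale)
  }
  ion_stack(counts, meta$channel_names,
            pixel_size_um = meta$pixel_size_um,
            dwell_time_ms = meta$dwell_time_ms,
            acquisition_tag = meta$acquisition_tag)
}

#' Sum an ion-count stack over planes
#'
#' The standard reduction before enrichment calculation: summing all (or a
#' contiguous range of) acquisition planes channel by channel.
#'
#' @param stack A `nanosip_stack`.
#' @param planes Integer vector of plane indices; default all planes.
#' @return An object of class `nanosip_summed`: list with `counts`
#'   (`[row, col, channel]` array), `channel_names`, and `provenance`.
#' @export
sum_planes <- function(stack, planes = NULL) {
  stopifnot(inherits(stack, "nanosip_stack"))
  np <- n_planes(stack)
  if (is.null(planes)) planes <- seq_len(np)
  if (length(planes) == 0L) stop("empty plane range", call. = FALSE)
  if (any(planes < 1L | planes > np))
    stop("plane indices out of bounds (stack has ", np, " planes)",
         call. = FALSE)
  sub <- stack$counts[, , , planes, drop = FALSE]
  counts <- colSums(aperm(sub, c(4, 1, 2, 3)), dims = 1)
  dimnames(counts) <- list(NULL, NULL, stack$channel_names)
  structure(
    list(counts = counts, channel_names = stack$channel_names,
         pixel_size_um = stack$pixel_size_um,
         provenance = list(acquisition_tag = stack$acquisition_tag,
                           planes = as.integer(planes))),
    class = "nanosip_summed")
}

#' @export
print.nanosip_summed <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Summed ion image: %d x %d px, %d channels (planes %s)\n",
              d[1], d[2], d[3],
              paste(range(x$provenance$planes), collapse = "-")))
  invisible(x)
}

#' Extract one channel of a summed image
#' @param summed A `nanosip_summed`.
#' @param name Channel name, e.g. `"12C14N"`.
#' @return A numeric matrix of counts.
#' @export
channel <- function(summed, name) {
  stopifnot(inherits(summed, "nanosip_summed"))
  if (!name %in% summed$channel_names)
    stop("summed image has no channel ", name, call. = FALSE)
  m <- summed$counts[, , name, drop = FALSE]
  dim(m) <- dim(summed$counts)[1:2]
  m
}
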