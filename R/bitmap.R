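#' Multi-channel binary mask stack
#'
#' A `mask_stack` holds up to 32 aligned binary mask planes (one per
#' anatomy/lesion channel) plus the channel registry that names them.
#' Planes for absent classes are all-zero; the stack is always stored at the
#' full fixed width of 32 planes so that the packed representation has a
#' fixed layout.
#'
#' @param planes integer/numeric array `H x W x k` (k <= 32) of 0/1 values,
#'   or `H x W x 32`. Missing trailing planes are zero-filled.
#' @param registry a [channel_registry]; defaults to [canonical_registry()].
#' @return An object of class `mask_stack` with fields `planes`
#'   (`H x W x 32` integer array) and `registry`.
#' @export
mask_stack <- function(planes, registry = canonical_registry()) {
  stopifnot(is.array(planes), length(dim(planes)) == 3L)
  d <- dim(planes)
  if (d[3] > 32L) stop("at most 32 mask planes are supported", call. = FALSE)
  storage.mode(planes) <- "integer"
  bad <- which(!(planes == 0L | planes == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-binary value in mask plane for channel %d",
                 bad[1, 3] - 1L), call. = FALSE)
  }
  full <- array(0L, dim = c(d[1], d[2], 32L))
  full[, , seq_len(d[3])] <- planes
  structure(list(planes = full, registry = registry), class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$planes)
  fg <- apply(x$planes, 3, sum)
  cat(sprintf("<mask_stack> %d x %d, %d/32 non-empty channels\n",
              d[1], d[2], sum(fg > 0)))
  invisible(x)
}

.check_stack_planes <- function(planes) {
  stopifnot(is.array(planes), length(dim(planes)) == 3L, dim(planes)[3] == 32L)
}

#' Pack a binary mask stack into a 4-channel 8-bit image
#'
#' Bit-packs the 32 binary planes of a [mask_stack] into the four 8-bit
#' channels of an RGBA image: channels 0-7 go to R, 8-15 to G, 16-23 to B and
#' 24-31 to A, with the lowest-numbered plane of each group on the least
#' significant bit. Per pixel,
#' `R = sum_{i=0..7} 2^i * mask_i`, and analogously for G, B, A.
#'
#' @param stack a [mask_stack] (or a bare `H x W x 32` binary array).
#' @return A `bitmap_png` object: list with `channels`, an `H x W x 4`
#'   integer array with values in `[0, 255]`.
#' @seealso [decode_bitmap()], [write_bitmap_png()]
#' @export
encode_bitmap <- function(stack) {
  planes <- if (inherits(stack, "mask_stack")) stack$planes else
    mask_stack(stack)$planes
  .check_stack_planes(planes)
  d <- dim(planes)
  m <- matrix(as.integer(planes), nrow = d[1] * d[2], ncol = 32L)
  pw <- as.integer(2^(0:7))
  out <- array(0L, dim = c(d[1], d[2], 4L))
  for (k in 0:3) {
    grp <- m[, (8L * k + 1L):(8L * k + 8L), drop = FALSE]
    out[, , k + 1L] <- as.integer(grp %*% pw)
  }
  structure(list(channels = out), class = "bitmap_png")
}

#' Unpack a 4-channel 8-bit image into a binary mask stack
#'
#' Inverse of [encode_bitmap()]: plane `i` is bit `i mod 8` of channel
#' `floor(i / 8)` (R, G, B, A in that order), i.e.
#' `mask_i = floor(I_{i %/% 8} / 2^(i %% 8)) mod 2`.
#'
#' @param img a `bitmap_png` (from [encode_bitmap()] or [read_bitmap_png()]),
#'   or a bare `H x W x 4` integer array with values in `[0, 255]`.
#' @param registry registry attached to the resulting stack.
#' @return A [mask_stack].
#' @export
decode_bitmap <- function(img, registry = canonical_registry()) {
  ch <- if (inherits(img, "bitmap_png")) img$channels else img
  if (!is.array(ch) || length(dim(ch)) != 3L || dim(ch)[3] != 4L) {
    stop("expected a 4-channel (RGBA) 8-bit image, got dims: ",
         paste(if (is.array(ch)) dim(ch) else length(ch), collapse = " x "),
         call. = FALSE)
  }
  storage.mode(ch) <- "integer"
  if (any(ch < 0L | ch > 255L)) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  d <- dim(ch)
  planes <- array(0L, dim = c(d[1], d[2], 32L))
  for (i in 0:31) {
    v <- ch[, , i %/% 8L + 1L]
    planes[, , i + 1L] <- bitwAnd(bitwShiftR(v, i %% 8L), 1L)
  }
  mask_stack(planes, registry = registry)
}

#' Write / read a packed mask image as an RGBA PNG file
#'
#' The packed 4-channel image is stored as a standard 8-bit RGBA PNG
#' (no interlacing, default lossless compression; the alpha channel carries
#' data and is never premultiplied). The round trip
#' `read_bitmap_png(write_bitmap_png(x))` is exact in every channel value.
#'
#' @param img a `bitmap_png`.
#' @param path file path ending in `.png`.
#' @return `write_bitmap_png` returns `path` invisibly; `read_bitmap_png`
#'   returns a `bitmap_png`.
#' @export
write_bitmap_png <- function(img, path) {
  ch <- if (inherits(img, "bitmap_png")) img$channels else img
  stopifnot(is.array(ch), length(dim(ch)) == 3L, dim(ch)[3] == 4L)
  png::writePNG(ch / 255, target = path)
  invisible(path)
}

#' @rdname write_bitmap_png
#' @export
read_bitmap_png <- function(path) {
  raw <- tryCatch(png::readPNG(path),
                  error = function(e) stop("not a readable PNG file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (!is.array(raw) || length(dim(raw)) != 3L || dim(raw)[3] != 4L) {
    ct <- if (is.matrix(raw)) "grayscale" else
      if (is.array(raw) && dim(raw)[3] == 3L) "RGB" else "unknown"
    stop("expected an RGBA PNG, detected color type: ", ct, call. = FALSE)
  }
  ch <- array(as.integer(round(raw * 255)), dim = dim(raw))
  structure(list(channels = ch), class = "bitmap_png")
}

#' Per-channel foreground pixel counts of a packed mask image
#'
#' @param x a `bitmap_png`, [mask_stack], or path to a packed PNG.
#' @param registry registry used to label channels.
#' @return data.frame with columns `channel_index`, `class_name`,
#'   `foreground_pixels` for all 32 channels (reserved channels are labelled
#'   `<reserved>`).
#' @export
inspect_bitmap <- function(x, registry = canonical_registry()) {
  stack <- if (inherits(x, "mask_stack")) x
    else if (inherits(x, "bitmap_png")) decode_bitmap(x, registry)
    else decode_bitmap(read_bitmap_png(x), registry)
  counts <- apply(stack$planes, 3, sum)
  nm <- rep("<reserved>", 32)
  nm[registry$entries$channel_index + 1L] <- registry$entries$class_name
  data.frame(channel_index = 0:31, class_name = nm,
             foreground_pixels = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Export / import per-class grayscale mask PNGs
#'
#' Each non-reserved channel is written as an 8-bit grayscale PNG with
#' foreground 255 and background 0, named `<index>_<class>.png`. The importer
#' accepts the same layout and binarises at 128.
#'
#' @param stack a [mask_stack].
#' @param dir directory to write to / read from (created if needed).
#' @param registry registry naming the files on import.
#' @return `export_mask_pngs` returns the written paths invisibly;
#'   `import_mask_pngs` returns a [mask_stack].
#' @export
export_mask_pngs <- function(stack, dir) {
  stopifnot(inherits(stack, "mask_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ent <- stack$registry$entries
  paths <- character(0)
  for (r in seq_len(nrow(ent))) {
    i <- ent$channel_index[r]
    p <- file.path(dir, sprintf("%02d_%s.png", i,
                                gsub("[^a-z0-9]+", "_", ent$class_name[r])))
    png::writePNG(stack$planes[, , i + 1L] * 1.0, target = p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname export_mask_pngs
#' @export
import_mask_pngs <- function(dir, registry = canonical_registry()) {
  files <- list.files(dir, pattern = "^[0-9]{2}_.*\\.png$", full.names = TRUE)
  if (length(files) == 0) stop("no mask PNGs found in ", dir, call. = FALSE)
  idx <- as.integer(sub("^([0-9]{2})_.*$", "\\1", basename(files)))
  first <- png::readPNG(files[1])
  h <- dim(as.matrix(first))[1]; w <- dim(as.matrix(first))[2]
  planes <- array(0L, dim = c(h, w, 32L))
  for (k in seq_along(files)) {
    m <- png::readPNG(files[k])
    if (is.array(m) && length(dim(m)) == 3L) m <- m[, , 1]
    planes[, , idx[k] + 1L] <- as.integer(m >= 0.5)
  }
  mask_stack(planes, registry = registry)
}
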