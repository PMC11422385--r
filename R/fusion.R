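#' RGB fundus image container
#'
#' @param pixels `H x W x 3` numeric/integer array with 8-bit values in
#'   `[0, 255]` (R, G, B planes).
#' @param image_id,patient_id identifier strings.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, image_id = "img", patient_id = "pat") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L)) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, image_id = as.character(image_id),
                 patient_id = as.character(patient_id)),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %s (patient %s), %d x %d\n",
              x$image_id, x$patient_id, d[1], d[2]))
  invisible(x)
}

# Default attention channel set: the anatomy and lesion classes the
# diagnosis network is steered towards.
.default_attention_classes <- c(
  "optic cup", "optic disc", "macula", "hemorrhage", "cotton wool spots",
  "preretinal fibrosis", "atrophic arc", "choroidal atrophy",
  "choroidal neovascularization", "exudation", "macular atrophy",
  "leopard/tessellated fundus"
)

#' Select the mask channels used for lesion attention
#'
#' Resolves class names to channel indices. The default set is the attention
#' list used by the diagnosis model: optic cup, optic disc, macula,
#' hemorrhage, cotton wool spots, preretinal fibrosis, atrophic arc,
#' choroidal atrophy, choroidal neovascularization, exudation, macular
#' atrophy, and leopard/tessellated fundus (12 channels under the canonical
#' registry).
#'
#' @param registry a [channel_registry].
#' @param names class names to select; `NULL` or `"default"` selects the
#'   default attention set.
#' @return Sorted integer vector of channel indices.
#' @export
select_attention_channels <- function(registry = canonical_registry(),
                                      names = NULL) {
  if (is.null(names) || identical(names, "default")) {
    names <- .default_attention_classes
  }
  lookup_channels(registry, names)
}

#' Collapse selected mask channels into a binary fusion map
#'
#' Logical OR of the selected planes, scaled to `{0, 255}`. This is the
#' fixed-weight 3x1x1 channel-fusion convolution (zero weight on the red and
#' green kernels, unit weight on blue) followed by threshold activation,
#' expressed directly as a bitwise operation.
#'
#' @param stack a [mask_stack].
#' @param channels integer vector of channel indices in `[0, 31]`.
#' @return `H x W` integer matrix with values in `{0, 255}`
#'   (a lesion fusion map).
#' @export
collapse_channels <- function(stack, channels) {
  stopifnot(inherits(stack, "mask_stack"))
  channels <- as.integer(channels)
  if (any(channels < 0L | channels > 31L)) {
    stop("channel indices must lie in [0, 31]", call. = FALSE)
  }
  d <- dim(stack$planes)
  if (length(channels) == 0) {
    return(matrix(0L, d[1], d[2]))
  }
  sel <- stack$planes[, , channels + 1L, drop = FALSE]
  any_fg <- apply(sel, c(1, 2), max)
  matrix(as.integer(any_fg) * 255L, d[1], d[2])
}

#' Threshold activation
#'
#' Binarises a single-channel 8-bit field: output is 255 where the input
#' strictly exceeds `t`, else 0.
#'
#' @param field numeric/integer matrix.
#' @param t threshold in `[0, 255]`.
#' @return Integer matrix in `{0, 255}`.
#' @export
threshold_activation <- function(field, t) {
  stopifnot(is.matrix(field))
  if (length(t) != 1 || is.na(t) || t < 0 || t > 255) {
    stop("threshold t must be a single value in [0, 255]", call. = FALSE)
  }
  matrix(as.integer(field > t) * 255L, nrow(field), ncol(field))
}

#' Compose a lesion-focused image
#'
#' Produces the classifier input: the original R and G planes are passed
#' through unchanged, while the blue plane is saturated to 255 at every
#' fusion-map pixel that lies inside the field of view (FOV). The FOV mask is
#' the threshold activation of the per-pixel maximum over R, G, B, which
#' separates the retina from the black camera background; lesion pixels
#' falling on the background are ignored. Formally, with binary
#' `L = fusion AND FOV`, the output blue plane is
#' `(B AND NOT L) OR (255 AND L)` - the reversed-map bit-and of the original
#' followed by a bit-or with the fusion map.
#'
#' @param img a [fundus_image].
#' @param fusion `H x W` fusion map in `{0, 255}` (see [collapse_channels()]).
#' @param fov_threshold 8-bit threshold separating background from retina
#'   (default 10).
#' @return A `fundus_image` whose blue plane carries the lesion attention.
#' @export
compose_lesion_focused <- function(img, fusion, fov_threshold = 10L) {
  stopifnot(inherits(img, "fundus_image"), is.matrix(fusion))
  d <- dim(img$pixels)
  if (!all(dim(fusion) == d[1:2])) {
    stop(sprintf("fusion map shape %d x %d does not match image %d x %d",
                 nrow(fusion), ncol(fusion), d[1], d[2]), call. = FALSE)
  }
  if (!all(fusion %in% c(0L, 255L))) {
    stop("fusion map must be binary in {0, 255}", call. = FALSE)
  }
  fov <- threshold_activation(pmax(img$pixels[, , 1], img$pixels[, , 2],
                                   img$pixels[, , 3]), fov_threshold)
  lesion <- fusion == 255L & fov == 255L
  out <- img$pixels
  b <- out[, , 3]
  b[lesion] <- 255L
  out[, , 3] <- b
  fundus_image(out, image_id = img$image_id, patient_id = img$patient_id)
}

#' In-memory/disk cache for lesion-focused image generation
#'
#' Creates a cache keyed by (image id, registry version, selected channel
#' set, threshold). The first call for a key invokes the producer and stores
#' the result (in memory, and as a PNG under `dir` if given); later calls
#' with an equal key return the stored image byte-identically without
#' invoking the producer. Hit/miss counters are exposed.
#'
#' @param dir optional directory for a persistent PNG-backed cache layer.
#' @return A `fusion_cache` object (an environment).
#' @export
fusion_cache <- function(dir = NULL) {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$dir <- dir
  e$hits <- 0L
  e$misses <- 0L
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  class(e) <- "fusion_cache"
  e
}

#' Build a fusion cache key
#'
#' @param image_id image identifier.
#' @param registry_version registry version string.
#' @param channels integer channel set.
#' @param threshold FOV threshold.
#' @return Single string; equal keys imply byte-identical cached outputs.
#' @export
fusion_cache_key <- function(image_id, registry_version, channels, threshold) {
  paste(image_id, registry_version,
        paste(sort(as.integer(channels)), collapse = ","),
        as.integer(threshold), sep = "|")
}

.key_digest <- function(key) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(charToRaw(key), tf)
  unname(tools::md5sum(tf))
}

#' Compute a lesion-focused image through a cache
#'
#' @param cache a [fusion_cache()].
#' @param key key string from [fusion_cache_key()].
#' @param producer zero-argument function returning a [fundus_image];
#'   must be deterministic for the key.
#' @return The cached or freshly produced `fundus_image`.
#' @export
cached_fusion <- function(cache, key, producer) {
  stopifnot(inherits(cache, "fusion_cache"), is.character(key),
            is.function(producer))
  if (exists(key, envir = cache$store, inherits = FALSE)) {
    cache$hits <- cache$hits + 1L
    return(get(key, envir = cache$store, inherits = FALSE))
  }
  if (!is.null(cache$dir)) {
    f <- file.path(cache$dir, paste0(.key_digest(key), ".png"))
    if (file.exists(f)) {
      img <- tryCatch({
        px <- png::readPNG(f)
        fundus_image(array(as.integer(round(px * 255)), dim = dim(px)),
                     image_id = key)
      }, error = function(e) {
        warning("corrupt cache entry for key '", key, "'; recomputing",
                call. = FALSE)
        NULL
      })
      if (!is.null(img)) {
        cache$hits <- cache$hits + 1L
        assign(key, img, envir = cache$store)
        return(img)
      }
    }
  }
  cache$misses <- cache$misses + 1L
  img <- producer()
  stopifnot(inherits(img, "fundus_image"))
  assign(key, img, envir = cache$store)
  if (!is.null(cache$dir)) {
    f <- file.path(cache$dir, paste0(.key_digest(key), ".png"))
    png::writePNG(img$pixels / 255, target = f)
  }
  img
}

#' Cache hit/miss statistics
#' @param cache a [fusion_cache()].
#' @return list with `hits`, `misses`, `hit_rate`.
#' @export
cache_stats <- function(cache) {
  tot <- cache$hits + cache$misses
  list(hits = cache$hits, misses = cache$misses,
       hit_rate = if (tot == 0) NA_real_ else cache$hits / tot)
}

#' Lesion-focused image for one fundus image and mask stack
#'
#' Convenience wrapper: collapse the selected channels of `stack` and
#' composite them onto `img`, optionally through a cache.
#'
#' @inheritParams compose_lesion_focused
#' @param stack a [mask_stack] aligned with `img`.
#' @param channels channel index set (default: attention set).
#' @param cache optional [fusion_cache()].
#' @return A `fundus_image`.
#' @export
lesion_focused_image <- function(img, stack,
                                 channels = select_attention_channels(
                                   stack$registry),
                                 fov_threshold = 10L, cache = NULL) {
  producer <- function() {
    fusion <- collapse_channels(stack, channels)
    compose_lesion_focused(img, fusion, fov_threshold)
  }
  if (is.null(cache)) return(producer())
  key <- fusion_cache_key(img$image_id, stack$registry$version, channels,
                          fov_threshold)
  cached_fusion(cache, key, producer)
}
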