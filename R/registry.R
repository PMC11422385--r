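#' Channel registry for lesion-mask channels
#'
#' A channel registry maps anatomy/lesion class names to bit-plane indices of
#' the packed BITMAP format. Indices must be unique and lie in `0..31`; with
#' the canonical 20-class registry, indices 20-31 are reserved and always
#' decode to all-zero planes.
#'
#' @param entries data.frame with columns `class_name` (character) and
#'   `channel_index` (integer in `[0, 31]`).
#' @param version single string identifying the registry revision.
#' @return An object of class `channel_registry`.
#' @seealso [canonical_registry()]
#' @export
channel_registry <- function(entries, version = "custom-1") {
  stopifnot(is.data.frame(entries),
            all(c("class_name", "channel_index") %in% names(entries)))
  nm <- as.character(entries$class_name)
  idx <- as.integer(entries$channel_index)
  if (any(!nzchar(nm)) || anyNA(nm)) {
    stop("registry class names must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("registry class names must be unique: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(idx) || any(idx < 0L | idx > 31L)) {
    stop("channel indices must be integers in [0, 31]", call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("channel indices must be unique", call. = FALSE)
  }
  structure(
    list(entries = data.frame(class_name = nm, channel_index = idx,
                              stringsAsFactors = FALSE),
         version = as.character(version)[1]),
    class = "channel_registry"
  )
}

# Canonical class order of the packaged segmentation report (one row per
# anatomy/lesion class); index = row position - 1.
.canonical_classes <- c(
  "optic cup",                         # 0
  "optic disc",                        # 1
  "retinal vessel",                    # 2
  "macula",                            # 3
  "hemorrhage",                        # 4
  "cotton wool spots",                 # 5
  "drusen",                            # 6
  "atrophic arc",                      # 7
  "choroidal atrophy",                 # 8
  "choroidal neovascularization",      # 9
  "exudation",                         # 10
  "macular degeneration",              # 11
  "geographic atrophy",                # 12
  "retinal nerve fiber layer defects", # 13
  "retinal defect",                    # 14
  "sclera exposure",                   # 15
  "tessellation",                      # 16
  "retinal neovascularization",        # 17
  "vitreous hemorrhage",               # 18
  "retinal detachment"                 # 19
)

# Alternate spellings used across the clinical literature for the same
# channel; lookups accept any of them. "preretinal fibrosis" is filed under
# retinal neovascularization (fibrovascular proliferation) and "macular
# atrophy" under macular degeneration, the closest canonical classes.
.class_aliases <- c(
  "optic disk"            = "optic disc",
  "disk"                  = "optic disc",
  "cup"                   = "optic cup",
  "macular"               = "macula",
  "vessel"                = "retinal vessel",
  "cotton-wool spot"      = "cotton wool spots",
  "cotton wool spot"      = "cotton wool spots",
  "exudates"              = "exudation",
  "atrophy arc"           = "atrophic arc",
  "atrophic crescent"     = "atrophic arc",
  "leopard fundus"        = "tessellation",
  "tessellated fundus"    = "tessellation",
  "tessellated retina"    = "tessellation",
  "leopard/tessellated fundus" = "tessellation",
  "scleral show"          = "sclera exposure",
  "neovessels elsewhere"  = "retinal neovascularization",
  "preretinal fibrosis"   = "retinal neovascularization",
  "macular atrophy"       = "macular degeneration",
  "rnfl defects"          = "retinal nerve fiber layer defects",
  "geogrraphic atrophy"   = "geographic atrophy"
)

#' Canonical 20-class channel registry
#'
#' The fixed registry used throughout the package: 20 anatomy/lesion classes
#' at channel indices 0-19 (optic cup = 0 ... retinal detachment = 19);
#' indices 20-31 are reserved and always decode to all-zero planes.
#'
#' @return A `channel_registry`.
#' @examples
#' reg <- canonical_registry()
#' lookup_channels(reg, "optic cup")
#' @export
canonical_registry <- function() {
  channel_registry(
    data.frame(class_name = .canonical_classes,
               channel_index = seq_along(.canonical_classes) - 1L,
               stringsAsFactors = FALSE),
    version = "canonical-20/1"
  )
}

.normalize_class_name <- function(x) {
  x <- tolower(trimws(x))
  hit <- match(x, names(.class_aliases))
  x[!is.na(hit)] <- .class_aliases[hit[!is.na(hit)]]
  x
}

#' Look up channel indices for class names
#'
#' Resolves class names (including documented alternate spellings such as
#' "optic disk" or "tessellated retina") to channel indices.
#'
#' @param registry a `channel_registry`.
#' @param names character vector of class names.
#' @return Integer vector of channel indices (unique, sorted; possibly empty).
#' @export
lookup_channels <- function(registry, names) {
  stopifnot(inherits(registry, "channel_registry"))
  if (length(names) == 0) return(integer(0))
  key <- .normalize_class_name(names)
  tab_key <- .normalize_class_name(registry$entries$class_name)
  hit <- match(key, tab_key)
  if (anyNA(hit)) {
    bad <- names[is.na(hit)]
    stop("unknown class name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(registry$entries$class_name, collapse = ", "),
         call. = FALSE)
  }
  sort(unique(registry$entries$channel_index[hit]))
}

#' @export
print.channel_registry <- function(x, ...) {
  cat("<channel_registry> version", x$version, "with",
      nrow(x$entries), "classes\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}
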