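# Synthetic fundus-like image generator: a circular field of view on a black
# background, a bright optic disc containing a brighter cup, a darker macula,
# dark branching vessels radiating from the disc, and class-specific lesion
# blobs rendered both into the image and into the matching registry mask
# channels. Purely array arithmetic; all randomness comes from the R RNG
# seeded explicitly.

#' Configuration for the synthetic fundus generator
#'
#' @param size image side in pixels (square), default 256.
#' @param seed RNG seed.
#' @param fov_radius_frac field-of-view radius as a fraction of `size/2`.
#' @param disc_center disc center as fractions of size `c(row, col)`.
#' @param disc_radii disc ellipse radii as fractions of size.
#' @param cup_to_disc_ratio cup radius / disc radius, in `[0, 1)`.
#' @param macula_center,macula_radius macula geometry (fractions of size).
#' @param n_vessels number of vessel walks from the disc rim.
#' @param vessel_tortuosity angular noise of the vessel random walk (radians
#'   per step).
#' @param noise_sd additive Gaussian pixel noise on the 8-bit scale.
#' @return Object of class `synth_fundus_config`.
#' @export
synth_fundus_config <- function(size = 256L, seed = 1L,
                                fov_radius_frac = 0.96,
                                disc_center = c(0.50, 0.68),
                                disc_radii = c(0.085, 0.075),
                                cup_to_disc_ratio = 0.4,
                                macula_center = c(0.52, 0.36),
                                macula_radius = 0.06,
                                n_vessels = 8L,
                                vessel_tortuosity = 0.25,
                                noise_sd = 3) {
  cfg <- list(size = as.integer(size), seed = as.integer(seed),
              fov_radius_frac = fov_radius_frac,
              disc_center = disc_center, disc_radii = disc_radii,
              cup_to_disc_ratio = cup_to_disc_ratio,
              macula_center = macula_center, macula_radius = macula_radius,
              n_vessels = as.integer(n_vessels),
              vessel_tortuosity = vessel_tortuosity, noise_sd = noise_sd)
  if (cup_to_disc_ratio < 0 || cup_to_disc_ratio >= 1) {
    stop("cup_to_disc_ratio must lie in [0, 1)", call. = FALSE)
  }
  fov_r <- fov_radius_frac * size / 2
  ctr <- size / 2
  for (pt in list(c(disc_center, max(disc_radii)),
                  c(macula_center, macula_radius))) {
    d <- sqrt(sum((pt[1:2] * size - ctr)^2)) + pt[3] * size
    if (d > fov_r) {
      stop("configured geometry falls outside the field of view",
           call. = FALSE)
    }
  }
  structure(cfg, class = "synth_fundus_config")
}

.ellipse_mask <- function(size, cy, cx, ry, rx) {
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
}

.stamp_disk <- function(mask, cy, cx, r) {
  size <- nrow(mask)
  y0 <- max(1L, floor(cy - r)); y1 <- min(size, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(size, ceiling(cx + r))
  if (y0 > y1 || x0 > x1) return(mask)
  yy <- y0:y1; xx <- x0:x1
  sub <- outer((yy - cy)^2, (xx - cx)^2, "+") <= r^2
  mask[yy, xx] <- mask[yy, xx] | sub
  mask
}

.paint <- function(px, where, color, alpha = 1) {
  for (c in 1:3) {
    plane <- px[, , c]
    plane[where] <- (1 - alpha) * plane[where] + alpha * color[c]
    px[, , c] <- plane
  }
  px
}

#' Generate one synthetic fundus image with anatomy masks
#'
#' Renders the field-of-view disk on a black background, the optic disc with
#' its inner cup, the macula, and branching vessels walking out from the
#' disc rim; fills the anatomy mask channels (optic cup, optic disc, retinal
#' vessel, macula) accordingly. Deterministic for a given config seed.
#'
#' @param config a [synth_fundus_config()].
#' @param image_id,patient_id identifiers stored on the image.
#' @return Object of class `synthetic_fundus`: list with `image`
#'   ([fundus_image]), `masks` ([mask_stack]), `geom` (resolved pixel
#'   geometry) and `config`.
#' @export
generate_fundus <- function(config = synth_fundus_config(),
                            image_id = "synth", patient_id = "p0") {
  set.seed(config$seed)
  S <- config$size
  ctr <- (S + 1) / 2
  fov_r <- config$fov_radius_frac * S / 2
  row <- matrix(seq_len(S), S, S)
  col <- matrix(seq_len(S), S, S, byrow = TRUE)
  fov <- (row - ctr)^2 + (col - ctr)^2 <= fov_r^2

  geom <- list(
    fov_center = c(ctr, ctr), fov_radius = fov_r,
    disc_center = config$disc_center * S,
    disc_radii = config$disc_radii * S,
    cup_radii = config$disc_radii * S * config$cup_to_disc_ratio,
    macula_center = config$macula_center * S,
    macula_radius = config$macula_radius * S
  )

  px <- array(0, dim = c(S, S, 3))
  grad <- 1 - 0.25 * sqrt((row - ctr)^2 + (col - ctr)^2) / fov_r
  base <- list(r = 185, g = 95, b = 45)
  px[, , 1][fov] <- (base$r * grad)[fov]
  px[, , 2][fov] <- (base$g * grad)[fov]
  px[, , 3][fov] <- (base$b * grad)[fov]

  macula <- .ellipse_mask(S, geom$macula_center[1], geom$macula_center[2],
                          geom$macula_radius, geom$macula_radius) & fov
  px <- .paint(px, macula, c(130, 55, 30))

  # vessels: random walks leaving the disc rim
  vessel <- matrix(FALSE, S, S)
  dc <- geom$disc_center
  for (v in seq_len(config$n_vessels)) {
    ang <- stats::runif(1, 0, 2 * pi)
    pos <- dc + 0.95 * c(sin(ang) * geom$disc_radii[1],
                         cos(ang) * geom$disc_radii[2])
    dir <- ang + stats::rnorm(1, 0, 0.3)
    n_steps <- round(stats::runif(1, 0.45, 0.75) * S / 2)
    thick <- stats::runif(1, 1.3, 2.2)
    branch_at <- if (stats::runif(1) < 0.6) sample(10:n_steps, 1) else NA
    walk <- function(pos, dir, steps, thick) {
      for (s in seq_len(steps)) {
        dir <- dir + stats::rnorm(1, 0, config$vessel_tortuosity)
        pos <- pos + 2 * c(sin(dir), cos(dir))
        if (sum((pos - c(ctr, ctr))^2) > (0.97 * fov_r)^2) break
        vessel <<- .stamp_disk(vessel, pos[1], pos[2],
                               max(0.8, thick * (1 - s / (1.4 * steps))))
      }
      list(pos = pos, dir = dir, step = s)
    }
    st <- walk(pos, dir, if (is.na(branch_at)) n_steps else branch_at, thick)
    if (!is.na(branch_at)) {
      walk(st$pos, st$dir + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9),
           n_steps - branch_at, thick * 0.7)
      walk(st$pos, st$dir, n_steps - branch_at, thick * 0.8)
    }
  }
  vessel <- vessel & fov
  px <- .paint(px, vessel, c(105, 35, 30))

  disc <- .ellipse_mask(S, dc[1], dc[2], geom$disc_radii[1],
                        geom$disc_radii[2]) & fov
  px <- .paint(px, disc, c(225, 160, 95))
  cup <- matrix(FALSE, S, S)
  if (config$cup_to_disc_ratio > 0) {
    cup <- .ellipse_mask(S, dc[1], dc[2], geom$cup_radii[1],
                         geom$cup_radii[2]) & fov
    px <- .paint(px, cup, c(255, 240, 185))
  }

  if (config$noise_sd > 0) {
    nz <- array(stats::rnorm(S * S * 3, 0, config$noise_sd), dim = dim(px))
    for (c in 1:3) px[, , c][fov] <- px[, , c][fov] + nz[, , c][fov]
  }
  px <- pmin(pmax(round(px), 0), 255)
  storage.mode(px) <- "integer"

  planes <- array(0L, dim = c(S, S, 32L))
  planes[, , 1] <- cup * 1L      # optic cup
  planes[, , 2] <- disc * 1L     # optic disc
  planes[, , 3] <- vessel * 1L   # retinal vessel
  planes[, , 4] <- macula * 1L   # macula

  structure(list(image = fundus_image(px, image_id, patient_id),
                 masks = mask_stack(planes),
                 geom = geom, config = config),
            class = "synthetic_fundus")
}

.lesion_channel <- function(name) {
  lookup_channels(canonical_registry(), name)
}

.rand_point_near <- function(center, max_r, fov_center, fov_r) {
  repeat {
    ang <- stats::runif(1, 0, 2 * pi)
    rr <- sqrt(stats::runif(1)) * max_r
    p <- center + rr * c(sin(ang), cos(ang))
    if (sum((p - fov_center)^2) < (0.92 * fov_r)^2) return(p)
  }
}

.add_blobs <- function(fd, n, r_range, color, channel, center, max_r,
                       render) {
  S <- fd$config$size
  plane <- fd$masks$planes[, , channel + 1L]
  for (k in seq_len(n)) {
    p <- .rand_point_near(center, max_r, fd$geom$fov_center,
                          fd$geom$fov_radius)
    r <- stats::runif(1, r_range[1], r_range[2])
    blob <- .stamp_disk(matrix(FALSE, S, S), p[1], p[2], r)
    plane[blob] <- 1L
    if (render) {
      px <- fd$image$pixels * 1.0
      px <- .paint(px, blob, color)
      px <- pmin(pmax(round(px), 0), 255)
      storage.mode(px) <- "integer"
      fd$image$pixels <- px
    }
  }
  fd$masks$planes[, , channel + 1L] <- plane
  fd
}

.add_flames <- function(fd, n, sector, len_range, color, channel, render) {
  # elongated hemorrhage streaks radiating from the disc within a sector
  S <- fd$config$size
  plane <- fd$masks$planes[, , channel + 1L]
  dc <- fd$geom$disc_center
  strk <- matrix(FALSE, S, S)
  for (k in seq_len(n)) {
    ang <- stats::runif(1, sector[1], sector[2])
    start <- stats::runif(1, 1.2, 2.5) * max(fd$geom$disc_radii)
    len <- stats::runif(1, len_range[1], len_range[2])
    for (s in seq(0, len, by = 1.5)) {
      p <- dc + (start + s) * c(sin(ang), cos(ang))
      if (sum((p - fd$geom$fov_center)^2) > (0.92 * fd$geom$fov_radius)^2)
        break
      strk <- .stamp_disk(strk, p[1], p[2], 1.8 * S / 256)
    }
  }
  plane[strk] <- 1L
  fd$masks$planes[, , channel + 1L] <- plane
  if (render) {
    px <- fd$image$pixels * 1.0
    px <- .paint(px, strk, color)
    px <- pmin(pmax(round(px), 0), 255)
    storage.mode(px) <- "integer"
    fd$image$pixels <- px
  }
  fd
}

#' Add a disease signature to a synthetic fundus
#'
#' Renders class-specific lesions into the image and the matching registry
#' mask channels. Signatures: GLAU enlarges the optic cup to a cup-to-disc
#' ratio >= 0.8; AMD places drusen/exudate blobs within one disc diameter of
#' the macula center; RVO draws sectoral flame hemorrhages along a vessel
#' sector; DR scatters microaneurysm dots and hemorrhage blobs, with
#' neovessel curls and exudates added at the late grade; NORM adds nothing.
#' `grade` controls lesion burden monotonically (late >= early in lesion
#' pixels).
#'
#' @param fd a `synthetic_fundus` from [generate_fundus()].
#' @param disease one of `"GLAU"`, `"AMD"`, `"RVO"`, `"DR"`, `"NORM"`.
#' @param grade `"early"` or `"late"` (ignored for NORM).
#' @param render if `FALSE`, lesions are written into the mask channels only
#'   and the rendered image is left untouched (so the class signal lives
#'   exclusively in the mask channels).
#' @param seed optional RNG seed; default continues the current RNG stream.
#' @return The modified `synthetic_fundus`.
#' @export
add_disease_signature <- function(fd, disease, grade = "early",
                                  render = TRUE, seed = NULL) {
  stopifnot(inherits(fd, "synthetic_fundus"))
  if (!disease %in% c("GLAU", "AMD", "RVO", "DR", "NORM")) {
    stop("unknown disease: ", disease, call. = FALSE)
  }
  if (!grade %in% c("early", "late")) {
    stop("grade must be 'early' or 'late'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (disease == "NORM") return(fd)
  S <- fd$config$size
  late <- grade == "late"
  dark_red <- c(110, 28, 22)
  yellow <- c(238, 212, 120)
  white <- c(240, 238, 225)

  if (disease == "GLAU") {
    cdr <- if (late) 0.92 else 0.82
    cup <- .ellipse_mask(S, fd$geom$disc_center[1], fd$geom$disc_center[2],
                         fd$geom$disc_radii[1] * cdr,
                         fd$geom$disc_radii[2] * cdr)
    cup <- cup & (fd$masks$planes[, , 2] == 1L)
    fd$masks$planes[, , 1] <- cup * 1L
    fd$geom$cup_radii <- fd$geom$disc_radii * cdr
    if (render) {
      px <- .paint(fd$image$pixels * 1.0, cup, c(255, 240, 185))
      px <- pmin(pmax(round(px), 0), 255)
      storage.mode(px) <- "integer"
      fd$image$pixels <- px
    }
  } else if (disease == "AMD") {
    disc_diam <- 2 * max(fd$geom$disc_radii)
    mc <- fd$geom$macula_center
    fd <- .add_blobs(fd, if (late) 14 else 6, c(2.5, 5) * S / 256, yellow,
                     .lesion_channel("drusen"), mc, 0.4 * disc_diam, render)
    fd <- .add_blobs(fd, if (late) 8 else 4, c(3, 6) * S / 256, yellow,
                     .lesion_channel("exudation"), mc, 0.45 * disc_diam,
                     render)
    if (late) {
      fd <- .add_blobs(fd, 3, c(5, 8) * S / 256, c(150, 120, 90),
                       .lesion_channel("macular degeneration"), mc,
                       0.3 * disc_diam, render)
    }
  } else if (disease == "RVO") {
    base_ang <- stats::runif(1, 0, 2 * pi)
    half <- if (late) 1.1 else 0.55
    fd <- .add_flames(fd, if (late) 28 else 18,
                      c(base_ang - half, base_ang + half),
                      c(0.12, 0.30) * S, dark_red,
                      .lesion_channel("hemorrhage"), render)
    if (late) {
      fd <- .add_blobs(fd, 5, c(3, 6) * S / 256, white,
                       .lesion_channel("cotton wool spots"),
                       fd$geom$fov_center, 0.55 * fd$geom$fov_radius, render)
    }
  } else if (disease == "DR") {
    ctr <- fd$geom$fov_center
    fd <- .add_blobs(fd, if (late) 34 else 14, c(1.2, 2.4) * S / 256,
                     dark_red, .lesion_channel("hemorrhage"), ctr,
                     0.75 * fd$geom$fov_radius, render)
    fd <- .add_blobs(fd, if (late) 10 else 4, c(2.5, 5) * S / 256,
                     dark_red, .lesion_channel("hemorrhage"), ctr,
                     0.7 * fd$geom$fov_radius, render)
    if (late) {
      fd <- .add_blobs(fd, 8, c(2, 4) * S / 256, yellow,
                       .lesion_channel("exudation"), ctr,
                       0.6 * fd$geom$fov_radius, render)
      fd <- .add_flames(fd, 8, c(0, 2 * pi), c(0.03, 0.08) * S,
                        c(140, 40, 40),
                        .lesion_channel("retinal neovascularization"), render)
    }
  }
  fd
}

#' Total lesion foreground pixels of a synthetic fundus
#'
#' Counts foreground pixels over the lesion channels (everything except the
#' four anatomy channels) plus the cup channel, which disease signatures may
#' enlarge.
#'
#' @param fd a `synthetic_fundus`.
#' @return Integer pixel count.
#' @export
lesion_pixel_count <- function(fd) {
  sum(fd$masks$planes[, , -(2:4)])
}

#' Generate a patient-structured synthetic cohort
#'
#' Assigns each patient a disease (multinomial draw from `mix`) and a grade
#' (uniform early/late for diseased patients), then renders
#' `images_per_patient` fundus images per patient with per-image geometry
#' jitter. All of a patient's images share the disease label. Reproducible
#' per seed.
#'
#' @param n_patients number of patients.
#' @param mix named numeric vector of class proportions over
#'   GLAU/AMD/RVO/DR/NORM (must sum to 1).
#' @param images_per_patient images rendered per patient.
#' @param seed RNG seed.
#' @param size image side in pixels.
#' @param render_lesions if `FALSE`, disease signatures are written into the
#'   mask channels only (no class signal in the rendered image).
#' @return Object of class `synthetic_cohort`: list with `manifest`
#'   (data.frame: image_id, patient_id, disease, grade) and `images`
#'   (named list of `synthetic_fundus`).
#' @export
generate_cohort <- function(n_patients, mix = c(GLAU = 0.2, AMD = 0.2,
                                                RVO = 0.2, DR = 0.2,
                                                NORM = 0.2),
                            images_per_patient = 1L, seed = 1L, size = 256L,
                            render_lesions = TRUE) {
  if (abs(sum(mix) - 1) > 1e-8) stop("class mix must sum to 1",
                                     call. = FALSE)
  classes <- names(mix)[mix > 0]
  if (n_patients < length(classes)) {
    stop("n_patients (", n_patients, ") is smaller than the number of ",
         "requested classes (", length(classes), ")", call. = FALSE)
  }
  set.seed(seed)
  diseases <- sample(names(mix), n_patients, replace = TRUE, prob = mix)
  grades <- ifelse(diseases == "NORM", "early",
                   sample(c("early", "late"), n_patients, replace = TRUE))
  manifest <- NULL
  images <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    for (im in seq_len(images_per_patient)) {
      iid <- sprintf("%s_I%02d", pid, im)
      sub_seed <- sample.int(.Machine$integer.max %/% 2, 1)
      cfg <- synth_fundus_config(
        size = size, seed = sub_seed,
        disc_center = c(0.50, 0.68) + stats::runif(2, -0.02, 0.02),
        disc_radii = c(0.085, 0.075) * stats::runif(1, 0.95, 1.05),
        cup_to_disc_ratio = stats::runif(1, 0.30, 0.45),
        macula_center = c(0.52, 0.36) + stats::runif(2, -0.02, 0.02),
        n_vessels = sample(6:9, 1)
      )
      fd <- generate_fundus(cfg, image_id = iid, patient_id = pid)
      fd <- add_disease_signature(fd, diseases[p], grades[p],
                                  render = render_lesions)
      images[[iid]] <- fd
      manifest <- rbind(manifest,
                        data.frame(image_id = iid, patient_id = pid,
                                   disease = diseases[p], grade = grades[p],
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(manifest = manifest, images = images, seed = seed,
                 render_lesions = render_lesions),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d images, %d patients\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id))))
  print(table(x$manifest$disease))
  invisible(x)
}

#' Patient-disjoint train/validation/test split
#'
#' Randomly partitions patients into three sets with a 7:1:2 patient-count
#' ratio (within one patient of the exact proportions; 10 patients split
#' exactly 7/1/2). No patient appears in two sets.
#'
#' @param patient_ids character vector, one entry per sample.
#' @param ratios length-3 numeric ratio (default `c(7, 1, 2)`).
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_indices_by_patient <- function(patient_ids, ratios = c(7, 1, 2),
                                     seed = 1L) {
  pats <- unique(patient_ids)
  if (length(pats) < 10) stop("need at least 10 patients", call. = FALSE)
  set.seed(seed)
  pats <- sample(pats)
  n <- length(pats)
  exact <- n * ratios / sum(ratios)
  counts <- floor(exact)
  rem <- exact - counts
  for (k in order(rem, decreasing = TRUE)[seq_len(n - sum(counts))]) {
    counts[k] <- counts[k] + 1
  }
  counts <- pmax(counts, 1)
  while (sum(counts) > n) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1
  sets <- list(train = pats[seq_len(counts[1])],
               val = pats[counts[1] + seq_len(counts[2])],
               test = pats[counts[1] + counts[2] + seq_len(counts[3])])
  lapply(sets, function(s) which(patient_ids %in% s))
}

#' Split a cohort into train/validation/test manifests by patient
#'
#' @param cohort a `synthetic_cohort` (or its manifest data.frame).
#' @param ratios,seed see [split_indices_by_patient()].
#' @return list of three manifest data.frames (`train`, `val`, `test`), each
#'   a subset of the cohort manifest with a `split` column added.
#' @export
split_by_patient <- function(cohort, ratios = c(7, 1, 2), seed = 1L) {
  man <- if (inherits(cohort, "synthetic_cohort")) cohort$manifest else cohort
  ix <- split_indices_by_patient(man$patient_id, ratios, seed)
  out <- lapply(names(ix), function(nm) {
    m <- man[ix[[nm]], , drop = FALSE]
    m$split <- nm
    m
  })
  names(out) <- names(ix)
  out
}

#' Write a cohort to disk
#'
#' Images as PNG, masks as packed BITMAP PNG, and a manifest CSV.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  man$image_path <- file.path(dir, paste0(man$image_id, ".png"))
  man$bitmap_path <- file.path(dir, paste0(man$image_id, "_masks.png"))
  for (r in seq_len(nrow(man))) {
    fd <- cohort$images[[man$image_id[r]]]
    png::writePNG(fd$image$pixels / 255, target = man$image_path[r])
    write_bitmap_png(encode_bitmap(fd$masks), man$bitmap_path[r])
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}
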