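test_that("generation is deterministic per seed and respects geometry", {
  cfg <- synth_fundus_config(size = 96, seed = 12)
  a <- generate_fundus(cfg)
  b <- generate_fundus(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$masks$planes, b$masks$planes)

  # zero cup-to-disc ratio leaves the cup channel empty
  c0 <- generate_fundus(synth_fundus_config(size = 96, seed = 3,
                                            cup_to_disc_ratio = 0))
  expect_equal(sum(c0$masks$planes[, , 1]), 0)

  # geometry outside the field of view is rejected
  expect_error(synth_fundus_config(disc_center = c(0.5, 0.98)),
               "field of view")
  expect_error(synth_fundus_config(cup_to_disc_ratio = 1.2), "\\[0, 1\\)")
})

test_that("rendered disc is self-consistent with its mask", {
  fd <- generate_fundus(synth_fundus_config(size = 128, seed = 9))
  bright <- (fd$image$pixels[, , 1] > 205) * 1L
  expect_gte(compute_iou(bright, fd$masks$planes[, , 2]), 0.9)
  # black background outside the FOV
  corner <- fd$image$pixels[1:3, 1:3, ]
  expect_true(all(corner == 0L))
})

test_that("disease signatures fill the expected channels monotonically", {
  base <- generate_fundus(synth_fundus_config(size = 128, seed = 21))
  norm <- add_disease_signature(base, "NORM", "early")
  expect_equal(sum(norm$masks$planes[, , 5:32]), 0)

  early <- add_disease_signature(base, "DR", "early", seed = 8)
  late <- add_disease_signature(base, "DR", "late", seed = 8)
  expect_gt(lesion_pixel_count(late), lesion_pixel_count(early))

  gl <- add_disease_signature(base, "GLAU", "early", seed = 1)
  cup_frac <- sum(gl$masks$planes[, , 1]) / sum(gl$masks$planes[, , 2])
  expect_gte(cup_frac, 0.8^2 * 0.9)   # area ratio of a cdr >= 0.8 cup

  amd <- add_disease_signature(base, "AMD", "late", seed = 5)
  lesions <- amd$masks$planes[, , 7] | amd$masks$planes[, , 11]
  cent <- colMeans(which(lesions == 1, arr.ind = TRUE))
  dd <- 2 * max(amd$geom$disc_radii)
  expect_lt(sqrt(sum((cent - amd$geom$macula_center)^2)), dd)

  expect_error(add_disease_signature(base, "XYZ"), "unknown disease")
  expect_error(add_disease_signature(base, "DR", "severe"), "early")
})

test_that("cohorts are patient-labelled, reproducible and well mixed", {
  all_norm <- generate_cohort(5, mix = c(NORM = 1), seed = 2, size = 64)
  expect_true(all(vapply(all_norm$images, function(f) {
    sum(f$masks$planes[, , 5:32]) == 0
  }, logical(1))))

  expect_error(generate_cohort(3, seed = 1, size = 64), "smaller than")

  c1 <- generate_cohort(12, images_per_patient = 2, seed = 5, size = 64)
  c2 <- generate_cohort(12, images_per_patient = 2, seed = 5, size = 64)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$images[[3]]$image$pixels, c2$images[[3]]$image$pixels)
  # every patient's images share one label
  tab <- table(c1$manifest$patient_id, c1$manifest$disease)
  expect_true(all(rowSums(tab > 0) == 1))

  # class counts of a uniform mix stay inside multinomial 99% bounds
  big <- generate_cohort(100, seed = 31, size = 64)
  counts <- table(factor(big$manifest$disease,
                         levels = c("GLAU", "AMD", "RVO", "DR", "NORM")))
  expect_true(all(counts >= qbinom(0.005, 100, 0.2) &
                  counts <= qbinom(0.995, 100, 0.2)))
})

test_that("patient splits hit the 7:1:2 shape with zero leakage", {
  pids <- paste0("p", 1:10)
  ix <- split_indices_by_patient(pids, seed = 1)
  expect_equal(lengths(ix), c(train = 7L, val = 1L, test = 2L))

  expect_error(split_indices_by_patient(paste0("p", 1:5)), "at least 10")

  pids2 <- rep(paste0("q", 1:50), each = 3)
  ix2 <- split_indices_by_patient(pids2, seed = 3)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_length(intersect(pids2[ix2[[pair[1]]]], pids2[ix2[[pair[2]]]]), 0)
  }

  pids3 <- paste0("r", 1:1000)
  ix3 <- split_indices_by_patient(pids3, seed = 7)
  props <- lengths(ix3) / 1000
  expect_true(all(abs(props - c(0.7, 0.1, 0.2)) <= 0.01))

  coh <- generate_cohort(12, images_per_patient = 2, seed = 5, size = 64)
  mans <- split_by_patient(coh, seed = 2)
  expect_named(mans, c("train", "val", "test"))
  expect_equal(sum(vapply(mans, nrow, integer(1))), nrow(coh$manifest))
  expect_equal(unique(mans$train$split), "train")
})

test_that("cohort masks survive pack -> PNG -> unpack bit-exactly", {
  coh <- generate_cohort(10, seed = 13, size = 64)
  dir <- withr::local_tempdir()
  man_path <- write_cohort(coh, dir)
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  expect_equal(nrow(man), 10)
  for (r in seq_len(nrow(man))) {
    st <- decode_bitmap(read_bitmap_png(man$bitmap_path[r]))
    expect_identical(st$planes, coh$images[[man$image_id[r]]]$masks$planes)
  }
})

test_that("fusion only touches pixels inside rendered lesion regions", {
  fd <- generate_fundus(synth_fundus_config(size = 128, seed = 17))
  fd <- add_disease_signature(fd, "AMD", "late", seed = 2)
  channels <- select_attention_channels(canonical_registry())
  foc <- lesion_focused_image(fd$image, fd$masks, channels)
  fus <- collapse_channels(fd$masks, channels)
  changed <- which(foc$pixels != fd$image$pixels, arr.ind = TRUE)
  expect_true(all(changed[, 3] == 3))              # blue plane only
  expect_true(all(fus[changed[, 1:2, drop = FALSE]] == 255L))
  # an all-zero stack leaves the image untouched end to end
  empty <- mask_stack(array(0L, c(128, 128, 32)))
  foc0 <- lesion_focused_image(fd$image, empty, channels)
  expect_identical(foc0$pixels, fd$image$pixels)
})
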