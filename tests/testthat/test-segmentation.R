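test_that("normalization stats follow the mean / RMS definition", {
  a <- flat_image(4, 4, r = 100, g = 100, b = 100)
  b <- flat_image(4, 4, r = 140, g = 160, b = 120)
  st <- compute_normalization_stats(list(a, b))
  expect_equal(st$mean, c(120, 130, 110), ignore_attr = TRUE)
  expect_equal(st$sd, c(20, 30, 10), ignore_attr = TRUE)

  # constant dataset has zero spread -> degenerate error
  expect_error(compute_normalization_stats(list(a)), "zero standard")
  expect_error(compute_normalization_stats(list()), "at least one")

  # random set against a naive two-pass loop, to 8 decimals
  set.seed(6)
  imgs <- lapply(1:4, function(i) {
    fundus_image(array(sample(0:255, 5 * 5 * 3, TRUE), c(5, 5, 3)))
  })
  got <- compute_normalization_stats(imgs)
  all_px <- do.call(rbind, lapply(imgs, function(im) {
    matrix(as.numeric(im$pixels), ncol = 3)
  }))
  mu <- colMeans(all_px)
  sdv <- sqrt(colMeans(sweep(all_px, 2, mu)^2))
  expect_equal(got$mean, mu, tolerance = 1e-9)
  expect_equal(got$sd, sdv, tolerance = 1e-9)
})

test_that("normalize_image centers, scales and resizes", {
  stats <- structure(list(mean = c(100, 80, 60), sd = c(10, 20, 30)),
                     class = "normalization_stats")
  img <- flat_image(32, 32, 100, 80, 60)
  out <- normalize_image(img, stats, size = 32)
  expect_equal(dim(out), c(32, 32, 3))
  expect_true(all(abs(out) < 1e-9))

  id_stats <- structure(list(mean = c(0, 0, 0), sd = c(1, 1, 1)),
                        class = "normalization_stats")
  img2 <- flat_image(32, 32, 7, 9, 11)
  out2 <- normalize_image(img2, id_stats, size = 32)
  expect_equal(out2[1, 1, ], c(7, 9, 11))

  # one-pixel hand check
  out3 <- normalize_image(img2, stats, size = 32)
  expect_equal(out3[5, 5, 1], (7 - 100) / 10)
})

test_that("IoU matches counting, is symmetric, and handles empty masks", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(compute_iou(a, a), 1)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(compute_iou(a, b), 0)
  # 1 intersection pixel out of a 3-pixel union
  pred <- matrix(c(1, 1, 0), 3, 1)
  tru <- matrix(c(1, 0, 1), 3, 1)
  expect_equal(compute_iou(pred, tru), 1 / 3)
  expect_equal(compute_iou(pred, tru), compute_iou(tru, pred))
  z <- matrix(0, 2, 2)
  expect_equal(compute_iou(z, z), 1)
  expect_error(compute_iou(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")

  set.seed(44)
  for (rep in 1:10) {
    x <- matrix(rbinom(36, 1, 0.4), 6, 6)
    y <- matrix(rbinom(36, 1, 0.4), 6, 6)
    expect_equal(compute_iou(x, y), compute_iou(y, x))
  }
})

test_that("lesion score is the 0.4/0.6 convex combination to 6 decimals", {
  expect_equal(compute_lesion_score(0.944777, 0.668727), 0.779147)
  expect_equal(compute_lesion_score(0.697246, 0.420536), 0.531220)
  for (x in c(0, 0.25, 0.5, 1)) {
    expect_equal(compute_lesion_score(x, x), x)
  }
  expect_error(compute_lesion_score(1.2, 0.5), "\\[0, 1\\]")
})

test_that("model spec validates its inputs", {
  expect_error(seg_model_spec(width_multiplier = 0), "\\(0, 1\\]")
  expect_error(seg_model_spec(width_multiplier = 1.5), "\\(0, 1\\]")
  expect_error(seg_model_spec(input_size = 100), "multiple of 32")
})

test_that("U-shaped forward keeps the spatial contract at any width", {
  for (mult in c(0.0625, 0.25)) {
    m <- build_retina_unet(seg_model_spec("optic cup", mult, 64, seed = 2))
    out <- segmentation_forward(m, array(0, c(64, 64, 3)))
    ch <- function(c) max(1, ceiling(c * mult))
    expect_equal(out$shapes$stem, c(32, 32, ch(64)))
    expect_equal(out$shapes$pooled, c(16, 16, ch(64)))
    expect_equal(out$shapes$encoder_out, c(2, 2, ch(512)))
    expect_equal(out$shapes$decoder_first, c(4, 4, ch(256)))
    expect_equal(out$shapes$decoder_last, c(64, 64, ch(16)))
    expect_equal(out$shapes$head, c(64, 64, 1))
    expect_true(all(is.finite(out$probs)))
    expect_true(all(out$probs >= 0 & out$probs <= 1))
  }
})

test_that("a small model recovers the optic disc on 50 synthetic images", {
  set.seed(11)
  imgs <- lapply(1:50, function(i) {
    cfg <- synth_fundus_config(size = 128, seed = 1000 + i,
                               disc_center = c(0.5, 0.68) +
                                 runif(2, -0.04, 0.04),
                               disc_radii = c(0.085, 0.075) *
                                 runif(1, 0.85, 1.15),
                               cup_to_disc_ratio = runif(1, 0.3, 0.5))
    generate_fundus(cfg, image_id = paste0("i", i),
                    patient_id = paste0("p", i))
  })
  stats <- compute_normalization_stats(lapply(imgs, function(f) f$image))
  sz <- 96
  samples <- lapply(imgs, function(f) {
    list(x = normalize_image(f$image, stats, size = sz),
         target = resize_array(f$masks$planes[, , 2] * 1.0, sz, sz,
                               method = "nearest"),
         patient_id = f$image$patient_id)
  })
  mdl <- build_retina_unet(seg_model_spec("optic disc", 0.25, sz, seed = 3))
  tr <- train_segmentation(mdl, samples,
                           config = list(seed = 3, lr = 5e-3,
                                         batch_size = 8, max_epochs = 12,
                                         patience = 4))
  ious <- vapply(tr$split$val, function(i) {
    compute_iou(predict_mask(tr$model, samples[[i]]$x), samples[[i]]$target)
  }, numeric(1))
  expect_gte(mean(ious), 0.7)

  # shuffled-label control: destroying the image-mask pairing leaves the
  # model near the no-signal floor
  set.seed(99)
  perm <- sample(seq_along(samples))
  shuffled <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    s$target <- samples[[perm[i]]]$target
    s
  })
  mdl2 <- build_retina_unet(seg_model_spec("optic disc", 0.125, sz,
                                           seed = 3))
  tr2 <- train_segmentation(mdl2, shuffled,
                            config = list(seed = 3, lr = 5e-3,
                                          batch_size = 8, max_epochs = 4,
                                          patience = 4))
  ious2 <- vapply(tr2$split$val, function(i) {
    compute_iou(predict_mask(tr2$model, shuffled[[i]]$x),
                shuffled[[i]]$target)
  }, numeric(1))
  expect_lt(mean(ious2), 0.3)
})

test_that("segmentation training is seeded-deterministic and guarded", {
  samples <- tiny_seg_samples(n = 10, size = 32)
  cfg <- list(seed = 5, lr = 2e-3, batch_size = 4, max_epochs = 2,
              patience = 2)
  m1 <- build_retina_unet(seg_model_spec("optic disc", 0.0625, 32, seed = 7))
  t1 <- train_segmentation(m1, samples, cfg)
  m2 <- build_retina_unet(seg_model_spec("optic disc", 0.0625, 32, seed = 7))
  t2 <- train_segmentation(m2, samples, cfg)
  expect_equal(t1$log, t2$log)
  # train / validation patients never overlap
  pids <- vapply(samples, function(s) s$patient_id, character(1))
  expect_length(intersect(pids[t1$split$train], pids[t1$split$val]), 0)

  # all-negative class refuses to train
  neg <- lapply(samples, function(s) {
    s$target <- s$target * 0
    s
  })
  m3 <- build_retina_unet(seg_model_spec("drusen", 0.0625, 32, seed = 7))
  expect_error(train_segmentation(m3, neg, cfg), "refusing to train")
})
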