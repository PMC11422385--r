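test_that("classifier spec enforces the nine-stage architectural contract", {
  spec <- classifier_spec(num_classes = 5, width_multiplier = 0.1,
                          input_size = 32)
  expect_s3_class(spec, "classifier_spec")
  expect_error(classifier_spec(num_classes = 1), ">= 2")
  expect_error(classifier_spec(width_multiplier = 2), "\\(0, 1\\]")

  bad <- classifier_stage_table()
  bad$expansion[3] <- 4
  expect_error(classifier_spec(stages = bad), "expansion")
  bad2 <- classifier_stage_table()
  bad2$kernel[4] <- 7
  expect_error(classifier_spec(stages = bad2), "kernel")
  bad3 <- classifier_stage_table()[1:8, ]
  expect_error(classifier_spec(stages = bad3), "stage table")
})

test_that("softmax head yields normalized scores of the right length", {
  set.seed(1)
  model <- build_classifier(classifier_spec(num_classes = 5,
                                            width_multiplier = 0.1,
                                            input_size = 32, seed = 3))
  imgs <- lapply(1:3, function(i) {
    fundus_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)),
                 image_id = paste0("i", i), patient_id = paste0("p", i))
  })
  preds <- predict_proba(model, imgs,
                         class_names = c("GLAU", "AMD", "RVO", "DR", "NORM"))
  sc <- as.matrix(preds[, c("GLAU", "AMD", "RVO", "DR", "NORM")])
  expect_equal(ncol(sc), 5)
  expect_true(all(sc >= 0))
  expect_equal(rowSums(sc), rep(1, 3), tolerance = 1e-6)

  # width multiplier shrinks the parameter count strictly
  big <- build_classifier(classifier_spec(5, 0.5, 32, seed = 3))
  small <- build_classifier(classifier_spec(5, 0.1, 32, seed = 3))
  expect_lt(count_params(small), count_params(big))
})

test_that("inference is batch-invariant, reproducible, and robust to PNG
           round-trips", {
  model <- build_classifier(classifier_spec(3, 0.1, 32, seed = 11))
  expect_equal(nrow(predict_proba(model, list())), 0)
  set.seed(2)
  imgs <- lapply(1:5, function(i) {
    fundus_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)),
                 image_id = paste0("i", i))
  })
  batch <- predict_proba(model, imgs)
  single <- do.call(rbind, lapply(imgs, function(im) {
    predict_proba(model, list(im))
  }))
  expect_equal(as.matrix(batch[, -(1:2)]), as.matrix(single[, -(1:2)]),
               tolerance = 1e-5, ignore_attr = TRUE)

  model2 <- build_classifier(classifier_spec(3, 0.1, 32, seed = 11))
  expect_equal(predict_proba(model2, imgs), batch)

  # scores invariant to an image PNG write/read cycle
  tf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(imgs[[1]]$pixels / 255, tf)
  back <- png::readPNG(tf)
  img_rt <- fundus_image(array(as.integer(round(back * 255)), dim(back)),
                         image_id = "i1")
  expect_equal(predict_proba(model, list(img_rt))[, -(1:2)],
               batch[1, -(1:2)], ignore_attr = TRUE)
})

test_that("training is deterministic, early-stops, and guards the split", {
  set.seed(4)
  imgs <- lapply(1:24, function(i) {
    pid <- paste0("p", (i - 1) %/% 2 + 1)   # 12 patients, 2 images each
    fundus_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)),
                 image_id = paste0("i", i), patient_id = pid)
  })
  labels <- factor(rep(c("A", "B"), 12))
  cfg <- list(seed = 3, lr = 1e-3, batch_size = 8, max_epochs = 4,
              patience = 1)
  t1 <- train_diagnosis(build_classifier(classifier_spec(2, 0.05, 32,
                                                         seed = 5)),
                        imgs, labels, config = cfg)
  t2 <- train_diagnosis(build_classifier(classifier_spec(2, 0.05, 32,
                                                         seed = 5)),
                        imgs, labels, config = cfg)
  expect_equal(t1$log, t2$log)

  # early stopping: never more than best epoch + patience epochs
  best <- which.min(t1$log$val_loss)
  expect_lte(nrow(t1$log), best + cfg$patience)

  # head size must match the label set
  expect_error(train_diagnosis(build_classifier(classifier_spec(5, 0.05, 32)),
                               imgs, labels, config = cfg),
               "does not match")

  # overlapping patients across splits are a hard error
  bad_split <- list(train = 1:16, val = 15:20, test = 21:24)
  expect_error(train_diagnosis(build_classifier(classifier_spec(2, 0.05, 32)),
                               imgs, labels, config = cfg, split = bad_split),
               "overlap")
})

test_that("grading head replacement validates labels and outputs two ways", {
  base <- build_classifier(classifier_spec(5, 0.05, 32, seed = 2))
  set.seed(9)
  imgs <- lapply(1:24, function(i) {
    pid <- paste0("g", (i - 1) %/% 2 + 1)
    fundus_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)),
                 image_id = paste0("i", i), patient_id = pid)
  })
  glabels <- rep(c("early", "late"), 12)
  cfg <- list(seed = 1, lr = 1e-3, batch_size = 8, max_epochs = 1,
              patience = 1)
  ft <- fine_tune_grading(base, imgs, glabels, config = cfg)
  expect_equal(ft$model$spec$num_classes, 2L)
  preds <- predict_proba(ft$model, imgs[1:2],
                         class_names = c("early", "late"))
  expect_equal(rowSums(as.matrix(preds[, c("early", "late")])), c(1, 1),
               tolerance = 1e-6)
  expect_error(fine_tune_grading(base, imgs, rep(c("mild", "severe"), 12),
                                 config = cfg),
               "early, late|exactly")
})
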