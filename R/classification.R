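#' Reference nine-stage architecture table of the diagnosis network
#'
#' The mobile-inverted-bottleneck (MBConv) stage table: stage 1 is a standard
#' 3x3 stride-2 convolution, stages 2-8 repeat MBConv blocks with expansion
#' factor 1 or 6 and kernel 3x3 or 5x5, stage 9 is a 1x1 convolution followed
#' by global average pooling and a fully connected softmax head.
#'
#' @return data.frame with columns `stage`, `operator`, `kernel`, `stride`,
#'   `expansion`, `channels`, `layers`.
#' @export
classifier_stage_table <- function() {
  data.frame(
    stage = 1:9,
    operator = c("conv", rep("mbconv", 7), "head"),
    kernel = c(3, 3, 3, 5, 3, 5, 5, 3, 1),
    stride = c(2, 1, 2, 2, 2, 1, 2, 1, 1),
    expansion = c(NA, 1, 6, 6, 6, 6, 6, 6, NA),
    channels = c(32, 16, 24, 40, 80, 112, 192, 320, 1280),
    layers = c(1, 1, 2, 2, 3, 3, 4, 1, 1)
  )
}

#' Specification of the diagnosis classifier
#'
#' @param num_classes number of output classes (>= 2); the five-disease
#'   head uses GLAU, AMD, RVO, DR, NORM.
#' @param width_multiplier channel scaling in `(0, 1]` for desk-scale runs;
#'   channel counts are `ceiling(base * multiplier)`.
#' @param input_size spatial input size (multiple of 32).
#' @param seed RNG seed for weight initialisation.
#' @param stages stage table; defaults to [classifier_stage_table()].
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(num_classes = 5L, width_multiplier = 1,
                            input_size = 224L, seed = 1L,
                            stages = classifier_stage_table()) {
  if (num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  if (width_multiplier <= 0 || width_multiplier > 1) {
    stop("width_multiplier must lie in (0, 1]", call. = FALSE)
  }
  st <- stages
  if (nrow(st) != 9 || st$operator[1] != "conv" || st$stride[1] != 2 ||
      st$operator[9] != "head") {
    stop("invalid stage table: stage 1 must be a stride-2 convolution and ",
         "stage 9 the 1x1-conv + pool + fully-connected head", call. = FALSE)
  }
  mb <- st$operator == "mbconv"
  if (!all(st$expansion[mb] %in% c(1, 6))) {
    stop("invalid stage table: MBConv expansion factors must be 1 or 6",
         call. = FALSE)
  }
  if (!all(st$kernel[mb] %in% c(3, 5))) {
    stop("invalid stage table: MBConv kernels must be 3x3 or 5x5",
         call. = FALSE)
  }
  structure(list(num_classes = as.integer(num_classes),
                 width_multiplier = width_multiplier,
                 input_size = as.integer(input_size),
                 seed = as.integer(seed), stages = st),
            class = "classifier_spec")
}

.mbconv <- function(cin, cout, kernel, stride, expansion) {
  b <- new.env(parent = emptyenv())
  cexp <- cin * expansion
  b$residual <- (stride == 1 && cin == cout)
  if (expansion != 1) {
    b$expand <- nn_conv(1, 1, cin, cexp)
    b$bn0 <- nn_bn(cexp)
    b$act0 <- nn_act("swish")
  }
  b$dw <- nn_conv(kernel, kernel, cexp, cexp, stride = stride,
                  pad = kernel %/% 2, groups = cexp)
  b$bn1 <- nn_bn(cexp)
  b$act1 <- nn_act("swish")
  b$project <- nn_conv(1, 1, cexp, cout)
  b$bn2 <- nn_bn(cout)
  b
}

.mbconv_layers <- function(b) {
  ls <- list(b$dw, b$bn1, b$act1, b$project, b$bn2)
  if (!is.null(b$expand)) ls <- c(list(b$expand, b$bn0, b$act0), ls)
  ls
}

.mbconv_fwd <- function(b, x, train) {
  h <- x
  if (!is.null(b$expand)) {
    h <- layer_forward(b$act0,
           layer_forward(b$bn0, layer_forward(b$expand, h, train), train),
           train)
  }
  h <- layer_forward(b$act1,
         layer_forward(b$bn1, layer_forward(b$dw, h, train), train), train)
  h <- layer_forward(b$bn2, layer_forward(b$project, h, train), train)
  if (b$residual) h <- h + x
  h
}

.mbconv_bwd <- function(b, gy) {
  g <- layer_backward(b$project, layer_backward(b$bn2, gy))
  g <- layer_backward(b$dw, layer_backward(b$bn1, layer_backward(b$act1, g)))
  if (!is.null(b$expand)) {
    g <- layer_backward(b$expand,
                        layer_backward(b$bn0, layer_backward(b$act0, g)))
  }
  if (b$residual) g <- g + gy
  g
}

#' Build the diagnosis classifier
#'
#' Constructs the nine-stage mobile-inverted-bottleneck network of
#' [classifier_spec()]: batch-normalised, swish-activated, with a softmax
#' head whose outputs sum to one.
#'
#' @param spec a [classifier_spec()].
#' @return Object of class `diagnosis_net`.
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  set.seed(spec$seed)
  m <- spec$width_multiplier
  ch <- function(c) as.integer(max(1, ceiling(c * m)))
  st <- spec$stages
  M <- new.env(parent = emptyenv())
  M$spec <- spec
  M$stem <- nn_conv(st$kernel[1], st$kernel[1], 3, ch(st$channels[1]),
                    stride = st$stride[1], pad = st$kernel[1] %/% 2)
  M$stem_bn <- nn_bn(ch(st$channels[1]))
  M$stem_act <- nn_act("swish")
  blocks <- list()
  cin <- ch(st$channels[1])
  for (s in 2:8) {
    for (rep_i in seq_len(st$layers[s])) {
      stride <- if (rep_i == 1) st$stride[s] else 1L
      cout <- ch(st$channels[s])
      blocks[[length(blocks) + 1]] <-
        .mbconv(cin, cout, st$kernel[s], stride, st$expansion[s])
      cin <- cout
    }
  }
  M$blocks <- blocks
  M$top <- nn_conv(1, 1, cin, ch(st$channels[9]))
  M$top_bn <- nn_bn(ch(st$channels[9]))
  M$top_act <- nn_act("swish")
  M$fc <- nn_dense(ch(st$channels[9]), spec$num_classes)
  M$layers <- c(list(M$stem, M$stem_bn, M$stem_act),
                unlist(lapply(blocks, .mbconv_layers), recursive = FALSE),
                list(M$top, M$top_bn, M$top_act, M$fc))
  class(M) <- "diagnosis_net"
  M
}

.clf_forward <- function(M, x, train = FALSE) {
  h <- layer_forward(M$stem_act,
         layer_forward(M$stem_bn, layer_forward(M$stem, x, train), train),
         train)
  for (b in M$blocks) h <- .mbconv_fwd(b, h, train)
  h <- layer_forward(M$top_act,
         layer_forward(M$top_bn, layer_forward(M$top, h, train), train),
         train)
  M$pool_dim <- dim(h)
  feat <- global_avgpool_forward(h)
  layer_forward(M$fc, feat, train)         # logits (N, K)
}

.clf_backward <- function(M, g_logits) {
  g <- layer_backward(M$fc, g_logits)
  g <- global_avgpool_backward(g, M$pool_dim)
  g <- layer_backward(M$top,
         layer_backward(M$top_bn, layer_backward(M$top_act, g)))
  for (b in rev(M$blocks)) g <- .mbconv_bwd(b, g)
  g <- layer_backward(M$stem,
         layer_backward(M$stem_bn, layer_backward(M$stem_act, g)))
  invisible(g)
}

#' Number of trainable parameters of a model
#' @param model a `diagnosis_net` or `retina_unet`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    sum(vapply(l$pnames, function(p) length(get(p, envir = l)), numeric(1)),
        0)
  }, numeric(1)))
}

.stack_images <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, dim = c(d[1], d[2], d[3], length(images)))
  for (k in seq_along(images)) x[, , , k] <- images[[k]]
  x
}

# 8-bit image -> classifier input scale [-1, 1]
.clf_preprocess <- function(img, size) {
  px <- if (inherits(img, "fundus_image")) img$pixels else img
  r <- resize_array(px * 1.0, size, size, method = "bilinear")
  r / 127.5 - 1
}

#' Class probabilities for a set of images
#'
#' @param model a trained (or freshly built) `diagnosis_net`.
#' @param images list of [fundus_image] objects or `H x W x 3` 8-bit arrays.
#' @param class_names optional class labels for the score columns.
#' @param batch_size inference batch size.
#' @return data.frame with one row per image: `image_id`, `patient_id` and
#'   one score column per class; scores are softmax outputs summing to 1.
#' @export
predict_proba <- function(model, images, class_names = NULL,
                          batch_size = 32L) {
  K <- model$spec$num_classes
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K))
  stopifnot(length(class_names) == K)
  if (length(images) == 0) {
    out <- data.frame(image_id = character(0), patient_id = character(0))
    for (cn in class_names) out[[cn]] <- numeric(0)
    return(out)
  }
  size <- model$spec$input_size
  ids <- vapply(images, function(im)
    if (inherits(im, "fundus_image")) im$image_id else "img", character(1))
  pids <- vapply(images, function(im)
    if (inherits(im, "fundus_image")) im$patient_id else "pat", character(1))
  xs <- lapply(images, .clf_preprocess, size = size)
  probs <- matrix(0, length(images), K)
  for (start in seq(1, length(xs), by = batch_size)) {
    ix <- start:min(start + batch_size - 1, length(xs))
    logits <- .clf_forward(model, .stack_images(xs[ix]), train = FALSE)
    z <- logits - apply(logits, 1, max)
    p <- exp(z) / rowSums(exp(z))
    probs[ix, ] <- p
  }
  out <- data.frame(image_id = ids, patient_id = pids,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) out[[class_names[k]]] <- probs[, k]
  out
}

#' Train the diagnosis classifier
#'
#' Splits the cohort by patient ID into training, internal validation and
#' internal test sets in a 7:1:2 ratio (no patient appears in two sets;
#' violations are a hard error), trains with Adam on softmax cross-entropy,
#' stops early when the validation loss has not improved for `patience`
#' epochs, and restores the best-validation-loss weights. Deterministic for
#' a given seed.
#'
#' @param model a `diagnosis_net`.
#' @param images list of [fundus_image]s (or 8-bit arrays).
#' @param labels factor/character vector of class labels, one per image.
#' @param patient_ids character vector, one per image; taken from the images
#'   when `NULL`.
#' @param config list with `seed`, `lr`, `batch_size`, `max_epochs`,
#'   `patience`.
#' @param split optional precomputed list of index vectors `train`, `val`,
#'   `test`; patient disjointness is still asserted.
#' @return list with `model`, `log` (per-epoch losses), `split`, `classes`.
#' @export
train_diagnosis <- function(model, images, labels, patient_ids = NULL,
                            config = list(seed = 1L, lr = 1e-3,
                                          batch_size = 32L, max_epochs = 20L,
                                          patience = 3L),
                            split = NULL) {
  classes <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  y <- match(as.character(labels), classes)
  if (length(classes) != model$spec$num_classes) {
    stop("label set size (", length(classes), ") does not match model head (",
         model$spec$num_classes, ")", call. = FALSE)
  }
  if (is.null(patient_ids)) {
    patient_ids <- vapply(images, function(im) im$patient_id, character(1))
  }
  if (is.null(split)) {
    split <- split_indices_by_patient(patient_ids, c(7, 1, 2),
                                      seed = config$seed)
  }
  for (pair in list(c("train", "val"), c("train", "test"), c("val", "test"))) {
    ov <- intersect(patient_ids[split[[pair[1]]]], patient_ids[split[[pair[2]]]])
    if (length(ov) > 0) {
      stop("patient ID overlap between ", pair[1], " and ", pair[2], ": ",
           paste(utils::head(ov, 3), collapse = ", "), call. = FALSE)
    }
  }
  size <- model$spec$input_size
  xs <- lapply(images, .clf_preprocess, size = size)
  set.seed(config$seed)
  layers <- model$layers
  eval_loss <- function(ix) {
    tot <- 0
    for (start in seq(1, length(ix), by = config$batch_size)) {
      jx <- ix[start:min(start + config$batch_size - 1, length(ix))]
      logits <- .clf_forward(model, .stack_images(xs[jx]), train = FALSE)
      tot <- tot + softmax_ce(logits, y[jx])$loss * length(jx)
    }
    tot / length(ix)
  }
  best <- list(loss = Inf, snap = NULL, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  t_adam <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(split$train)
    tl <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      ix <- ord[start:min(start + config$batch_size - 1, length(ord))]
      xb <- .stack_images(xs[ix])
      if (isTRUE(config$augment_hflip %||% TRUE)) {
        # random left-right flips; label-preserving for fundus geometry
        flip <- stats::runif(length(ix)) < 0.5
        if (any(flip)) {
          xb[, , , flip] <- xb[, rev(seq_len(dim(xb)[2])), , flip,
                               drop = FALSE]
        }
      }
      logits <- .clf_forward(model, xb, train = TRUE)
      ls <- softmax_ce(logits, y[ix])
      .clf_backward(model, ls$grad)
      t_adam <- t_adam + 1L
      adam_step(layers, config$lr, t_adam,
                weight_decay = config$weight_decay %||% 1e-4)
      tl <- c(tl, ls$loss)
    }
    vl <- eval_loss(split$val)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(tl),
                                 val_loss = vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, snap = snapshot_params(layers), epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  if (!is.null(best$snap)) restore_params(layers, best$snap)
  list(model = model, log = log, split = split, classes = classes)
}

#' Fine-tune a trained diagnosis model into a two-way grading model
#'
#' Replaces the fully connected head with a 2-way softmax (labels must be
#' exactly `early` and `late`); every other weight is initialised from the
#' base model, inheriting its learned fundus features, and training proceeds
#' as in [train_diagnosis()].
#'
#' @param base trained `diagnosis_net`.
#' @param images,labels,patient_ids grading cohort (labels in
#'   `{"early", "late"}`).
#' @param config training configuration as in [train_diagnosis()].
#' @return list as returned by [train_diagnosis()]; the model head has
#'   output length 2.
#' @export
fine_tune_grading <- function(base, images, labels, patient_ids = NULL,
                              config = list(seed = 1L, lr = 1e-3,
                                            batch_size = 32L, max_epochs = 10L,
                                            patience = 3L)) {
  lab <- sort(unique(as.character(labels)))
  if (!identical(lab, c("early", "late"))) {
    stop("grading labels must be exactly {early, late}, got: ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  spec2 <- base$spec
  spec2$num_classes <- 2L
  grading <- build_classifier(spec2)
  # copy every weight except the classification head
  n <- length(base$layers)
  snap <- snapshot_params(base$layers[-n])
  restore_params(grading$layers[-length(grading$layers)], snap)
  # batch-norm running statistics are re-estimated on the grading cohort:
  # the base stats describe the diseases task's activation distribution
  for (l in grading$layers) {
    if (l$type == "bn") l$r_init <- FALSE
  }
  train_diagnosis(grading, images, factor(labels, levels = c("early", "late")),
                  patient_ids, config)
}
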