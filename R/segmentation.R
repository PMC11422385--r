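#' Per-channel normalization statistics of a fundus image dataset
#'
#' The per-channel mean is the average over all pixels of all images; the
#' per-channel standard deviation is the root mean square of the
#' mean-subtracted values. Both are retained at full double precision
#' (well beyond 8 decimal digits).
#'
#' @param images list of [fundus_image] objects (or `H x W x 3` arrays),
#'   all on the 8-bit scale.
#' @return Object of class `normalization_stats`: list with `mean` and `sd`,
#'   numeric triples (R, G, B).
#' @export
compute_normalization_stats <- function(images) {
  if (length(images) == 0) stop("need at least one image", call. = FALSE)
  px <- lapply(images, function(im) {
    if (inherits(im, "fundus_image")) im$pixels else im
  })
  n_per <- vapply(px, function(a) prod(dim(a)[1:2]), numeric(1))
  sums <- vapply(px, function(a) colSums(matrix(as.numeric(a), ncol = 3)),
                 numeric(3))
  mu <- rowSums(sums) / sum(n_per)
  sq <- vapply(px, function(a) {
    m <- sweep(matrix(as.numeric(a), ncol = 3), 2, mu)
    colSums(m^2)
  }, numeric(3))
  sdv <- sqrt(rowSums(sq) / sum(n_per))
  if (any(sdv <= 0)) {
    stop("degenerate normalization: zero standard deviation in channel(s) ",
         paste(c("R", "G", "B")[sdv <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv), class = "normalization_stats")
}

#' @export
print.normalization_stats <- function(x, ...) {
  cat("<normalization_stats>\n  mean:",
      paste(formatC(x$mean, digits = 8, format = "f"), collapse = " "),
      "\n  sd:  ",
      paste(formatC(x$sd, digits = 8, format = "f"), collapse = " "), "\n")
  invisible(x)
}

#' Resize an image or mask array
#'
#' Bilinear interpolation for images, nearest-neighbour for masks (so labels
#' stay binary).
#'
#' @param x matrix or `H x W x C` array.
#' @param h,w output size.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Resized array of the same rank.
#' @export
resize_array <- function(x, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  filt <- if (method == "bilinear") "bilinear" else "none"
  y <- EBImage::resize(x, w = h, h = w, filter = filt)
  as.array(y)
}

#' Normalize and resize a fundus image for the segmentation network
#'
#' `output = (resized(img) - mean) / sd` per channel, as 32-bit-style floats.
#'
#' @param img [fundus_image] or `H x W x 3` array on the 8-bit scale.
#' @param stats [compute_normalization_stats()] output.
#' @param size output spatial size (default 256).
#' @return `size x size x 3` numeric array.
#' @export
normalize_image <- function(img, stats, size = 256L) {
  stopifnot(inherits(stats, "normalization_stats"))
  if (any(stats$sd <= 0)) stop("zero standard deviation", call. = FALSE)
  px <- if (inherits(img, "fundus_image")) img$pixels else img
  r <- resize_array(px * 1.0, size, size, method = "bilinear")
  for (c in 1:3) r[, , c] <- (r[, , c] - stats$mean[c]) / stats$sd[c]
  r
}

#' Specification of a Retina-UNet segmentation model
#'
#' A U-shaped network with a residual 18-layer encoder and a five-stage
#' decoder with skip connections. At width multiplier 1 and input size 256
#' the forward pass realises the reference shape contract:
#' input `256x256x3` -> stem `128x128x64` -> pooled `64x64x64` -> encoder
#' output `8x8x512` -> first decoder stage `16x16x256` -> last decoder stage
#' `256x256x16` -> head `256x256x1` (per-pixel probability).
#'
#' @param target_class class name this binary model segments.
#' @param width_multiplier channel-width scaling in `(0, 1]`; channel counts
#'   are `ceiling(base * multiplier)`. Spatial sizes are unaffected.
#' @param input_size spatial input size (default 256).
#' @param seed RNG seed used for weight initialisation.
#' @return Object of class `seg_model_spec`.
#' @export
seg_model_spec <- function(target_class = "optic disc", width_multiplier = 1,
                           input_size = 256L, seed = 1L) {
  if (!is.numeric(width_multiplier) || length(width_multiplier) != 1 ||
      width_multiplier <= 0 || width_multiplier > 1) {
    stop("width_multiplier must lie in (0, 1]", call. = FALSE)
  }
  if (input_size %% 32L != 0L) {
    stop("input_size must be a multiple of 32", call. = FALSE)
  }
  structure(list(target_class = target_class,
                 width_multiplier = width_multiplier,
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "seg_model_spec")
}

.basic_block <- function(cin, cout, stride) {
  b <- new.env(parent = emptyenv())
  b$conv1 <- nn_conv(3, 3, cin, cout, stride = stride, pad = 1)
  b$bn1 <- nn_bn(cout)
  b$act1 <- nn_act("relu")
  b$conv2 <- nn_conv(3, 3, cout, cout, stride = 1, pad = 1)
  b$bn2 <- nn_bn(cout)
  b$act_out <- nn_act("relu")
  if (stride != 1 || cin != cout) {
    b$convs <- nn_conv(1, 1, cin, cout, stride = stride, pad = 0)
    b$bns <- nn_bn(cout)
  }
  b
}

.basic_block_layers <- function(b) {
  ls <- list(b$conv1, b$bn1, b$act1, b$conv2, b$bn2, b$act_out)
  if (!is.null(b$convs)) ls <- c(ls, list(b$convs, b$bns))
  ls
}

.basic_block_fwd <- function(b, x, train) {
  h <- layer_forward(b$conv1, x, train)
  h <- layer_forward(b$bn1, h, train)
  h <- layer_forward(b$act1, h, train)
  h <- layer_forward(b$conv2, h, train)
  h <- layer_forward(b$bn2, h, train)
  idt <- if (is.null(b$convs)) x else
    layer_forward(b$bns, layer_forward(b$convs, x, train), train)
  layer_forward(b$act_out, h + idt, train)
}

.basic_block_bwd <- function(b, gy) {
  g <- layer_backward(b$act_out, gy)
  g_idt <- g
  g1 <- layer_backward(b$bn2, g)
  g1 <- layer_backward(b$conv2, g1)
  g1 <- layer_backward(b$act1, g1)
  g1 <- layer_backward(b$bn1, g1)
  g1 <- layer_backward(b$conv1, g1)
  g2 <- if (is.null(b$convs)) g_idt else
    layer_backward(b$convs, layer_backward(b$bns, g_idt))
  g1 + g2
}

.dec_stage <- function(cin, cout) {
  d <- new.env(parent = emptyenv())
  d$conv <- nn_conv(3, 3, cin, cout, stride = 1, pad = 1)
  d$bn <- nn_bn(cout)
  d$act <- nn_act("relu")
  d
}

.dec_fwd <- function(d, x, train) {
  layer_forward(d$act,
                layer_forward(d$bn, layer_forward(d$conv, x, train), train),
                train)
}

.dec_bwd <- function(d, gy) {
  layer_backward(d$conv, layer_backward(d$bn, layer_backward(d$act, gy)))
}

#' Build a Retina-UNet segmentation model
#'
#' @param spec a [seg_model_spec()].
#' @return Object of class `retina_unet` with `$forward(x, train)` returning
#'   a list with per-pixel probabilities, logits and the checkpoint shapes,
#'   and internal machinery used by [train_segmentation()].
#' @export
build_retina_unet <- function(spec) {
  stopifnot(inherits(spec, "seg_model_spec"))
  set.seed(spec$seed)
  m <- spec$width_multiplier
  ch <- function(c) as.integer(max(1, ceiling(c * m)))
  M <- new.env(parent = emptyenv())
  M$spec <- spec
  M$stem_conv <- nn_conv(7, 7, 3, ch(64), stride = 2, pad = 3)
  M$stem_bn <- nn_bn(ch(64))
  M$stem_act <- nn_act("relu")
  M$pool <- nn_pool(3, 2, 1)
  stage <- function(cin, cout, stride) {
    list(.basic_block(cin, cout, stride), .basic_block(cout, cout, 1))
  }
  M$enc1 <- stage(ch(64), ch(64), 1)
  M$enc2 <- stage(ch(64), ch(128), 2)
  M$enc3 <- stage(ch(128), ch(256), 2)
  M$enc4 <- stage(ch(256), ch(512), 2)
  M$dec0 <- .dec_stage(ch(512) + ch(256), ch(256))
  M$dec1 <- .dec_stage(ch(256) + ch(128), ch(128))
  M$dec2 <- .dec_stage(ch(128) + ch(64), ch(64))
  M$dec3 <- .dec_stage(ch(64) + ch(64), ch(32))
  M$dec4 <- .dec_stage(ch(32), ch(16))
  M$head <- nn_conv(1, 1, ch(16), 1, stride = 1, pad = 0)
  M$layers <- c(list(M$stem_conv, M$stem_bn, M$stem_act),
                unlist(lapply(c(M$enc1, M$enc2, M$enc3, M$enc4),
                              .basic_block_layers), recursive = FALSE),
                list(M$pool),
                unlist(lapply(list(M$dec0, M$dec1, M$dec2, M$dec3, M$dec4),
                              function(d) list(d$conv, d$bn, d$act)),
                       recursive = FALSE),
                list(M$head))
  class(M) <- "retina_unet"
  M
}

.unet_forward <- function(M, x, train = FALSE) {
  stage_fwd <- function(blocks, h) {
    for (b in blocks) h <- .basic_block_fwd(b, h, train)
    h
  }
  s0 <- layer_forward(M$stem_act,
          layer_forward(M$stem_bn,
            layer_forward(M$stem_conv, x, train), train), train)
  p <- layer_forward(M$pool, s0, train)
  e1 <- stage_fwd(M$enc1, p)
  e2 <- stage_fwd(M$enc2, e1)
  e3 <- stage_fwd(M$enc3, e2)
  e4 <- stage_fwd(M$enc4, e3)
  d0 <- .dec_fwd(M$dec0, concat_channels(upsample2_forward(e4), e3), train)
  d1 <- .dec_fwd(M$dec1, concat_channels(upsample2_forward(d0), e2), train)
  d2 <- .dec_fwd(M$dec2, concat_channels(upsample2_forward(d1), e1), train)
  d3 <- .dec_fwd(M$dec3, concat_channels(upsample2_forward(d2), s0), train)
  d4 <- .dec_fwd(M$dec4, upsample2_forward(d3), train)
  logits <- layer_forward(M$head, d4, train)
  M$skip_ch <- c(dim(e3)[3], dim(e2)[3], dim(e1)[3], dim(s0)[3])
  shapes <- list(stem = dim(s0)[1:3], pooled = dim(p)[1:3],
                 encoder_out = dim(e4)[1:3], decoder_first = dim(d0)[1:3],
                 decoder_last = dim(d4)[1:3], head = dim(logits)[1:3])
  list(probs = 1 / (1 + exp(-logits)), logits = logits, shapes = shapes)
}

.unet_backward <- function(M, g_logits) {
  split_cc <- function(g, skip_ch) {
    n_up <- dim(g)[3] - skip_ch
    list(up = g[, , seq_len(n_up), , drop = FALSE],
         skip = g[, , n_up + seq_len(skip_ch), , drop = FALSE])
  }
  stage_bwd <- function(blocks, g) {
    for (b in rev(blocks)) g <- .basic_block_bwd(b, g)
    g
  }
  g <- layer_backward(M$head, g_logits)
  g <- upsample2_backward(.dec_bwd(M$dec4, g))
  sp <- split_cc(.dec_bwd(M$dec3, g), M$skip_ch[4])
  g_d2 <- upsample2_backward(sp$up); g_s0a <- sp$skip
  sp <- split_cc(.dec_bwd(M$dec2, g_d2), M$skip_ch[3])
  g_d1 <- upsample2_backward(sp$up); g_e1a <- sp$skip
  sp <- split_cc(.dec_bwd(M$dec1, g_d1), M$skip_ch[2])
  g_d0 <- upsample2_backward(sp$up); g_e2a <- sp$skip
  sp <- split_cc(.dec_bwd(M$dec0, g_d0), M$skip_ch[1])
  g_e4 <- upsample2_backward(sp$up); g_e3a <- sp$skip
  g_e3 <- stage_bwd(M$enc4, g_e4) + g_e3a
  g_e2 <- stage_bwd(M$enc3, g_e3) + g_e2a
  g_e1 <- stage_bwd(M$enc2, g_e2) + g_e1a
  g_p <- stage_bwd(M$enc1, g_e1)
  g_s0 <- layer_backward(M$pool, g_p) + g_s0a
  g_s0 <- layer_backward(M$stem_act, g_s0)
  g_s0 <- layer_backward(M$stem_bn, g_s0)
  layer_backward(M$stem_conv, g_s0)
  invisible(NULL)
}

#' Forward pass of a segmentation model
#'
#' @param model a `retina_unet`.
#' @param x `H x W x 3 x N` array (or a single `H x W x 3` image).
#' @param train logical; `TRUE` uses batch statistics and keeps caches.
#' @return list with `probs` (per-pixel probabilities in `[0, 1]`), `logits`
#'   and `shapes` (the six checkpoint shapes).
#' @export
segmentation_forward <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  .unet_forward(model, x, train = train)
}

#' Intersection over union of two binary masks
#'
#' `|pred & truth| / |pred | truth|`; defined as 1 when both masks are empty.
#'
#' @param pred,truth binary matrices/arrays of identical shape.
#' @return Numeric scalar in `[0, 1]`.
#' @export
compute_iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    stop("mask shapes differ", call. = FALSE)
  }
  p <- pred > 0.5
  t <- truth > 0.5
  u <- sum(p | t)
  if (u == 0) return(1.0)
  sum(p & t) / u
}

#' Segmentation report score
#'
#' Convex combination of training and validation IoU with weights 0.4 and
#' 0.6, rounded to six decimals - the per-class summary score of the
#' segmentation report.
#'
#' @param iou_train,iou_val IoU values in `[0, 1]`.
#' @return Numeric scalar, rounded to 6 decimals.
#' @export
compute_lesion_score <- function(iou_train, iou_val) {
  if (any(c(iou_train, iou_val) < 0) || any(c(iou_train, iou_val) > 1)) {
    stop("IoU values must lie in [0, 1]", call. = FALSE)
  }
  round(0.4 * iou_train + 0.6 * iou_val, 6)
}

#' Split samples into train/validation with patient-disjoint IDs
#'
#' @param patient_ids character vector, one per sample.
#' @param ratio train:val ratio as a length-2 numeric (default `c(4, 1)`).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `val`; the patient
#'   sets are disjoint by construction and asserted.
#' @export
patient_train_val_split <- function(patient_ids, ratio = c(4, 1), seed = 1L) {
  pats <- unique(patient_ids)
  if (length(pats) < 2) stop("need at least two patients", call. = FALSE)
  set.seed(seed)
  pats <- sample(pats)
  n_val <- max(1L, round(length(pats) * ratio[2] / sum(ratio)))
  val_p <- pats[seq_len(n_val)]
  train_p <- setdiff(pats, val_p)
  stopifnot(length(intersect(train_p, val_p)) == 0)
  list(train = which(patient_ids %in% train_p),
       val = which(patient_ids %in% val_p))
}

#' Train a binary segmentation model
#'
#' Trains with pixel-wise binary cross-entropy plus a Dice term (equal
#' weights) and Adam; samples are split 4:1 into patient-disjoint training
#' and validation sets; the weights with the lowest validation loss are
#' returned. Deterministic for a given seed.
#'
#' @param model a `retina_unet` from [build_retina_unet()].
#' @param samples list of samples, each a list with `x` (normalized
#'   `S x S x 3` array), `target` (binary `S x S` matrix) and `patient_id`.
#' @param config list with `seed`, `lr`, `batch_size`, `max_epochs`,
#'   `patience`.
#' @return list with `model` (best weights restored), `log` (per-epoch
#'   data.frame of train/validation loss) and `split`.
#' @export
train_segmentation <- function(model, samples,
                               config = list(seed = 1L, lr = 1e-3,
                                             batch_size = 8L, max_epochs = 15L,
                                             patience = 3L)) {
  n_pos <- sum(vapply(samples, function(s) sum(s$target) > 0, logical(1)))
  if (n_pos == 0) {
    stop("no positive samples for class '", model$spec$target_class,
         "'; refusing to train", call. = FALSE)
  }
  pids <- vapply(samples, function(s) s$patient_id, character(1))
  split <- patient_train_val_split(pids, c(4, 1), seed = config$seed)
  stopifnot(length(intersect(pids[split$train], pids[split$val])) == 0)
  set.seed(config$seed)
  make_batch <- function(ix) {
    S <- dim(samples[[ix[1]]]$x)[1]
    xb <- array(0, dim = c(S, S, 3, length(ix)))
    tb <- array(0, dim = c(S, S, 1, length(ix)))
    for (k in seq_along(ix)) {
      xb[, , , k] <- samples[[ix[k]]]$x
      tb[, , 1, k] <- samples[[ix[k]]]$target
    }
    list(x = xb, t = tb)
  }
  layers <- model$layers
  best <- list(loss = Inf, snap = NULL, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  t_adam <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(split$train)
    tr_losses <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      ix <- ord[start:min(start + config$batch_size - 1, length(ord))]
      b <- make_batch(ix)
      out <- .unet_forward(model, b$x, train = TRUE)
      ls <- bce_dice(out$logits, b$t)
      .unet_backward(model, ls$grad)
      t_adam <- t_adam + 1L
      adam_step(layers, config$lr, t_adam)
      tr_losses <- c(tr_losses, ls$loss)
    }
    vl <- 0
    for (start in seq(1, length(split$val), by = config$batch_size)) {
      ix <- split$val[start:min(start + config$batch_size - 1,
                                length(split$val))]
      b <- make_batch(ix)
      out <- .unet_forward(model, b$x, train = FALSE)
      vl <- vl + bce_dice(out$logits, b$t)$loss * length(ix)
    }
    vl <- vl / length(split$val)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(tr_losses),
                                 val_loss = vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, snap = snapshot_params(layers), epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  if (!is.null(best$snap)) restore_params(layers, best$snap)
  list(model = model, log = log, split = split)
}

#' Predict a binary mask for one normalized image
#'
#' @param model trained `retina_unet`.
#' @param x normalized `S x S x 3` array.
#' @param threshold binarisation threshold (default 0.5).
#' @return Binary `S x S` matrix.
#' @export
predict_mask <- function(model, x, threshold = 0.5) {
  out <- segmentation_forward(model, x, train = FALSE)
  (out$probs[, , 1, 1] > threshold) * 1L
}
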