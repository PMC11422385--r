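# Shared fixtures: small random mask stacks, reference bit-packing oracle,
# tiny flat test images.

rand_stack <- function(h = 8, w = 8, p = 0.3) {
  mask_stack(array(rbinom(h * w * 32, 1, p), dim = c(h, w, 32L)))
}

# independent per-pixel, per-bit summation loop (the codec oracle)
oracle_encode <- function(planes) {
  d <- dim(planes)
  out <- array(0L, dim = c(d[1], d[2], 4L))
  for (h in seq_len(d[1])) for (w in seq_len(d[2])) for (i in 0:31) {
    k <- i %/% 8 + 1
    out[h, w, k] <- out[h, w, k] + planes[h, w, i + 1] * 2^(i %% 8)
  }
  storage.mode(out) <- "integer"
  out
}

# exhaustive concordant-pair AUC oracle (ties count one half)
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

flat_image <- function(h = 16, w = 16, r = 120, g = 80, b = 40,
                       image_id = "img", patient_id = "pat") {
  px <- array(0L, dim = c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  fundus_image(px, image_id, patient_id)
}

tiny_seg_samples <- function(n = 12, size = 32) {
  lapply(seq_len(n), function(i) {
    cfg <- synth_fundus_config(size = 64, seed = 5000 + i,
                               cup_to_disc_ratio = 0.4)
    fd <- generate_fundus(cfg, image_id = paste0("i", i),
                          patient_id = paste0("p", i))
    list(x = (resize_array(fd$image$pixels * 1.0, size, size,
                           "bilinear") - 100) / 60,
         target = resize_array(fd$masks$planes[, , 2] * 1.0, size, size,
                               method = "nearest"),
         patient_id = paste0("p", i))
  })
}
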