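# Shared fixtures and brute-force oracles, all generated in code.

# 64x64 noisy disk: radius-15 bright disk (0.9) on dark background (0.1),
# additive Gaussian noise, seeded. The canonical segmentation fixture.
disk_field <- function(n = 64, r = 15, inside = 0.9, bg = 0.1,
                       noise_sd = 0.05, seed = 0) {
  c0 <- (n + 1) / 2
  d <- sqrt(outer((1:n - c0)^2, (1:n - c0)^2, `+`))
  f <- ifelse(d <= r, inside, bg)
  withr::with_seed(seed, f + matrix(stats::rnorm(n * n, 0, noise_sd), n, n))
}

disk_mask <- function(n = 64, r = 15) {
  c0 <- (n + 1) / 2
  sqrt(outer((1:n - c0)^2, (1:n - c0)^2, `+`)) <= r
}

# uniform-color disk on a uniform background, with its exact mask
color_disk_frame <- function(cx, cy, n = 96, r = 10,
                             col = c(200, 56, 120), bg = c(40, 40, 40)) {
  f <- array(rep(bg, each = n * n), dim = c(n, n, 3))
  dd <- sqrt(matrix(rep((1:n - cx)^2, each = n), n, n) +
               matrix(rep((1:n - cy)^2, n), n, n))
  msk <- dd <= r
  for (ch in 1:3) {
    pl <- f[, , ch]
    pl[msk] <- col[ch]
    f[, , ch] <- pl
  }
  list(frame = f, mask = msk)
}

# --- independent brute-force oracles (kept deliberately naive) ---

brute_region_means <- function(field, phi) {
  s1 <- 0; n1 <- 0; s2 <- 0; n2 <- 0
  for (i in seq_len(nrow(field))) for (j in seq_len(ncol(field))) {
    if (phi[i, j] >= 0) {
      s1 <- s1 + field[i, j]; n1 <- n1 + 1
    } else {
      s2 <- s2 + field[i, j]; n2 <- n2 + 1
    }
  }
  c(m1 = s1 / n1, m2 = s2 / n2)
}

brute_color_model <- function(frame, window, quantizer) {
  nb <- quantizer$bins_per_channel
  scale <- nb / (quantizer$channel_max + 1)
  probs <- numeric(quantizer$n_bins)
  tot <- 0
  x0 <- max(1, round(window$center[1] - window$half[1]))
  x1 <- min(dim(frame)[2], round(window$center[1] + window$half[1]))
  y0 <- max(1, round(window$center[2] - window$half[2]))
  y1 <- min(dim(frame)[1], round(window$center[2] + window$half[2]))
  for (y in y0:y1) for (x in x0:x1) {
    u2 <- ((x - window$center[1]) / window$half[1])^2 +
      ((y - window$center[2]) / window$half[2])^2
    w <- exp(-0.5 * u2)
    b1 <- min(floor(frame[y, x, 1] * scale), nb - 1)
    b2 <- min(floor(frame[y, x, 2] * scale), nb - 1)
    b3 <- min(floor(frame[y, x, 3] * scale), nb - 1)
    idx <- b1 + nb * b2 + nb * nb * b3 + 1
    probs[idx] <- probs[idx] + w
    tot <- tot + w
  }
  probs / tot
}

brute_bhattacharyya <- function(q, p) {
  s <- 0
  for (i in seq_along(q)) s <- s + sqrt(q[i] * p[i])
  s
}

brute_iou <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] && b[i, j]) inter <- inter + 1
    if (a[i, j] || b[i, j]) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

# default benchmark run shared by tracker and acceptance tests
run_benchmark <- function(motion = "linear", iters_per_frame = 50,
                          window_update = "from_mask", spec = NULL) {
  if (is.null(spec)) spec <- scene_spec(motion = motion)
  seqs <- generate_sequence(spec)
  # the manual frame-1 selection: the snug bounding box of the object
  ij <- which(seqs$gt_masks[[1]], arr.ind = TRUE)
  box <- c(min(ij[, 2]), min(ij[, 1]),
           diff(range(ij[, 2])) + 1, diff(range(ij[, 1])) + 1)
  cfg <- tracker_config(iters_per_frame = iters_per_frame,
                        window_update = window_update)
  res <- track_sequence(seqs$frames, box, cfg)
  list(seq = seqs, results = res,
       eval = evaluate_tracking(lapply(res, `[[`, "mask"), seqs$gt_masks))
}
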