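# independent oracles and small fixture builders used across the suite

# naive loop-summation colour moments over masked pixels of one channel
naive_channel_moments <- function(vals) {
  n <- length(vals)
  mu <- 0
  for (v in vals) mu <- mu + v
  mu <- mu / n
  m2 <- 0; m3 <- 0
  for (v in vals) {
    m2 <- m2 + (v - mu)^2
    m3 <- m3 + (v - mu)^3
  }
  m2 <- m2 / n; m3 <- m3 / n
  c(mean = mu, second = sqrt(m2), third = sign(m3) * abs(m3)^(1 / 3))
}

naive_color_moments <- function(img, mask) {
  hsv <- rgb_to_hsv(img)
  chans <- list(img[, , 1], img[, , 2], img[, , 3],
                hsv[, , 1], hsv[, , 2], hsv[, , 3])
  out <- unlist(lapply(chans, function(ch) naive_channel_moments(ch[mask])))
  names(out) <- as.vector(t(outer(c("R", "G", "B", "H", "S", "V"),
                                  c("mean", "second", "third"),
                                  paste, sep = "_")))
  out
}

# Monte-Carlo IoU oracle by area sampling over the union's bounding box
mc_iou <- function(a, b, n = 20000, seed = 42) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
    y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
    xs <- runif(n, x0, x1); ys <- runif(n, y0, y1)
    in_a <- xs >= a[1] & xs < a[3] & ys >= a[2] & ys < a[4]
    in_b <- xs >= b[1] & xs < b[3] & ys >= b[2] & ys < b[4]
    sum(in_a & in_b) / sum(in_a | in_b)
  })
}

# brute-force all-points AP: every distinct threshold evaluated from
# scratch with explicit loops, envelope computed by scanning
brute_force_ap <- function(scores, is_tp, n_pos) {
  ord <- order(-scores, seq_along(scores))
  scores <- scores[ord]; is_tp <- is_tp[ord]
  thr <- unique(scores)
  pts <- data.frame(p = numeric(0), r = numeric(0))
  for (t in thr) {
    keep <- scores >= t
    tp <- sum(is_tp[keep]); fp <- sum(!is_tp[keep])
    pts <- rbind(pts, data.frame(p = tp / (tp + fp), r = tp / n_pos))
  }
  pts <- pts[order(pts$r, -pts$p), ]
  ap <- 0; prev_r <- 0
  for (i in seq_len(nrow(pts))) {
    env <- max(pts$p[i:nrow(pts)])   # precision envelope from the right
    ap <- ap + (pts$r[i] - prev_r) * env
    prev_r <- pts$r[i]
  }
  ap
}

# filled disk mask
make_disk <- function(H, W, cy, cx, r) {
  outer(seq_len(H), seq_len(W),
        function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# two disks fused by a thin rectangular neck
make_dumbbell <- function() {
  m <- make_disk(60, 90, 30, 25, 10) | make_disk(60, 90, 30, 65, 10)
  m[29:31, 25:65] <- TRUE
  m
}

# a small scene config used by the fast unit tests
small_scene <- function(seed, n = 5) {
  scene_config(width_px = 260L, height_px = 260L, n_kernels = n, seed = seed)
}

random_bbox <- function() {
  x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 50)
  bbox(x0, y0, x0 + runif(1, 1, 40), y0 + runif(1, 1, 40))
}

# best-Jaccard match of each truth mask against a label map
truth_jaccards <- function(truths, labels) {
  sapply(truths, function(tr) {
    best <- 0
    for (k in seq_len(max(labels))) {
      mk <- labels == k
      best <- max(best, sum(mk & tr$mask) / sum(mk | tr$mask))
    }
    best
  })
}
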