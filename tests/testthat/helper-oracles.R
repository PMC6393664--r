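# Independent oracles, implemented with plain loops so they share no code
# path with the package internals they check.

# 1-based symmetric mirror reflection
mirror1 <- function(i, n) {
  if (n == 1) return(1L)
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_window_sd <- function(hist, r, c, s) {
  r0 <- max(1, r - s); r1 <- min(nrow(hist), r + s)
  c0 <- max(1, c - s); c1 <- min(ncol(hist), c + s)
  stats::sd(as.vector(hist[r0:r1, c0:c1]))
}

oracle_patch_ssd <- function(hist, ri, ci, rj, cj, p) {
  ssd <- 0
  for (dr in -p:p) for (dc in -p:p) {
    a <- hist[mirror1(ri + dr, nrow(hist)), mirror1(ci + dc, ncol(hist))]
    b <- hist[mirror1(rj + dr, nrow(hist)), mirror1(cj + dc, ncol(hist))]
    ssd <- ssd + (a - b)^2
  }
  ssd
}

# Brute-force quadruple-loop reconstruction sweep (hard class constraint)
oracle_reconstruct <- function(est, hist, mask, p, s, h = NULL) {
  nr <- nrow(est); nc <- ncol(est)
  out <- matrix(0, nr, nc)
  npatch <- (2 * p + 1)^2
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    hi <- if (is.null(h)) {
      max(oracle_window_sd(hist, r, c, s) * sqrt(4 * npatch), 1e-6)
    } else h
    wsum <- 0; acc <- 0
    for (rr in max(1, r - s):min(nr, r + s)) {
      for (cc in max(1, c - s):min(nc, c + s)) {
        if (mask[rr, cc] != mask[r, c]) next
        w <- exp(-oracle_patch_ssd(hist, r, c, rr, cc, p) / hi^2)
        wsum <- wsum + w
        acc <- acc + w * est[rr, cc]
      }
    }
    out[r, c] <- if (wsum > 0) acc / wsum else est[r, c]
  }
  out
}

# Nested-loop block mean
oracle_block_mean <- function(x, f) {
  nr <- nrow(x) %/% f; nc <- ncol(x) %/% f
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- mean(x[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  out
}

# Welch statistic straight from the formula
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

# Brute-force single dilation with the 3x3 (8-connectivity) structuring
# element, looping over every pixel
oracle_dilate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && m[rr, cc])
        out[r, c] <- TRUE
    }
  }
  out
}

# Direct joint-histogram MI (nats)
oracle_mi <- function(a, b, bins) {
  bi <- function(x) {
    rng <- range(x)
    if (rng[2] <= rng[1]) return(rep(1L, length(x)))
    pmin(floor((as.vector(x) - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins)
  }
  ia <- bi(a); ib <- bi(b)
  joint <- matrix(0, bins, bins)
  for (k in seq_along(ia)) joint[ia[k], ib[k]] <- joint[ia[k], ib[k]] + 1
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  mi <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  mi
}

entropy_binned <- function(x, bins) {
  rng <- range(x)
  idx <- pmin(floor((as.vector(x) - rng[1]) / (rng[2] - rng[1]) * bins) + 1L,
              bins)
  p <- tabulate(idx, bins) / length(idx)
  -sum(p[p > 0] * log(p[p > 0]))
}

# small continuous-mode fixture dataset
make_fixture_ds <- function(mode = "continuous") {
  spectral_dataset(
    positions = rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
    mz = rep(list(c(333.15, 333.25, 400.0)), 4),
    intensity = list(c(1, 2, 3), c(4, 5, 6), c(0, 0, 0), c(7, 8, 9)),
    pixel_size_um = 40, mode = mode)
}

# Glyph-phantom replicate runs shared by the improvement and convergence
# acceptance checks; memoised so the replicates are computed once.
.glyph_cache <- new.env(parent = emptyenv())
glyph_replicates <- function(seeds = 1:20) {
  key <- paste0("s", paste(seeds, collapse = "_"))
  if (!is.null(.glyph_cache[[key]])) return(.glyph_cache[[key]])
  cfg <- pbsr_config(clamp_negative = FALSE)
  out <- lapply(seeds, function(s) {
    b <- generate_phantom(phantom_config("glyph", noise_sd = 0.05, seed = s))
    pb <- run_pipeline(b$lr_observed, b$histology, b$mask,
                       target_factor = 4, cfg = cfg)
    li <- linear_upsample(b$lr_observed, 4)
    roi <- b$mask$labels == 2
    ring <- make_ring(roi, 2, clip = b$mask$labels > 0)
    list(
      ssim_pbsr = ssim(as.matrix(pb), b$truth_hr$values),
      ssim_li = ssim(li$values, b$truth_hr$values),
      d_pbsr = cohens_d(as.matrix(pb)[ring$area1], as.matrix(pb)[ring$area2]),
      d_li = cohens_d(li$values[ring$area1], li$values[ring$area2]),
      convergence = attr(pb, "convergence"),
      consistency_rel = max(abs(as.matrix(block_downsample(as.matrix(pb), 4)) -
                                  b$lr_observed$values)) /
        max(b$lr_observed$values))
  })
  .glyph_cache[[key]] <- out
  out
}
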