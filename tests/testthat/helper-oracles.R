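# Independent brute-force oracles for the texture engines and UPGMA.
# These deliberately use naive element-by-element loops, not the package's
# vectorized paths.

# Exhaustive pair enumeration over the 8 unit offsets at `distance`.
oracle_glcm <- function(lev, mask, G, distance = 1) {
  offs <- list(c(0, distance), c(0, -distance), c(distance, 0),
               c(-distance, 0), c(distance, distance),
               c(-distance, -distance), c(distance, -distance),
               c(-distance, distance))
  h <- nrow(lev); w <- ncol(lev)
  P <- matrix(0, G, G)
  for (r in 1:h) for (c in 1:w) {
    if (!mask[r, c]) next
    for (off in offs) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      if (!mask[r2, c2]) next
      P[lev[r, c] + 1, lev[r2, c2] + 1] <- P[lev[r, c] + 1,
                                             lev[r2, c2] + 1] + 1
    }
  }
  P / sum(P)
}

# Literal formula evaluation of the 10 GLCM features by double loop.
oracle_glcm_features <- function(P) {
  G <- nrow(P)
  px <- rowSums(P)
  mu <- 0
  for (i in 1:G) mu <- mu + (i - 1) * px[i]
  s2 <- 0
  for (i in 1:G) s2 <- s2 + ((i - 1) - mu)^2 * px[i]
  u <- e <- h <- inr <- corr <- cs <- cp <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    u <- u + p^2
    if (p > 0) e <- e - p * log2(p)
    h <- h + p / (1 + ((i - 1) - (j - 1))^2)
    inr <- inr + ((i - 1) - (j - 1))^2 * p
    if (s2 > 0) corr <- corr + ((i - 1) - mu) * ((j - 1) - mu) * p / s2
    cs <- cs + ((i - 1) + (j - 1) - 2 * mu)^3 * p
    cp <- cp + ((i - 1) + (j - 1) - 2 * mu)^4 * p
  }
  c(GLCMm = mu, GLCMv = s2, GLCMu = u, GLCMe = e, GLCMh = h, GLCMi = inr,
    GLCMc = corr, GLCMcs = cs, GLCMcp = cp, GLCMmp = max(P))
}

# Explicit per-orientation scan producing (level, length) runs.
oracle_runs <- function(lev, mask, orientation) {
  h <- nrow(lev); w <- ncol(lev)
  lines <- switch(as.character(orientation),
    "0" = lapply(1:h, function(r) cbind(rep(r, w), 1:w)),
    "90" = lapply(1:w, function(c) cbind(1:h, rep(c, h))),
    "45" = lapply(1:(h + w - 1), function(s) {
      rr <- intersect(1:h, (s - w + 1):s)
      rr <- sort(rr, decreasing = TRUE)
      cbind(rr, s + 1 - rr)
    }),
    "135" = lapply(-(h - 1):(w - 1), function(d) {
      rr <- intersect(1:h, (1 - d):(w - d))
      cbind(rr, rr + d)
    }))
  out <- NULL
  for (ln in lines) {
    cur_lev <- NA; cur_len <- 0
    for (k in seq_len(nrow(ln))) {
      r <- ln[k, 1]; c <- ln[k, 2]
      v <- if (mask[r, c]) lev[r, c] else NA
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev)) out <- rbind(out, c(cur_lev, cur_len))
        cur_lev <- v; cur_len <- if (is.na(v)) 0 else 1
      }
    }
    if (!is.na(cur_lev)) out <- rbind(out, c(cur_lev, cur_len))
  }
  if (is.null(out)) data.frame(level = integer(), length = integer()) else
    data.frame(level = out[, 1], length = out[, 2])
}

oracle_glrm <- function(lev, mask, G) {
  runs <- do.call(rbind, lapply(c(0, 45, 90, 135), function(o)
    oracle_runs(lev, mask, o)))
  lmax <- max(runs$length)
  R <- matrix(0, G, lmax)
  for (k in seq_len(nrow(runs)))
    R[runs$level[k] + 1, runs$length[k]] <-
      R[runs$level[k] + 1, runs$length[k]] + 1
  R
}

oracle_glrm_features <- function(R, n_pixels, n_orientations = 4) {
  n_r <- sum(R)
  sr <- lr <- ent <- 0
  for (g in seq_len(nrow(R))) for (l in seq_len(ncol(R))) {
    r <- R[g, l]
    sr <- sr + r / l^2
    lr <- lr + r * l^2
    p <- r / n_r
    if (p > 0) ent <- ent - p * log2(p)
  }
  c(GLRMsr = sr / n_r, GLRMlr = lr / n_r,
    GLRMglnu = sum(rowSums(R)^2) / n_r,
    GLRMrlnu = sum(colSums(R)^2) / n_r,
    GLRMrr = n_r / (n_orientations * n_pixels), GLRMe = ent)
}

# Random masked patch that is guaranteed non-degenerate (a 2x2 in-mask
# block exists, so both engines have pairs/runs to count).
random_patch <- function(seed, min_size = 4, max_size = 12, G = 8) {
  set.seed(seed)
  h <- sample(min_size:max_size, 1)
  w <- sample(min_size:max_size, 1)
  lev <- matrix(sample(0:(G - 1), h * w, replace = TRUE), h, w)
  mask <- matrix(runif(h * w) < 0.8, h, w)
  mask[1:2, 1:2] <- TRUE
  list(lev = lev, mask = mask, G = G)
}

# Textbook UPGMA (size-weighted average linkage) returning the cophenetic
# distance matrix; naive O(n^3) agglomeration.
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  active <- as.list(seq_len(n))
  d <- D
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  sizes <- rep(1, n)
  cl <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  while (length(members) > 1) {
    m <- length(members)
    best <- c(1, 2); bestd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- bestd; coph[b, a] <- bestd
    }
    new_members <- c(members[[i]], members[[j]])
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- sapply(seq_len(m)[-c(i, j)], function(k)
      (ni * d[i, k] + nj * d[j, k]) / (ni + nj))
    keep <- seq_len(m)[-c(i, j)]
    d2 <- matrix(0, m - 1, m - 1)
    if (length(keep)) {
      d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
      d2[m - 1, seq_along(keep)] <- newd
      d2[seq_along(keep), m - 1] <- newd
    }
    d <- d2
    members <- c(members[keep], list(new_members))
  }
  coph
}

# Directional autocorrelation of in-mask intensities at an integer lag.
autocor_at_lag <- function(gray, mask, dr, dc) {
  h <- nrow(gray); w <- ncol(gray)
  a <- c(); b <- c()
  for (r in 1:h) for (c in 1:w) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
    if (mask[r, c] && mask[r2, c2]) {
      a <- c(a, gray[r, c]); b <- c(b, gray[r2, c2])
    }
  }
  cor(a, b)
}

# A small rendered plate shared by segmentation/trait tests.
make_test_plate <- function(n = 5, seed = 11, canvas = c(220, 220),
                            tex = texture_params()) {
  grains <- lapply(seq_len(n), function(i)
    list(shape = grain_shape(14, 8, (i - 1) * pi / max(n, 1)), tex = tex))
  render_plate(grains, canvas = canvas, seed = seed)
}

jaccard <- function(m1, m2) sum(m1 & m2) / sum(m1 | m2)

# Paste a bounding-box mask into full-canvas coordinates.
full_mask <- function(truth_row, canvas_hw) {
  m <- matrix(FALSE, canvas_hw[1], canvas_hw[2])
  bb <- decode_mask_rle(truth_row$mask_rle, truth_row$height,
                        truth_row$width)
  m[truth_row$row0 + seq_len(truth_row$height),
    truth_row$col0 + seq_len(truth_row$width)] <- bb
  m
}
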