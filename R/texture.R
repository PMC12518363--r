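# Omnidirectional second-order texture descriptors: gray-level co-occurrence
# (Haralick) and gray-level run-length (Galloway) statistics accumulated over
# all 8 unit pixel offsets (4 scan orientations for runs).

#' Quantize gray intensities into G levels
#'
#' Uniform binning: `level = floor(gray * G / 256)`, monotone in gray, with
#' levels in `[0, G)`.
#'
#' @param gray numeric vector/matrix of intensities in `[0, 255]`.
#' @param G number of gray levels, `>= 2`.
#' @return integer levels, same shape as `gray`.
#' @export
#' @examples
#' quantize_levels(c(0, 128, 255), G = 32)
quantize_levels <- function(gray, G = 32) {
  if (G < 2) stop("parameter error: G must be >= 2")
  lev <- floor(gray * G / 256)
  lev[lev > G - 1] <- G - 1
  storage.mode(lev) <- "integer"
  lev
}

# The 8 unit offsets (row, col): 4 orientations and their opposites.
glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(c(0L, d), c(0L, -d), c(d, 0L), c(-d, 0L),
       c(d, d), c(-d, -d), c(d, -d), c(-d, d))
}

# Offset a raster: pairs (p, p + off) with both pixels valid; returns the
# level values at p and p + off as two aligned vectors.
shift_pairs <- function(lev, off) {
  h <- nrow(lev); w <- ncol(lev)
  dr <- off[1]; dc <- off[2]
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  if (!length(r1) || !length(c1)) return(NULL)
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Accumulate an omnidirectional gray-level co-occurrence matrix
#'
#' Counts ordered in-mask pixel pairs `(p, p + offset)` for each of the 8
#' unit offsets at the given distance, sums the counts, and normalizes to
#' probabilities.  Because every offset's opposite is also counted, the
#' result is symmetric by construction.
#'
#' @param levels integer raster of quantized levels in `[0, G)`.
#' @param mask logical raster (same shape); `FALSE` pixels are ignored. May
#'   be omitted if `levels` already carries `NA` outside the region.
#' @param G number of gray levels (defaults to `max(levels) + 1`).
#' @param distance offset distance in px, `>= 1`.
#' @return object of class `cooccurrence_matrix`: `P` (G x G probability
#'   matrix), `G`, `pair_count`.
#' @export
#' @examples
#' lev <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
#' glcm_accumulate(lev, G = 2)$P
glcm_accumulate <- function(levels, mask = NULL, G = NULL, distance = 1L) {
  if (distance < 1) stop("parameter error: distance must be >= 1")
  lev <- levels
  storage.mode(lev) <- "integer"
  if (!is.null(mask)) lev[!mask] <- NA_integer_
  if (all(is.na(lev))) stop("degenerate region: empty mask")
  if (is.null(G)) G <- max(lev, na.rm = TRUE) + 1L
  counts <- numeric(G * G)
  for (off in glcm_offsets(distance)) {
    pr <- shift_pairs(lev, off)
    if (is.null(pr) || !length(pr$a)) next
    counts <- counts + tabulate(pr$a * G + pr$b + 1L, nbins = G * G)
  }
  total <- sum(counts)
  if (total == 0)
    stop("degenerate region: no valid neighbour pair at distance ", distance)
  structure(list(P = matrix(counts / total, G, G, byrow = TRUE), G = G,
                 pair_count = total), class = "cooccurrence_matrix")
}

#' GLCM (Haralick-type) features of a co-occurrence matrix
#'
#' With symmetric `P`, marginal mean `mu = sum(i * p_x(i))` and variance
#' `sigma2 = sum((i - mu)^2 * p_x(i))` over levels `i` (0-based):
#' mean, variance, uniformity (energy) `sum(p^2)`, entropy
#' `-sum(p log2 p)`, homogeneity (inverse difference moment)
#' `sum(p / (1 + (i - j)^2))`, inertia (contrast) `sum((i - j)^2 p)`,
#' correlation `sum((i - mu)(j - mu) p) / sigma2` (0 when `sigma2 = 0`),
#' cluster shade `sum((i + j - 2 mu)^3 p)`, cluster prominence
#' `sum((i + j - 2 mu)^4 p)`, and maximum probability.
#'
#' @param M a [glcm_accumulate()] result.
#' @return named numeric vector: `GLCMm`, `GLCMv`, `GLCMu`, `GLCMe`,
#'   `GLCMh`, `GLCMi`, `GLCMc`, `GLCMcs`, `GLCMcp`, `GLCMmp`.
#' @export
glcm_features <- function(M) {
  stopifnot(inherits(M, "cooccurrence_matrix"))
  P <- M$P; G <- M$G
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum((0:(G - 1)) * px)
  s2 <- sum(((0:(G - 1)) - mu)^2 * px)
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  corr <- if (s2 > 0) sum((i - mu) * (j - mu) * P) / s2 else 0
  c(GLCMm = mu,
    GLCMv = s2,
    GLCMu = sum(P^2),
    GLCMe = ent,
    GLCMh = sum(P / (1 + (i - j)^2)),
    GLCMi = sum((i - j)^2 * P),
    GLCMc = corr,
    GLCMcs = sum((i + j - 2 * mu)^3 * P),
    GLCMcp = sum((i + j - 2 * mu)^4 * P),
    GLCMmp = max(P))
}

# Scan lines of a raster along one of the 4 orientations, as lists of
# (row, col) index matrices in scan order.
scan_lines <- function(h, w, orientation) {
  if (orientation == 0) {
    lapply(seq_len(h), function(r) cbind(r, seq_len(w)))
  } else if (orientation == 90) {
    lapply(seq_len(w), function(c) cbind(seq_len(h), c))
  } else if (orientation == 45) {
    # anti-diagonals, scanned up-right
    lapply(seq_len(h + w - 1), function(s) {
      r <- min(s, h):max(1, s - w + 1)
      cbind(r, s + 1 - r)
    })
  } else if (orientation == 135) {
    # main diagonals, scanned down-right
    lapply((-(h - 1)):(w - 1), function(d) {
      r <- max(1, 1 - d):min(h, w - d)
      cbind(r, r + d)
    })
  } else stop("orientation must be one of 0, 45, 90, 135")
}

#' Extract constant-level runs along one scan orientation
#'
#' Runs are maximal segments of consecutive in-mask pixels sharing one
#' quantized level; out-of-mask pixels break runs.  Every in-mask pixel
#' belongs to exactly one run per orientation.
#'
#' @param levels integer level raster (`NA` allowed outside the mask).
#' @param mask logical raster or `NULL`.
#' @param orientation scan direction in degrees: 0 (rows), 45
#'   (anti-diagonals), 90 (columns) or 135 (diagonals).
#' @return data frame with columns `level` and `length`, one row per run.
#' @export
#' @examples
#' extract_runs(matrix(c(0L, 0L, 1L, 1L, 1L, 0L), 1), orientation = 0)
extract_runs <- function(levels, mask = NULL, orientation = 0) {
  lev <- levels
  if (!is.null(mask)) lev[!mask] <- NA_integer_
  if (is.vector(lev)) lev <- matrix(lev, 1)
  out_lev <- integer(0); out_len <- integer(0)
  for (line in scan_lines(nrow(lev), ncol(lev), orientation)) {
    v <- lev[line]
    v[is.na(v)] <- -1L
    r <- rle(v)
    keep <- r$values >= 0
    out_lev <- c(out_lev, r$values[keep])
    out_len <- c(out_len, r$lengths[keep])
  }
  data.frame(level = out_lev, length = out_len)
}

#' Accumulate an omnidirectional gray-level run-length matrix
#'
#' Runs from the four scan orientations (0, 45, 90, 135 degrees) are pooled
#' into a level x run-length count matrix.  The 8 directions of the
#' co-occurrence step collapse to 4 orientations here: a run read forward or
#' backward is the same run.  Invariant:
#' `sum(l * r(g, l)) = 4 * n_pixels`.
#'
#' @inheritParams extract_runs
#' @param G number of gray levels (defaults to `max(levels) + 1`).
#' @return object of class `runlength_set`: `R` (G x Lmax count matrix),
#'   `G`, `n_runs`, `n_pixels`, `n_orientations = 4`.
#' @export
glrm_accumulate <- function(levels, mask = NULL, G = NULL) {
  lev <- levels
  storage.mode(lev) <- "integer"
  if (!is.null(mask)) lev[!mask] <- NA_integer_
  n_pixels <- sum(!is.na(lev))
  if (n_pixels == 0) stop("degenerate region: empty mask")
  if (is.null(G)) G <- max(lev, na.rm = TRUE) + 1L
  runs <- do.call(rbind, lapply(c(0, 45, 90, 135), function(o)
    extract_runs(lev, orientation = o)))
  lmax <- max(runs$length)
  R <- matrix(0, G, lmax)
  tab <- table(factor(runs$level, levels = 0:(G - 1)),
               factor(runs$length, levels = 1:lmax))
  R[] <- as.numeric(tab)
  structure(list(R = R, G = G, n_runs = nrow(runs), n_pixels = n_pixels,
                 n_orientations = 4L), class = "runlength_set")
}

#' GLRM (Galloway-type) features of a run-length set
#'
#' With run counts `r(g, l)` and `n_r = sum(r)`: short-run emphasis
#' `sum(r / l^2) / n_r`, long-run emphasis `sum(r * l^2) / n_r`, gray-level
#' non-uniformity `sum_g (sum_l r)^2 / n_r`, run-length non-uniformity
#' `sum_l (sum_g r)^2 / n_r`, run ratio `n_r / (n_orientations * n_pixels)`,
#' and run entropy `-sum((r / n_r) log2 (r / n_r))`.
#'
#' @param S a [glrm_accumulate()] result (or any list with elements `R`,
#'   `n_pixels`, `n_orientations`).
#' @return named numeric vector: `GLRMsr`, `GLRMlr`, `GLRMglnu`,
#'   `GLRMrlnu`, `GLRMrr`, `GLRMe`.
#' @export
glrm_features <- function(S) {
  R <- S$R
  n_r <- sum(R)
  stopifnot(n_r > 0)
  l <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  p <- R / n_r
  nz <- p > 0
  c(GLRMsr = sum(R / l^2) / n_r,
    GLRMlr = sum(R * l^2) / n_r,
    GLRMglnu = sum(rowSums(R)^2) / n_r,
    GLRMrlnu = sum(colSums(R)^2) / n_r,
    GLRMrr = n_r / (S$n_orientations * S$n_pixels),
    GLRMe = -sum(p[nz] * log2(p[nz])))
}
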