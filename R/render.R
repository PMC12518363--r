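#' Elliptical grain silhouette
#'
#' @param a,b semi-axes in pixels (major, minor); the full minor axis `2*b`
#'   must be at least 8 px so the surface model has room to act.
#' @param theta orientation of the major axis in radians, measured from the
#'   image row direction.
#' @return an object of class `grain_shape`.
#' @export
grain_shape <- function(a, b, theta = 0) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("invalid geometry: ellipse semi-axes must be positive")
  if (2 * min(a, b) < 8)
    stop("invalid geometry: full axes must be >= 8 px")
  structure(list(a = a, b = b, theta = theta), class = "grain_shape")
}

# Stationary band-limited noise field: white noise smoothed by a separable
# Gaussian kernel (SD = scale px), rescaled to unit variance.  The noise
# field is generated with a margin and convolved in "valid" mode so edge
# pixels have the same variance as interior ones.
smoothed_noise <- function(h, w, scale) {
  if (scale < 0.3) return(matrix(rnorm(h * w), h, w))
  hw <- max(1L, as.integer(ceiling(3 * scale)))
  t <- seq(-hw, hw)
  k <- exp(-t^2 / (2 * scale^2))
  k <- k / sum(k)
  z <- matrix(rnorm((h + 2 * hw) * (w + 2 * hw)), h + 2 * hw, w + 2 * hw)
  band <- function(n) {
    m <- matrix(0, n, n + 2 * hw)
    for (j in seq_along(k)) m[cbind(seq_len(n), seq_len(n) + j - 1L)] <- k[j]
    m
  }
  f <- band(h) %*% z %*% t(band(w))
  f / sum(k^2)  # smoothing shrinks the SD by sum(k^2) for a separable kernel
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Render one synthetic grain patch
#'
#' Rasterizes an elliptical grain with the surface model of
#' [texture_params()]: in-mask intensity is the base gray minus a parabolic
#' rim shading, plus band-limited roughness noise, plus a sinusoid in the
#' grain's own frame.  With `wrinkle_axis = "along"` the ridges run along the
#' major axis (the sinusoid's phase varies in the across-axis coordinate);
#' with `"across"` the folds are transverse.  Out-of-mask pixels are left at
#' `NA`.  Identical `(shape, tex, seed)` give bit-identical output.
#'
#' @param shape a [grain_shape()].
#' @param tex a [texture_params()].
#' @param seed integer seed for the grain's noise and wrinkle phase.
#' @return a list of class `grain_patch`: `gray` (integer matrix, `NA`
#'   outside the mask), `rgb` (height x width x 3 array, `NA` outside),
#'   `mask` (logical matrix), `shape`, `tex`.
#' @export
#' @examples
#' g <- render_grain(grain_shape(16, 9, pi / 6), texture_params(), seed = 1)
#' table(g$mask)
render_grain <- function(shape, tex, seed) {
  stopifnot(inherits(shape, "grain_shape"), inherits(tex, "texture_params"))
  a <- shape$a; b <- shape$b; th <- shape$theta
  ex <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ey <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  pad <- 2L
  hh <- as.integer(2 * (ceiling(ex) + pad) + 1)
  ww <- as.integer(2 * (ceiling(ey) + pad) + 1)
  cr <- (hh + 1) / 2; cc <- (ww + 1) / 2
  rows <- matrix(seq_len(hh) - cr, hh, ww)
  cols <- matrix(seq_len(ww) - cc, hh, ww, byrow = TRUE)
  # grain-frame coordinates: u along the major axis, v across it
  u <- cos(th) * rows + sin(th) * cols
  v <- -sin(th) * rows + cos(th) * cols
  r2 <- (u / a)^2 + (v / b)^2
  mask <- r2 <= 1
  intensity <- with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    field <- tex$base_gray - tex$shading_depth * r2
    if (tex$wrinkle_amp > 0) {
      coord <- if (tex$wrinkle_axis == "along") v else u
      field <- field +
        tex$wrinkle_amp * sin(2 * pi * tex$wrinkle_freq / 100 * coord + phase)
    }
    if (tex$roughness_amp > 0)
      field <- field + tex$roughness_amp *
        smoothed_noise(hh, ww, tex$roughness_scale)
    field
  })
  gray <- matrix(NA_integer_, hh, ww)
  gray[mask] <- as.integer(round(clip255(intensity[mask])))
  rgb <- array(NA_real_, c(hh, ww, 3))
  for (ch in 1:3) {
    plane <- matrix(NA_real_, hh, ww)
    plane[mask] <- round(clip255(
      tex$base_color[ch] + (intensity[mask] - tex$base_gray)))
    rgb[, , ch] <- plane
  }
  structure(list(gray = gray, rgb = rgb, mask = mask, shape = shape,
                 tex = tex), class = "grain_patch")
}

encode_mask_rle <- function(mask) {
  r <- rle(as.vector(mask))
  paste0(ifelse(r$values, "t", "f"), r$lengths, collapse = ";")
}

#' @rdname render_plate
#' @param rle run-length string from the ground-truth table.
#' @param height,width bounding-box dimensions of the mask.
#' @export
decode_mask_rle <- function(rle, height, width) {
  parts <- strsplit(rle, ";", fixed = TRUE)[[1]]
  vals <- substr(parts, 1, 1) == "t"
  lens <- as.integer(substring(parts, 2))
  matrix(rep(vals, lens), height, width)
}

#' Render a plate of grains on a near-white background
#'
#' Places pre-specified grains at random non-overlapping positions (bounding
#' boxes separated by at least `min_gap` px and not touching the border) on a
#' uniform near-white background with mild discrete noise.
#'
#' @param grains list of `list(shape = grain_shape, tex = texture_params)`;
#'   may be empty.
#' @param canvas `c(width, height)` in pixels.
#' @param background_gray background intensity, `>= 245`.
#' @param bg_noise half-range of the uniform integer background jitter.
#' @param min_gap minimum gap between grain bounding boxes, px.
#' @param seed integer master seed; each grain's texture, its placement and
#'   the background use named substreams, so earlier grains are unaffected
#'   when more are added.
#' @param max_tries placement attempts per grain before a capacity error.
#' @return a list of class `grain_plate`: `image` (height x width x 3 array,
#'   0-255), `gray` (integer matrix), `truth` (data frame, one row per grain:
#'   identifiers, ellipse geometry, the texture parameters actually used, a
#'   0-based half-open bounding box and an RLE-encoded mask), and `masks`
#'   (list of logical bounding-box masks).
#' @export
#' @examples
#' pl <- render_plate(list(list(shape = grain_shape(12, 7),
#'                              tex = texture_params())),
#'                    canvas = c(80, 80), seed = 1)
#' pl$truth$area
render_plate <- function(grains, canvas = c(416, 416), background_gray = 250,
                         bg_noise = 2, min_gap = 4, seed = 1L,
                         max_tries = 200L) {
  stopifnot(background_gray >= 245, length(canvas) == 2)
  W <- as.integer(canvas[1]); H <- as.integer(canvas[2])
  patches <- lapply(seq_along(grains), function(i) {
    g <- grains[[i]]
    render_grain(g$shape, g$tex, substream_seed(seed, paste0("grain.", i)))
  })
  if (length(patches)) {
    need <- sum(vapply(patches, function(p)
      prod(dim(p$mask) + 2 * min_gap), 0))
    if (need > W * H)
      stop("canvas too small for ", length(patches), " grains at min_gap ",
           min_gap)
  }
  gray <- with_seed(substream_seed(seed, "background"), {
    matrix(as.integer(clip255(background_gray +
      sample(-bg_noise:bg_noise, H * W, replace = TRUE))), H, W)
  })
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- gray
  occ <- matrix(FALSE, H, W)
  truth <- vector("list", length(patches))
  masks <- vector("list", length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    ph <- nrow(p$mask); pw <- ncol(p$mask)
    if (ph + 2 > H || pw + 2 > W)
      stop("capacity error placing grain ", i, ": patch exceeds canvas")
    placed <- FALSE
    with_seed(substream_seed(seed, paste0("place.", i)), {
      for (t in seq_len(max_tries)) {
        r0 <- sample.int(H - ph - 1L, 1L) + 1L  # top row, keeps 1-px border
        c0 <- sample.int(W - pw - 1L, 1L) + 1L
        rg <- max(1L, r0 - min_gap):min(H, r0 + ph - 1L + min_gap)
        cg <- max(1L, c0 - min_gap):min(W, c0 + pw - 1L + min_gap)
        if (!any(occ[rg, cg])) {
          occ[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L)] <- TRUE
          rows <- r0:(r0 + ph - 1L); cols <- c0:(c0 + pw - 1L)
          sub <- gray[rows, cols]
          sub[p$mask] <- p$gray[p$mask]
          gray[rows, cols] <- sub
          for (ch in 1:3) {
            sub <- img[rows, cols, ch]
            sub[p$mask] <- p$rgb[, , ch][p$mask]
            img[rows, cols, ch] <- sub
          }
          truth[[i]] <- data.frame(
            grain = i, row0 = r0 - 1L, col0 = c0 - 1L, height = ph,
            width = pw, area = sum(p$mask),
            center_row = r0 - 1 + (ph - 1) / 2,
            center_col = c0 - 1 + (pw - 1) / 2,
            a = p$shape$a, b = p$shape$b, theta = p$shape$theta,
            base_gray = p$tex$base_gray, roughness_amp = p$tex$roughness_amp,
            roughness_scale = p$tex$roughness_scale,
            wrinkle_amp = p$tex$wrinkle_amp,
            wrinkle_freq = p$tex$wrinkle_freq,
            wrinkle_axis = p$tex$wrinkle_axis,
            shading_depth = p$tex$shading_depth,
            mask_rle = encode_mask_rle(p$mask),
            stringsAsFactors = FALSE)
          masks[[i]] <- p$mask
          placed <- TRUE
          break
        }
      }
    })
    if (!placed)
      stop("capacity error: could not place grain ", i, " after ",
           max_tries, " tries")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(grain = integer(), row0 = integer(), col0 = integer(),
               height = integer(), width = integer(), area = integer())
  structure(list(image = img, gray = gray, truth = truth, masks = masks,
                 canvas = c(W, H), seed = seed), class = "grain_plate")
}
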