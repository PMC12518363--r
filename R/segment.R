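#' Convert 8-bit RGB values to gray intensity (BT.601 luma)
#'
#' `gray = floor(0.299 R + 0.587 G + 0.114 B + 0.5)` (round half-up), the
#' ITU-R BT.601 luma of the pixel.
#'
#' @param r,g,b numeric vectors or matrices of 8-bit channel values (0-255).
#' @return values in `[0, 255]`, same shape as the inputs.
#' @export
#' @examples
#' rgb_to_gray(255, 0, 0)  # 76
rgb_to_gray <- function(r, g, b) {
  floor(0.299 * r + 0.587 * g + 0.114 * b + 0.5)
}

#' @rdname rgb_to_gray
#' @param image height x width x 3 array of 8-bit RGB values.
#' @export
image_to_gray <- function(image) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  g <- rgb_to_gray(image[, , 1], image[, , 2], image[, , 3])
  matrix(g, dim(image)[1], dim(image)[2])
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels of
# diagonally adjacent foreground pixels with a union-find over label ids.
label_components8 <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(round(lab)), nrow(fg), ncol(fg))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry)
  }
  h <- nrow(lab); w <- ncol(lab)
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- 1:(h - 1); r2 <- r1 + d[1]
    c1 <- if (d[2] > 0) 1:(w - 1) else 2:w
    c2 <- c1 + d[2]
    a <- lab[r1, c1]; b <- lab[r2, c2]
    pair <- a > 0 & b > 0 & a != b
    if (any(pair)) {
      ap <- a[pair]; bp <- b[pair]
      for (k in seq_along(ap)) union2(ap[k], bp[k])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment grains from a white-background plate image
#'
#' Global Otsu threshold on the BT.601 gray image (foreground = darker than
#' the threshold), one morphological opening of radius 1 to shed threshold
#' speckle, 8-connected component labeling, then size and border filters.
#' Regions are returned in reading order of their centroids (top-to-bottom,
#' then left-to-right).
#'
#' @param image height x width x 3 array of 8-bit RGB values (0-255), e.g.
#'   from [read_plate_png()] or a [render_plate()] `$image`.
#' @param min_area minimum component area in px^2; smaller components are
#'   dropped.
#' @param exclude_border drop components touching the image border.
#' @return list of `grain_region` objects, each with `mask` (logical matrix
#'   over the bounding box), `bbox` (`c(row0, col0, height, width)`, 0-based
#'   half-open), `pixels_rgb` (area x 3 matrix), `pixels_gray`, `area`,
#'   `centroid` (row, col; 0-based), `orientation` (major-axis angle,
#'   radians), and `gray` (bounding-box gray raster, `NA` outside the mask).
#' @export
#' @examples
#' pl <- render_plate(list(list(shape = grain_shape(12, 7),
#'                              tex = texture_params())),
#'                    canvas = c(96, 96), seed = 1)
#' length(segment_grains(pl$image))
segment_grains <- function(image, min_area = 200, exclude_border = TRUE) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("format error: expected an RGB image array (height x width x 3)")
  if (max(image, na.rm = TRUE) > 255 || min(image, na.rm = TRUE) < 0)
    stop("format error: expected 8-bit channel values in [0, 255]")
  gray <- image_to_gray(image)
  thr <- EBImage::otsu(EBImage::Image(gray / 255)) * 255
  fg <- gray < thr
  fg <- EBImage::opening(EBImage::Image(fg * 1),
                         EBImage::makeBrush(3, "disc")) > 0.5
  fg <- matrix(as.vector(fg), nrow(gray), ncol(gray))
  lab <- label_components8(fg)
  n <- max(lab)
  if (n == 0) return(list())
  h <- nrow(lab); w <- ncol(lab)
  regions <- list()
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    if (exclude_border &&
        (min(idx[, 1]) == 1 || max(idx[, 1]) == h ||
         min(idx[, 2]) == 1 || max(idx[, 2]) == w)) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    mask <- lab[r0:r1, c0:c1, drop = FALSE] == i
    px_r <- image[, , 1][idx]; px_g <- image[, , 2][idx]
    px_b <- image[, , 3][idx]
    grayv <- rgb_to_gray(px_r, px_g, px_b)
    graster <- matrix(NA_real_, r1 - r0 + 1, c1 - c0 + 1)
    graster[mask] <- gray[idx]
    # centroid and principal-axis orientation from second central moments
    mr <- mean(idx[, 1]); mc <- mean(idx[, 2])
    mu20 <- mean((idx[, 1] - mr)^2); mu02 <- mean((idx[, 2] - mc)^2)
    mu11 <- mean((idx[, 1] - mr) * (idx[, 2] - mc))
    regions[[length(regions) + 1L]] <- structure(list(
      mask = mask, bbox = c(row0 = r0 - 1L, col0 = c0 - 1L,
                            height = r1 - r0 + 1L, width = c1 - c0 + 1L),
      pixels_rgb = cbind(R = px_r, G = px_g, B = px_b),
      pixels_gray = grayv, area = nrow(idx),
      centroid = c(row = mr - 1, col = mc - 1),
      orientation = 0.5 * atan2(2 * mu11, mu20 - mu02),
      gray = graster), class = "grain_region")
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) r$centroid[1], 0),
               vapply(regions, function(r) r$centroid[2], 0))
  regions[ord]
}

#' @rdname segment_grains
#' @param region a `grain_region`.
#' @return `grain_grayscale`: the per-pixel BT.601 gray intensities of the
#'   in-mask pixels.
#' @export
grain_grayscale <- function(region) {
  stopifnot(inherits(region, "grain_region"), region$area > 0)
  rgb_to_gray(region$pixels_rgb[, 1], region$pixels_rgb[, 2],
              region$pixels_rgb[, 3])
}

#' Read a plate PNG as an 8-bit RGB array
#'
#' @param path PNG (or via `png::readPNG`-compatible reader) file path.
#' @return height x width x 3 array of integer values 0-255.
#' @export
read_plate_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}
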