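# Per-grain color descriptors: channel means in four color spaces.

# sRGB (0-255) -> YCbCr, BT.601 full range.
rgb_to_ycbcr <- function(r, g, b) {
  cbind(Y = 0.299 * r + 0.587 * g + 0.114 * b,
        Cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
        Cr = 128 + 0.5 * r - 0.418688 * g - 0.081312 * b)
}

# Circular mean of angles in degrees, result in [0, 360).
circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (m + 360) %% 360
}

#' Color-space means of a grain region
#'
#' Arithmetic means of the in-mask pixel components in RGB, HSV (hue in
#' degrees, averaged circularly; S and V in `[0, 1]`), CIELAB (sRGB under
#' D65; L in `[0, 100]`), and full-range BT.601 YCbCr (0-255).
#'
#' @param region a `grain_region` from [segment_grains()], or any list with
#'   a `pixels_rgb` matrix of 8-bit values.
#' @return named numeric vector `R, G, B, H, S, V, L, a, b, Y, Cr, Cb`.
#' @export
#' @examples
#' reg <- list(pixels_rgb = cbind(R = 255, G = 0, B = 0))
#' color_means(reg)[c("H", "S", "V")]
color_means <- function(region) {
  px <- region$pixels_rgb
  stopifnot(!is.null(px), nrow(px) > 0)
  r <- px[, 1]; g <- px[, 2]; b <- px[, 3]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  lab <- grDevices::convertColor(cbind(r, g, b) / 255, from = "sRGB",
                                 to = "Lab")
  ycc <- rgb_to_ycbcr(r, g, b)
  c(R = mean(r), G = mean(g), B = mean(b),
    H = circular_mean_deg(hsv[1, ] * 360),
    S = mean(hsv[2, ]), V = mean(hsv[3, ]),
    L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]),
    Y = mean(ycc[, "Y"]), Cr = mean(ycc[, "Cr"]), Cb = mean(ycc[, "Cb"]))
}
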