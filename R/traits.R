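#' Trait name sets
#'
#' `texture_trait_names()` returns the 16 texture descriptors (10 GLCM + 6
#' GLRM); `color_trait_names()` the 12 color-space means;
#' `trait_table_columns()` the full fixed CSV header of a trait table.
#'
#' @return character vectors.
#' @export
texture_trait_names <- function() {
  c("GLCMm", "GLCMv", "GLCMu", "GLCMe", "GLCMh", "GLCMi", "GLCMc",
    "GLCMcs", "GLCMcp", "GLCMmp",
    "GLRMsr", "GLRMlr", "GLRMglnu", "GLRMrlnu", "GLRMrr", "GLRMe")
}

#' @rdname texture_trait_names
#' @export
color_trait_names <- function() {
  c("R", "G", "B", "H", "S", "V", "L", "a", "b", "Y", "Cr", "Cb")
}

#' @rdname texture_trait_names
#' @export
trait_table_columns <- function() {
  c("genotype", "year", "plate", "grain",
    texture_trait_names(), color_trait_names())
}

#' Texture and color traits of one grain region
#'
#' Grayscale (BT.601) -> quantization to `G` levels -> omnidirectional GLCM
#' and GLRM -> 16 texture features, plus the 12 color means.
#'
#' @param region a `grain_region` from [segment_grains()].
#' @param levels number of gray levels `G` for quantization.
#' @param distance GLCM offset distance in px.
#' @return named numeric vector of the 28 trait values.
#' @export
grain_traits <- function(region, levels = 32, distance = 1) {
  lev <- quantize_levels(region$gray, G = levels)
  M <- glcm_accumulate(lev, G = levels, distance = distance)
  S <- glrm_accumulate(lev, G = levels)
  c(glcm_features(M), glrm_features(S), color_means(region))
}

#' Extract the trait table of one plate image
#'
#' Segments the plate and computes the 16 texture + 12 color traits per
#' grain.  Grains for which the co-occurrence step is degenerate (no valid
#' neighbour pair) are dropped with a warning.
#'
#' @param image height x width x 3 RGB array (0-255).
#' @param genotype,year,plate identifiers stored with every row.
#' @param levels gray-level count `G`.
#' @param distance GLCM offset distance, px.
#' @param min_area,exclude_border segmentation filters, see
#'   [segment_grains()].
#' @return data frame with the columns of [trait_table_columns()], one row
#'   per retained grain.
#' @export
#' @examples
#' pl <- render_plate(list(list(shape = grain_shape(12, 7),
#'                              tex = texture_params())),
#'                    canvas = c(96, 96), seed = 1)
#' extract_traits(pl$image, plate = "demo")[, 1:6]
extract_traits <- function(image, genotype = NA_character_,
                           year = NA_integer_, plate = NA_character_,
                           levels = 32, distance = 1, min_area = 200,
                           exclude_border = TRUE) {
  regions <- segment_grains(image, min_area = min_area,
                            exclude_border = exclude_border)
  rows <- list()
  for (i in seq_along(regions)) {
    vals <- tryCatch(grain_traits(regions[[i]], levels = levels,
                                  distance = distance),
                     error = function(e) {
                       warning("dropping grain ", i, " of plate ", plate,
                               ": ", conditionMessage(e), call. = FALSE)
                       NULL
                     })
    if (is.null(vals)) next
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = genotype, year = year, plate = plate, grain = i,
      as.list(vals), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(matrix(nrow = 0, ncol = length(trait_table_columns())))
    names(out) <- trait_table_columns()
    return(out)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Drop grains whose texture traits are extreme
#'
#' For each of the 16 texture traits, the mean and SD are computed once over
#' the unfiltered table; any grain with `|z| > k` in any texture trait is
#' removed (single pass, no iteration).  A trait with zero SD contributes
#' `z = 0` for every grain.
#'
#' @param table a trait table ([extract_traits()] output or compatible).
#' @param k SD multiplier; default 3.
#' @param traits columns to screen; defaults to the 16 texture traits
#'   present in the table.
#' @return the filtered table, with an attribute `n_dropped`.
#' @export
filter_outliers <- function(table, k = 3, traits = NULL) {
  if (is.null(traits))
    traits <- intersect(texture_trait_names(), names(table))
  if (nrow(table) < 3) {
    warning("fewer than 3 rows: outlier filter not applied")
    return(table)
  }
  keep <- rep(TRUE, nrow(table))
  for (tr in traits) {
    v <- table[[tr]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) next
    keep <- keep & abs(v - mean(v)) / s <= k
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}
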