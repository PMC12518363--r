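#' Texture parameters for one synthetic grain
#'
#' Describes the surface model used by [render_grain()]: a base coat
#' intensity, curvature shading towards the rim, band-limited roughness
#' noise, and a sinusoidal wrinkle pattern oriented in the grain's own frame.
#'
#' @param base_gray mean surface intensity of the unwrinkled coat (0-255).
#' @param base_color RGB triple (0-255) of the unwrinkled coat; per-pixel
#'   color is `base_color` shifted by the rendered intensity deviation so the
#'   luma of the rendered color tracks the gray channel.
#' @param roughness_amp standard deviation, in gray units, of the
#'   band-limited noise field added to the intensity (0 = perfectly smooth).
#' @param roughness_scale spatial correlation length of that noise, in
#'   pixels (the SD of the Gaussian smoothing kernel applied to white noise).
#' @param wrinkle_amp peak intensity modulation, in gray units, of the
#'   sinusoidal ridge pattern.
#' @param wrinkle_freq ridge count per 100 pixels.
#' @param wrinkle_axis `"along"` (ridges run along the grain's major axis;
#'   intensity varies across it) or `"across"` (transverse folds; intensity
#'   varies along the major axis).
#' @param shading_depth intensity drop at the grain rim (gray units),
#'   emulating 3-D curvature.
#' @return an object of class `texture_params` (a validated list).
#' @export
#' @examples
#' texture_params(base_gray = 150, roughness_amp = 10)
texture_params <- function(base_gray = 140,
                           base_color = c(170, 130, 80),
                           roughness_amp = 8,
                           roughness_scale = 2,
                           wrinkle_amp = 10,
                           wrinkle_freq = 6,
                           wrinkle_axis = c("along", "across"),
                           shading_depth = 25) {
  wrinkle_axis <- match.arg(wrinkle_axis)
  stopifnot(length(base_color) == 3L, all(base_color >= 0 & base_color <= 255),
            base_gray >= 0, base_gray <= 255)
  amps <- c(roughness_amp = roughness_amp, roughness_scale = roughness_scale,
            wrinkle_amp = wrinkle_amp, wrinkle_freq = wrinkle_freq,
            shading_depth = shading_depth)
  if (any(amps < 0))
    stop("texture amplitudes and scales must be >= 0: ",
         paste(names(amps)[amps < 0], collapse = ", "))
  structure(list(base_gray = base_gray, base_color = as.numeric(base_color),
                 roughness_amp = roughness_amp,
                 roughness_scale = roughness_scale,
                 wrinkle_amp = wrinkle_amp, wrinkle_freq = wrinkle_freq,
                 wrinkle_axis = wrinkle_axis, shading_depth = shading_depth),
            class = "texture_params")
}

# Continuous texture_params fields that panel effects may act on.
tex_numeric_fields <- c("base_gray", "roughness_amp", "roughness_scale",
                        "wrinkle_amp", "wrinkle_freq", "shading_depth")

# Fill a named effect vector to the full field set (absent fields -> 0).
expand_effect <- function(x, what) {
  out <- setNames(numeric(length(tex_numeric_fields)), tex_numeric_fields)
  if (is.null(x)) return(out)
  if (is.null(names(x)) && length(x) == 1L) {
    out[] <- x
    return(out)
  }
  bad <- setdiff(names(x), tex_numeric_fields)
  if (length(bad))
    stop(what, ": unknown texture parameter(s) ", paste(bad, collapse = ", "))
  out[names(x)] <- x
  out
}

#' Configuration of a synthetic multi-year grain panel
#'
#' Defines the sampling design emulated by [generate_panel()]: a set of
#' genotypes grown in several harvest years, with additive genotype and year
#' effects on the grain-surface texture parameters, and a germination model
#' with a year main effect and an optional weak trait linkage.
#'
#' Defaults describe a typical genebank storage panel: 44 genotypes harvested in
#' 2003, 2004, 2009 and 2014 with about 20 grains per genotype-year cell, a
#' negative year-rank slope on roughness (grains from later harvests, i.e.
#' shorter storage, are smoother), and germination declining with storage
#' duration.
#'
#' @param n_genotypes number of genotypes (lines), `>= 2`.
#' @param years strictly increasing integer vector of harvest years.
#' @param grains_per_cell grains rendered per genotype-year cell, `>= 1`.
#' @param genotype_sd named numeric vector: per-texture-parameter SD of the
#'   genotype random effects (names among `base_gray`, `roughness_amp`,
#'   `roughness_scale`, `wrinkle_amp`, `wrinkle_freq`, `shading_depth`).
#' @param year_slope named numeric vector: per-texture-parameter linear
#'   trend per unit of year rank.
#' @param noise_sd named numeric vector: per-grain residual SD.
#' @param base [texture_params()] giving the global mean surface.
#' @param germination list with elements `intercept` (logit scale),
#'   `year_offsets` (named per year, logit scale), `linkage` (coefficient on
#'   a standardized trait; 0 disables), `linked_trait` (texture parameter
#'   name the linkage acts through), `noise_sd` (logit-scale cell noise).
#' @param seed integer master seed; all randomness in the generators flows
#'   from it through named substreams.
#' @return an object of class `panel_config`.
#' @export
#' @examples
#' cfg <- panel_config(n_genotypes = 4, grains_per_cell = 3, seed = 1)
panel_config <- function(n_genotypes = 44,
                         years = c(2003L, 2004L, 2009L, 2014L),
                         grains_per_cell = 20,
                         genotype_sd = c(base_gray = 8, roughness_amp = 3,
                                         wrinkle_amp = 3),
                         year_slope = c(roughness_amp = -2),
                         noise_sd = c(base_gray = 3, roughness_amp = 1,
                                      wrinkle_amp = 1),
                         base = texture_params(roughness_amp = 14),
                         germination = list(intercept = 1.2,
                                            year_offsets = NULL,
                                            linkage = 0,
                                            linked_trait = "roughness_amp",
                                            noise_sd = 0.3),
                         seed = 1L) {
  if (n_genotypes < 2) stop("n_genotypes must be >= 2")
  if (grains_per_cell < 1) stop("grains_per_cell must be >= 1")
  years <- as.integer(years)
  if (length(years) < 1 || any(diff(years) <= 0))
    stop("years must be strictly increasing")
  if (is.null(germination$year_offsets)) {
    # germination declines with storage duration: oldest harvest lowest
    germination$year_offsets <- setNames(
      seq(-0.25 * (length(years) - 1), 0, length.out = length(years)), years)
  }
  if (is.null(germination$linkage)) germination$linkage <- 0
  if (is.null(germination$noise_sd)) germination$noise_sd <- 0
  structure(list(n_genotypes = as.integer(n_genotypes), years = years,
                 grains_per_cell = as.integer(grains_per_cell),
                 genotype_sd = expand_effect(genotype_sd, "genotype_sd"),
                 year_slope = expand_effect(year_slope, "year_slope"),
                 noise_sd = expand_effect(noise_sd, "noise_sd"),
                 base = base, germination = germination,
                 seed = as.integer(seed)),
            class = "panel_config")
}
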