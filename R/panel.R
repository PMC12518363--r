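#' Generate a multi-year genotype panel of grain plates
#'
#' For each genotype x harvest-year cell, the grain texture parameters are
#' the global mean plus a genotype random effect (drawn once per genotype
#' from a normal with SD `genotype_sd`), plus `year_slope` times the year
#' rank, plus per-grain residual noise.  One plate is rendered per cell.
#' Everything is reproducible from `cfg$seed` via named substreams.
#'
#' @param cfg a [panel_config()].
#' @param render if `FALSE`, skip rasterization and return only the metadata
#'   with the true per-grain texture parameters (fast path for statistical
#'   simulation, where the rendered pixels would be discarded anyway).
#' @param dir optional directory: rendered plates are written there as 8-bit
#'   RGB PNGs (`<plate>.png`) as they are produced instead of being kept in
#'   memory.
#' @return a list of class `grain_panel`: `metadata` (one row per grain:
#'   `genotype`, `year`, `plate`, `grain` and the true texture parameters),
#'   `truth` (per-grain geometry + RLE masks, when rendered), `plates`
#'   (named list of [render_plate()] results, when rendered in memory, else
#'   file paths), `config`.
#' @export
#' @examples
#' pan <- generate_panel(panel_config(n_genotypes = 3, grains_per_cell = 2,
#'                                    seed = 7), render = FALSE)
#' nrow(pan$metadata)
generate_panel <- function(cfg, render = TRUE, dir = NULL) {
  stopifnot(inherits(cfg, "panel_config"))
  seed <- cfg$seed
  years <- cfg$years
  ranks <- seq_along(years)
  genos <- sprintf("g%02d", seq_len(cfg$n_genotypes))
  base <- unlist(cfg$base[tex_numeric_fields])
  geno_eff <- lapply(seq_len(cfg$n_genotypes), function(g)
    with_seed(substream_seed(seed, paste0("genotype.", g)), {
      eff <- rnorm(length(tex_numeric_fields)) * cfg$genotype_sd
      axis <- sample(c("along", "across"), 1L)
      list(eff = eff, axis = axis)
    }))
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  meta <- list(); truth <- list(); plates <- list()
  for (g in seq_len(cfg$n_genotypes)) {
    for (yi in ranks) {
      plate_id <- sprintf("%s_y%d", genos[g], years[yi])
      cell_mean <- base + geno_eff[[g]]$eff + cfg$year_slope * ranks[yi]
      grains <- with_seed(substream_seed(seed, paste0("cell.", plate_id)), {
        lapply(seq_len(cfg$grains_per_cell), function(j) {
          par <- cell_mean + rnorm(length(tex_numeric_fields)) * cfg$noise_sd
          par[c("roughness_amp", "roughness_scale", "wrinkle_amp",
                "wrinkle_freq", "shading_depth")] <-
            pmax(par[c("roughness_amp", "roughness_scale", "wrinkle_amp",
                       "wrinkle_freq", "shading_depth")], 0)
          par["base_gray"] <- min(max(par["base_gray"], 0), 255)
          a <- max(10, rnorm(1, 16, 1.5))
          b <- max(6, rnorm(1, 9, 1))
          theta <- runif(1, 0, pi)
          tex <- texture_params(
            base_gray = par[["base_gray"]],
            base_color = clip255(cfg$base$base_color +
                                   (par[["base_gray"]] - cfg$base$base_gray)),
            roughness_amp = par[["roughness_amp"]],
            roughness_scale = par[["roughness_scale"]],
            wrinkle_amp = par[["wrinkle_amp"]],
            wrinkle_freq = par[["wrinkle_freq"]],
            wrinkle_axis = geno_eff[[g]]$axis,
            shading_depth = par[["shading_depth"]])
          list(shape = grain_shape(a, b, theta), tex = tex)
        })
      })
      meta_cell <- data.frame(
        genotype = genos[g], year = years[yi], plate = plate_id,
        grain = seq_len(cfg$grains_per_cell),
        t(vapply(grains, function(gr)
          unlist(gr$tex[tex_numeric_fields]), numeric(6))),
        wrinkle_axis = geno_eff[[g]]$axis, stringsAsFactors = FALSE)
      meta[[plate_id]] <- meta_cell
      if (render) {
        side <- as.integer(ceiling(sqrt(cfg$grains_per_cell * 1700 * 5)))
        pl <- render_plate(grains, canvas = c(max(side, 96), max(side, 96)),
                           seed = substream_seed(seed,
                                                 paste0("plate.", plate_id)))
        tr <- pl$truth
        tr <- data.frame(genotype = genos[g], year = years[yi],
                         plate = plate_id, tr, stringsAsFactors = FALSE)
        truth[[plate_id]] <- tr
        if (is.null(dir)) {
          plates[[plate_id]] <- pl
        } else {
          path <- file.path(dir, paste0(plate_id, ".png"))
          write_plate_png(pl, path)
          plates[[plate_id]] <- path
        }
      }
    }
  }
  structure(list(
    metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    truth = if (length(truth))
      do.call(rbind, c(truth, list(make.row.names = FALSE))) else NULL,
    plates = if (render) plates else NULL,
    config = cfg), class = "grain_panel")
}

#' Write a rendered plate as an 8-bit RGB PNG
#'
#' @param plate a [render_plate()] result.
#' @param path output file path.
#' @export
write_plate_png <- function(plate, path) {
  png::writePNG(plate$image / 255, path)
  invisible(path)
}

#' Generate per-cell germination rates for a panel
#'
#' Germination rate for each genotype x year cell is
#' `plogis(intercept + year_offset + linkage * z + noise)`, where `z` is the
#' standardized per-cell mean of the linked trait (only when `linkage != 0`).
#' The model has a year main effect and no genotype effect: in storage
#' panels, harvest year (storage duration) drives germination far more than
#' genotype does.
#'
#' @param cfg a [panel_config()]; the `germination` element supplies the
#'   model parameters.
#' @param traits optional data frame of per-cell trait means with columns
#'   `genotype`, `year` and the linked trait (named as in
#'   `cfg$germination$linked_trait`). Required when `linkage != 0`.
#' @return data frame with columns `genotype`, `year`, `rate` (in `[0, 1]`).
#' @export
#' @examples
#' cfg <- panel_config(n_genotypes = 3, seed = 2)
#' generate_germination(cfg)
generate_germination <- function(cfg, traits = NULL) {
  stopifnot(inherits(cfg, "panel_config"))
  gp <- cfg$germination
  genos <- sprintf("g%02d", seq_len(cfg$n_genotypes))
  cells <- expand.grid(genotype = genos, year = cfg$years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(cells$genotype, cells$year), , drop = FALSE]
  lin <- 0
  if (!is.null(gp$linkage) && gp$linkage != 0) {
    if (is.null(traits))
      stop("configuration error: germination linkage requested but no ",
           "trait means supplied")
    tcol <- gp$linked_trait
    if (!tcol %in% names(traits))
      stop("configuration error: linked trait '", tcol,
           "' not found in supplied trait means")
    idx <- match(paste(cells$genotype, cells$year),
                 paste(traits$genotype, traits$year))
    if (anyNA(idx))
      stop("trait means missing for cells: ",
           paste(paste(cells$genotype, cells$year)[is.na(idx)],
                 collapse = ", "))
    v <- traits[[tcol]][idx]
    z <- if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
    lin <- gp$linkage * z
  }
  offs <- gp$year_offsets[as.character(cells$year)]
  if (anyNA(offs)) stop("germination year_offsets missing for some years")
  eta <- gp$intercept + as.numeric(offs) + lin
  if (gp$noise_sd > 0)
    eta <- eta + with_seed(substream_seed(cfg$seed, "germination"),
                           rnorm(nrow(cells), 0, gp$noise_sd))
  data.frame(genotype = cells$genotype, year = cells$year,
             rate = pmin(pmax(plogis(eta), 0), 1), row.names = NULL)
}
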