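# File surfaces: bit-stable CSV (UTF-8, comma, ".", LF, 6 significant
# digits), YAML configs and JSON run manifests.

fmt_num <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    # formatC pads a vector to common width; strip it for clean CSV cells
    out <- trimws(formatC(signif(x, 6), format = "g", digits = 6))
    out[is.na(x)] <- "NA"
    out
  } else as.character(x)
}

#' Write a data frame as a bit-stable CSV
#'
#' UTF-8, comma-separated, "." decimal, LF line endings, no quotes, no row
#' names; doubles at 6 significant digits.  Identical data always produce
#' byte-identical files.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_stable_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), list(sep = ","))), con,
               sep = "\n")
  invisible(path)
}

write_manifest <- function(path, ...) {
  info <- list(..., package = "graintex",
               version = as.character(utils::packageVersion("graintex")))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a panel to disk
#'
#' Renders every genotype x year plate of a panel to `out_dir` as 8-bit RGB
#' PNGs and writes `metadata.csv` (one row per grain with the true texture
#' parameters), `ground_truth.csv` (geometry + RLE-encoded masks),
#' `germination.csv`, `panel_config.yaml` and `manifest.json`.
#'
#' @param cfg a [panel_config()]; alternatively a path to a YAML file with
#'   the config fields.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the metadata data frame.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- panel_config_from_yaml(cfg)
  stopifnot(inherits(cfg, "panel_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  img_dir <- file.path(out_dir, "plates")
  pan <- generate_panel(cfg, render = TRUE, dir = img_dir)
  write_stable_csv(pan$metadata, file.path(out_dir, "metadata.csv"))
  write_stable_csv(pan$truth, file.path(out_dir, "ground_truth.csv"))
  cell_means <- aggregate(pan$metadata[tex_numeric_fields],
                          by = pan$metadata[c("genotype", "year")],
                          FUN = mean)
  germ <- generate_germination(cfg, traits = cell_means)
  write_stable_csv(germ, file.path(out_dir, "germination.csv"))
  cfg_plain <- unclass(cfg)
  cfg_plain$base <- unclass(cfg_plain$base)
  # named vectors must go out as YAML maps, or the names are lost
  for (f in c("genotype_sd", "year_slope", "noise_sd"))
    cfg_plain[[f]] <- as.list(cfg_plain[[f]])
  cfg_plain$germination$year_offsets <-
    as.list(cfg_plain$germination$year_offsets)
  yaml::write_yaml(cfg_plain, file.path(out_dir, "panel_config.yaml"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "simulate", seed = cfg$seed,
                 config_hash = unname(tools::md5sum(
                   file.path(out_dir, "panel_config.yaml"))),
                 n_plates = length(pan$plates),
                 n_grains = nrow(pan$metadata))
  invisible(pan$metadata)
}

#' @rdname cmd_simulate
#' @param path YAML file with `panel_config` fields.
#' @export
panel_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- if (!is.null(y$base)) do.call(texture_params, y$base) else
    texture_params()
  args <- y[setdiff(names(y), "base")]
  for (f in c("genotype_sd", "year_slope", "noise_sd"))
    if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
  if (!is.null(args$germination$year_offsets))
    args$germination$year_offsets <- unlist(args$germination$year_offsets)
  do.call(panel_config, c(args, list(base = base)))
}

#' Extract traits from a directory of plate images
#'
#' Processes every PNG in `images_dir` through [segment_grains()] and
#' [extract_traits()].  If a `metadata.csv` from [cmd_simulate()] sits next
#' to the images (in `images_dir` or its parent), genotype and year are
#' taken from it by plate name; otherwise the file stem is the plate id.
#' Unreadable images are skipped with a warning (an error is raised only if
#' every image fails).
#'
#' @param images_dir directory containing `*.png` plates.
#' @param out_csv output trait-table CSV path; a JSON sidecar
#'   (`<out_csv>.json`) records the settings.
#' @param levels gray-level count `G`.
#' @param distance GLCM offset distance, px.
#' @param min_area minimum grain area, px^2.
#' @param outlier_filter apply [filter_outliers()] with `k = outlier_k`.
#' @param outlier_k SD multiplier of the grain filter.
#' @return invisibly, the trait table.
#' @export
cmd_extract <- function(images_dir, out_csv, levels = 32, distance = 1,
                        min_area = 200, outlier_filter = TRUE,
                        outlier_k = 3) {
  files <- sort(list.files(images_dir, pattern = "\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no PNG images found in ", images_dir)
  meta <- NULL
  for (cand in c(file.path(images_dir, "metadata.csv"),
                 file.path(dirname(images_dir), "metadata.csv")))
    if (file.exists(cand)) {
      meta <- read.csv(cand, stringsAsFactors = FALSE)
      break
    }
  tables <- list(); n_fail <- 0L
  for (f in files) {
    plate <- sub("\\.png$", "", basename(f))
    geno <- NA_character_; yr <- NA_integer_
    if (!is.null(meta)) {
      m <- meta[meta$plate == plate, , drop = FALSE]
      if (nrow(m)) {
        geno <- m$genotype[1]
        yr <- as.integer(m$year[1])
      }
    }
    tab <- tryCatch(
      extract_traits(read_plate_png(f), genotype = geno, year = yr,
                     plate = plate, levels = levels, distance = distance,
                     min_area = min_area),
      error = function(e) {
        warning("skipping unreadable image ", f, ": ",
                conditionMessage(e), call. = FALSE)
        n_fail <<- n_fail + 1L
        NULL
      })
    if (!is.null(tab)) tables[[plate]] <- tab
  }
  if (!length(tables)) stop("all ", n_fail, " images failed to process")
  table <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  if (outlier_filter && nrow(table) >= 3)
    table <- filter_outliers(table, k = outlier_k)
  write_stable_csv(table[, trait_table_columns()], out_csv)
  write_manifest(paste0(out_csv, ".json"), command = "extract",
                 levels = levels, distance = distance, min_area = min_area,
                 outlier_filter = outlier_filter, outlier_k = outlier_k,
                 n_images = length(files), n_failed = n_fail,
                 n_grains = nrow(table))
  invisible(table)
}

#' Run the full statistical report on a trait table
#'
#' Emits the correlation matrix, the UPGMA trait tree (Newick) with its
#' cluster cut, PCA loadings/scores/variance shares, the ANOVA
#' factor-contribution table, the year-trend table with permutation and
#' bootstrap bands, the germination-association table (skipped with a
#' notice when no germination file is given), and a JSON manifest with
#' seeds and settings.
#'
#' @param traits_csv trait-table CSV (schema of [trait_table_columns()]).
#' @param out_dir output directory (created if missing).
#' @param germination_csv optional CSV `(genotype, year, rate)`.
#' @param replicates randomization replicates, `>= 100`.
#' @param seed integer master seed for all stochastic stages.
#' @param unit observation unit for the correlation matrix.
#' @param distance trait-tree distance variant.
#' @param cut_height cluster-cut height on the ultrametric scale.
#' @return invisibly, a list with every computed table.
#' @export
cmd_analyze <- function(traits_csv, out_dir, germination_csv = NULL,
                        replicates = 2000, seed = 1L,
                        unit = c("grain", "line_mean"),
                        distance = c("one_minus_abs_r", "one_minus_r"),
                        cut_height = 0.25) {
  unit <- match.arg(unit)
  distance <- match.arg(distance)
  if (replicates < 100) stop("replicates must be >= 100")
  table <- read.csv(traits_csv, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trait_table_columns(), names(table))
  if (length(missing_cols))
    stop("trait table schema mismatch; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list()
  res$correlation <- correlation_matrix(table, unit = unit)
  cm <- data.frame(trait = rownames(res$correlation$r),
                   res$correlation$r, check.names = FALSE)
  write_stable_csv(cm, file.path(out_dir, "correlation_matrix.csv"))
  res$tree <- upgma_tree(res$correlation, distance = distance)
  writeLines(newick(res$tree), file.path(out_dir, "trait_tree.nwk"))
  cl <- cut_clusters(res$tree, cut_height)
  res$clusters <- data.frame(trait = names(cl), cluster = as.integer(cl))
  write_stable_csv(res$clusters, file.path(out_dir, "clusters.csv"))
  res$pca <- trait_pca(table)
  write_stable_csv(data.frame(trait = rownames(res$pca$loadings),
                              res$pca$loadings, check.names = FALSE),
                   file.path(out_dir, "pca_loadings.csv"))
  write_stable_csv(as.data.frame(res$pca$scores),
                   file.path(out_dir, "pca_scores.csv"))
  write_stable_csv(data.frame(component = colnames(res$pca$loadings),
                              share = res$pca$shares),
                   file.path(out_dir, "pca_shares.csv"))
  res$anova <- factor_contributions(table)
  write_stable_csv(res$anova, file.path(out_dir, "anova.csv"))
  res$year_trend <- year_trend(table, replicates = replicates,
                               seed = substream_seed(seed, "year_trend"))
  write_stable_csv(res$year_trend, file.path(out_dir, "year_trend.csv"))
  if (!is.null(germination_csv) && file.exists(germination_csv)) {
    germ <- read.csv(germination_csv, stringsAsFactors = FALSE)
    res$germination <- germination_association(
      table, germ, replicates = replicates,
      seed = substream_seed(seed, "germination"))
    write_stable_csv(res$germination, file.path(out_dir, "germination.csv"))
  } else {
    message("no germination table supplied: germination analysis skipped")
  }
  write_manifest(file.path(out_dir, "manifest.json"), command = "analyze",
                 seed = seed, replicates = replicates, unit = unit,
                 distance = distance, cut_height = cut_height,
                 traits_hash = unname(tools::md5sum(traits_csv)),
                 n_grains = nrow(table))
  invisible(res)
}
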