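#' Encode harvest years as trend covariates
#'
#' Three encodings of the four-harvest design: binary `year01` (0 for the
#' two early harvests 2003/2004, 1 for 2009/2014), calendar `year`, and
#' `yearrank` (1-4 in harvest order).
#'
#' @param year integer vector of calendar years.
#' @param mapping optional data frame with columns `year`, `year01`,
#'   `yearrank` overriding the default 2003/2004/2009/2014 mapping.
#' @return data frame with columns `year01`, `year`, `yearrank`, one row
#'   per input element.
#' @export
#' @examples
#' encode_year(c(2003, 2009))
encode_year <- function(year, mapping = NULL) {
  if (is.null(mapping))
    mapping <- data.frame(year = c(2003L, 2004L, 2009L, 2014L),
                          year01 = c(0L, 0L, 1L, 1L),
                          yearrank = 1:4)
  idx <- match(as.integer(year), mapping$year)
  if (anyNA(idx))
    stop("mapping error: unknown year(s) ",
         paste(unique(year[is.na(idx)]), collapse = ", "))
  data.frame(year01 = mapping$year01[idx], year = as.integer(year),
             yearrank = mapping$yearrank[idx])
}

#' Permutation or bootstrap null band for a Pearson correlation
#'
#' Replicates the correlation under randomization of `x` (`y` held fixed):
#' permutation mode reshuffles `x` without replacement, bootstrap mode
#' resamples `x` with replacement.  The band is the (min, max) of the
#' replicate correlations.  An observed correlation outside the bands of
#' BOTH modes is the significance rule used throughout the suite.
#'
#' @param x,y numeric vectors of equal length `>= 10`; neither constant.
#' @param replicates number of randomization replicates, `>= 100`.
#' @param mode `"permutation"` or `"bootstrap"`.
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @return list of class `null_band`: `min`, `max`, `replicates`, `mode`,
#'   `seed`, `r` (all replicate correlations).
#' @export
#' @examples
#' b <- null_band(rnorm(50), rnorm(50), replicates = 200, seed = 1)
#' c(b$min, b$max)
null_band <- function(x, y, replicates = 2000,
                      mode = c("permutation", "bootstrap"), seed = 1L) {
  mode <- match.arg(mode)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 10) stop("need at least 10 paired observations")
  if (replicates < 100) stop("replicates must be >= 100")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: constant x or y")
  r <- with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      xs <- if (mode == "permutation") x[sample.int(n)] else
        x[sample.int(n, replace = TRUE)]
      suppressWarnings(cor(xs, y))
    }, 0)
  })
  if (anyNA(r)) r <- r[!is.na(r)]  # constant bootstrap resample (rare)
  structure(list(min = min(r), max = max(r), replicates = replicates,
                 mode = mode, seed = seed, r = r), class = "null_band")
}

# Dual-band significance: outside the extremes of both tests.
dual_band_significant <- function(r_obs, perm, boot) {
  (r_obs < perm$min & r_obs < boot$min) |
    (r_obs > perm$max & r_obs > boot$max)
}

#' Year-trend correlations with randomization null bands
#'
#' For each texture trait, the Pearson correlation of the per-grain trait
#' value with each of the three year encodings (Year01, Year, YearRank),
#' plus permutation and bootstrap null bands (default 2000 replicates,
#' computed against the rank-coded year, the most conservative covariate)
#' and the dual-band significance flag for the YearRank correlation.
#'
#' @param table per-grain trait table with a `year` column.
#' @param traits trait columns; defaults to the 16 texture traits.
#' @param replicates randomization replicates per band.
#' @param seed integer master seed (per-trait substreams are derived).
#' @param band_covariate `"yearrank"` (default), `"year01"` or `"year"`:
#'   the encoding the bands are computed against.
#' @param mapping optional custom year mapping, see [encode_year()].
#' @return data frame in the trend-table layout: `trait`,
#'   `Year01`, `Year`, `YearRank`, `PermMin`, `PermMax`, `BootMin`,
#'   `BootMax`, `significant`.
#' @export
year_trend <- function(table, traits = NULL, replicates = 2000, seed = 1L,
                       band_covariate = c("yearrank", "year01", "year"),
                       mapping = NULL) {
  band_covariate <- match.arg(band_covariate)
  if (is.null(traits))
    traits <- intersect(texture_trait_names(), names(table))
  enc <- encode_year(table$year, mapping = mapping)
  rows <- list()
  for (tr in traits) {
    v <- table[[tr]]
    perm <- null_band(v, enc[[band_covariate]], replicates = replicates,
                      mode = "permutation",
                      seed = substream_seed(seed, paste0("perm.", tr)))
    boot <- null_band(v, enc[[band_covariate]], replicates = replicates,
                      mode = "bootstrap",
                      seed = substream_seed(seed, paste0("boot.", tr)))
    r_rank <- cor(v, enc$yearrank)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr,
      Year01 = cor(v, enc$year01),
      Year = cor(v, enc$year),
      YearRank = r_rank,
      PermMin = perm$min, PermMax = perm$max,
      BootMin = boot$min, BootMax = boot$max,
      significant = dual_band_significant(r_rank, perm, boot),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Germination-association test with randomization null bands
#'
#' Procedure: (1) attach each grain's cell germination rate and center it
#' by harvest-year means; (2) remove grains whose centered germination is
#' extreme (`|z| > outlier_k`); (3) standardize each trait to mean 0, SD 1
#' (within genotype by default, removing genotype-level signal); (4)
#' Pearson correlation of the standardized trait with centered germination
#' over grains; (5) permutation and bootstrap bands with the dual-band
#' significance rule.
#'
#' @param traits per-grain trait table with `genotype` and `year` columns.
#' @param germ data frame `(genotype, year, rate)` covering every
#'   genotype-year cell present in `traits`.
#' @param trait_names columns to test; defaults to the 16 texture traits.
#' @param replicates randomization replicates per band.
#' @param seed integer master seed.
#' @param standardize `"within_genotype"` (default) or `"pooled"`.
#' @param outlier_k SD multiplier for the centered-germination filter.
#' @return data frame: `trait`, `r`, `PermMin`, `PermMax`, `BootMin`,
#'   `BootMax`, `significant`, `n` — or an empty data frame with a warning
#'   when centered germination is degenerate (all zero).
#' @export
germination_association <- function(traits, germ, trait_names = NULL,
                                    replicates = 2000, seed = 1L,
                                    standardize = c("within_genotype",
                                                    "pooled"),
                                    outlier_k = 3) {
  standardize <- match.arg(standardize)
  if (is.null(trait_names))
    trait_names <- intersect(texture_trait_names(), names(traits))
  key <- paste(traits$genotype, traits$year)
  gkey <- paste(germ$genotype, germ$year)
  idx <- match(key, gkey)
  if (anyNA(idx))
    stop("missing germination for cells: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  rate <- germ$rate[idx]
  centered <- rate - ave(rate, traits$year)
  if (all(abs(centered) < 1e-12)) {
    warning("centered germination is identically zero; association ",
            "undefined, all traits skipped")
    return(data.frame(trait = character(), r = numeric(),
                      PermMin = numeric(), PermMax = numeric(),
                      BootMin = numeric(), BootMax = numeric(),
                      significant = logical(), n = integer()))
  }
  s <- sd(centered)
  keep <- if (s > 0) abs(centered - mean(centered)) / s <= outlier_k else
    rep(TRUE, length(centered))
  dat <- traits[keep, , drop = FALSE]
  centered <- centered[keep]
  zscale <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  rows <- list()
  for (tr in trait_names) {
    v <- dat[[tr]]
    z <- if (standardize == "within_genotype")
      as.numeric(unlist(ave(v, dat$genotype, FUN = zscale))) else zscale(v)
    if (sd(z) == 0) {
      warning("trait ", tr, " constant after standardization; skipped")
      next
    }
    r_obs <- cor(z, centered)
    perm <- null_band(z, centered, replicates = replicates,
                      mode = "permutation",
                      seed = substream_seed(seed, paste0("perm.", tr)))
    boot <- null_band(z, centered, replicates = replicates,
                      mode = "bootstrap",
                      seed = substream_seed(seed, paste0("boot.", tr)))
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, r = r_obs,
      PermMin = perm$min, PermMax = perm$max,
      BootMin = boot$min, BootMax = boot$max,
      significant = dual_band_significant(r_obs, perm, boot),
      n = length(z), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trait = character(), r = numeric(),
                      PermMin = numeric(), PermMax = numeric(),
                      BootMin = numeric(), BootMax = numeric(),
                      significant = logical(), n = integer()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
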