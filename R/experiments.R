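# Controlled simulation experiments exercising the full pipeline.

#' Factor-recovery experiment: do PC axes find roughness and wrinkling?
#'
#' Renders a panel of genotypes whose grain surfaces vary in two independent
#' generative factors - roughness amplitude (drawn uniformly per genotype)
#' and wrinkle orientation (ridges along vs across the grain axis, one draw
#' per genotype) - extracts the 16 texture descriptors per grain, averages
#' them per genotype, and runs the correlation-matrix PCA on the genotype
#' means.  Averaging over grains suppresses per-grain sampling noise so the
#' dominant component can align with the roughness mode and the second with
#' the orientation mode.
#'
#' The wrinkle frequency is low (3 ridges per 100 px) so a ridge period
#' exceeds the grain width: along-axis ridges then sample less of the
#' sinusoid than transverse folds, which is what makes orientation visible
#' to omnidirectional statistics on randomly rotated grains.
#'
#' @param seed integer seed.
#' @param n_genotypes genotypes (one roughness + one orientation draw each).
#' @param grains_per_genotype grains rendered and averaged per genotype.
#' @param roughness_range range of the per-genotype roughness amplitude.
#' @param wrinkle_amp,wrinkle_freq,shading_depth fixed surface parameters.
#' @param levels gray-level count for the texture features.
#' @return list: `cors` (2 x 2 matrix of correlations between PC1/PC2
#'   scores and the roughness/orientation factors), `pca` (the
#'   [trait_pca()] fit), `factors` (per-genotype draws), `means`
#'   (genotype-mean trait table).
#' @export
pca_recovery_experiment <- function(seed = 1, n_genotypes = 40,
                                    grains_per_genotype = 12,
                                    roughness_range = c(0, 18),
                                    wrinkle_amp = 22, wrinkle_freq = 3,
                                    shading_depth = 5, levels = 32) {
  res <- with_seed(seed, {
    F1 <- runif(n_genotypes, roughness_range[1], roughness_range[2])
    F2 <- sample(c(-1, 1), n_genotypes, replace = TRUE)
    means <- matrix(NA_real_, n_genotypes, 16)
    for (g in seq_len(n_genotypes)) {
      feats <- matrix(NA_real_, grains_per_genotype, 16)
      for (j in seq_len(grains_per_genotype)) {
        tex <- texture_params(
          roughness_amp = max(0, F1[g] + rnorm(1, 0, 0.5)),
          wrinkle_amp = wrinkle_amp, wrinkle_freq = wrinkle_freq,
          wrinkle_axis = if (F2[g] > 0) "along" else "across",
          shading_depth = shading_depth)
        shape <- grain_shape(max(20, rnorm(1, 26, 1.5)),
                             max(7, rnorm(1, 9, 0.7)), runif(1, 0, pi))
        patch <- render_grain(shape, tex,
                              seed = substream_seed(seed,
                                                    paste0(g, ".", j)))
        reg <- list(gray = patch$gray,
                    pixels_rgb = cbind(patch$rgb[, , 1][patch$mask],
                                       patch$rgb[, , 2][patch$mask],
                                       patch$rgb[, , 3][patch$mask]),
                    area = sum(patch$mask))
        feats[j, ] <- grain_traits(reg, levels = levels)[1:16]
      }
      means[g, ] <- colMeans(feats)
    }
    colnames(means) <- texture_trait_names()
    list(F1 = F1, F2 = F2, means = as.data.frame(means))
  })
  p <- trait_pca(res$means)
  cors <- rbind(PC1 = c(cor(p$scores[, 1], res$F1),
                        cor(p$scores[, 1], res$F2)),
                PC2 = c(cor(p$scores[, 2], res$F1),
                        cor(p$scores[, 2], res$F2)))
  colnames(cors) <- c("roughness", "orientation")
  list(cors = cors, pca = p,
       factors = data.frame(roughness = res$F1, orientation = res$F2),
       means = res$means)
}

#' Null-band magnitude experiment at a given design size
#'
#' Simulates `n` grains assigned (approximately) equally to the four
#' harvest years, draws a continuous trait independent of year, and runs
#' the permutation and bootstrap null bands of the trait against the
#' rank-coded year (or against a continuous covariate for the
#' germination-style setting), averaging each band extreme over seeds.
#'
#' @param n number of paired observations.
#' @param replicates randomization replicates per band.
#' @param n_seeds number of independent repetitions averaged.
#' @param seed master seed.
#' @param covariate `"yearrank"` for the year-trend setting or
#'   `"continuous"` for the germination-style pairing (both standardized,
#'   no true association).
#' @return data frame with averaged `perm_min`, `perm_max`, `boot_min`,
#'   `boot_max`.
#' @export
null_band_experiment <- function(n, replicates = 2000, n_seeds = 20,
                                 seed = 1,
                                 covariate = c("yearrank", "continuous")) {
  covariate <- match.arg(covariate)
  acc <- matrix(0, n_seeds, 4)
  for (s in seq_len(n_seeds)) {
    sub <- substream_seed(seed, paste0("nullband.", s))
    dat <- with_seed(sub, {
      y <- if (covariate == "yearrank")
        rep(1:4, length.out = n)[sample.int(n)] else rnorm(n)
      list(x = rnorm(n), y = y)
    })
    perm <- null_band(dat$x, dat$y, replicates = replicates,
                      mode = "permutation",
                      seed = substream_seed(sub, "perm"))
    boot <- null_band(dat$x, dat$y, replicates = replicates,
                      mode = "bootstrap",
                      seed = substream_seed(sub, "boot"))
    acc[s, ] <- c(perm$min, perm$max, boot$min, boot$max)
  }
  out <- colMeans(acc)
  data.frame(perm_min = out[1], perm_max = out[2],
             boot_min = out[3], boot_max = out[4], n = n,
             replicates = replicates, n_seeds = n_seeds)
}
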