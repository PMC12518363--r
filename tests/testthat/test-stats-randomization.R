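test_that("the harvest-year encodings follow the fixed mapping", {
  e <- encode_year(c(2003, 2004, 2009, 2014))
  expect_equal(e$year01, c(0, 0, 1, 1))
  expect_equal(e$year, c(2003, 2004, 2009, 2014))
  expect_equal(e$yearrank, 1:4)
  expect_error(encode_year(1999), "mapping error")
  custom <- data.frame(year = c(1999, 2001), year01 = c(0, 1),
                       yearrank = 1:2)
  expect_equal(encode_year(1999, mapping = custom)$yearrank, 1)
})

test_that("null bands are reproducible and track the extreme-value law", {
  set.seed(61)
  x <- rnorm(1000); y <- rnorm(1000)
  b1 <- null_band(x, y, replicates = 2000, seed = 5)
  b2 <- null_band(x, y, replicates = 2000, seed = 5)
  expect_identical(b1[c("min", "max")], b2[c("min", "max")])
  # oracle: expected maximum of m = 2000 approximately N(0, 1/sqrt(n-1))
  # correlations is (3.3 ... 3.6) / sqrt(n - 1) (Gumbel limit)
  mx <- mean(vapply(1:12, function(s)
    null_band(x, y, replicates = 2000, seed = s)$max, 0))
  sigma <- 1 / sqrt(999)
  expect_gt(mx, 3.2 * sigma)
  expect_lt(mx, 3.7 * sigma)
  # oversampled brute-force run bounds the same quantity
  big <- null_band(x, y, replicates = 20000, seed = 77)
  expect_gt(big$max, mx * 0.95)
})

test_that("bands widen with replicate count and cover the null", {
  set.seed(63)
  x <- rnorm(300); y <- rnorm(300)
  # under one seed the 100-replicate run is a prefix of the 2000-replicate
  # run, so the wider band contains the narrower one by construction
  wider <- 0
  for (s in 1:30) {
    b100 <- null_band(x, y, replicates = 100, seed = 400 + s)
    b2000 <- null_band(x, y, replicates = 2000, seed = 400 + s)
    if (b2000$max >= b100$max && b2000$min <= b100$min)
      wider <- wider + 1
  }
  expect_gte(wider, 30)
  # a reshuffled copy of y (true r = 0) falls inside the band almost always
  inside <- 0
  for (s in 1:40) {
    set.seed(900 + s)
    yy <- rnorm(200)
    xx <- sample(yy)
    b <- null_band(xx, yy, replicates = 2000, seed = s)
    r <- cor(xx, yy)
    if (r >= b$min && r <= b$max) inside <- inside + 1
  }
  expect_gte(inside, 39)
})

test_that("null-band half-width scales as 1 over sqrt(n)", {
  hw <- function(n, s) {
    set.seed(s)
    x <- rnorm(n); y <- rnorm(n)
    b <- null_band(x, y, replicates = 2000, seed = s)
    (b$max - b$min) / 2
  }
  h400 <- mean(vapply(1:20, function(s) hw(400, s), 0))
  h1600 <- mean(vapply(1:20, function(s) hw(1600, 100 + s), 0))
  expect_lt(abs(h400 / h1600 - 2), 0.3)  # +/- 15%
})

test_that("degenerate null-band inputs are rejected", {
  expect_error(null_band(rep(1, 50), rnorm(50)), "degenerate")
  expect_error(null_band(rnorm(5), rnorm(5)), "at least 10")
  expect_error(null_band(rnorm(50), rnorm(50), replicates = 50),
               ">= 100")
})

test_that("dual-band significance is never more liberal than either band", {
  set.seed(71)
  for (i in 1:50) {
    n <- 50
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    perm <- null_band(x, y, replicates = 200, seed = i)
    boot <- null_band(x, y, replicates = 200, mode = "bootstrap",
                      seed = 1000 + i)
    r <- cor(x, y)
    flag <- graintex:::dual_band_significant(r, perm, boot)
    single_perm <- r < perm$min || r > perm$max
    single_boot <- r < boot$min || r > boot$max
    expect_true(!flag || (single_perm && single_boot))
  }
})

test_that("year trends recover an injected roughness slope with matching sign", {
  cfg <- panel_config(n_genotypes = 44, grains_per_cell = 20,
                      year_slope = c(roughness_amp = 2), seed = 81)
  pan <- generate_panel(cfg, render = FALSE)
  yt <- year_trend(pan$metadata, traits = "roughness_amp",
                   replicates = 2000, seed = 7)
  expect_true(yt$significant)
  expect_gt(yt$YearRank, 0)
  # encodings are order-consistent for a monotone effect
  expect_equal(sign(yt$Year01), sign(yt$Year))
  expect_equal(sign(yt$Year), sign(yt$YearRank))
})

test_that("null panels flag almost no year-trend cells", {
  set.seed(83)
  n <- 800
  years <- rep(c(2003, 2004, 2009, 2014), each = n / 4)
  tab <- data.frame(year = years)
  for (tr in texture_trait_names()) tab[[tr]] <- rnorm(n)
  flagged <- 0
  for (s in 1:2) {
    yt <- year_trend(tab, replicates = 2000, seed = 90 + s)
    flagged <- flagged + sum(yt$significant)
  }
  expect_lte(flagged, 1)  # dual-band rule is conservative (~0.1% per cell)
})

test_that("germination association skips degenerate germination", {
  cfg <- panel_config(n_genotypes = 4, grains_per_cell = 3, seed = 3,
                      germination = list(intercept = 1,
                                         year_offsets = c("2003" = -0.4,
                                                          "2004" = -0.2,
                                                          "2009" = -0.1,
                                                          "2014" = 0),
                                         linkage = 0, noise_sd = 0))
  pan <- generate_panel(cfg, render = FALSE)
  germ <- generate_germination(cfg)
  # rate identical within year -> centered germination identically zero
  expect_warning(res <- germination_association(
    pan$metadata, germ, trait_names = "roughness_amp", replicates = 100),
    "identically zero")
  expect_equal(nrow(res), 0)
})

test_that("germination association is conservative under the null", {
  cfg <- panel_config(n_genotypes = 19, grains_per_cell = 17, seed = 5,
                      germination = list(intercept = 1, linkage = 0,
                                         noise_sd = 0.3))
  pan <- generate_panel(cfg, render = FALSE)
  tab <- pan$metadata
  set.seed(55)
  for (tr in texture_trait_names()) tab[[tr]] <- rnorm(nrow(tab))
  germ <- generate_germination(cfg)
  res <- germination_association(tab, germ, replicates = 2000, seed = 31)
  expect_equal(nrow(res), 16)
  expect_lte(sum(res$significant), 1)
})

test_that("an injected germination linkage is detected with high power", {
  # effect calibrated once so the realized grain-level correlation is ~0.15
  hits <- 0; seeds <- 1:10
  for (s in seeds) {
    cfg <- panel_config(n_genotypes = 19, grains_per_cell = 17,
                        genotype_sd = c(roughness_amp = 0.5),
                        year_slope = c(roughness_amp = 0),
                        noise_sd = c(roughness_amp = 3), seed = 7000 + s,
                        germination = list(intercept = 1, linkage = 0.6,
                                           linked_trait = "roughness_amp",
                                           noise_sd = 0.1))
    pan <- generate_panel(cfg, render = FALSE)
    cells <- aggregate(pan$metadata["roughness_amp"],
                       by = pan$metadata[c("genotype", "year")], FUN = mean)
    germ <- generate_germination(cfg, traits = cells)
    res <- germination_association(pan$metadata, germ,
                                   trait_names = "roughness_amp",
                                   replicates = 2000, seed = s)
    if (res$significant) hits <- hits + 1
  }
  expect_gte(hits / length(seeds), 0.8)
})

test_that("missing germination cells raise a listing error", {
  cfg <- panel_config(n_genotypes = 3, grains_per_cell = 2, seed = 2)
  pan <- generate_panel(cfg, render = FALSE)
  germ <- generate_germination(cfg)
  germ <- germ[germ$genotype != "g02", ]
  expect_error(germination_association(pan$metadata, germ,
                                       trait_names = "roughness_amp"),
               "missing germination.*g02")
})
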