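test_that("quantization hits the bin endpoints and matches a per-pixel loop", {
  expect_equal(quantize_levels(0, 32), 0L)
  expect_equal(quantize_levels(255, 32), 31L)
  expect_equal(quantize_levels(128, 2), 1L)
  expect_error(quantize_levels(10, 1), "parameter error")
  set.seed(5)
  g <- sample(0:255, 1000, replace = TRUE)
  loop <- vapply(g, function(x) floor(x * 8 / 256), 0)
  expect_equal(as.numeric(quantize_levels(g, 8)), loop)
})

test_that("GLCM of tiny patches matches hand enumeration", {
  # 2x2 constant patch: only (0,0) pairs
  M <- glcm_accumulate(matrix(0L, 2, 2), G = 2)
  expect_equal(M$P, matrix(c(1, 0, 0, 0), 2, 2))
  # 4x4 checkerboard: 84 ordered pairs, 48 unequal, 36 equal
  cb <- (row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2L
  M <- glcm_accumulate(cb, G = 2)
  expect_equal(M$pair_count, 84)
  expect_equal(M$P[1, 2], 2 / 7)
  expect_equal(M$P[2, 1], 2 / 7)
  expect_equal(M$P[1, 1], 3 / 14)
  expect_equal(M$P[2, 2], 3 / 14)
})

test_that("GLCM accumulation equals exhaustive pair enumeration on random patches", {
  for (s in 1:25) {
    pt <- random_patch(s, G = sample(c(2, 4, 8), 1))
    M <- glcm_accumulate(pt$lev, pt$mask, G = pt$G)
    expect_equal(M$P, oracle_glcm(pt$lev, pt$mask, pt$G), tolerance = 1e-12)
    expect_equal(sum(M$P), 1, tolerance = 1e-12)
    expect_equal(M$P, t(M$P))  # opposite offsets both counted
  }
})

test_that("isolated single pixels are a degenerate-region error", {
  mask <- matrix(FALSE, 3, 3); mask[2, 2] <- TRUE
  expect_error(glcm_accumulate(matrix(0L, 3, 3), mask, G = 2),
               "degenerate region")
})

test_that("GLCM features match hand values on degenerate and checkerboard matrices", {
  Mc <- glcm_accumulate(matrix(0L, 2, 2), G = 2)
  f <- glcm_features(Mc)
  expect_equal(unname(f[c("GLCMu", "GLCMe", "GLCMi", "GLCMh", "GLCMmp",
                          "GLCMv", "GLCMc")]),
               c(1, 0, 0, 1, 1, 0, 0))
  cb <- (row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2L
  f <- glcm_features(glcm_accumulate(cb, G = 2))
  expect_equal(unname(f["GLCMi"]), 4 / 7)
  expect_equal(unname(f["GLCMh"]), 5 / 7)
})

test_that("GLCM features equal the literal-formula oracle on random matrices", {
  for (s in 1:20) {
    set.seed(100 + s)
    P <- matrix(runif(16), 4, 4)
    P <- (P + t(P)); P <- P / sum(P)
    M <- structure(list(P = P, G = 4, pair_count = 1000),
                   class = "cooccurrence_matrix")
    expect_equal(glcm_features(M), oracle_glcm_features(P),
                 tolerance = 1e-12)
  }
})

test_that("run extraction splits on level changes and mask gaps", {
  seq1 <- matrix(c(0L, 0L, 1L, 1L, 1L, 0L), 1)
  r <- extract_runs(seq1, orientation = 0)
  expect_equal(r$level, c(0, 1, 0))
  expect_equal(r$length, c(2, 3, 1))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), 1)
  r <- extract_runs(seq1, mask, orientation = 0)
  expect_equal(r$level, c(0, 1, 1, 0))
  expect_equal(r$length, c(2, 1, 1, 1))
})

test_that("every in-mask pixel lies in exactly one run per orientation", {
  for (s in 1:10) {
    pt <- random_patch(200 + s)
    for (o in c(0, 45, 90, 135)) {
      r <- extract_runs(pt$lev, pt$mask, orientation = o)
      expect_equal(sum(r$length), sum(pt$mask))
    }
  }
})

test_that("run-length accumulation matches hand enumeration on simple patches", {
  S <- glrm_accumulate(matrix(0L, 4, 4), G = 2)
  expect_equal(S$n_runs, 22)  # 4+4 straight runs, 7+7 diagonal runs
  expect_equal(unname(glrm_features(S)["GLRMrr"]), 22 / 64)
  expect_equal(sum(S$R %*% seq_len(ncol(S$R))), 4 * 16)

  m1 <- matrix(TRUE, 1, 1)
  S1 <- glrm_accumulate(matrix(0L, 1, 1), m1, G = 2)
  expect_equal(S1$n_runs, 4)

  expect_error(glrm_accumulate(matrix(0L, 2, 2), matrix(FALSE, 2, 2)),
               "degenerate region")
})

test_that("single-run distributions give the closed-form GLRM features", {
  S <- structure(list(R = rbind(c(0, 0, 0, 0, 1), rep(0, 5)), G = 2,
                      n_runs = 1, n_pixels = 5, n_orientations = 1),
                 class = "runlength_set")
  f <- glrm_features(S)
  expect_equal(unname(f["GLRMsr"]), 1 / 25)
  expect_equal(unname(f["GLRMlr"]), 25)
  expect_equal(unname(f["GLRMe"]), 0)
  expect_equal(unname(f["GLRMrr"]), 1 / 5)
})

test_that("GLRM accumulation and features match the run-enumeration oracle", {
  for (s in 1:25) {
    pt <- random_patch(300 + s, G = sample(c(2, 4, 8), 1))
    S <- glrm_accumulate(pt$lev, pt$mask, G = pt$G)
    Ro <- oracle_glrm(pt$lev, pt$mask, pt$G)
    expect_equal(S$R, Ro)
    expect_equal(glrm_features(S),
                 oracle_glrm_features(Ro, sum(pt$mask)), tolerance = 1e-12)
    # conservation: every pixel in exactly one run per orientation
    expect_equal(sum(S$R %*% seq_len(ncol(S$R))), 4 * sum(pt$mask))
  }
})

test_that("omnidirectional features are invariant to 90-degree rotation", {
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  for (s in 1:10) {
    pt <- random_patch(400 + s)
    lev2 <- rot90(pt$lev); mask2 <- rot90(pt$mask)
    f1 <- c(glcm_features(glcm_accumulate(pt$lev, pt$mask, G = pt$G)),
            glrm_features(glrm_accumulate(pt$lev, pt$mask, G = pt$G)))
    f2 <- c(glcm_features(glcm_accumulate(lev2, mask2, G = pt$G)),
            glrm_features(glrm_accumulate(lev2, mask2, G = pt$G)))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("feature ranges respect their analytic bounds", {
  for (s in 1:10) {
    pt <- random_patch(500 + s)
    fg <- glcm_features(glcm_accumulate(pt$lev, pt$mask, G = pt$G))
    fr <- glrm_features(glrm_accumulate(pt$lev, pt$mask, G = pt$G))
    expect_true(fg["GLCMu"] > 0 && fg["GLCMu"] <= 1)
    expect_true(fg["GLCMmp"] > 0 && fg["GLCMmp"] <= 1)
    expect_gte(fg["GLCMe"], 0)
    expect_true(fg["GLCMh"] > 0 && fg["GLCMh"] <= 1)
    expect_gte(fg["GLCMi"], 0)
    expect_true(abs(fg["GLCMc"]) <= 1 + 1e-12)
    expect_true(fr["GLRMsr"] > 0 && fr["GLRMsr"] <= 1)
    expect_gte(fr["GLRMlr"], 1)
    expect_true(fr["GLRMrr"] > 0 && fr["GLRMrr"] <= 1)
  }
})
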