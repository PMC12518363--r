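test_that("correlation matrices satisfy affine invariance and match a direct oracle", {
  set.seed(9)
  tab <- data.frame(A = rnorm(50))
  tab$B <- 2 * tab$A + 1
  tab$C <- rnorm(50)
  cm <- correlation_matrix(tab, traits = c("A", "B", "C"))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r["A", "B"], 1)
  # brute-force covariance/SD oracle
  tab5 <- as.data.frame(matrix(rnorm(250), 50, 5))
  names(tab5) <- paste0("t", 1:5)
  cm5 <- correlation_matrix(tab5, traits = names(tab5))
  for (i in 1:5) for (j in 1:5) {
    x <- tab5[[i]]; y <- tab5[[j]]
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cm5$r[i, j], r_oracle, tolerance = 1e-12)
  }
})

test_that("constant traits are excluded with a warning and tiny tables error", {
  tab <- data.frame(A = rnorm(10), K = rep(1, 10))
  expect_warning(cm <- correlation_matrix(tab, traits = c("A", "K")),
                 "constant")
  expect_equal(cm$traits, "A")
  expect_error(correlation_matrix(data.frame(A = 1:2, B = 2:3),
                                  traits = c("A", "B")),
               "insufficient data")
})

test_that("line-mean unit correlates genotype means, not grains", {
  set.seed(21)
  tab <- data.frame(genotype = rep(c("g1", "g2", "g3", "g4"), each = 10),
                    A = rnorm(40), B = rnorm(40))
  cm <- correlation_matrix(tab, traits = c("A", "B"), unit = "line_mean")
  expect_equal(cm$n, 4)
  means <- aggregate(tab[c("A", "B")], by = tab["genotype"], mean)
  expect_equal(cm$r["A", "B"], cor(means$A, means$B), tolerance = 1e-12)
})

test_that("UPGMA reproduces the hand-built 3-trait tree", {
  r <- diag(3); dimnames(r) <- list(c("A", "B", "C"), c("A", "B", "C"))
  r["A", "B"] <- r["B", "A"] <- 0.9
  r["A", "C"] <- r["C", "A"] <- r["B", "C"] <- r["C", "B"] <- 0.1
  tr <- upgma_tree(r)
  # d(A,B) = 0.1 -> merge at 0.05 ultrametric; C joins at 0.9 / 2
  expect_equal(tr$merge_height, c(0.05, 0.45))
  expect_match(newick(tr), "A:0.05")
  cl <- cut_clusters(tr, 0.25)
  expect_equal(unname(cl[c("A", "B")]), c(1, 1))
  expect_equal(unname(cl["C"]), 2)
  expect_equal(length(unique(cut_clusters(tr, 0))), 3)
  expect_equal(length(unique(cut_clusters(tr, 1))), 1)
})

test_that("identical traits collapse to a star at height zero", {
  r <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(r)
  expect_equal(tr$merge_height, c(0, 0))
})

test_that("UPGMA cophenetic distances match a textbook oracle and ignore input order", {
  set.seed(33)
  n <- 8
  labs <- paste0("t", 1:n)
  r <- cor(matrix(rnorm(40 * n), 40, n))
  dimnames(r) <- list(labs, labs)
  tr <- upgma_tree(r)
  coph <- as.matrix(cophenetic(tr$hclust))
  D <- 1 - abs(r)
  oracle <- oracle_upgma_cophenetic(D)
  expect_equal(coph[labs, labs], oracle[labs, labs], tolerance = 1e-12)
  # permuting trait order leaves the tree unchanged
  perm <- sample(n)
  tr2 <- upgma_tree(r[perm, perm])
  expect_equal(tr$merge_height, tr2$merge_height)
  expect_equal(as.matrix(cophenetic(tr2$hclust))[labs, labs],
               coph[labs, labs], tolerance = 1e-12)
})

test_that("the one_minus_r distance separates anticorrelated traits", {
  r <- diag(2); dimnames(r) <- list(c("A", "B"), c("A", "B"))
  r["A", "B"] <- r["B", "A"] <- -0.9
  habs <- upgma_tree(r, distance = "one_minus_abs_r")$merge_height
  hraw <- upgma_tree(r, distance = "one_minus_r")$merge_height
  expect_equal(habs, 0.05)
  expect_equal(hraw, 0.95)
})

test_that("PCA on the correlation matrix honors its algebraic identities", {
  set.seed(41)
  tab <- data.frame(A = rnorm(200))
  tab$B <- tab$A * 3 + 5  # perfectly correlated pair
  p <- trait_pca(tab, traits = c("A", "B"))
  expect_equal(p$shares[1], 1, tolerance = 1e-12)

  k <- 5
  tab2 <- as.data.frame(matrix(rnorm(10000 * k), ncol = k))
  names(tab2) <- paste0("t", 1:k)
  p2 <- trait_pca(tab2, traits = names(tab2))
  expect_equal(sum(p2$shares), 1, tolerance = 1e-12)
  expect_true(all(abs(p2$shares - 1 / k) < 0.05))  # isotropic input
  expect_equal(crossprod(p2$loadings), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  # cor(PC1 scores, trait j) = loading_j * sqrt(eigenvalue_1)
  for (j in 1:k)
    expect_equal(cor(p2$scores[, 1], tab2[[j]]),
                 p2$loadings[j, 1] * p2$sdev[1], tolerance = 1e-8)
})
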