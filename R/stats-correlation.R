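#' Pearson correlation matrix of traits
#'
#' @param table trait table; numeric trait columns are used.
#' @param traits character vector of columns to correlate; defaults to all
#'   texture + color traits present.
#' @param unit `"grain"` (each row one observation) or `"line_mean"`
#'   (per-genotype means are the observations).
#' @return object of class `trait_cor`: `r` (symmetric matrix with unit
#'   diagonal), `traits`, `unit`, `n` (observations used). Constant columns
#'   are excluded with a warning.
#' @export
correlation_matrix <- function(table, traits = NULL,
                               unit = c("grain", "line_mean")) {
  unit <- match.arg(unit)
  if (is.null(traits))
    traits <- intersect(c(texture_trait_names(), color_trait_names()),
                        names(table))
  dat <- table[, traits, drop = FALSE]
  if (unit == "line_mean") {
    dat <- aggregate(dat, by = list(genotype = table$genotype), FUN = mean)
    dat <- dat[, traits, drop = FALSE]
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3)
    stop("insufficient data: need at least 3 observations")
  sds <- vapply(dat, sd, 0)
  if (any(sds == 0)) {
    warning("excluding constant trait(s): ",
            paste(names(sds)[sds == 0], collapse = ", "))
    dat <- dat[, sds > 0, drop = FALSE]
  }
  structure(list(r = cor(dat), traits = colnames(dat), unit = unit,
                 n = nrow(dat)), class = "trait_cor")
}

#' UPGMA trait-similarity tree from a correlation matrix
#'
#' The distance between traits is `d = 1 - |r|` (default) or `d = 1 - r`;
#' the tree is average-linkage (UPGMA) agglomeration of that distance.
#' Merge heights are reported on the ultrametric scale (tip-to-node height
#' = merge distance / 2).  Traits are sorted lexicographically before
#' clustering so ties break deterministically by smallest leaf name.
#'
#' @param C a [correlation_matrix()] result, or a plain symmetric
#'   correlation matrix with dimnames.
#' @param distance `"one_minus_abs_r"` or `"one_minus_r"`.
#' @return object of class `trait_tree`: `hclust` (merge heights on the
#'   distance scale), `merge_height` (ultrametric, = height/2), `phylo`
#'   (an [ape::as.phylo()] tree with branch lengths on the ultrametric
#'   scale), `labels`, `distance`.
#' @export
#' @examples
#' r <- diag(3); dimnames(r) <- list(c("A", "B", "C"), c("A", "B", "C"))
#' r["A", "B"] <- r["B", "A"] <- 0.9
#' r["A", "C"] <- r["C", "A"] <- r["B", "C"] <- r["C", "B"] <- 0.1
#' upgma_tree(r)$merge_height
upgma_tree <- function(C, distance = c("one_minus_abs_r", "one_minus_r")) {
  distance <- match.arg(distance)
  r <- if (inherits(C, "trait_cor")) C$r else C
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  ord <- order(rownames(r))
  r <- r[ord, ord]
  d <- if (distance == "one_minus_abs_r") 1 - abs(r) else 1 - r
  hc <- hclust(as.dist(d), method = "average")
  structure(list(hclust = hc, merge_height = hc$height / 2,
                 phylo = ape::as.phylo(hc), labels = hc$labels,
                 distance = distance), class = "trait_tree")
}

#' @rdname upgma_tree
#' @param tree a `trait_tree`.
#' @param ... passed on.
#' @export
newick <- function(tree, ...) UseMethod("newick")

#' @export
newick.trait_tree <- function(tree, ...) ape::write.tree(tree$phylo, ...)

#' Cut a trait tree into clusters at a height
#'
#' Clusters are the connected leaf sets whose merges lie at or below `h` on
#' the ultrametric scale (tip-to-node = merge distance / 2).  Cluster ids
#' are numbered by first appearance in leaf order.
#'
#' @param tree a `trait_tree`.
#' @param h cut height, `>= 0`, on the `merge_height` scale.
#' @return named integer vector: trait -> cluster id.
#' @export
cut_clusters <- function(tree, h) {
  stopifnot(inherits(tree, "trait_tree"), h >= 0)
  cutree(tree$hclust, h = 2 * h)
}

#' PCA of traits on the correlation matrix
#'
#' Each trait is standardized (mean 0, SD 1) and the correlation matrix is
#' eigendecomposed.  Components are ordered by decreasing eigenvalue and
#' the sign of each is fixed so its largest-magnitude loading is positive.
#' Constant traits are excluded with a warning.
#'
#' @param table trait table.
#' @param traits columns to include; defaults to the 16 texture traits.
#' @return object of class `trait_pca`: `loadings` (trait x component,
#'   orthonormal), `scores` (observation x component), `shares`
#'   (per-component variance shares, summing to 1), `sdev`, `traits`.
#' @export
trait_pca <- function(table, traits = NULL) {
  if (is.null(traits))
    traits <- intersect(texture_trait_names(), names(table))
  dat <- table[, traits, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(traits) + 1)
    stop("insufficient data: need more observations than traits")
  sds <- vapply(dat, sd, 0)
  if (any(sds == 0)) {
    warning("excluding constant trait(s): ",
            paste(names(sds)[sds == 0], collapse = ", "))
    dat <- dat[, sds > 0, drop = FALSE]
  }
  z <- scale(as.matrix(dat))
  eg <- eigen(cor(as.matrix(dat)), symmetric = TRUE)
  load <- eg$vectors
  for (k in seq_len(ncol(load))) {
    m <- which.max(abs(load[, k]))
    if (load[m, k] < 0) load[, k] <- -load[, k]
  }
  dimnames(load) <- list(colnames(dat), paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  ev <- pmax(eg$values, 0)
  structure(list(loadings = load, scores = scores, shares = ev / sum(ev),
                 sdev = sqrt(ev), traits = colnames(dat)),
            class = "trait_pca")
}
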