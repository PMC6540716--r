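# Ordination and clustering of exudate profiles: PCA, RDA constrained on a
# predictor matrix, partial RDA, detrended correspondence analysis for the
# neighborhood community, and agglomerative hierarchical clustering.

.ordination_result <- function(kind, site_scores, eigenvalues, total_variance,
                               constrained = NULL, conditioned = 0,
                               extra = list()) {
  proportions <- if (total_variance > 0) eigenvalues / total_variance else
    rep(0, length(eigenvalues))
  structure(
    c(list(kind = kind, site_scores = site_scores,
           eigenvalues = eigenvalues, axis_proportions = proportions,
           total_variance = total_variance,
           constrained_proportion = if (is.null(constrained)) NA_real_ else
             if (total_variance > 0) constrained / total_variance else 0,
           conditioned_variance = conditioned),
      extra),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes, total variance %.4g\n",
              x$kind, nrow(x$site_scores), ncol(x$site_scores),
              x$total_variance))
  k <- min(6L, length(x$eigenvalues))
  cat("  first axis proportions: ",
      paste(sprintf("%.2f%%", 100 * x$axis_proportions[seq_len(k)]),
            collapse = ", "), "\n")
  if (!is.na(x$constrained_proportion)) {
    cat(sprintf("  constrained proportion: %.4f\n", x$constrained_proportion))
  }
  invisible(x)
}

#' Principal component analysis
#'
#' PCA by singular value decomposition of the column-centered (optionally
#' scaled) matrix; eigenvalue of axis i is `s_i^2 / (n - 1)` so the
#' eigenvalues sum to the total variance. Site scores are principal
#' coordinates (`U %*% diag(s)`).
#'
#' @param x numeric matrix, samples in rows.
#' @param center,scale center / scale columns before decomposition.
#' @return an `ordination_result` (kind "PCA").
#' @export
pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  xc <- scale(x, center = center, scale = scale)
  if (scale) xc[, attr(xc, "scaled:scale") == 0] <- 0
  xc <- xc[, , drop = FALSE]  # strip scaling attributes
  attr(xc, "scaled:center") <- NULL
  attr(xc, "scaled:scale") <- NULL
  n <- nrow(xc)
  total <- sum(xc^2) / (n - 1)
  sv <- svd(xc)
  keep <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-9
  if (!any(keep)) {
    scores <- matrix(0, n, 1, dimnames = list(rownames(x), "PC1"))
    return(.ordination_result("PCA", scores, 0, total))
  }
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  dimnames(scores) <- list(rownames(x),
                           paste0("PC", seq_len(ncol(scores))))
  .ordination_result("PCA", scores, d^2 / (n - 1), total,
                     extra = list(rotation = sv$v[, keep, drop = FALSE]))
}

# core constrained decomposition shared by rda()/partial_rda():
# Y and X are already centered (Y possibly residualized). `x_scale` is the
# largest singular value of the predictor matrix before any residualization,
# the reference against which negligible directions are pruned.
.rda_core <- function(Yc, Xc, total, conditioned, kind, rownames_y,
                      x_scale = NULL) {
  n <- nrow(Yc)
  sx <- svd(Xc)
  ref <- if (is.null(x_scale) || x_scale <= 0) sx$d[1] else x_scale
  pos <- if (ref > 0) sx$d > ref * 1e-9 else rep(FALSE, length(sx$d))
  rank_x <- sum(pos)
  if (rank_x >= n - 1L && rank_x > 0L) {
    stop("saturated model: rank(X) must be below the number of samples",
         call. = FALSE)
  }
  fitted <- if (rank_x > 0L) {
    u <- sx$u[, pos, drop = FALSE]
    u %*% crossprod(u, Yc)
  } else {
    matrix(0, n, ncol(Yc))
  }
  resid <- Yc - fitted
  svf <- svd(fitted)
  svr <- svd(resid)
  keep_f <- svf$d > max(svf$d[1], .Machine$double.eps) * 1e-8
  keep_r <- svr$d > max(svr$d[1], .Machine$double.eps) * 1e-8
  eig_c <- svf$d[keep_f]^2 / (n - 1)
  eig_u <- svr$d[keep_r]^2 / (n - 1)
  scores_c <- svf$u[, keep_f, drop = FALSE] %*%
    diag(svf$d[keep_f], sum(keep_f))
  scores_u <- svr$u[, keep_r, drop = FALSE] %*%
    diag(svr$d[keep_r], sum(keep_r))
  if (!length(eig_c)) {
    eig_c <- numeric(0)
    scores_c <- matrix(0, n, 0)
  }
  colnames_c <- if (ncol(scores_c)) paste0(substr(kind, 1, 3),
                                           seq_len(ncol(scores_c)))
  dimnames(scores_c) <- list(rownames_y, colnames_c)
  .ordination_result(
    kind, scores_c, eig_c, total,
    constrained = sum(eig_c), conditioned = conditioned,
    extra = list(unconstrained_eigenvalues = eig_u,
                 unconstrained_scores = scores_u,
                 rank_x = rank_x)
  )
}

#' Redundancy analysis
#'
#' Constrains the response matrix to the column space of a predictor matrix:
#' Y is column-centered, regressed on the (centered) predictors by a
#' rank-revealing least-squares fit, and the fitted values are decomposed by
#' SVD. Constrained eigenvalues are `s_i^2/(n-1)`; axis proportions are
#' relative to the total variance of centered Y, so the constrained
#' proportion is the ordinary multivariate R-squared. Residual (unconstrained)
#' axes are returned alongside.
#'
#' @param Y response matrix (samples x features); centered internally.
#' @param X predictor matrix (numeric; dummy-code factors, e.g. with
#'   [indicator_matrix()]). Any coding spanning the same column space gives
#'   the same result.
#' @return an `ordination_result` (kind "RDA") with
#'   `unconstrained_eigenvalues`, `unconstrained_scores` and `rank_x`.
#' @export
rda <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X need matching rows", call. = FALSE)
  if (nrow(Y) < 2L) stop("need at least 2 samples", call. = FALSE)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  total <- sum(Yc^2) / (n - 1)
  .rda_core(Yc, Xc, total, 0, "RDA", rownames(Y))
}

#' Partial redundancy analysis
#'
#' RDA of Y on X after removing the conditioning matrix Z from both: Y and X
#' are residualized on (centered) Z, and the variance captured by Z is
#' reported separately as conditioned variance. Conditioned + constrained +
#' unconstrained variance equals the total variance of centered Y.
#'
#' @param Y response matrix.
#' @param X predictor matrix.
#' @param Z conditioning matrix.
#' @return an `ordination_result` (kind "partialRDA").
#' @export
partial_rda <- function(Y, X, Z) {
  Y <- as.matrix(Y); X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(Y) != nrow(X) || nrow(Y) != nrow(Z)) {
    stop("Y, X, Z need matching rows", call. = FALSE)
  }
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  total <- sum(Yc^2) / (n - 1)
  qz <- qr(Zc)
  Yr <- qr.resid(qz, Yc)
  Xr <- qr.resid(qz, Xc)
  conditioned <- (sum(Yc^2) - sum(Yr^2)) / (n - 1)
  x_scale <- if (any(Xc != 0)) svd(Xc, nu = 0, nv = 0)$d[1] else 0
  .rda_core(Yr, Xr, total, conditioned, "partialRDA", rownames(Y),
            x_scale = x_scale)
}

#' One-hot indicator coding of a label vector
#'
#' @param labels factor or character vector.
#' @param prefix optional column-name prefix.
#' @return binary matrix with one column per level.
#' @export
indicator_matrix <- function(labels, prefix = "") {
  f <- factor(labels)
  m <- stats::model.matrix(~ f - 1)
  colnames(m) <- paste0(prefix, levels(f))
  rownames(m) <- names(labels)
  m
}

#' Detrended correspondence analysis
#'
#' Correspondence analysis of a nonnegative community matrix (reciprocal
#' averaging via SVD of the standardized residual matrix), with axes beyond
#' the first detrended by segments: the axis-1 ordering is cut into
#' `n_segments` equal-width segments and the weighted within-segment mean of
#' each higher axis is subtracted (no nonlinear rescaling). Axis 1 is the
#' plain CA axis 1. Site scores are row principal coordinates.
#'
#' @param community nonnegative matrix samples x species.
#' @param n_segments number of detrending segments (default 26).
#' @param n_axes number of axes to return (default 4).
#' @return an `ordination_result` (kind "DCA"); eigenvalues are the CA
#'   eigenvalues of the returned axes (all in `[0, 1]`).
#' @export
dca <- function(community, n_segments = 26L, n_axes = 4L) {
  m <- as.matrix(community)
  if (any(m < 0)) stop("community matrix must be nonnegative", call. = FALSE)
  keep_r <- rowSums(m) > 0
  keep_c <- colSums(m) > 0
  if (!any(keep_r) || !any(keep_c)) {
    stop("all-zero community matrix", call. = FALSE)
  }
  m <- m[keep_r, keep_c, drop = FALSE]
  p <- m / sum(m)
  r <- rowSums(p)
  cc <- colSums(p)
  s <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(s)
  n_axes <- min(n_axes, sum(sv$d > 1e-12))
  if (n_axes < 1L) n_axes <- 1L
  d <- sv$d[seq_len(n_axes)]
  # row principal coordinates
  scores <- sweep(sv$u[, seq_len(n_axes), drop = FALSE], 1, sqrt(r), "/")
  scores <- sweep(scores, 2, d, "*")
  if (n_axes > 1L) {
    ax1 <- scores[, 1]
    brk <- seq(min(ax1), max(ax1), length.out = n_segments + 1L)
    seg <- findInterval(ax1, brk, rightmost.closed = TRUE, all.inside = TRUE)
    for (j in 2:n_axes) {
      mu <- tapply(scores[, j] * r, seg, sum) / tapply(r, seg, sum)
      scores[, j] <- scores[, j] - mu[as.character(seg)]
    }
  }
  dimnames(scores) <- list(rownames(m), paste0("DCA", seq_len(n_axes)))
  .ordination_result("DCA", scores, d^2, sum(sv$d^2))
}

#' Agglomerative hierarchical clustering
#'
#' Clusters sample profiles by an agglomerative merge sequence (complete
#' linkage by default, the classical default for distance-based clustering
#' of community profiles; single and average linkage available). The default
#' metric is Euclidean distance, which on a binary matrix is the square root
#' of the Hamming distance.
#'
#' @param x numeric matrix (samples x features) or a [stats::dist] object.
#' @param metric distance metric passed to [stats::dist()] when `x` is a
#'   matrix.
#' @param linkage one of "complete", "single", "average".
#' @return an object of classes `exumet_dendrogram` and `hclust` (merge
#'   matrix, heights, labels, order, method), usable with
#'   [stats::cophenetic()], [stats::cutree()] and [ape::as.phylo()].
#' @export
hierarchical_cluster <- function(x, metric = "euclidean",
                                 linkage = c("complete", "single",
                                             "average")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(x, "dist")) x else stats::dist(x, method = metric)
  labels <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- as.matrix(d)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  code <- -seq_len(n)       # hclust codes: negative = singleton
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which.min(D)
    j <- (idx - 1L) %/% n + 1L
    i <- idx - (j - 1L) * n
    height[step] <- D[i, j]
    merge[step, ] <- sort(c(code[i], code[j]))
    new_row <- switch(linkage,
      complete = pmax(D[i, ], D[j, ]),
      single = pmin(D[i, ], D[j, ]),
      average = (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    )
    new_row[i] <- Inf
    D[i, ] <- new_row
    D[, i] <- new_row
    D[j, ] <- Inf
    D[, j] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    code[i] <- step
  }
  order <- .dendrogram_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = linkage,
                 dist.method = if (inherits(x, "dist"))
                   attr(x, "method") else metric,
                 call = match.call()),
            class = c("exumet_dendrogram", "hclust"))
}

.dendrogram_order <- function(merge) {
  expand <- function(row) {
    unlist(lapply(merge[row, ], function(code) {
      if (code < 0) -code else expand(code)
    }))
  }
  expand(nrow(merge))
}

#' Export a dendrogram as a Newick tree string
#'
#' Branch lengths are derived from merge heights (ultrametric tree:
#' leaf depth equals the root height).
#'
#' @param dendro an `hclust`-like object.
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
dendrogram_newick <- function(dendro, file = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(dendro))
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Shannon diversity of a cover vector
#'
#' `H = -sum(p_i log p_i)` over the nonzero cover proportions (natural
#' logarithm). For a matrix, one value per row.
#'
#' @param cover nonnegative vector of covers, or a matrix (samples in rows).
#' @return Shannon index (scalar or per-row vector).
#' @export
shannon_diversity <- function(cover) {
  if (is.matrix(cover)) {
    return(apply(cover, 1, shannon_diversity))
  }
  if (any(cover < 0)) stop("covers must be nonnegative", call. = FALSE)
  s <- sum(cover)
  if (s <= 0) stop("all-zero cover vector", call. = FALSE)
  p <- cover[cover > 0] / s
  -sum(p * log(p))
}
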