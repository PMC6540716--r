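# Variance partitioning of exudate composition over predictor sets,
# Procrustes trait-exudate correlation with permutation test, and the
# land-use-intensity index.

#' Adjusted multivariate R-squared of a constrained ordination
#'
#' Ezekiel's adjustment of the RDA constrained proportion:
#' `R2adj = 1 - (1 - R2) * (n - 1) / (n - p - 1)` with `p = rank(X)` after
#' centering. Can be negative, which is what produces negative variance
#' fractions under unbalanced designs.
#'
#' @param Y response matrix.
#' @param X predictor matrix (numeric / dummy-coded).
#' @return scalar adjusted R-squared.
#' @export
adjusted_r2 <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  p <- qx$rank
  if (n <= p + 1) {
    stop("adjusted R2 undefined: need n > rank(X) + 1", call. = FALSE)
  }
  total <- sum(Yc^2)
  # constrained proportion of the corresponding RDA, via the same
  # rank-revealing projection (no axis decomposition needed)
  r2 <- if (total > 0) sum(qr.fitted(qx, Yc)^2) / total else 0
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variance partitioning over 2-4 predictor sets
#'
#' Computes the adjusted R-squared of every non-empty union of the predictor
#' sets by redundancy analysis, then solves the inclusion-exclusion system
#' for the unique and shared fractions. The fractions plus the residual
#' (`1 - adjR2(all sets)`) sum to 1 by construction. Fractions can be
#' negative under unbalanced designs and are conventionally read as 0.
#'
#' @param Y response matrix (samples x features).
#' @param predictor_sets named list of 2-4 row-aligned predictor matrices
#'   (e.g. `list(Species = ..., Plot = ..., Traits = ...)`).
#' @return object of class `partition_result`: `subset_adjR2` (named by
#'   `+`-joined set unions), `fractions` (unique fractions named by set,
#'   shared fractions named by `&`-joined sets, plus `Residual`), `n`,
#'   `set_names`.
#' @export
variance_partition <- function(Y, predictor_sets) {
  k <- length(predictor_sets)
  if (k < 1L || k > 4L) {
    stop("1 to 4 predictor sets are supported", call. = FALSE)
  }
  if (is.null(names(predictor_sets)) || any(!nzchar(names(predictor_sets)))) {
    names(predictor_sets) <- paste0("X", seq_len(k))
  }
  Y <- as.matrix(Y)
  sets <- lapply(predictor_sets, as.matrix)
  if (any(vapply(sets, nrow, 1L) != nrow(Y))) {
    stop("all predictor sets must be row-aligned with Y", call. = FALSE)
  }
  nm <- names(sets)
  subsets <- lapply(seq_len(2^k - 1L), function(b) which(bitwAnd(b, 2^(seq_len(k) - 1L)) > 0))
  subset_names <- vapply(subsets, function(s) paste(nm[s], collapse = "+"),
                         character(1))
  r2 <- vapply(subsets, function(s) {
    adjusted_r2(Y, do.call(cbind, sets[s]))
  }, numeric(1))
  names(r2) <- subset_names

  # inclusion-exclusion: R(U) = sum of fractions f(S) over S intersecting U
  m <- length(subsets)
  A <- matrix(0, m, m)
  for (u in seq_len(m)) {
    for (s in seq_len(m)) {
      if (length(intersect(subsets[[u]], subsets[[s]]))) A[u, s] <- 1
    }
  }
  f <- solve(A, r2)
  frac_names <- vapply(subsets, function(s) paste(nm[s], collapse = "&"),
                       character(1))
  names(f) <- frac_names
  residual <- 1 - r2[[length(r2)]]
  fractions <- c(f, Residual = residual)
  structure(list(subset_adjR2 = r2, fractions = fractions,
                 n = nrow(Y), set_names = nm),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Variance partition over %d predictor sets (%s), n = %d\n",
              length(x$set_names), paste(x$set_names, collapse = ", "), x$n))
  print(round(100 * x$fractions, 2))
  cat("  (percent of total variance; fractions sum to 100)\n")
  invisible(x)
}

#' Eight-column layout of a three-set partition
#'
#' Arranges the fractions of a three-set [variance_partition()] as the
#' conventional report row: the three unique fractions, the three pairwise
#' shared fractions, the triple shared fraction and the residual.
#'
#' @param partition a `partition_result` over exactly 3 sets.
#' @param percent report percentages (default TRUE).
#' @return named numeric vector of length 8.
#' @export
partition_layout3 <- function(partition, percent = TRUE) {
  stopifnot(inherits(partition, "partition_result"))
  nm <- partition$set_names
  if (length(nm) != 3L) stop("layout requires exactly 3 sets", call. = FALSE)
  f <- partition$fractions
  out <- c(f[nm[1]], f[nm[2]], f[nm[3]],
           f[paste(nm[1], nm[2], sep = "&")],
           f[paste(nm[2], nm[3], sep = "&")],
           f[paste(nm[1], nm[3], sep = "&")],
           f[paste(nm, collapse = "&")],
           f["Residual"])
  names(out) <- c(nm, paste(nm[1], nm[2], sep = " + "),
                  paste(nm[2], nm[3], sep = " + "),
                  paste(nm[1], nm[3], sep = " + "),
                  paste(nm, collapse = " + "), "Residuals")
  if (percent) out * 100 else out
}

.procrustes_prepare <- function(X, symmetric) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ss <- sum(Xc^2)
  if (symmetric) {
    if (ss <= 0) stop("degenerate configuration (zero spread)", call. = FALSE)
    Xc <- Xc / sqrt(ss)
  }
  list(x = Xc, center = ctr, ss = ss)
}

#' Procrustes superimposition of two configurations
#'
#' Centers both configurations, in symmetric mode scales each to unit sum of
#' squares, and finds the orthogonal rotation (from the SVD of the
#' cross-product) plus uniform scaling that minimizes the residual sum of
#' squares `m2` when fitting Y onto X. In symmetric mode
#' `m2 = 1 - (sum of singular values)^2` and the Procrustes correlation is
#' `sqrt(1 - m2)`. Configurations with different column counts are padded
#' with zero columns.
#'
#' @param X_config target configuration (samples x axes), e.g. PCA site
#'   scores of the exudate matrix.
#' @param Y_config configuration rotated onto the target, e.g. PCA site
#'   scores of the trait matrix.
#' @param symmetric symmetric (scale-free) analysis (default TRUE).
#' @return object of class `procrustes_result`: `rotation`, `scaling`,
#'   `translation`, `m2`, `correlation`, plus centered inputs.
#' @export
procrustes_fit <- function(X_config, Y_config, symmetric = TRUE) {
  X_config <- as.matrix(X_config); Y_config <- as.matrix(Y_config)
  if (nrow(X_config) != nrow(Y_config)) {
    stop("configurations need equal row counts", call. = FALSE)
  }
  if (nrow(X_config) < 3L) stop("need at least 3 rows", call. = FALSE)
  p <- max(ncol(X_config), ncol(Y_config))
  pad <- function(m) {
    if (ncol(m) < p) cbind(m, matrix(0, nrow(m), p - ncol(m))) else m
  }
  px <- .procrustes_prepare(pad(X_config), symmetric)
  py <- .procrustes_prepare(pad(Y_config), symmetric)
  sv <- svd(crossprod(px$x, py$x))
  rotation <- sv$v %*% t(sv$u)
  traceW <- sum(sv$d)
  if (symmetric) {
    scaling <- traceW          # both configurations have unit SS
    m2 <- 1 - traceW^2
  } else {
    scaling <- traceW / py$ss
    m2 <- px$ss - traceW^2 / py$ss
  }
  m2 <- max(m2, 0)
  corr <- if (symmetric) sqrt(max(0, 1 - m2)) else NA_real_
  structure(list(rotation = rotation, scaling = scaling,
                 translation = list(X = px$center, Y = py$center),
                 m2 = m2, correlation = corr, symmetric = symmetric,
                 X = px$x, Y = py$x),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes fit (%s): m2 = %.4f",
              if (x$symmetric) "symmetric" else "asymmetric", x$m2))
  if (!is.na(x$correlation)) cat(sprintf(", correlation = %.4f", x$correlation))
  cat("\n")
  if (!is.null(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation_p, x$n_permutations))
  }
  invisible(x)
}

#' Procrustes permutation test (protest)
#'
#' Permutation test of the symmetric Procrustes correlation: the rows of the
#' second configuration are shuffled `n_permutations` times and the p-value
#' is `(1 + #{perm >= observed}) / (1 + n_permutations)`.
#'
#' @inheritParams procrustes_fit
#' @param n_permutations number of row permutations (default 999).
#' @param seed integer seed (mandatory: the test is Monte-Carlo).
#' @return a `procrustes_result` with `permutation_p`, `n_permutations` and
#'   `permutation_stats` added.
#' @export
protest <- function(X_config, Y_config, n_permutations = 999L, seed) {
  fit <- procrustes_fit(X_config, Y_config, symmetric = TRUE)
  n <- nrow(fit$X)
  stats_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      sum(svd(crossprod(fit$X, fit$Y[sample.int(n), , drop = FALSE]))$d)
    }, numeric(1))
  })
  fit$permutation_stats <- stats_perm
  fit$n_permutations <- as.integer(n_permutations)
  fit$permutation_p <- (1 + sum(stats_perm >= fit$correlation)) /
    (1 + n_permutations)
  fit
}

#' Land-use-intensity index
#'
#' `LUI = F_i/F_r + M_i/M_r + G_i/G_r` per plot and year, where F, M, G are
#' fertilization (kg N ha^-1 yr^-1), mowing frequency (yr^-1) and grazing
#' intensity, and the reference values are the component means within the
#' site (region) over all plot-years. The multi-year mean per plot is
#' reported alongside.
#'
#' @param components data.frame with columns plot, region, year,
#'   fertilization, mowing, grazing (see [generate_lui_components()]).
#' @param reference_means optional data.frame region/fertilization/mowing/
#'   grazing overriding the within-site means.
#' @return list with `records` (per plot-year: components, references, lui)
#'   and `by_plot` (per plot: mean LUI over the covered years).
#' @export
lui_index <- function(components, reference_means = NULL) {
  need <- c("plot", "region", "year", "fertilization", "mowing", "grazing")
  if (!all(need %in% names(components))) {
    stop("`components` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(components$fertilization < 0) || any(components$mowing < 0) ||
      any(components$grazing < 0)) {
    stop("components must be nonnegative", call. = FALSE)
  }
  if (is.null(reference_means)) {
    reference_means <- do.call(rbind, lapply(split(components,
                                                   components$region),
                                             function(d) {
      data.frame(region = d$region[1],
                 fertilization = mean(d$fertilization),
                 mowing = mean(d$mowing),
                 grazing = mean(d$grazing),
                 stringsAsFactors = FALSE)
    }))
  }
  idx <- match(components$region, reference_means$region)
  if (anyNA(idx)) stop("reference means missing for some region", call. = FALSE)
  fr <- reference_means$fertilization[idx]
  mr <- reference_means$mowing[idx]
  gr <- reference_means$grazing[idx]
  if (any(fr <= 0) || any(mr <= 0) || any(gr <= 0)) {
    stop("zero reference mean: LUI undefined", call. = FALSE)
  }
  records <- components
  records$F_r <- fr; records$M_r <- mr; records$G_r <- gr
  records$lui <- components$fertilization / fr + components$mowing / mr +
    components$grazing / gr
  by_plot <- do.call(rbind, lapply(split(records, records$plot), function(d) {
    data.frame(plot = d$plot[1], region = d$region[1],
               lui_mean = mean(d$lui), n_years = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(by_plot) <- NULL
  list(records = records, by_plot = by_plot)
}
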