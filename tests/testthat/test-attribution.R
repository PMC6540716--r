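test_that("adjusted R2 follows the Ezekiel formula and its limits", {
  set.seed(1)
  g <- rep(letters[1:3], each = 8)
  X <- indicator_matrix(g)
  Y <- X %*% matrix(rnorm(18), 3, 6)
  expect_equal(adjusted_r2(Y, X), 1, tolerance = 1e-10)
  noise <- matrix(rnorm(24 * 2), 24, 2)
  r2a <- adjusted_r2(matrix(rnorm(24 * 6), 24, 6), noise)
  r2o <- adj_r2_oracle(matrix(rnorm(24 * 6), 24, 6), noise)
  expect_true(is.finite(r2a) && is.finite(r2o))
  expect_error(adjusted_r2(Y[1:4, ], matrix(rnorm(20), 4, 5)), "n > rank")
})

test_that("adjusted R2 is unbiased near zero under the null", {
  skip_if_not_installed("vegan")
  set.seed(2)
  reps <- 500
  vals <- vapply(seq_len(reps), function(i) {
    adjusted_r2(matrix(rnorm(40 * 5), 40, 5), matrix(rnorm(40 * 20), 40, 20))
  }, numeric(1))
  se <- stats::sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals)), 3 * se)
  # spot-check one draw against vegan
  Y <- matrix(rnorm(40 * 5), 40, 5); X <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(adjusted_r2(Y, X),
               vegan::RsquareAdj(vegan::rda(Y ~ X))$adj.r.squared,
               tolerance = 1e-10)
})

test_that("three-set partition matches the subset-model oracle", {
  set.seed(3)
  n <- 60
  X1 <- matrix(rnorm(n * 3), n, 3)
  X2 <- matrix(rnorm(n * 3), n, 3)
  X3 <- matrix(rnorm(n * 2), n, 2)
  Y <- X1 %*% matrix(rnorm(30), 3, 10) + X2 %*% matrix(rnorm(30), 3, 10) +
    matrix(rnorm(n * 10), n, 10)
  vp <- variance_partition(Y, list(A = X1, B = X2, C = X3))
  # oracle: the 7 subset models fitted independently via dense hat matrices
  r <- list(A = adj_r2_oracle(Y, X1), B = adj_r2_oracle(Y, X2),
            C = adj_r2_oracle(Y, X3),
            AB = adj_r2_oracle(Y, cbind(X1, X2)),
            AC = adj_r2_oracle(Y, cbind(X1, X3)),
            BC = adj_r2_oracle(Y, cbind(X2, X3)),
            ABC = adj_r2_oracle(Y, cbind(X1, X2, X3)))
  f <- vp$fractions
  expect_equal(f[["A"]], r$ABC - r$BC, tolerance = 1e-10)
  expect_equal(f[["B"]], r$ABC - r$AC, tolerance = 1e-10)
  expect_equal(f[["C"]], r$ABC - r$AB, tolerance = 1e-10)
  expect_equal(f[["A&B"]], r$AC + r$BC - r$C - r$ABC, tolerance = 1e-10)
  expect_equal(f[["A&C"]], r$AB + r$BC - r$B - r$ABC, tolerance = 1e-10)
  expect_equal(f[["B&C"]], r$AB + r$AC - r$A - r$ABC, tolerance = 1e-10)
  expect_equal(f[["Residual"]], 1 - r$ABC, tolerance = 1e-10)
  expect_equal(sum(f), 1, tolerance = 1e-10)
  lay <- partition_layout3(vp, percent = FALSE)
  expect_equal(length(lay), 8L)
  expect_equal(sum(lay), 1, tolerance = 1e-10)
})

test_that("partition fractions agree with vegan::varpart", {
  skip_if_not_installed("vegan")
  set.seed(4)
  n <- 50
  X1 <- matrix(rnorm(n * 2), n, 2); X2 <- matrix(rnorm(n * 3), n, 3)
  Y <- X1 %*% matrix(rnorm(2 * 8), 2, 8) + matrix(rnorm(n * 8), n, 8)
  vp <- variance_partition(Y, list(A = X1, B = X2))
  vv <- vegan::varpart(Y, X1, X2)
  ind <- vv$part$indfract
  expect_equal(unname(vp$fractions[c("A", "B", "A&B", "Residual")]),
               ind$Adj.R.square, tolerance = 1e-10)
})

test_that("degenerate partitions behave per contract", {
  set.seed(5)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  X <- matrix(rnorm(30 * 2), 30, 2)
  vp1 <- variance_partition(Y, list(X = X))
  expect_equal(unname(vp1$fractions["X"]), adjusted_r2(Y, X),
               tolerance = 1e-12)
  expect_equal(unname(vp1$fractions["Residual"]),
               1 - adjusted_r2(Y, X), tolerance = 1e-12)
  expect_error(variance_partition(Y, rep(list(X), 5)), "1 to 4")
  expect_error(partition_layout3(variance_partition(Y, list(A = X, B = X))),
               "3 sets")
})

test_that("orthogonal predictors share (almost) no variance", {
  set.seed(6)
  n <- 400
  q <- qr.Q(qr(matrix(rnorm(n * 11), n, 11)))[, -1]  # orthogonal to 1
  X1 <- q[, 1:5]; X2 <- q[, 6:10]
  Y <- X1 %*% matrix(rnorm(5 * 12), 5, 12) +
    X2 %*% matrix(rnorm(5 * 12), 5, 12) + matrix(rnorm(n * 12), n, 12)
  vp <- variance_partition(Y, list(A = X1, B = X2))
  expect_lt(abs(vp$fractions[["A&B"]]), 0.02)
})

test_that("Procrustes correlation is a similarity invariant", {
  set.seed(7)
  X <- matrix(rnorm(60), 20, 3)
  ident <- procrustes_fit(X, X)
  expect_equal(ident$correlation, 1, tolerance = 1e-12)
  expect_equal(ident$m2, 0, tolerance = 1e-12)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Y <- X %*% rot * 5 + matrix(2, 20, 3)
  expect_equal(procrustes_fit(X, Y)$correlation, 1, tolerance = 1e-12)
  expect_error(procrustes_fit(X[1:2, ], X[1:2, ]), "3 rows")
})

test_that("Procrustes statistics match the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(8)
  X <- matrix(rnorm(300), 100, 3)
  Y <- matrix(rnorm(300), 100, 3)
  ours <- procrustes_fit(X, Y)
  ref <- vegan::procrustes(X, Y, symmetric = TRUE)
  expect_equal(ours$m2, ref$ss, tolerance = 1e-10)
  expect_equal(ours$correlation, sqrt(1 - ref$ss), tolerance = 1e-10)
  # differing column counts are padded, as in the reference implementation
  Y2 <- matrix(rnorm(200), 100, 2)
  expect_equal(procrustes_fit(X, Y2)$m2,
               vegan::procrustes(X, Y2, symmetric = TRUE)$ss,
               tolerance = 1e-10)
})

test_that("protest p-values honour the add-one convention and the seed", {
  set.seed(9)
  X <- matrix(rnorm(90), 30, 3)
  same <- protest(X, X, n_permutations = 99, seed = 5)
  expect_equal(same$permutation_p, 1 / 100)
  a <- protest(X, matrix(rnorm(90), 30, 3), n_permutations = 199, seed = 7)
  b <- protest(X, a$Y, n_permutations = 199, seed = 7)
  expect_identical(a$permutation_p, b$permutation_p)
  expect_gte(a$permutation_p, 1 / 200)
})

test_that("trait-exudate Procrustes responds to the shared species signal", {
  d <- generate_design(seed = 10)
  corrs <- vapply(c(0, 0.6, 2), function(eff) {
    ft <- generate_feature_table(
      d, truth_spec(n_specific_per_species = 30L, n_blank_contaminant = 0,
                    n_singleton = 0), seed = 11)
    tr <- generate_traits(d, species_effect_size = eff, seed = 12)
    pa <- to_presence_absence(ft$table)
    protest(pca(pa)$site_scores[, 1:10],
            pca(scale(tr))$site_scores[, 1:10],
            n_permutations = 99, seed = 3)$correlation
  }, numeric(1))
  expect_true(all(diff(corrs) > 0))
  # strong shared structure is detected
  ft <- generate_feature_table(d, truth_spec(), seed = 11)
  tr <- generate_traits(d, species_effect_size = 2, noise_sd = 0.3,
                        seed = 3)
  pa <- to_presence_absence(ft$table)
  pt <- protest(pca(pa)$site_scores[, 1:10],
                pca(scale(tr))$site_scores[, 1:10],
                n_permutations = 199, seed = 3)
  expect_lte(pt$permutation_p, 0.05)
})

test_that("LUI reproduces the standardization identities", {
  plots <- data.frame(plot = c("p1", "p2", "p3"), region = "ALB")
  comp <- data.frame(plot = rep(plots$plot, 2), region = "ALB",
                     year = rep(2006:2007, each = 3),
                     fertilization = 30, mowing = 2, grazing = 100)
  res <- lui_index(comp)
  expect_true(all(abs(res$records$lui - 3) < 1e-12))
  # F doubled, M zero, G at reference: 2 + 0 + 1 = 3
  comp2 <- comp
  comp2$fertilization[1] <- 2 * mean(comp$fertilization)
  comp2$mowing[1] <- 0
  ref <- data.frame(region = "ALB", fertilization = 30, mowing = 2,
                    grazing = 100)
  res2 <- lui_index(comp2, reference_means = ref)
  expect_equal(res2$records$lui[1], 3)
  expect_error(lui_index(comp, data.frame(region = "ALB", fertilization = 0,
                                          mowing = 2, grazing = 100)),
               "zero reference")
})

test_that("multi-year LUI means match a hand-computed average", {
  d <- generate_design(seed = 13)
  comp <- generate_lui_components(d$plots, years = 2006:2014, seed = 14)
  res <- lui_index(comp)
  expect_equal(sort(unique(comp$year)), 2006:2014)
  # recompute for one plot by hand
  p <- res$by_plot$plot[5]
  rows <- res$records[res$records$plot == p, ]
  hand <- mean(rows$fertilization / rows$F_r + rows$mowing / rows$M_r +
                 rows$grazing / rows$G_r)
  expect_equal(res$by_plot$lui_mean[res$by_plot$plot == p], hand,
               tolerance = 1e-12)
  expect_equal(res$by_plot$n_years[1], 9L)
})
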