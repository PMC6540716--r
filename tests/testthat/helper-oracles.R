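# Independent oracles used to validate the analytical code paths. These are
# deliberately naive (explicit summation, dense hat matrices, O(n^3) loops)
# and share no code with the implementation.

# upper binomial tail by direct pmf summation
pmf_tail_oracle <- function(k, size, p0) {
  if (k <= 0) return(1)
  x <- k:size
  sum(choose(size, x) * p0^x * (1 - p0)^(size - x))
}

# RDA by explicit pseudoinverse hat matrix + dense eigendecomposition
rda_oracle <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  ginv <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
  H <- Xc %*% ginv
  fitted <- H %*% Yc
  ev <- eigen(crossprod(fitted) / (n - 1), symmetric = TRUE)$values
  ev_res <- eigen(crossprod(Yc - fitted) / (n - 1), symmetric = TRUE)$values
  list(
    eig_constrained = ev[ev > max(ev[1], 1e-300) * 1e-7],
    eig_unconstrained = ev_res[ev_res > max(ev_res[1], 1e-300) * 1e-7],
    total = sum(Yc^2) / (n - 1),
    r2 = sum(fitted^2) / sum(Yc^2),
    rank = sum(pos)
  )
}

adj_r2_oracle <- function(Y, X) {
  o <- rda_oracle(Y, X)
  n <- nrow(as.matrix(Y))
  1 - (1 - o$r2) * (n - 1) / (n - o$rank - 1)
}

# O(n^3) complete-linkage agglomeration recording the cophenetic matrix
cophenetic_oracle <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  repeat {
    if (length(members) == 1L) break
    best <- c(Inf, 0, 0)
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (a >= b) next
        h <- max(D[members[[a]], members[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    a <- best[2]; b <- best[3]
    coph[members[[a]], members[[b]]] <- best[1]
    coph[members[[b]], members[[a]]] <- best[1]
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- NULL
  }
  dimnames(coph) <- dimnames(D)
  coph
}

# direct evaluation of the Scheffe inequality for every pair
scheffe_oracle <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  mse <- sum(unlist(tapply(values, groups,
                           function(v) (v - mean(v))^2))) / (N - k)
  pairs <- utils::combn(levels(groups), 2)
  sig <- logical(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    lhs <- abs(means[[a]] - means[[b]])
    rhs <- sqrt((k - 1) * stats::qf(1 - alpha, k - 1, N - k) * mse *
                  (1 / ns[[a]] + 1 / ns[[b]]))
    sig[i] <- lhs > rhs
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], significant = sig,
             stringsAsFactors = FALSE)
}

# small hand-built feature table: 4 exudate + 4 blank samples, with a
# known contaminant, a singleton and two clean features
tiny_feature_table <- function() {
  m <- rbind(
    #          clean1 clean2 contam single
    exu1 = c(  5,     0,     7,     0),
    exu2 = c(  6,     2,     0,     0),
    exu3 = c(  0,     3,     0,     9),
    exu4 = c(  4,     1,     0,     0),
    blank1 = c(0,     0,     8,     0),
    blank2 = c(0,     0,     6,     0),
    blank3 = c(0,     0,     0,     0),
    blank4 = c(0,     0,     0,     0)
  )
  colnames(m) <- c("clean1", "clean2", "contam", "single")
  meta <- data.frame(
    sample_id = rownames(m),
    species = c("A", "A", "B", "B", NA, NA, NA, NA),
    growth_form = c("forb", "forb", "grass", "grass", NA, NA, NA, NA),
    plot = c("p1", "p2", "p1", "p2", NA, NA, NA, NA),
    region = "R1",
    sample_type = rep(c("exudate", "blank"), each = 4),
    stringsAsFactors = FALSE
  )
  feature_table(m, meta)
}
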