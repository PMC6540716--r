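# Chemical richness per sample, species-level ANOVA and Scheffe post hoc
# with a compact-letter display.

#' Chemical richness per sample
#'
#' Number of features detected in each sample: the row sums of the binary
#' presence/absence matrix.
#'
#' @param pa binary matrix (samples x features), e.g. a `pa_matrix`.
#' @return named integer vector of per-sample richness.
#' @export
chemical_richness <- function(pa) {
  if (!all(pa %in% c(0L, 1L))) {
    stop("`pa` must be binary (0/1)", call. = FALSE)
  }
  rs <- rowSums(pa)
  storage.mode(rs) <- "integer"
  rs
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition of a numeric response over a
#' grouping factor, fitted with [stats::aov()]. Two degenerate limits have a
#' defined contract: zero between-group variance reports F = 0, p = 1;
#' zero within-group variance with distinct means reports F = Inf, p = 0.
#'
#' @param values numeric response (e.g. per-sample chemical richness).
#' @param groups grouping labels, one per value.
#' @return list with `F`, `df1`, `df2`, `p`, and the fitted `aov` object.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) {
    stop("need at least 2 groups for ANOVA", call. = FALSE)
  }
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  if (length(values) <= nlevels(groups)) {
    stop("need total N > number of groups", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  # perfect fits trip anova's reliability warning; both degenerate limits
  # are handled explicitly below
  tab <- suppressWarnings(stats::anova(fit))
  ss_b <- tab$`Sum Sq`[1]
  ss_w <- tab$`Sum Sq`[2]
  df1 <- tab$Df[1]
  df2 <- tab$Df[2]
  if (ss_b <= .Machine$double.eps * max(1, ss_w)) {
    f <- 0; p <- 1
  } else if (ss_w <= .Machine$double.eps * ss_b) {
    f <- Inf; p <- 0
  } else {
    f <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
  }
  list(F = f, df1 = df1, df2 = df2, p = p, fit = fit)
}

#' Scheffe post hoc test with compact-letter display
#'
#' All-pairs comparisons after a one-way ANOVA using the Scheffe criterion:
#' the pair (i, j) is significant iff
#' \deqn{|m_i - m_j| > \sqrt{(k-1)\,F_{\alpha,k-1,N-k}\,MSE\,(1/n_i + 1/n_j)}.}
#' Letters are assigned with the insert-and-absorb algorithm so that two
#' groups share a letter iff their contrast is non-significant; groups are
#' lettered in order of descending mean, which makes the display
#' deterministic.
#'
#' @param values numeric response.
#' @param groups grouping labels.
#' @param alpha significance level (default 0.05).
#' @return list of class `scheffe_result`: `pairs` (data.frame group_a,
#'   group_b, diff, critical, p, significant), `letters` (named character
#'   vector), `means`, `alpha`, `anova` (the [one_way_anova()] result).
#' @export
scheffe_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  aov_res <- one_way_anova(values, groups)
  k <- nlevels(groups)
  n <- tapply(values, groups, length)
  means <- tapply(values, groups, mean)
  N <- length(values)
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / (N - k)
  fcrit <- stats::qf(1 - alpha, k - 1, N - k)

  combs <- utils::combn(levels(groups), 2)
  diffs <- abs(means[combs[1, ]] - means[combs[2, ]])
  crit <- sqrt((k - 1) * fcrit * mse *
                 (1 / n[combs[1, ]] + 1 / n[combs[2, ]]))
  # Scheffe p-value of each contrast (F-scale), for reporting
  fstat <- (diffs^2 / (mse * (1 / n[combs[1, ]] + 1 / n[combs[2, ]]))) / (k - 1)
  pvals <- stats::pf(fstat, k - 1, N - k, lower.tail = FALSE)
  if (mse <= 0) {
    sig <- diffs > 0
    pvals <- ifelse(sig, 0, 1)
  } else {
    sig <- diffs > crit
  }
  pairs <- data.frame(group_a = combs[1, ], group_b = combs[2, ],
                      diff = as.numeric(diffs), critical = as.numeric(crit),
                      p = as.numeric(pvals), significant = as.logical(sig),
                      stringsAsFactors = FALSE)
  letters <- compact_letters(pairs, order(means, decreasing = TRUE),
                             levels(groups))
  structure(list(pairs = pairs, letters = letters, means = means,
                 n = n, mse = mse, alpha = alpha, anova = aov_res),
            class = "scheffe_result")
}

#' @export
print.scheffe_result <- function(x, ...) {
  cat(sprintf("Scheffe post hoc (alpha = %g): %d of %d pairs significant\n",
              x$alpha, sum(x$pairs$significant), nrow(x$pairs)))
  ord <- order(x$means, decreasing = TRUE)
  print(data.frame(mean = round(x$means[ord], 2), n = as.integer(x$n[ord]),
                   letters = x$letters[names(x$means)[ord]]))
  invisible(x)
}

# Insert-and-absorb compact letter display. `pairs` must carry group_a,
# group_b, significant; `order_idx` fixes the lettering order (descending
# mean); `groups` is the full level set.
compact_letters <- function(pairs, order_idx, groups) {
  cols <- list(groups)  # start: one column holding every group
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (u in seq_along(new_cols)) {
      for (v in seq_along(new_cols)) {
        if (u != v && keep[u] &&
            all(new_cols[[u]] %in% new_cols[[v]]) &&
            (length(new_cols[[u]]) < length(new_cols[[v]]) || u > v)) {
          keep[u] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the highest-ranked group they contain, then letter
  ordered_groups <- groups[order_idx]
  first_rank <- vapply(cols, function(col) {
    min(match(col, ordered_groups))
  }, numeric(1))
  cols <- cols[order(first_rank)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    lab <- letters[(i - 1L) %% 26L + 1L]
    if (i > 26L) lab <- paste0(lab, (i - 1L) %/% 26L)
    for (g in cols[[i]]) out[g] <- paste0(out[g], lab)
  }
  out
}

#' Species-level richness summary
#'
#' Per-group mean, median and quartiles of chemical richness, the one-way
#' ANOVA over groups, and the Scheffe compact-letter display.
#'
#' @param pa binary presence/absence matrix.
#' @param groups grouping labels (e.g. species), one per sample row.
#' @param alpha significance level for the post hoc test.
#' @param response `"sample"` (default) analyzes per-sample richness;
#'   `"summary"` aggregates to one median per group-by-plot cell first.
#' @return list with `richness` (per sample), `summary` (per group),
#'   `anova`, `scheffe`.
#' @export
richness_summary <- function(pa, groups, alpha = 0.05,
                             response = c("sample", "summary")) {
  response <- match.arg(response)
  rich <- chemical_richness(pa)
  groups <- factor(groups)
  vals <- as.numeric(rich)
  grp <- groups
  if (response == "summary") {
    meta <- attr(pa, "metadata")
    cell <- if (!is.null(meta) && "plot" %in% names(meta)) {
      interaction(groups, meta$plot, drop = TRUE)
    } else {
      groups
    }
    vals <- as.numeric(tapply(rich, cell, stats::median))
    grp <- factor(vapply(strsplit(names(tapply(rich, cell, stats::median)),
                                  ".", fixed = TRUE),
                         `[[`, character(1), 1L))
  }
  sch <- scheffe_posthoc(vals, grp, alpha)
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- rich[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               letters = unname(sch$letters[g]),
               stringsAsFactors = FALSE)
  }))
  list(richness = rich, summary = summ, anova = sch$anova, scheffe = sch)
}
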