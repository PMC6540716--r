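# One-vs-rest exact binomial species-specificity screen and shared-compound
# accounting on the presence/absence matrix.

#' Per-group occurrence frequencies of every feature
#'
#' Counts, for each feature and each group, how many samples of the group
#' contain the feature (k) out of the group size (n).
#'
#' @param pa binary matrix samples x features.
#' @param grouping group label per sample row.
#' @return list with `k` (features x groups occurrence counts) and `n`
#'   (named group sizes).
#' @export
compound_frequencies <- function(pa, grouping) {
  if (!is.factor(grouping)) grouping <- factor(grouping)
  if (length(grouping) != nrow(pa)) {
    stop("`grouping` must label every sample row", call. = FALSE)
  }
  n <- table(grouping)
  if (any(n == 0L)) stop("empty group in `grouping`", call. = FALSE)
  k <- t(rowsum(pa + 0, grouping))  # features x groups
  storage.mode(k) <- "integer"
  list(k = k, n = stats::setNames(as.integer(n), names(n)))
}

#' One-vs-rest exact binomial specificity p-value
#'
#' Tests whether a compound is more frequent in a focal group than in the
#' rest of the community. Conditional on the total number of occurrences
#' `T = k_focal + k_other`, under exchangeability each occurrence falls in
#' the focal group with probability `p0 = n_focal / (n_focal + n_other)`;
#' the reported p-value is the one-sided upper tail
#' `P(X >= k_focal)` for `X ~ Binomial(T, p0)`. Specificity at confidence
#' 0.95 corresponds to a p-value below 0.05.
#'
#' @param k_focal,n_focal occurrences and sample count in the focal group.
#' @param k_other,n_other occurrences and sample count elsewhere.
#'   All four arguments are vectorized.
#' @return numeric vector of one-sided p-values in (0, 1].
#' @export
binomial_specificity <- function(k_focal, n_focal, k_other, n_other) {
  if (any(k_focal < 0) || any(k_other < 0) ||
      any(k_focal > n_focal) || any(k_other > n_other)) {
    stop("need 0 <= k <= n on both sides", call. = FALSE)
  }
  total <- k_focal + k_other
  if (any(total == 0L)) {
    stop("undefined: compound never observed (k_focal + k_other = 0)",
         call. = FALSE)
  }
  p0 <- n_focal / (n_focal + n_other)
  stats::pbinom(k_focal - 1, total, p0, lower.tail = FALSE)
}

#' Screen every feature for species specificity
#'
#' Runs the one-vs-rest exact binomial test for every (feature, species)
#' pair, flags features specific at the given confidence criterion, and
#' attributes each specific feature to the single species with the smallest
#' qualifying p-value (ties broken by species label order, so per-species
#' counts are disjoint). Declared genus groups (several species pooled as
#' focal against all remaining species) are screened the same way.
#'
#' @param pa binary matrix samples x features (already filtered).
#' @param species_labels species per sample row.
#' @param criterion confidence criterion (default 0.95, i.e. p < 0.05).
#' @param growth_form_labels optional growth form per sample row, used for
#'   the sharing summary.
#' @param genus_groups optional named list of species vectors to pool, e.g.
#'   `list(Galium = c("Galium_mollugo", "Galium_verum"))`.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, mirroring the plain per-test criterion; `"BH"`
#'   available).
#' @return list of class `specificity_screen`: `records` (per feature x
#'   species data.frame with k/n on both sides, p-value and flag),
#'   `assignment` (per specific feature, the attributed species),
#'   `genus_records` (as `records`, for genus groups), `summary`
#'   (a sharing/specificity count summary; see [shared_compounds()]).
#' @export
screen_all <- function(pa, species_labels, criterion = 0.95,
                       growth_form_labels = NULL, genus_groups = NULL,
                       adjust = "none") {
  species_labels <- factor(species_labels)
  if (nlevels(species_labels) < 2L) {
    stop("need at least 2 species to screen", call. = FALSE)
  }
  stopifnot_scalar_number(criterion, "criterion", 0, 1)
  alpha <- 1 - criterion
  freq <- compound_frequencies(pa, species_labels)
  k <- freq$k
  n <- freq$n
  N <- sum(n)
  total <- rowSums(k)
  feat <- rownames(k)
  keep <- total >= 1L

  long <- do.call(rbind, lapply(colnames(k), function(sp) {
    data.frame(
      feature_id = feat[keep], focal_group = sp,
      k_focal = k[keep, sp], n_focal = n[[sp]],
      k_other = total[keep] - k[keep, sp], n_other = N - n[[sp]],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  long$p_value <- binomial_specificity(long$k_focal, long$n_focal,
                                       long$k_other, long$n_other)
  long$p_adjusted <- stats::p.adjust(long$p_value, method = adjust)
  long$specific <- long$p_adjusted < alpha

  # exclusive attribution: smallest qualifying p, ties by label order
  sig <- long[long$specific, , drop = FALSE]
  assignment <- if (nrow(sig)) {
    sig <- sig[order(sig$feature_id, sig$p_adjusted, sig$focal_group), ,
               drop = FALSE]
    sig[!duplicated(sig$feature_id), c("feature_id", "focal_group",
                                       "p_adjusted"), drop = FALSE]
  } else {
    data.frame(feature_id = character(), focal_group = character(),
               p_adjusted = numeric(), stringsAsFactors = FALSE)
  }
  rownames(assignment) <- NULL

  genus_records <- NULL
  if (!is.null(genus_groups)) {
    genus_records <- do.call(rbind, lapply(names(genus_groups), function(g) {
      members <- genus_groups[[g]]
      if (!all(members %in% levels(species_labels))) {
        stop("genus group ", g, " names unknown species", call. = FALSE)
      }
      kf <- rowSums(k[keep, members, drop = FALSE])
      nf <- sum(n[members])
      data.frame(
        feature_id = feat[keep], focal_group = g,
        k_focal = kf, n_focal = nf,
        k_other = total[keep] - kf, n_other = N - nf,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }))
    genus_records$p_value <- binomial_specificity(
      genus_records$k_focal, genus_records$n_focal,
      genus_records$k_other, genus_records$n_other)
    genus_records$p_adjusted <- stats::p.adjust(genus_records$p_value,
                                                method = adjust)
    genus_records$specific <- genus_records$p_adjusted < alpha
  }

  per_species <- stats::setNames(integer(ncol(k)), colnames(k))
  tab <- table(assignment$focal_group)
  per_species[names(tab)] <- as.integer(tab)

  summary <- list(
    n_considered = sum(total >= 2L),
    n_specific = nrow(assignment),
    per_species_specific = per_species
  )
  if (!is.null(growth_form_labels)) {
    gf <- tapply(as.character(growth_form_labels),
                 as.character(species_labels), function(x) x[1])
    by_form <- tapply(per_species, gf[names(per_species)], sum)
    summary$growth_form_specific <- stats::setNames(as.integer(by_form),
                                                    names(by_form))
    summary$shared_between_growth_forms <-
      shared_compounds(pa, growth_form_labels)$n_shared
  }
  if (!is.null(genus_records)) {
    summary$genus_specific <- stats::setNames(
      as.integer(tapply(genus_records$specific, genus_records$focal_group,
                        sum)),
      names(genus_groups)
    )
  }
  structure(list(records = long, assignment = assignment,
                 genus_records = genus_records, summary = summary,
                 criterion = criterion),
            class = "specificity_screen")
}

#' @export
print.specificity_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Specificity screen (criterion %.2f): %d features considered (>= 2 occurrences)\n",
              x$criterion, s$n_considered))
  cat(sprintf("  %d specific features attributed; per species:\n", s$n_specific))
  print(s$per_species_specific)
  if (!is.null(s$growth_form_specific)) {
    cat("  by growth form: ",
        paste(names(s$growth_form_specific), s$growth_form_specific,
              sep = "=", collapse = ", "), "\n")
    cat(sprintf("  shared between growth forms: %d\n",
                s$shared_between_growth_forms))
  }
  if (!is.null(s$genus_specific)) {
    cat("  genus-specific: ",
        paste(names(s$genus_specific), s$genus_specific, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compounds shared between growth forms
#'
#' Restricting to features that occur at least `min_occurrence` times over
#' all samples, counts the features present in at least one sample of each
#' growth form.
#'
#' @param pa binary matrix samples x features.
#' @param growth_form_labels growth form per sample row (two levels
#'   expected, e.g. forb/grass).
#' @param min_occurrence minimum total occurrence for a feature to be
#'   considered (default 2).
#' @return list with `n_considered`, `n_shared`, `shared_features`,
#'   `per_form_present` (features present in each form among considered).
#' @export
shared_compounds <- function(pa, growth_form_labels, min_occurrence = 2L) {
  forms <- factor(growth_form_labels)
  if (nlevels(forms) < 2L) {
    stop("both growth forms must be represented", call. = FALSE)
  }
  total <- colSums(pa)
  considered <- total >= min_occurrence
  freq <- compound_frequencies(pa[, considered, drop = FALSE], forms)
  present <- freq$k > 0L
  shared <- rowSums(present) == nlevels(forms)
  list(
    n_considered = sum(considered),
    n_shared = sum(shared),
    shared_features = rownames(freq$k)[shared],
    per_form_present = colSums(present)
  )
}
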