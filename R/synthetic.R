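# Synthetic study generator: emulates an unbalanced multi-species phytometer
# design (10 grassland species, two growth forms, 3 regions, 46 plots,
# 389 exudate samples plus water controls) with planted ground truth for
# every downstream stage.

.default_species <- data.frame(
  species = c("Achillea_millefolium", "Galium_mollugo", "Galium_verum",
              "Plantago_lanceolata", "Ranunculus_acris",
              "Alopecurus_pratensis", "Arrhenatherum_elatius",
              "Dactylis_glomerata", "Lolium_perenne", "Poa_pratensis"),
  growth_form = rep(c("forb", "grass"), each = 5L),
  genus = c("Achillea", "Galium", "Galium", "Plantago", "Ranunculus",
            "Alopecurus", "Arrhenatherum", "Dactylis", "Lolium", "Poa"),
  stringsAsFactors = FALSE
)

# Per-species sample counts of the emulated field campaign (total 389).
.default_counts <- c(38L, 41L, 37L, 39L, 28L, 40L, 40L, 48L, 37L, 41L)

#' Generate a phytometer study design
#'
#' Builds the sample layout the rest of the pipeline consumes: species with
#' growth-form (and genus) assignment, plots with region assignment, an
#' unbalanced sample list, and water-control (blank) samples. The default
#' parameters emulate a grassland phytometer campaign with 10 species (five
#' forbs, five grasses, including two congeneric \emph{Galium} species),
#' 46 plots in three regions and 389 exudate samples.
#'
#' @param n_species number of species. With the default 10 the canonical
#'   species set is used; otherwise generic forb/grass labels are generated
#'   (first half forbs).
#' @param n_plots number of plots, assigned round-robin to three regions.
#' @param per_species_counts integer vector of samples per species.
#' @param n_blanks number of water-control samples.
#' @param seed integer seed; the same seed yields an identical design.
#' @return an object of class `study_design`: a list with `species`
#'   (data.frame species/growth_form/genus), `plots` (plot/region),
#'   `samples` (sample_id/species/plot) and `blanks` (sample_id/region).
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d$samples)  # 389
#' @export
generate_design <- function(n_species = 10L,
                            n_plots = 46L,
                            per_species_counts = NULL,
                            n_blanks = 12L,
                            seed) {
  if (n_species < 1L) stop("invalid design: need at least one species", call. = FALSE)
  if (n_plots < 1L) stop("invalid design: need at least one plot", call. = FALSE)
  if (is.null(per_species_counts)) {
    per_species_counts <- if (n_species == 10L) .default_counts else
      rep(30L, n_species)
  }
  if (length(per_species_counts) != n_species) {
    stop("`per_species_counts` must have one entry per species", call. = FALSE)
  }
  if (any(per_species_counts < 1L)) {
    stop("invalid design: per-species counts must be positive", call. = FALSE)
  }

  species <- if (n_species == 10L) {
    .default_species
  } else {
    n_forb <- ceiling(n_species / 2)
    data.frame(
      species = c(sprintf("Forb_%02d", seq_len(n_forb)),
                  sprintf("Grass_%02d", seq_len(n_species - n_forb))),
      growth_form = rep(c("forb", "grass"), c(n_forb, n_species - n_forb)),
      genus = c(sprintf("ForbGenus_%02d", seq_len(n_forb)),
                sprintf("GrassGenus_%02d", seq_len(n_species - n_forb))),
      stringsAsFactors = FALSE
    )
  }

  regions <- c("ALB", "HAI", "SCH")
  plots <- data.frame(
    plot = sprintf("P%02d", seq_len(n_plots)),
    region = regions[(seq_len(n_plots) - 1L) %% 3L + 1L],
    stringsAsFactors = FALSE
  )

  with_seed(seed, {
    samples <- do.call(rbind, lapply(seq_len(n_species), function(i) {
      n_i <- per_species_counts[i]
      data.frame(
        species = species$species[i],
        plot = sample(plots$plot, n_i, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }))
    samples$sample_id <- sprintf("S%03d_%s", seq_len(nrow(samples)),
                                 abbreviate(samples$species, 6))
    samples <- samples[, c("sample_id", "species", "plot")]
    blanks <- if (n_blanks > 0L) {
      data.frame(
        sample_id = sprintf("Blank_%02d", seq_len(n_blanks)),
        region = regions[(seq_len(n_blanks) - 1L) %% 3L + 1L],
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(sample_id = character(), region = character())
    }
    structure(
      list(species = species, plots = plots, samples = samples,
           blanks = blanks, seed = seed),
      class = "study_design"
    )
  })
}

#' @export
print.study_design <- function(x, ...) {
  cat("Phytometer study design\n")
  cat(sprintf("  %d species (%d forbs, %d grasses), %d plots, %d samples, %d blanks\n",
              nrow(x$species), sum(x$species$growth_form == "forb"),
              sum(x$species$growth_form == "grass"), nrow(x$plots),
              nrow(x$samples), nrow(x$blanks)))
  invisible(x)
}

#' Ground-truth specification for the synthetic feature table
#'
#' Declares how many features of each class to plant and their occupancy
#' parameters. Classes: `shared` (present across species), `species_specific`
#' (elevated occupancy in one focal species), `genus_specific` (elevated in a
#' pooled genus group), `blank_contaminant` (prevalent in water controls) and
#' `singleton` (exactly one occurrence). Occupancy is Bernoulli per sample
#' with a logistic plot effect on the log-odds scale.
#'
#' @param n_shared number of features occurring across the community.
#' @param shared_occupancy scalar occupancy or range (length 2) from which
#'   per-feature shared occupancies are drawn uniformly.
#' @param n_specific_per_species named (or unnamed, recycled) integer vector
#'   of species-specific features per species. The default plants 534 across
#'   the forbs and 91 across the grasses (625 total).
#' @param occupancy_focal,occupancy_background occupancy of specific features
#'   in focal vs non-focal samples.
#' @param n_genus_specific features specific to the pooled genus group (the
#'   two congeneric species when present); 0 disables.
#' @param n_blank_contaminant contaminant features; each occurs in at least
#'   `blank_min_fraction` of blanks (membership Bernoulli(`blank_occupancy`),
#'   topped up) and in exudate samples with `contaminant_sample_occupancy`.
#' @param n_singleton features planted in exactly one exudate sample.
#' @param plot_effect_sd standard deviation of per-plot log-odds shifts.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity law given
#'   presence.
#' @param blank_occupancy,blank_min_fraction,contaminant_sample_occupancy
#'   contaminant occupancy parameters.
#' @return a list of class `truth_spec`.
#' @export
truth_spec <- function(n_shared = 270L,
                       shared_occupancy = c(0.30, 0.90),
                       n_specific_per_species = NULL,
                       occupancy_focal = 0.8,
                       occupancy_background = 0.02,
                       n_genus_specific = 150L,
                       n_blank_contaminant = 100L,
                       n_singleton = 80L,
                       plot_effect_sd = 0.5,
                       intensity_meanlog = 10,
                       intensity_sdlog = 1,
                       blank_occupancy = 0.9,
                       blank_min_fraction = 0.5,
                       contaminant_sample_occupancy = 0.25) {
  for (nm in c("occupancy_focal", "occupancy_background", "blank_occupancy",
               "blank_min_fraction", "contaminant_sample_occupancy")) {
    stopifnot_scalar_number(get(nm), nm, 0, 1)
  }
  if (any(shared_occupancy < 0) || any(shared_occupancy > 1)) {
    stop("`shared_occupancy` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(plot_effect_sd, "plot_effect_sd", 0)
  structure(
    list(n_shared = n_shared, shared_occupancy = shared_occupancy,
         n_specific_per_species = n_specific_per_species,
         occupancy_focal = occupancy_focal,
         occupancy_background = occupancy_background,
         n_genus_specific = n_genus_specific,
         n_blank_contaminant = n_blank_contaminant,
         n_singleton = n_singleton,
         plot_effect_sd = plot_effect_sd,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog,
         blank_occupancy = blank_occupancy,
         blank_min_fraction = blank_min_fraction,
         contaminant_sample_occupancy = contaminant_sample_occupancy),
    class = "truth_spec"
  )
}

# default allocation of species-specific features: forbs carry most of them
.default_specific_counts <- function(species) {
  forb <- species$growth_form == "forb"
  n_forb <- sum(forb)
  n_grass <- sum(!forb)
  counts <- integer(nrow(species))
  if (n_forb > 0) {
    base <- 534L %/% n_forb
    counts[forb] <- base
    counts[which(forb)[seq_len(534L - base * n_forb)]] <-
      counts[which(forb)[seq_len(534L - base * n_forb)]] + 1L
  }
  if (n_grass > 0) {
    base <- 91L %/% n_grass
    counts[!forb] <- base
    counts[which(!forb)[seq_len(91L - base * n_grass)]] <-
      counts[which(!forb)[seq_len(91L - base * n_grass)]] + 1L
  }
  stats::setNames(counts, species$species)
}

#' Generate a synthetic LC-MS feature table with planted truth
#'
#' Realizes a samples-by-features intensity matrix from a [generate_design()]
#' layout and a [truth_spec()]. Presence is Bernoulli per sample with a
#' logistic link: `logit(p) = logit(occupancy) + plot_effect[plot]`; given
#' presence, intensities are log-normal. Feature ids carry a synthetic m/z
#' (90-1000) and retention time (0.01-18 min) annotation.
#'
#' @param design a `study_design`.
#' @param truth a `truth_spec`.
#' @param seed integer seed.
#' @return a list with `table` (a [feature_table()]) and `truth` (data.frame
#'   feature_id/class/focal/occupancy_focal/occupancy_background).
#' @export
generate_feature_table <- function(design, truth = truth_spec(), seed) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_spec"))
  species <- design$species
  samples <- design$samples
  n_samp <- nrow(samples)
  n_blank <- nrow(design$blanks)

  spec_counts <- truth$n_specific_per_species
  if (is.null(spec_counts)) {
    spec_counts <- .default_specific_counts(species)
  } else if (is.null(names(spec_counts))) {
    spec_counts <- stats::setNames(rep_len(spec_counts, nrow(species)),
                                   species$species)
  }
  if (!all(names(spec_counts) %in% species$species)) {
    stop("parameter error: specific features name an unknown species",
         call. = FALSE)
  }

  genus_tab <- table(species$genus)
  genus_group <- names(genus_tab)[genus_tab >= 2L][1]
  n_genus <- if (is.na(genus_group)) 0L else truth$n_genus_specific

  classes <- c(rep("shared", truth$n_shared),
               rep("species_specific", sum(spec_counts)),
               rep("genus_specific", n_genus),
               rep("blank_contaminant", truth$n_blank_contaminant),
               rep("singleton", truth$n_singleton))
  focal <- c(rep(NA_character_, truth$n_shared),
             rep(names(spec_counts), spec_counts),
             rep(genus_group, n_genus),
             rep(NA_character_, truth$n_blank_contaminant + truth$n_singleton))
  n_feat <- length(classes)

  with_seed(seed, {
    mz <- round(stats::runif(n_feat, 90, 1000), 4)
    rt <- round(stats::runif(n_feat, 0.01, 18), 2)
    feature_id <- sprintf("F%04d_mz%09.4f_rt%05.2f", seq_len(n_feat), mz, rt)

    occ_shared <- if (length(truth$shared_occupancy) == 1L) {
      rep(truth$shared_occupancy, truth$n_shared)
    } else {
      stats::runif(truth$n_shared, truth$shared_occupancy[1],
                   truth$shared_occupancy[2])
    }
    occ_focal <- ifelse(classes == "shared", NA, truth$occupancy_focal)
    occ_focal[classes == "shared"] <- occ_shared
    occ_bg <- ifelse(classes == "shared", occ_shared,
                     truth$occupancy_background)

    plot_eff <- stats::setNames(
      stats::rnorm(nrow(design$plots), 0, truth$plot_effect_sd),
      design$plots$plot
    )
    sample_plot_eff <- plot_eff[samples$plot]

    # presence in exudate samples
    pres <- matrix(0L, n_samp, n_feat)
    in_focal <- matrix(FALSE, n_samp, n_feat)
    is_spec <- classes %in% c("species_specific", "genus_specific")
    if (any(is_spec)) {
      focal_species <- lapply(focal, function(f) {
        if (is.na(f)) character() else
          species$species[species$species == f | species$genus == f]
      })
      for (j in which(is_spec)) {
        in_focal[, j] <- samples$species %in% focal_species[[j]]
      }
    }
    for (j in seq_len(n_feat)) {
      cl <- classes[j]
      if (cl == "singleton") next
      if (cl == "blank_contaminant") {
        p <- stats::plogis(stats::qlogis(
          max(truth$contaminant_sample_occupancy, 1e-12)) + sample_plot_eff)
        pres[, j] <- stats::rbinom(n_samp, 1L, p)
        next
      }
      occ <- ifelse(in_focal[, j], occ_focal[j], occ_bg[j])
      lo <- ifelse(occ <= 0, -Inf, ifelse(occ >= 1, Inf, stats::qlogis(occ)))
      p <- stats::plogis(lo + sample_plot_eff)
      p[lo == -Inf] <- 0
      p[lo == Inf] <- 1
      pres[, j] <- stats::rbinom(n_samp, 1L, p)
    }
    for (j in which(classes == "singleton")) {
      pres[sample.int(n_samp, 1L), j] <- 1L
    }

    # presence in blanks: contaminants only, guaranteed prevalence
    pres_blank <- matrix(0L, n_blank, n_feat)
    if (n_blank > 0L) {
      min_k <- ceiling(truth$blank_min_fraction * n_blank)
      for (j in which(classes == "blank_contaminant")) {
        hit <- stats::rbinom(n_blank, 1L, truth$blank_occupancy)
        short <- min_k - sum(hit)
        if (short > 0L) {
          hit[sample(which(hit == 0L), short)] <- 1L
        }
        pres_blank[, j] <- hit
      }
    }

    all_pres <- rbind(pres, pres_blank)
    intens <- matrix(0, nrow(all_pres), n_feat)
    nz <- which(all_pres == 1L)
    intens[nz] <- stats::rlnorm(length(nz), truth$intensity_meanlog,
                                truth$intensity_sdlog)
    rownames(intens) <- c(samples$sample_id, design$blanks$sample_id)
    colnames(intens) <- feature_id

    meta <- data.frame(
      sample_id = c(samples$sample_id, design$blanks$sample_id),
      species = c(samples$species, rep(NA_character_, n_blank)),
      growth_form = c(species$growth_form[match(samples$species,
                                                species$species)],
                      rep(NA_character_, n_blank)),
      plot = c(samples$plot, rep(NA_character_, n_blank)),
      region = c(design$plots$region[match(samples$plot, design$plots$plot)],
                 design$blanks$region),
      sample_type = c(rep("exudate", n_samp), rep("blank", n_blank)),
      stringsAsFactors = FALSE
    )

    tab <- feature_table(intens, meta)
    truth_df <- data.frame(
      feature_id = feature_id, class = classes, focal = focal,
      occupancy_focal = occ_focal, occupancy_background = occ_bg,
      stringsAsFactors = FALSE
    )
    list(table = tab, truth = truth_df)
  })
}

.default_traits <- c("SLA", "LDMC", "LAR", "RSR", "RDMC", "RMV", "RVol",
                     "RCC", "RNC", "RCNR", "RPC", "RKC", "RMgC", "RCaC",
                     "DM_leaves", "DM_roots", "DM_total", "DM_above")

#' Generate species-structured plant functional traits
#'
#' Simulates the 18 above- and belowground functional traits used alongside
#' the exudate profiles (specific leaf area, dry-matter contents, root
#' element concentrations, biomass fractions, ...). Each trait decomposes as
#' species mean + plot shift + residual noise, all Gaussian, so the strength
#' of species structure (and hence the recoverable trait-exudate Procrustes
#' correlation) is controlled by `species_effect_size`.
#'
#' @param design a `study_design`.
#' @param species_effect_size sd of species means (0 = traits carry no
#'   species signal).
#' @param plot_sd sd of plot shifts.
#' @param noise_sd residual sd (must be >= 0).
#' @param traits trait names (columns).
#' @param seed integer seed.
#' @return numeric matrix samples x traits with sample ids as row names.
#' @export
generate_traits <- function(design, species_effect_size = 1,
                            plot_sd = 0.3, noise_sd = 0.5,
                            traits = .default_traits, seed) {
  stopifnot(inherits(design, "study_design"))
  if (noise_sd < 0) stop("parameter error: `noise_sd` must be >= 0", call. = FALSE)
  if (plot_sd < 0) stop("parameter error: `plot_sd` must be >= 0", call. = FALSE)
  n <- nrow(design$samples)
  p <- length(traits)
  with_seed(seed, {
    sp_mean <- matrix(stats::rnorm(nrow(design$species) * p, 0,
                                   species_effect_size),
                      nrow(design$species), p,
                      dimnames = list(design$species$species, traits))
    pl_shift <- matrix(stats::rnorm(nrow(design$plots) * p, 0, plot_sd),
                       nrow(design$plots), p,
                       dimnames = list(design$plots$plot, traits))
    x <- sp_mean[design$samples$species, , drop = FALSE] +
      pl_shift[design$samples$plot, , drop = FALSE] +
      matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
    dimnames(x) <- list(design$samples$sample_id, traits)
    x
  })
}

#' Generate local-neighborhood cover records
#'
#' Per-sample percent-cover vectors over a pool of neighbor species recorded
#' in a 15 cm radius. Covers are plot-structured: each plot carries a sparse
#' mean composition (Bernoulli occupancy times Gamma abundance) and samples
#' within a plot scatter log-normally around it, so ordination of the table
#' clusters samples by plot.
#'
#' @param design a `study_design`.
#' @param n_neighbor_species size of the neighbor species pool.
#' @param plot_occupancy probability a neighbor species occurs in a plot.
#' @param seed integer seed.
#' @return numeric matrix samples x neighbor species (covers, >= 0; every
#'   row has positive total cover).
#' @export
generate_neighborhood <- function(design, n_neighbor_species = 30L,
                                  plot_occupancy = 0.25, seed) {
  stopifnot(inherits(design, "study_design"))
  stopifnot_scalar_number(plot_occupancy, "plot_occupancy", 0, 1)
  pool <- sprintf("Neighbor_%02d", seq_len(n_neighbor_species))
  with_seed(seed, {
    np <- nrow(design$plots)
    occ <- matrix(stats::rbinom(np * n_neighbor_species, 1L, plot_occupancy),
                  np, n_neighbor_species)
    # every plot hosts at least one neighbor species
    empty <- rowSums(occ) == 0L
    occ[cbind(which(empty), sample.int(n_neighbor_species, sum(empty),
                                       replace = TRUE))] <- 1L
    abund <- matrix(stats::rgamma(np * n_neighbor_species, shape = 2,
                                  scale = 10), np, n_neighbor_species)
    plot_mean <- occ * abund
    rownames(plot_mean) <- design$plots$plot
    idx <- match(design$samples$plot, design$plots$plot)
    n <- nrow(design$samples)
    noise <- matrix(stats::rlnorm(n * n_neighbor_species, 0, 0.3),
                    n, n_neighbor_species)
    x <- plot_mean[idx, , drop = FALSE] * noise
    dimnames(x) <- list(design$samples$sample_id, pool)
    x
  })
}

#' Generate per-plot land-use components
#'
#' Simulates yearly fertilization (kg N ha^-1 yr^-1), mowing frequency
#' (cuts yr^-1) and grazing intensity (livestock-unit grazing days) per plot,
#' the raw components of the land-use-intensity index. Plot-level base
#' levels persist across years with moderate year-to-year variation.
#'
#' @param plots data.frame with columns `plot` and `region` (e.g.
#'   `design$plots`).
#' @param years integer vector of years (default 2006-2014).
#' @param seed integer seed.
#' @return data.frame plot/region/year/fertilization/mowing/grazing.
#' @export
generate_lui_components <- function(plots, years = 2006:2014, seed) {
  if (is.null(plots$plot) || is.null(plots$region)) {
    stop("`plots` must have columns plot and region", call. = FALSE)
  }
  if (length(years) < 1L) stop("need at least one year", call. = FALSE)
  np <- nrow(plots)
  with_seed(seed, {
    base_f <- stats::rgamma(np, shape = 1.2, scale = 30)
    base_m <- stats::runif(np, 0, 3)
    base_g <- stats::rgamma(np, shape = 1.0, scale = 120)
    out <- do.call(rbind, lapply(years, function(y) {
      data.frame(
        plot = plots$plot, region = plots$region, year = y,
        fertilization = pmax(0, base_f * stats::rlnorm(np, 0, 0.2)),
        mowing = stats::rpois(np, base_m),
        grazing = pmax(0, base_g * stats::rlnorm(np, 0, 0.3)),
        stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate MS/MS fragment spectra with planted compound classes
#'
#' Builds negative-mode product-ion spectra whose diagnostic peaks follow a
#' class-rule table (see [default_class_rules()]): for each planted label the
#' spectrum receives either the characteristic fragment ion or a fragment at
#' `precursor - neutral_loss`. Diagnostic peaks are intense (well above the
#' absolute and relative intensity gates); optional noise peaks are drawn at
#' random m/z with intensities spanning both sides of the absolute gate.
#'
#' @param rule_db a class-rule data.frame ([default_class_rules()] format).
#' @param planted_classes list of character vectors (one label set per
#'   spectrum) or a character vector (one label per spectrum).
#' @param noise_peaks number of noise peaks added per spectrum.
#' @param seed integer seed.
#' @param precursor_range range of precursor m/z to draw from.
#' @param base_intensity intensity scale of the base peak.
#' @return list of `fragment_spectrum` objects; each carries its planted
#'   labels in `attr(sp, "planted_labels")`.
#' @export
generate_spectra <- function(rule_db, planted_classes, noise_peaks = 0L,
                             seed, precursor_range = c(350, 900),
                             base_intensity = 1e5) {
  planted <- if (is.list(planted_classes)) planted_classes else
    as.list(planted_classes)
  unknown <- setdiff(unique(unlist(planted)), rule_db$label)
  if (length(unknown)) {
    stop("configuration error: planted class absent from rule_db: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_along(planted), function(i) {
      labels <- planted[[i]]
      prec <- stats::runif(1, precursor_range[1], precursor_range[2])
      mz <- numeric()
      for (lab in labels) {
        rules <- rule_db[rule_db$label == lab, , drop = FALSE]
        r <- rules[sample.int(nrow(rules), 1L), , drop = FALSE]
        mz <- c(mz, if (r$kind == "neutral_loss") prec - r$target_mz else
          r$target_mz)
      }
      intensity <- stats::runif(length(mz), 0.4, 1) * base_intensity
      if (noise_peaks > 0L) {
        noise_mz <- stats::runif(noise_peaks, 50, prec - 5)
        # half the noise sits below the absolute intensity gate
        noise_int <- ifelse(stats::runif(noise_peaks) < 0.5,
                            stats::runif(noise_peaks, 10, 900),
                            stats::runif(noise_peaks, 2000, 0.9 * base_intensity))
        mz <- c(mz, noise_mz)
        intensity <- c(intensity, noise_int)
      }
      ord <- order(mz)
      sp <- fragment_spectrum(
        spectrum_id = sprintf("SYN%04d", i),
        precursor_mz = prec,
        retention_time = round(stats::runif(1, 0.5, 17.5), 2),
        peaks = cbind(mz = mz[ord], intensity = intensity[ord])
      )
      attr(sp, "planted_labels") <- sort(unique(labels))
      sp
    })
  })
}
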