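# End-to-end orchestration: configuration, synthetic-input writing, the
# filtering -> statistics -> ordination -> attribution -> classification
# pipeline, and a YAML run manifest.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()], with
#' every tunable documented by its name. Values supplied in `...` (or read
#' from a YAML file via [read_pipeline_config()]) override the defaults.
#'
#' @param seed master seed; every stochastic step derives its seed from it.
#' @param outdir output directory.
#' @param ... overrides of the default entries.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("exumet_run_"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    # input paths (NULL => simulate)
    feature_matrix = NULL, sample_metadata = NULL, traits = NULL,
    neighborhood = NULL, lui_components = NULL, spectra = NULL,
    rule_table = NULL,
    # preprocess
    blank_fraction = 0.5, presence_threshold = 0,
    # statistics
    alpha = 0.05, specificity_criterion = 0.95, min_occurrence = 2L,
    p_adjust = "none",
    # ordination / attribution
    dca_segments = 26L, n_permutations = 999L, procrustes_axes = NULL,
    linkage = "complete", cluster_metric = "euclidean",
    # msclass
    abs_intensity_min = 1000, rel_intensity_min = 0.1,
    n_spectra = 200L, noise_peaks = 5L,
    # simulation
    sim = list(n_blanks = 12L)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("unknown configuration entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  .validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

.validate_config <- function(cfg) {
  stopifnot_scalar_number(cfg$blank_fraction, "blank_fraction", 0, 1)
  stopifnot_scalar_number(cfg$specificity_criterion, "specificity_criterion",
                          0, 1)
  stopifnot_scalar_number(cfg$alpha, "alpha", 0, 1)
  stopifnot_scalar_number(cfg$presence_threshold, "presence_threshold", 0)
  stopifnot_scalar_number(cfg$n_permutations, "n_permutations", 1)
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop("a seed is mandatory", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @param ... further overrides applied after the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

#' Write all synthetic study inputs to a directory
#'
#' Generates (seeded) the feature table with metadata and ground truth,
#' traits, neighborhood covers, land-use components and MS/MS spectra, and
#' writes them as UTF-8 TSV files plus an MGF, the on-disk layout
#' [run_pipeline()] reads.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param truth a [truth_spec()].
#' @param n_blanks number of water-control samples.
#' @param n_spectra number of synthetic MS/MS spectra.
#' @param noise_peaks noise peaks per spectrum.
#' @return invisibly, a named vector of written paths.
#' @export
write_study_inputs <- function(outdir, seed, truth = truth_spec(),
                               n_blanks = 12L, n_spectra = 200L,
                               noise_peaks = 5L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  design <- generate_design(n_blanks = n_blanks, seed = seed)
  ft <- generate_feature_table(design, truth, seed = seed + 1L)
  traits <- generate_traits(design, seed = seed + 2L)
  nbh <- generate_neighborhood(design, seed = seed + 3L)
  lui <- generate_lui_components(design$plots, seed = seed + 4L)
  rules <- default_class_rules()
  plantable <- setdiff(unique(rules$label), c("hydroxylated", "carboxylated"))
  planted <- with_seed(seed + 5L, {
    lapply(seq_len(n_spectra), function(i) {
      sample(plantable, sample.int(2L, 1L))
    })
  })
  spectra <- generate_spectra(rules, planted, noise_peaks = noise_peaks,
                              seed = seed + 6L)
  paths <- c(
    feature_matrix = file.path(outdir, "feature_matrix.tsv"),
    sample_metadata = file.path(outdir, "sample_metadata.tsv"),
    ground_truth = file.path(outdir, "ground_truth.tsv"),
    traits = file.path(outdir, "traits.tsv"),
    neighborhood = file.path(outdir, "neighborhood.tsv"),
    lui_components = file.path(outdir, "lui_components.tsv"),
    spectra = file.path(outdir, "spectra.mgf"),
    spectra_truth = file.path(outdir, "spectra_truth.tsv")
  )
  write_feature_table(ft$table, paths["feature_matrix"],
                      paths["sample_metadata"])
  .write_tsv(ft$truth, paths["ground_truth"])
  .write_tsv(data.frame(sample_id = rownames(traits), traits,
                        check.names = FALSE), paths["traits"])
  .write_tsv(data.frame(sample_id = rownames(nbh), nbh,
                        check.names = FALSE), paths["neighborhood"])
  .write_tsv(lui, paths["lui_components"])
  write_mgf(spectra, paths["spectra"])
  .write_tsv(data.frame(
    spectrum_id = vapply(spectra, `[[`, character(1), "spectrum_id"),
    planted_labels = vapply(spectra, function(s)
      paste(attr(s, "planted_labels"), collapse = ";"), character(1))
  ), paths["spectra_truth"])
  invisible(paths)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full exudate-community pipeline
#'
#' Orchestrates every stage on a synthetic or user-supplied study: feature
#' filtering (blank-contaminant then singleton removal), binarization,
#' chemical-richness statistics with Scheffe letters, the binomial
#' specificity screen with sharing summary, RDA on species indicators,
#' hierarchical clustering (Newick export), trait-exudate Procrustes with
#' permutation test, variance partitioning per growth form (Species / Plot /
#' Traits and Species / Plot / LNH, plus single-variable partitions over
#' traits, LUI and neighborhood descriptors), the LUI table, and MS/MS
#' class annotation. When planted ground truth is available a recovery
#' report (specificity sensitivity / false-positive rate, class-recovery
#' rate) is written as well. All outputs are TSV/Newick/YAML under
#' `config$outdir`; a manifest records every parameter.
#'
#' @param config a [pipeline_config()] (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @return invisibly, a list with the main in-memory results and the vector
#'   of written files.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(x, name) {
    p <- file.path(outdir, name)
    .write_tsv(x, p)
    written <<- c(written, p)
    p
  }

  # ---- inputs -------------------------------------------------------------
  simulated <- is.null(config$feature_matrix)
  indir <- file.path(outdir, "inputs")
  if (simulated) {
    .stage("simulate", {
      sim <- config$sim
      paths <- write_study_inputs(
        indir, seed = config$seed,
        truth = do.call(truth_spec,
                        sim[setdiff(names(sim), "n_blanks")]),
        n_blanks = if (is.null(sim$n_blanks)) 12L else sim$n_blanks,
        n_spectra = config$n_spectra, noise_peaks = config$noise_peaks
      )
      config$feature_matrix <- paths[["feature_matrix"]]
      config$sample_metadata <- paths[["sample_metadata"]]
      config$traits <- paths[["traits"]]
      config$neighborhood <- paths[["neighborhood"]]
      config$lui_components <- paths[["lui_components"]]
      config$spectra <- paths[["spectra"]]
      written <- c(written, unname(paths))
    })
  }
  tab <- .stage("read", read_feature_table(config$feature_matrix,
                                           config$sample_metadata))

  # ---- preprocess ---------------------------------------------------------
  pa <- .stage("filter", {
    tab <- filter_blank_features(tab, config$blank_fraction,
                                 config$presence_threshold)
    tab <- filter_singletons(tab, config$presence_threshold)
    to_presence_absence(tab, config$presence_threshold)
  })
  meta <- pa_metadata(pa)
  emit(data.frame(sample_id = rownames(pa), pa, check.names = FALSE),
       "presence_absence.tsv")

  # ---- richness -----------------------------------------------------------
  rich <- .stage("richness", richness_summary(pa, meta$species,
                                              alpha = config$alpha))
  emit(rich$summary, "richness_summary.tsv")
  emit(data.frame(statistic = c("F", "df1", "df2", "p"),
                  value = c(rich$anova$F, rich$anova$df1, rich$anova$df2,
                            rich$anova$p)),
       "richness_anova.tsv")

  # ---- specificity --------------------------------------------------------
  genus_groups <- .stage("specificity", {
    sp <- unique(meta[, c("species", "growth_form")])
    genera <- sub("_.*", "", sp$species)
    dup <- unique(genera[duplicated(genera)])
    if (length(dup)) {
      stats::setNames(lapply(dup, function(g)
        sp$species[genera == g]), dup)
    } else {
      NULL
    }
  })
  screen <- .stage("specificity",
                   screen_all(pa, meta$species,
                              criterion = config$specificity_criterion,
                              growth_form_labels = meta$growth_form,
                              genus_groups = genus_groups,
                              adjust = config$p_adjust))
  emit(screen$records, "specificity_records.tsv")
  emit(screen$assignment, "specificity_assignment.tsv")
  emit(data.frame(species = names(screen$summary$per_species_specific),
                  n_specific = screen$summary$per_species_specific),
       "specificity_per_species.tsv")
  summ <- screen$summary
  emit(data.frame(
    quantity = c("n_considered", "n_specific",
                 paste0("specific_", names(summ$growth_form_specific)),
                 "shared_between_growth_forms",
                 if (!is.null(summ$genus_specific))
                   paste0("genus_specific_", names(summ$genus_specific))),
    value = c(summ$n_considered, summ$n_specific,
              summ$growth_form_specific, summ$shared_between_growth_forms,
              summ$genus_specific)),
    "sharing_summary.tsv")

  # ---- ordination & clustering -------------------------------------------
  species_ind <- indicator_matrix(meta$species)
  ord <- .stage("ordination", rda(pa, species_ind))
  emit(data.frame(sample_id = rownames(pa),
                  species = meta$species,
                  ord$site_scores, check.names = FALSE),
       "rda_site_scores.tsv")
  emit(data.frame(axis = seq_along(ord$eigenvalues),
                  eigenvalue = ord$eigenvalues,
                  proportion = ord$axis_proportions),
       "rda_eigenvalues.tsv")
  dendro <- .stage("cluster", hierarchical_cluster(
    pa, metric = config$cluster_metric, linkage = config$linkage))
  newick_path <- file.path(outdir, "dendrogram.newick")
  dendrogram_newick(dendro, newick_path)
  written <- c(written, newick_path)

  # ---- traits, neighborhood, attribution ---------------------------------
  traits <- nbh <- NULL
  proc <- NULL
  partitions <- list()
  if (!is.null(config$traits)) {
    traits_df <- utils::read.delim(config$traits, check.names = FALSE)
    traits <- as.matrix(traits_df[, -1, drop = FALSE])
    rownames(traits) <- traits_df[[1]]
    common <- intersect(rownames(pa), rownames(traits))
    proc <- .stage("procrustes", {
      px <- pca(pa[common, , drop = FALSE])
      py <- pca(scale(traits[common, , drop = FALSE]))
      ax <- config$procrustes_axes
      sx <- if (is.null(ax)) px$site_scores else
        px$site_scores[, seq_len(min(ax, ncol(px$site_scores))), drop = FALSE]
      sy <- if (is.null(ax)) py$site_scores else
        py$site_scores[, seq_len(min(ax, ncol(py$site_scores))), drop = FALSE]
      protest(sx, sy, n_permutations = config$n_permutations,
              seed = config$seed + 100L)
    })
    emit(data.frame(
      statistic = c("correlation", "m2", "permutation_p", "n_permutations",
                    "n_samples"),
      value = c(proc$correlation, proc$m2, proc$permutation_p,
                proc$n_permutations, length(common))),
      "procrustes.tsv")
  }
  if (!is.null(config$neighborhood)) {
    nbh_df <- utils::read.delim(config$neighborhood, check.names = FALSE)
    nbh <- as.matrix(nbh_df[, -1, drop = FALSE])
    rownames(nbh) <- nbh_df[[1]]
  }
  lui_tab <- NULL
  if (!is.null(config$lui_components)) {
    comp <- utils::read.delim(config$lui_components, check.names = FALSE)
    lui_tab <- .stage("lui", lui_index(comp))
    emit(lui_tab$by_plot, "lui_by_plot.tsv")
  }
  if (!is.null(traits)) {
    partitions <- .stage("varpart", {
      out <- list()
      for (form in stats::na.omit(unique(meta$growth_form))) {
        sel <- rownames(pa)[meta$growth_form %in% form]
        sel <- intersect(sel, rownames(traits))
        if (!is.null(nbh)) sel <- intersect(sel, rownames(nbh))
        Y <- pa[sel, , drop = FALSE]
        msel <- meta[match(sel, meta$sample_id), ]
        sets <- list(Species = indicator_matrix(msel$species),
                     Plot = indicator_matrix(msel$plot),
                     Traits = traits[sel, , drop = FALSE])
        vp_tr <- variance_partition(Y, sets)
        out[[paste0(form, "_traits")]] <- vp_tr
        emit(data.frame(fraction = names(vp_tr$fractions),
                        value = vp_tr$fractions),
             sprintf("varpart_%s_traits.tsv", form))
        if (!is.null(nbh)) {
          lnh <- cbind(cover_total = rowSums(nbh[sel, , drop = FALSE]),
                       richness = rowSums(nbh[sel, , drop = FALSE] > 0),
                       shannon = shannon_diversity(nbh[sel, , drop = FALSE]),
                       dca(nbh[sel, , drop = FALSE],
                           n_segments = config$dca_segments)$site_scores)
          vp_lnh <- variance_partition(
            Y, list(Species = sets$Species, Plot = sets$Plot, LNH = lnh))
          out[[paste0(form, "_lnh")]] <- vp_lnh
          emit(data.frame(fraction = names(vp_lnh$fractions),
                          value = vp_lnh$fractions),
               sprintf("varpart_%s_lnh.tsv", form))
          # single-variable partitions (traits, LUI, neighborhood descriptors)
          sv <- traits[sel, , drop = FALSE]
          if (!is.null(lui_tab)) {
            sv <- cbind(sv, LUI = lui_tab$by_plot$lui_mean[
              match(msel$plot, lui_tab$by_plot$plot)])
          }
          sv <- cbind(sv, lnh[, c("cover_total", "richness", "shannon"),
                              drop = FALSE],
                      lnh[, grep("^DCA", colnames(lnh)), drop = FALSE])
          rows <- lapply(colnames(sv), function(v) {
            vp <- variance_partition(Y, list(
              Species = sets$Species, Plot = sets$Plot, SV = sv[, v,
                                                                drop = FALSE]))
            data.frame(variable = v, t(partition_layout3(vp)),
                       check.names = FALSE)
          })
          out[[paste0(form, "_single_variables")]] <- do.call(rbind, rows)
          emit(out[[paste0(form, "_single_variables")]],
               sprintf("varpart_%s_single_variables.tsv", form))
        }
      }
      out
    })
  }

  # ---- MS/MS classification ----------------------------------------------
  classes <- NULL
  if (!is.null(config$spectra)) {
    classes <- .stage("classify", {
      rules <- if (is.null(config$rule_table)) default_class_rules() else
        utils::read.delim(config$rule_table, check.names = FALSE)
      spectra <- read_spectra(config$spectra)
      spectra <- lapply(spectra, clean_spectrum,
                        abs_intensity_min = config$abs_intensity_min,
                        rel_intensity_min = config$rel_intensity_min)
      classify_batch(spectra, rules)
    })
    emit(data.frame(label = names(classes$counts),
                    count = classes$counts),
         "class_counts.tsv")
    emit(do.call(rbind, lapply(classes$annotations, function(a) {
      data.frame(spectrum_id = a$spectrum_id,
                 labels = paste(a$class_labels, collapse = ";"),
                 unclassified = a$unclassified)
    })), "class_annotations.tsv")
  }

  # ---- recovery against planted truth ------------------------------------
  recovery <- NULL
  truth_path <- file.path(indir, "ground_truth.tsv")
  if (simulated && file.exists(truth_path)) {
    recovery <- .stage("recovery", {
      truth <- utils::read.delim(truth_path)
      planted <- truth[truth$class == "species_specific", ]
      hit <- merge(planted, screen$assignment, by = "feature_id")
      sens <- if (nrow(planted)) nrow(hit) / nrow(planted) else NA
      correct <- if (nrow(planted))
        sum(hit$focal == hit$focal_group) / nrow(planted) else NA
      null_feat <- truth$feature_id[truth$class == "shared"]
      fpr <- mean(null_feat %in% screen$assignment$feature_id)
      st <- utils::read.delim(file.path(indir, "spectra_truth.tsv"))
      got <- vapply(classes$annotations, function(a)
        paste(a$class_labels, collapse = ";"), character(1))
      class_rec <- mean(got[match(st$spectrum_id, vapply(
        classes$annotations, `[[`, character(1), "spectrum_id"))] ==
          st$planted_labels)
      data.frame(metric = c("specificity_sensitivity",
                            "specificity_correct_attribution",
                            "shared_feature_flag_rate",
                            "class_recovery_rate"),
                 value = c(sens, correct, fpr, class_rec))
    })
    emit(recovery, "recovery.tsv")
  }

  # ---- manifest -----------------------------------------------------------
  params <- config[setdiff(names(config), "outdir")]
  # record input locations relative to the run directory so that a rerun
  # into a different directory produces an identical manifest
  path_fields <- c("feature_matrix", "sample_metadata", "traits",
                   "neighborhood", "lui_components", "spectra", "rule_table")
  for (pf in path_fields) {
    if (!is.null(params[[pf]])) {
      params[[pf]] <- if (simulated)
        file.path("inputs", basename(params[[pf]])) else params[[pf]]
    }
  }
  manifest <- list(
    package = "exumet",
    version = as.character(utils::packageVersion("exumet")),
    parameters = params,
    outputs = basename(written)
  )
  manifest_path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  written <- c(written, manifest_path)

  invisible(list(pa = pa, richness = rich, screen = screen, rda = ord,
                 dendrogram = dendro, procrustes = proc,
                 partitions = partitions, lui = lui_tab,
                 classes = classes, recovery = recovery,
                 files = written, outdir = outdir))
}
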