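test_that("design generation reproduces the unbalanced field layout", {
  d <- generate_design(seed = 1)
  expect_s3_class(d, "study_design")
  expect_equal(nrow(d$samples), 389L)
  counts <- table(factor(d$samples$species, levels = d$species$species))
  expect_equal(as.integer(counts),
               c(38L, 41L, 37L, 39L, 28L, 40L, 40L, 48L, 37L, 41L))
  expect_setequal(unique(d$plots$region), c("ALB", "HAI", "SCH"))
  expect_true(all(d$samples$plot %in% d$plots$plot))
  expect_true(all(d$samples$species %in% d$species$species))
})

test_that("degenerate and invalid designs behave per contract", {
  d1 <- generate_design(n_species = 1, n_plots = 1,
                        per_species_counts = 1, n_blanks = 0, seed = 3)
  expect_equal(nrow(d1$samples), 1L)
  expect_error(generate_design(n_species = 0, seed = 1), "invalid design")
  expect_error(generate_design(n_plots = 0, seed = 1), "invalid design")
  expect_error(generate_design(per_species_counts = rep(0L, 10), seed = 1),
               "positive")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(generate_design(seed = 7), generate_design(seed = 7))
  d <- generate_design(seed = 7)
  expect_identical(generate_feature_table(d, truth_spec(), seed = 8),
                   generate_feature_table(d, truth_spec(), seed = 8))
  expect_identical(generate_traits(d, seed = 2), generate_traits(d, seed = 2))
  expect_identical(generate_neighborhood(d, seed = 2),
                   generate_neighborhood(d, seed = 2))
  expect_identical(generate_lui_components(d$plots, seed = 2),
                   generate_lui_components(d$plots, seed = 2))
  rules <- default_class_rules()
  expect_identical(generate_spectra(rules, c("sulfated", "flavonoid"),
                                    noise_peaks = 3, seed = 5),
                   generate_spectra(rules, c("sulfated", "flavonoid"),
                                    noise_peaks = 3, seed = 5))
})

test_that("ground-truth labels partition the feature set", {
  d <- generate_design(seed = 1)
  ft <- generate_feature_table(d, truth_spec(), seed = 2)
  expect_equal(nrow(ft$truth), ncol(ft$table$intensities))
  expect_setequal(ft$truth$feature_id, colnames(ft$table$intensities))
  expect_equal(unname(table(ft$truth$class)[c("shared", "species_specific",
                                              "genus_specific",
                                              "blank_contaminant",
                                              "singleton")]),
               c(270L, 625L, 150L, 100L, 80L),
               ignore_attr = TRUE)
  # specific features name an existing species or genus group
  foc <- ft$truth$focal[ft$truth$class == "species_specific"]
  expect_true(all(foc %in% d$species$species))
  expect_true(all(ft$truth$focal[ft$truth$class == "genus_specific"] ==
                    "Galium"))
})

test_that("boundary occupancies are realized exactly", {
  d <- generate_design(seed = 4)
  ts <- truth_spec(n_shared = 0, n_genus_specific = 0,
                   n_blank_contaminant = 0, n_singleton = 0,
                   n_specific_per_species = c(Galium_verum = 3L),
                   occupancy_focal = 1, occupancy_background = 0,
                   plot_effect_sd = 0.8)
  ft <- generate_feature_table(d, ts, seed = 5)
  pres <- ft$table$intensities > 0
  focal <- ft$table$metadata$species %in% "Galium_verum"
  expect_true(all(pres[focal, ]))
  expect_true(all(!pres[!focal, ]))
})

test_that("singletons occur exactly once and contaminants dominate blanks", {
  d <- generate_design(seed = 1)
  ft <- generate_feature_table(d, truth_spec(), seed = 2)
  meta <- ft$table$metadata
  exu <- meta$sample_type == "exudate"
  singles <- ft$truth$feature_id[ft$truth$class == "singleton"]
  expect_true(all(colSums(ft$table$intensities[exu, singles] > 0) == 1L))
  contam <- ft$truth$feature_id[ft$truth$class == "blank_contaminant"]
  blank_frac <- colMeans(ft$table$intensities[!exu, contam] > 0)
  expect_true(all(blank_frac >= 0.5))
  clean <- ft$truth$feature_id[ft$truth$class != "blank_contaminant"]
  expect_true(all(ft$table$intensities[!exu, clean] == 0))
})

test_that("realized null occupancy is within binomial sampling error", {
  d <- generate_design(seed = 6)
  ts <- truth_spec(n_shared = 100, shared_occupancy = 0.3,
                   n_specific_per_species = c(Poa_pratensis = 0L),
                   n_genus_specific = 0, n_blank_contaminant = 0,
                   n_singleton = 0, plot_effect_sd = 0)
  ft <- generate_feature_table(d, ts, seed = 7)
  exu <- ft$table$metadata$sample_type == "exudate"
  n_draws <- sum(exu) * 100
  rate <- mean(ft$table$intensities[exu, ] > 0)
  se <- sqrt(0.3 * 0.7 / n_draws)
  expect_lt(abs(rate - 0.3), 3 * se)
})

test_that("trait generator honours its effect-size dials", {
  d <- generate_design(seed = 1)
  tr0 <- generate_traits(d, species_effect_size = 0, plot_sd = 0,
                         noise_sd = 1, seed = 3)
  fit <- one_way_anova(tr0[, 1], d$samples$species)
  expect_gt(fit$p, 1e-4)  # no planted species signal
  tr_exact <- generate_traits(d, species_effect_size = 1, plot_sd = 0.5,
                              noise_sd = 0, seed = 3)
  cell <- paste(d$samples$species, d$samples$plot)
  spread <- tapply(tr_exact[, 1], cell, function(v) diff(range(v)))
  expect_true(all(spread == 0))  # noise-free: one point per species x plot
  expect_error(generate_traits(d, noise_sd = -1, seed = 1), "noise_sd")
})

test_that("neighborhood covers are plot-structured and nonnegative", {
  d <- generate_design(seed = 1)
  nb <- generate_neighborhood(d, seed = 5)
  expect_true(all(nb >= 0))
  expect_true(all(rowSums(nb) > 0))
  # DCA axis 1 separates plots: within-plot variance well below total
  sc <- dca(nb)$site_scores[, 1]
  within <- mean(tapply(sc, d$samples$plot, stats::var), na.rm = TRUE)
  expect_lt(within, 0.2 * stats::var(sc))
})

test_that("spectra carry the diagnostic peaks of their planted classes", {
  rules <- default_class_rules()
  sp <- generate_spectra(rules, list("sulfated", "glycosylated"),
                         noise_peaks = 0, seed = 11)
  # sulfated: fragment at precursor - SO3 (79.9568)
  loss1 <- sp[[1]]$precursor_mz - sp[[1]]$peaks[, "mz"]
  expect_true(any(abs(loss1 - monoisotopic_mass("SO3")) < 1e-9))
  expect_equal(monoisotopic_mass("SO3"), 79.9568, tolerance = 1e-4)
  # glycosylated: a sugar neutral loss, e.g. hexose C6H10O5 = 162.0528
  expect_equal(monoisotopic_mass("C6H10O5"), 162.0528, tolerance = 1e-4)
  loss2 <- sp[[2]]$precursor_mz - sp[[2]]$peaks[, "mz"]
  sugar <- rules$target_mz[rules$label == "glycosylated"]
  expect_true(any(abs(outer(loss2, sugar, "-")) < 1e-9))
  expect_error(generate_spectra(rules, "no_such_class", seed = 1),
               "absent from rule_db")
})
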