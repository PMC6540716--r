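test_that("rule-table masses come from atomic masses", {
  rules <- default_class_rules()
  expect_equal(rules$target_mz[rules$rule_id == "hexose_loss"], 162.0528,
               tolerance = 1e-4)
  expect_equal(rules$target_mz[rules$rule_id == "sulfate_loss"], 79.9568,
               tolerance = 1e-4)
  expect_equal(rules$target_mz[rules$rule_id == "phosphate_loss"], 79.9663,
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)
  expect_error(monoisotopic_mass("C2Xx3"), "parse|tabulated")
})

test_that("MGF writing and reading round-trip synthetic spectra", {
  rules <- default_class_rules()
  sp <- generate_spectra(rules, list("flavonoid", c("glycosylated", "sulfated")),
                         noise_peaks = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_spectra(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$spectrum_id, sp[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_mz, sp[[i]]$precursor_mz,
                 tolerance = 1e-9)
    expect_equal(back[[i]]$peaks, sp[[i]]$peaks, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # spectra without peaks are retained
  empty <- fragment_spectrum("empty", 300.1, 1.5,
                             matrix(numeric(0), 0, 2))
  write_mgf(list(empty), path)
  expect_equal(read_spectra(path)[[1]]$spectrum_id, "empty")
})

test_that("MSP input is parsed and precursor-less records are rejected", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: demo1", "PrecursorMZ: 431.1292",
               "RetentionTime: 3.45", "Num Peaks: 2",
               "269.0763 10000", "161.0 2500", "",
               "Name: demo2", "PrecursorMZ: 300.05", "Num Peaks: 1",
               "100.1 5000"), path)
  sp <- read_spectra(path)
  expect_length(sp, 2L)
  expect_equal(sp[[1]]$precursor_mz, 431.1292)
  expect_equal(nrow(sp[[1]]$peaks), 2L)
  writeLines(c("Name: broken", "Num Peaks: 1", "100.1 5000"), path)
  expect_error(read_spectra(path), "broken")
})

test_that("cleaning applies strict thresholds and base-peak normalization", {
  sp <- fragment_spectrum("t", 500,
                          peaks = cbind(c(100, 200, 300, 400),
                                        c(500, 1000, 4000, 40000)))
  cl <- clean_spectrum(sp)
  # 500 and the exactly-1000 peak are removed (strict >)
  expect_equal(cl$peaks[, "mz"], c(300, 400), ignore_attr = TRUE)
  expect_equal(max(cl$peaks[, "intensity"]), 1)
  # 4000/40000 = 0.1 is NOT above the strict relative gate
  expect_equal(cl$peaks[, "eligible"], c(0, 1), ignore_attr = TRUE)
  all_low <- clean_spectrum(fragment_spectrum("l", 500,
                                              peaks = cbind(100, 900)))
  expect_equal(nrow(all_low$peaks), 0L)
})

test_that("neutral losses are precursor minus fragment, positives only", {
  sp <- clean_spectrum(fragment_spectrum(
    "g", 431.1292, peaks = cbind(c(269.0763, 431.1292, 440.0),
                                 c(5e4, 2e4, 3e3))))
  nl <- neutral_losses(sp)
  expect_equal(nrow(nl), 1L)  # zero and negative losses discarded
  expect_equal(nl$loss_mz, 431.1292 - 269.0763, tolerance = 1e-10)
  expect_equal(nl$loss_mz, 162.0529, tolerance = 1e-4)
})

test_that("annotation matches diagnostic fragments and losses", {
  rules <- default_class_rules()
  hex <- monoisotopic_mass("C6H10O5")
  sp <- fragment_spectrum("a", 431.1292,
                          peaks = cbind(c(431.1292 - hex, 163.0395),
                                        c(5e4, 6e4)))
  ann <- annotate_spectrum(sp, rules)
  expect_true("glycosylated" %in% ann$class_labels)
  expect_true("hydroxycinnamic acid" %in% ann$class_labels)
  expect_false(ann$unclassified)
  expect_true(all(abs(ann$matched_rules$delta_mz) <=
                    rules$tolerance[match(ann$matched_rules$rule_id,
                                          rules$rule_id)]))
  none <- annotate_spectrum(fragment_spectrum("n", 400,
                                              peaks = cbind(111.111, 5e4)),
                            rules)
  expect_true(none$unclassified)
  expect_length(none$class_labels, 0L)
  expect_error(annotate_spectrum(sp, rules[0, ]), "empty rule table")
})

test_that("SO3 and HPO3 losses are distinguished at the default tolerance", {
  rules <- default_class_rules()
  prec <- 600
  sp_s <- fragment_spectrum("s", prec,
                            peaks = cbind(prec - monoisotopic_mass("SO3"), 5e4))
  sp_p <- fragment_spectrum("p", prec,
                            peaks = cbind(prec - monoisotopic_mass("HPO3"), 5e4))
  expect_equal(annotate_spectrum(sp_s, rules)$class_labels, "sulfated")
  expect_equal(annotate_spectrum(sp_p, rules)$class_labels, "phosphorylated")
})

test_that("annotation is invariant to rule order and monotone in tolerance", {
  rules <- default_class_rules()
  sp <- generate_spectra(rules, list(c("glycosylated", "flavonoid")),
                         noise_peaks = 6, seed = 5)[[1]]
  a1 <- annotate_spectrum(sp, rules)
  a2 <- annotate_spectrum(sp, rules[rev(seq_len(nrow(rules))), ])
  expect_equal(a1$class_labels, a2$class_labels)
  tight <- rules; tight$tolerance <- rules$tolerance / 50
  a3 <- annotate_spectrum(sp, tight)
  expect_true(all(a3$class_labels %in% a1$class_labels))
})

test_that("noise-free batches are recovered perfectly, noise degrades gracefully", {
  rules <- default_class_rules()
  plantable <- setdiff(unique(rules$label), c("hydroxylated", "carboxylated"))
  set.seed(6)
  planted <- lapply(1:60, function(i) sample(plantable, sample(1:3, 1)))
  clean <- generate_spectra(rules, planted, noise_peaks = 0, seed = 7)
  got <- lapply(classify_batch(clean, rules)$annotations, `[[`, "class_labels")
  expect_equal(got, lapply(planted, function(x) sort(unique(x))))
  # nested near-target noise: per-spectrum correctness can only decay
  with_noise <- function(sp, k) {
    if (k == 0) return(sp)
    idx <- seq_len(k)
    near <- ifelse(rules$kind[idx] == "neutral_loss",
                   sp$precursor_mz - (rules$target_mz[idx] + 0.002),
                   rules$target_mz[idx] + 0.002)  # inside tolerance
    sp$peaks <- rbind(sp$peaks, cbind(mz = near,
                                      intensity = rep(5e4, k)))
    sp
  }
  acc <- vapply(0:4, function(k) {
    noisy <- lapply(clean, with_noise, k = k)
    got_k <- lapply(classify_batch(noisy, rules)$annotations,
                    `[[`, "class_labels")
    mean(mapply(identical, got_k,
                lapply(planted, function(x) sort(unique(x)))))
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 0))
  expect_lt(acc[5], 1)
})

test_that("batch tabulation covers groups and the unclassified bucket", {
  rules <- default_class_rules()
  sp <- c(generate_spectra(rules, list("flavonoid", "sulfated"),
                           noise_peaks = 0, seed = 8),
          list(fragment_spectrum("x", 400, peaks = cbind(123.456, 5e4))))
  res <- classify_batch(sp, rules, groups = c("sp1", "sp2", "sp1"))
  expect_equal(unname(res$counts[c("flavonoid", "sulfated", "unclassified")]),
               c(1L, 1L, 1L))
  expect_equal(dim(res$by_group), c(3L, 2L))
  empty <- classify_batch(list(), rules)
  expect_length(empty$annotations, 0L)
})
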