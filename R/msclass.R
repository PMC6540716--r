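# MS/MS compound-class annotation: spectrum container, MGF/MSP I/O,
# intensity cleaning, neutral-loss computation and matching of diagnostic
# fragments / neutral losses against a class-rule table.

#' Construct a fragment spectrum
#'
#' @param spectrum_id identifier.
#' @param precursor_mz precursor m/z (negative-mode deprotonated molecule
#'   assumed).
#' @param retention_time retention time in minutes (NA allowed).
#' @param peaks two-column matrix (`mz`, `intensity`); intensities must be
#'   nonnegative.
#' @return object of class `fragment_spectrum`.
#' @export
fragment_spectrum <- function(spectrum_id, precursor_mz,
                              retention_time = NA_real_, peaks) {
  if (is.null(dim(peaks))) peaks <- matrix(peaks, ncol = 2)
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) && any(peaks[, "intensity"] < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      is.na(precursor_mz)) {
    stop("missing precursor m/z for spectrum ", spectrum_id, call. = FALSE)
  }
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = precursor_mz,
                 retention_time = retention_time,
                 peaks = peaks),
            class = "fragment_spectrum")
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat(sprintf("Fragment spectrum %s: precursor %.4f m/z, RT %.2f min, %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$retention_time,
              nrow(x$peaks)))
  invisible(x)
}

#' Write spectra to an MGF file
#'
#' One BEGIN IONS/END IONS block per spectrum with TITLE (spectrum id),
#' PEPMASS (precursor m/z) and RTINSECONDS.
#'
#' @param spectra list of `fragment_spectrum`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_mgf <- function(spectra, path) {
  lines <- unlist(lapply(spectra, function(sp) {
    c("BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      paste0("PEPMASS=", format(sp$precursor_mz, digits = 15)),
      if (!is.na(sp$retention_time))
        paste0("RTINSECONDS=", format(sp$retention_time * 60, digits = 15)),
      if (nrow(sp$peaks))
        paste(format(sp$peaks[, "mz"], digits = 15, trim = TRUE),
              format(sp$peaks[, "intensity"], digits = 15, trim = TRUE)),
      "END IONS", "")
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.read_mgf <- function(lines) {
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    title <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else
      sprintf("spectrum_%04d", i)
    if (!"PEPMASS" %in% keys) {
      stop("missing precursor (PEPMASS) in spectrum ", title, call. = FALSE)
    }
    prec <- as.numeric(strsplit(vals[keys == "PEPMASS"][1], "\\s+")[[1]][1])
    rt <- if ("RTINSECONDS" %in% keys)
      as.numeric(vals[keys == "RTINSECONDS"][1]) / 60 else NA_real_
    peak_lines <- block[!is_kv & nzchar(trimws(block))]
    peaks <- if (length(peak_lines)) {
      do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"),
                            function(x) as.numeric(x[1:2])))
    } else {
      matrix(numeric(0), 0, 2)
    }
    fragment_spectrum(title, prec, rt, peaks)
  })
}

.read_msp <- function(lines) {
  name_idx <- grep("^NAME:", toupper(lines))
  if (!length(name_idx)) stop("malformed MSP: no Name records", call. = FALSE)
  bounds <- c(name_idx, length(lines) + 1L)
  lapply(seq_along(name_idx), function(i) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, ":"), toupper(block))
      if (length(hit)) trimws(sub("^[^:]*:", "", block[hit[1]])) else NA
    }
    title <- get_field("NAME")
    prec <- suppressWarnings(as.numeric(get_field("PRECURSORMZ")))
    if (is.na(prec)) {
      stop("missing precursor (PrecursorMZ) in spectrum ", title,
           call. = FALSE)
    }
    rt <- suppressWarnings(as.numeric(get_field("RETENTIONTIME")))
    peak_lines <- block[grepl("^\\s*[0-9]", block) &
                          !grepl(":", block, fixed = TRUE)]
    peaks <- if (length(peak_lines)) {
      do.call(rbind, lapply(strsplit(trimws(peak_lines), "[[:space:];]+"),
                            function(x) as.numeric(x[1:2])))
    } else {
      matrix(numeric(0), 0, 2)
    }
    fragment_spectrum(title, prec, rt, peaks)
  })
}

#' Read MS/MS spectra from MGF or MSP
#'
#' Format is chosen by file extension (`.mgf` / `.msp`), falling back to
#' content sniffing. Records without a precursor m/z raise an error naming
#' the spectrum.
#'
#' @param path input file.
#' @return list of `fragment_spectrum`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mgf" || (ext != "msp" && any(lines == "BEGIN IONS"))) {
    .read_mgf(lines)
  } else {
    .read_msp(lines)
  }
}

#' Clean and normalize a fragment spectrum
#'
#' Removes fragments at or below the absolute intensity threshold, then
#' normalizes the surviving intensities to the base peak (maximum = 1).
#' Fragments whose normalized intensity exceeds `rel_intensity_min` are
#' flagged as eligible for fragment-rule matching (`eligible` column); all
#' surviving fragments contribute neutral losses.
#'
#' @param spectrum a `fragment_spectrum`.
#' @param abs_intensity_min absolute threshold; peaks with intensity
#'   strictly above it survive (default 1000).
#' @param rel_intensity_min relative gate (strict) for fragment matching
#'   (default 0.1).
#' @return the spectrum with peaks columns `mz`, `intensity` (normalized),
#'   `eligible`; an empty peak list is allowed.
#' @export
clean_spectrum <- function(spectrum, abs_intensity_min = 1000,
                           rel_intensity_min = 0.1) {
  stopifnot(inherits(spectrum, "fragment_spectrum"))
  pk <- spectrum$peaks
  keep <- pk[, "intensity"] > abs_intensity_min
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk)) {
    norm <- pk[, "intensity"] / max(pk[, "intensity"])
    pk <- cbind(mz = pk[, "mz"], intensity = norm,
                eligible = as.numeric(norm > rel_intensity_min))
  } else {
    pk <- matrix(numeric(0), 0, 3,
                 dimnames = list(NULL, c("mz", "intensity", "eligible")))
  }
  out <- spectrum
  out$peaks <- pk
  attr(out, "cleaned") <- TRUE
  out
}

#' Neutral losses of a cleaned spectrum
#'
#' `loss = precursor_mz - fragment_mz` for every retained fragment;
#' non-positive losses (fragment at or above the precursor) are discarded.
#'
#' @param spectrum a cleaned `fragment_spectrum` (see [clean_spectrum()]).
#' @return data.frame with `loss_mz` and `from_fragment` (the fragment m/z).
#' @export
neutral_losses <- function(spectrum) {
  stopifnot(inherits(spectrum, "fragment_spectrum"))
  if (is.null(attr(spectrum, "cleaned"))) {
    spectrum <- clean_spectrum(spectrum)
  }
  loss <- spectrum$precursor_mz - spectrum$peaks[, "mz"]
  keep <- loss > 0
  data.frame(loss_mz = loss[keep],
             from_fragment = spectrum$peaks[keep, "mz"],
             row.names = NULL)
}

#' Default compound-class rule table
#'
#' A compact table of diagnostic neutral losses and fragment ions for
#' negative-mode semi-polar plant metabolites: sugar losses (hexose,
#' deoxyhexose, pentose, glucuronyl) marking glycosylation, SO3 and HPO3
#' losses marking sulfation and phosphorylation, malonyl / water / CO2
#' losses, and characteristic hydroxycinnamic-acid and flavonoid fragment
#' ions (deprotonated coumaroyl, caffeoyl, feruloyl; retro-Diels-Alder and
#' aglycone fragments). All target masses are computed from monoisotopic
#' atomic masses via [monoisotopic_mass()].
#'
#' @param tolerance matching tolerance in Da applied to every rule
#'   (default 0.005).
#' @return data.frame of class rules: rule_id, kind (`fragment` /
#'   `neutral_loss`), formula, target_mz, tolerance, label.
#' @export
default_class_rules <- function(tolerance = 0.005) {
  stopifnot_scalar_number(tolerance, "tolerance", 1e-6)
  rules <- data.frame(
    rule_id = c("hexose_loss", "deoxyhexose_loss", "pentose_loss",
                "glucuronyl_loss", "sulfate_loss", "phosphate_loss",
                "malonyl_loss", "water_loss", "co2_loss",
                "coumaroyl_frag", "caffeoyl_frag", "feruloyl_frag",
                "flavonoid_rda_frag", "flavone_aglycone_frag",
                "kaempferol_aglycone_frag"),
    kind = c(rep("neutral_loss", 9), rep("fragment", 6)),
    formula = c("C6H10O5", "C6H10O4", "C5H8O4", "C6H8O6", "SO3", "HPO3",
                "C3H2O3", "H2O", "CO2",
                "C9H7O3", "C9H7O4", "C10H9O4",
                "C7H3O4", "C15H9O5", "C15H9O6"),
    label = c("glycosylated", "glycosylated", "glycosylated", "glycosylated",
              "sulfated", "phosphorylated", "malonylated", "hydroxylated",
              "carboxylated",
              "hydroxycinnamic acid", "hydroxycinnamic acid",
              "hydroxycinnamic acid", "flavonoid", "flavonoid", "flavonoid"),
    stringsAsFactors = FALSE
  )
  # fragment targets are deprotonated ions: formula mass minus a proton is
  # already encoded by the radical formulas above (C9H7O3- etc.)
  rules$target_mz <- monoisotopic_mass(rules$formula)
  rules$tolerance <- tolerance
  rules[, c("rule_id", "kind", "formula", "target_mz", "tolerance", "label")]
}

#' Annotate a spectrum with compound-class labels
#'
#' Matches fragment rules against the eligible fragment m/z values
#' (normalized intensity above the relative gate) and neutral-loss rules
#' against the spectrum's neutral losses, each within the rule's tolerance.
#' Matched labels are deduplicated; modifiers (glycosylated, sulfated,
#' phosphorylated, ...) may co-occur with class labels.
#'
#' @param spectrum a `fragment_spectrum` (cleaned automatically if needed).
#' @param rules a rule table ([default_class_rules()] format).
#' @return list of class `class_annotation`: `spectrum_id`, `matched_rules`
#'   (data.frame rule_id/kind/label/observed_mz/delta_mz), `class_labels`
#'   (sorted, deduplicated), `unclassified`.
#' @export
annotate_spectrum <- function(spectrum, rules) {
  if (is.null(rules) || !nrow(rules)) {
    stop("empty rule table", call. = FALSE)
  }
  if (is.null(attr(spectrum, "cleaned"))) {
    spectrum <- clean_spectrum(spectrum)
  }
  frag_mz <- spectrum$peaks[spectrum$peaks[, "eligible"] > 0, "mz"]
  losses <- neutral_losses(spectrum)
  hits <- do.call(rbind, lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    obs <- if (r$kind == "fragment") frag_mz else losses$loss_mz
    if (!length(obs)) return(NULL)
    delta <- obs - r$target_mz
    m <- abs(delta) <= r$tolerance
    if (!any(m)) return(NULL)
    data.frame(rule_id = r$rule_id, kind = r$kind, label = r$label,
               observed_mz = obs[m], delta_mz = delta[m],
               stringsAsFactors = FALSE)
  }))
  labels <- if (is.null(hits)) character() else sort(unique(hits$label))
  structure(list(spectrum_id = spectrum$spectrum_id,
                 matched_rules = if (is.null(hits))
                   data.frame(rule_id = character(), kind = character(),
                              label = character(), observed_mz = numeric(),
                              delta_mz = numeric()) else hits,
                 class_labels = labels,
                 unclassified = length(labels) == 0L),
            class = "class_annotation")
}

#' Classify a batch of spectra
#'
#' Annotates every spectrum and tabulates label counts, optionally split by
#' a per-spectrum grouping attribute (e.g. the species a specific compound
#' was attributed to).
#'
#' @param spectra list of `fragment_spectrum`.
#' @param rules rule table.
#' @param groups optional grouping vector, one entry per spectrum.
#' @return list with `annotations` (per spectrum), `counts` (label counts,
#'   including `unclassified`), and `by_group` (label x group table) when
#'   `groups` is given.
#' @export
classify_batch <- function(spectra, rules, groups = NULL) {
  if (!length(spectra)) {
    return(list(annotations = list(),
                counts = stats::setNames(integer(0), character(0)),
                by_group = NULL))
  }
  ann <- lapply(spectra, annotate_spectrum, rules = rules)
  labs <- lapply(ann, function(a) {
    if (a$unclassified) "unclassified" else a$class_labels
  })
  counts <- sort(table(unlist(labs)), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  by_group <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(spectra))
    long <- data.frame(
      label = unlist(labs),
      group = rep(as.character(groups), lengths(labs)),
      stringsAsFactors = FALSE
    )
    by_group <- table(long$label, long$group)
  }
  list(annotations = ann, counts = counts, by_group = by_group)
}
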