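#' Pipeline configuration
#'
#' Bundles every tunable of the annotation pipeline with its default. All
#' tolerances must be positive. A config round-trips through YAML via
#' [write_config()] / [read_config()].
#'
#' @param precursor_tol_ppm precursor / series / formula matching tolerance
#'   in ppm (default 5; the measured errors this targets are sub-ppm, so 5
#'   ppm is conservative while still rejecting decoys).
#' @param frag_tol fragment m/z tolerance in Da (default 0.35, wide because
#'   ion-trap fragments are nominal-mass).
#' @param min_score minimum cosine score for a library identification
#'   (default 0.7).
#' @param isomer_min_score minimum cosine between an isomer candidate and
#'   its canonical partner (default 0.6).
#' @param rt_min_gap,rt_max_gap allowed RT gap between consecutive series
#'   members, minutes (defaults 0.2 and 1.5, bracketing the ~0.7 min per
#'   CH2 increment of the pseudane series).
#' @param rt_tol minimum RT separation for distinct isomers, minutes
#'   (default 0.05).
#' @param diagnostic_mz diagnostic class fragment m/z (default 159).
#' @param rdbe_min,rdbe_max RDBE window for formula candidates (defaults 0
#'   and 20).
#' @param element_bounds named per-element maximum counts for formula
#'   enumeration (default [default_element_bounds()]).
#' @param nitrogen_rule apply the nitrogen parity rule when enumerating
#'   formulas (default FALSE; even-electron ions).
#' @param seed RNG seed recorded with the run (default 1).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `aq_config`.
#' @export
pipeline_config <- function(precursor_tol_ppm = 5, frag_tol = 0.35,
                            min_score = 0.7, isomer_min_score = 0.6,
                            rt_min_gap = 0.2, rt_max_gap = 1.5, rt_tol = 0.05,
                            diagnostic_mz = 159, rdbe_min = 0, rdbe_max = 20,
                            element_bounds = default_element_bounds(),
                            nitrogen_rule = FALSE, seed = 1,
                            log_level = "info") {
  cfg <- list(precursor_tol_ppm = precursor_tol_ppm, frag_tol = frag_tol,
              min_score = min_score, isomer_min_score = isomer_min_score,
              rt_min_gap = rt_min_gap, rt_max_gap = rt_max_gap, rt_tol = rt_tol,
              diagnostic_mz = diagnostic_mz, rdbe_min = rdbe_min,
              rdbe_max = rdbe_max,
              element_bounds = as.list(element_bounds),
              nitrogen_rule = isTRUE(nitrogen_rule),
              seed = as.integer(seed), log_level = log_level)
  for (k in c("precursor_tol_ppm", "frag_tol", "min_score", "isomer_min_score",
              "rt_max_gap", "rt_tol"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config field ", k, " must be positive", call. = FALSE)
  if (cfg$rt_min_gap < 0 || cfg$rt_min_gap >= cfg$rt_max_gap)
    stop("need 0 <= rt_min_gap < rt_max_gap", call. = FALSE)
  class(cfg) <- "aq_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config an `aq_config` (for `write_config`).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$element_bounds <- unlist(raw$element_bounds)
  do.call(pipeline_config, raw)
}

.log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(...))
  invisible(NULL)
}

#' Annotate an LC-MS/MS feature table
#'
#' Runs the full annotation cascade in memory: molecular-formula enumeration
#' for every feature, spectral-library matching for every feature with an
#' MS/MS spectrum, CH2 homologous-series detection, chain-length anchoring
#' against the library, RT-trend isomer resolution, and rule-based
#' classification. Deterministic given features, library and config.
#'
#' @param features list of `aq_feature` objects (spectra attached).
#' @param library list of `aq_library_entry` objects (may be empty).
#' @param config an `aq_config` from [pipeline_config()].
#' @return An `aq_annotation` data frame (see [classify_features()]) with
#'   attributes `series` (list of resolved `aq_series`) and `config`.
#' @examples
#' sp <- read_mgf(aq_example("table1_spectra.mgf"))
#' feats <- read_feature_table(aq_example("table1_features.csv"), spectra = sp)
#' lib <- read_msp(aq_example("pseudane_library.msp"))
#' ann <- annotate_features(feats, lib, pipeline_config(log_level = "quiet"))
#' summary(ann)
#' @export
annotate_features <- function(features, library = list(),
                              config = pipeline_config()) {
  stopifnot(inherits(config, "aq_config"))
  bounds <- unlist(config$element_bounds)
  .log(config, "annotating %d feature(s) against %d library entrie(s)",
       length(features), length(library))
  cand <- lapply(features, function(f)
    enumerate_formulas(f$mz, tol_ppm = config$precursor_tol_ppm,
                       bounds = bounds, rdbe_min = config$rdbe_min,
                       rdbe_max = config$rdbe_max,
                       nitrogen_rule = config$nitrogen_rule))
  names(cand) <- vapply(features, `[[`, "", "feature_id")
  hits <- lapply(features, function(f) {
    if (is.null(f$spectrum)) return(NULL)
    match_library(f$spectrum, library,
                  precursor_tol_ppm = config$precursor_tol_ppm,
                  frag_tol = config$frag_tol, min_score = config$min_score)
  })
  names(hits) <- names(cand)
  series <- detect_series(features, mz_tol_ppm = config$precursor_tol_ppm,
                          rt_min_gap = config$rt_min_gap,
                          rt_max_gap = config$rt_max_gap)
  series <- lapply(series, function(s) {
    s <- anchor_series(s, library, config$precursor_tol_ppm)
    if (nrow(s$members) >= 3L)
      s <- resolve_isomers(s, features, rt_tol = config$rt_tol,
                           frag_tol = config$frag_tol,
                           isomer_min_score = config$isomer_min_score,
                           diagnostic_mz = config$diagnostic_mz)
    s
  })
  .log(config, "found %d series", length(series))
  cand <- .propagate_series_formulas(cand, series, features)
  ann <- classify_features(features, cand, hits, series,
                           min_score = config$min_score,
                           diagnostic_mz = config$diagnostic_mz,
                           frag_tol = config$frag_tol)
  attr(ann, "series") <- series
  attr(ann, "config") <- config
  ann
}

# Series-context formula assignment: a canonical member of a CH2 homologous
# series whose own accurate-mass search returned nothing inherits the
# formula of the nearest member that has one, shifted by the appropriate
# number of CH2 units. This is the series-regularity inference itself: the
# homologue relationship pins down the composition even when a single
# scan's mass error falls outside the search window.
.propagate_series_formulas <- function(cand, series, features) {
  mz_of <- stats::setNames(vapply(features, `[[`, 0, "mz"),
                           vapply(features, `[[`, "", "feature_id"))
  for (s in series) {
    m <- s$members
    has <- vapply(m$feature_id, function(id)
      !is.null(cand[[id]]) && nrow(cand[[id]]) > 0, TRUE)
    if (all(has) || !any(has)) next
    for (i in which(!has)) {
      j <- which(has)[which.min(abs(m$member_index[which(has)] - m$member_index[i]))]
      donor <- cand[[m$feature_id[j]]][1, ]
      dn <- m$member_index[i] - m$member_index[j]
      f <- parse_formula(donor$formula, "protonated_ion")
      cc <- f$counts
      cc["C"] <- cc["C"] + dn
      cc["H"] <- cc["H"] + 2L * dn
      if (any(is.na(cc)) || cc["C"] <= 0 || cc["H"] <= 0) next
      f2 <- formula_counts(cc, "protonated_ion")
      mz <- ion_mz(f2)
      cand[[m$feature_id[i]]] <- data.frame(
        formula = format(f2), theoretical_mz = mz,
        ppm_error = ppm_error(mz_of[[m$feature_id[i]]], mz),
        rdbe = rdbe(f2), stringsAsFactors = FALSE)
    }
  }
  cand
}

#' Run the annotation pipeline on files and write reports
#'
#' File-level wrapper around [annotate_features()]: reads a feature table,
#' MGF spectra and an MSP library, annotates, and writes a TSV report with
#' fixed column order, a JSON summary (class counts plus a series table)
#' and a per-feature evidence log. Outputs are bit-stable given identical
#' inputs and config; nothing is written if any stage fails.
#'
#' @param features_path CSV/TSV feature table.
#' @param spectra_path MGF file, or `NULL` if the table carries no spectra.
#' @param library_path MSP library, or `NULL` for library-free annotation.
#' @param out_prefix path prefix for `"<prefix>.tsv"`, `"<prefix>.json"` and
#'   `"<prefix>.log"`; `NULL` writes nothing.
#' @param config an `aq_config`.
#' @return The `aq_annotation` invisibly, with `summary` attribute.
#' @export
run_annotation <- function(features_path, spectra_path = NULL,
                           library_path = NULL, out_prefix = NULL,
                           config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  spectra <- if (!is.null(spectra_path))
    stage("read_mgf", read_mgf(spectra_path)) else NULL
  features <- stage("read_feature_table",
                    read_feature_table(features_path, spectra = spectra))
  library <- if (!is.null(library_path))
    stage("read_msp", read_msp(library_path)) else list()
  ann <- stage("annotate", annotate_features(features, library, config))
  counts <- summary(ann)
  attr(ann, "summary") <- counts
  if (!is.null(out_prefix)) {
    series <- attr(ann, "series")
    report_cols <- c("feature_id", "rt_min", "mz", "class", "best_formula",
                     "ppm", "best_library_hit", "score", "series_id",
                     "member_index", "evidence")
    utils::write.table(format(as.data.frame(ann)[, report_cols], digits = 12,
                              trim = TRUE),
                       paste0(out_prefix, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    series_tab <- lapply(series, function(s) list(
      series_id = s$series_id,
      n_members = nrow(s$members),
      n_isomer_candidates = sum(s$isomers$status == "isomer_candidate"),
      anchored = isTRUE(s$anchored),
      member_indices = s$members$member_index))
    jsonlite::write_json(list(class_counts = counts, series = series_tab),
                         paste0(out_prefix, ".json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    writeLines(sprintf("%s\t%s\t%s", ann$feature_id, ann$class, ann$evidence),
               paste0(out_prefix, ".log"))
    .log(config, "wrote %s.{tsv,json,log}", out_prefix)
  }
  invisible(ann)
}

#' Score an annotation against synthetic ground truth
#'
#' Treats every non-`unknown` prediction as a positive call; a call is
#' correct when the predicted class equals the generated class. Precision is
#' correct calls over calls made, recall is correct calls over true
#' non-`unknown` features.
#'
#' @param annotation an `aq_annotation`.
#' @param truth ground-truth data frame from [generate_pseudane_dataset()].
#' @return A list with `precision`, `recall`, `n_calls`, `n_true`.
#' @export
score_annotation <- function(annotation, truth) {
  m <- merge(as.data.frame(annotation)[, c("feature_id", "class")],
             truth[, c("feature_id", "true_class")], by = "feature_id")
  called <- m$class != "unknown"
  positive <- m$true_class != "unknown"
  correct <- called & m$class == m$true_class
  list(precision = if (any(called)) sum(correct) / sum(called) else 1,
       recall = if (any(positive)) sum(correct) / sum(positive) else 1,
       n_calls = sum(called), n_true = sum(positive))
}

#' End-to-end demonstration on a generated dataset
#'
#' Generates a synthetic pseudane dataset, annotates it with default (or
#' overridden) settings, and scores the result against the generator's
#' ground truth.
#'
#' @param seed RNG seed for the generator.
#' @param config an `aq_config`.
#' @param ... overrides passed to [generate_pseudane_dataset()]
#'   (e.g. `ppm_sigma`, `decoy_count`).
#' @return A list with `precision`, `recall`, `ok` (both equal to 1),
#'   `annotation`, `truth`.
#' @export
run_demo <- function(seed = 7, config = pipeline_config(), ...) {
  ds <- generate_pseudane_dataset(seed = seed, ...)
  ann <- annotate_features(ds$features, ds$library, config)
  sc <- score_annotation(ann, ds$truth)
  .log(config, "demo seed %d: precision %.3f, recall %.3f", seed,
       sc$precision, sc$recall)
  c(sc, list(ok = sc$precision == 1 && sc$recall == 1,
             annotation = ann, truth = ds$truth))
}
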