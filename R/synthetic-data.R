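#' Generate a ground-truthed synthetic pseudane LC-MS/MS dataset
#'
#' Emulates the measurement structure of an Orbitrap/ion-trap screening run
#' over the pseudane-III...XI homologous series: precursor masses carry
#' multiplicative sub-ppm noise, retention times follow a linear
#' chain-length trend with Gaussian jitter, and MS/MS spectra are nominal
#' fragment ladders built from the 2-alkylquinolin-4(1H)-one scaffold ion
#' set {132, 146, 159, 172, 186, 200, 214} truncated below the precursor,
#' plus the precursor-derived peak. Optionally adds two same-formula isomer
#' twins (RT offsets -0.07 min at chain length 5 and -0.14 min at 6, the
#' displacement pattern of the two novel alkylquinolones the series model is
#' built around) and off-series decoy features. Everything is reproducible
#' from the seed and a ground-truth table records the intended class of
#' every feature.
#'
#' @param seed integer RNG seed.
#' @param ppm_sigma standard deviation of the relative precursor mass error
#'   in ppm (default 0.3, sub-ppm as on a 30,000-FWHM Orbitrap).
#' @param rt_intercept,rt_slope linear RT model in minutes: RT(n) =
#'   intercept + slope * n for alkyl chain length n (defaults 2.46 and 0.70,
#'   placing pseudane-III near 4.56 min).
#' @param rt_sigma RT jitter standard deviation in minutes (default 0.005,
#'   the sub-second run-to-run retention repeatability of modern UHPLC —
#'   necessarily small against the 0.07 min isomer displacement, or the
#'   instrument could not have resolved the twin peaks at all).
#' @param include_isomers add the two isomer twins (default TRUE).
#' @param decoy_count number of random non-quinolone decoy features
#'   (default 5); decoy ion masses are redrawn until at least 20 ppm away
#'   from every series mass.
#' @param dropout_rate probability that a feature loses its MS/MS spectrum
#'   (default 0). A dropout rate of 1 together with isomer twins is refused:
#'   isomer evidence is purely spectral.
#' @param intensity_jitter_sd lognormal sigma of the fragment intensity
#'   jitter around base 100 (default 0.2).
#' @param out_dir optional directory; when given, the dataset is also
#'   written as `features.csv`, `spectra.mgf`, `library.msp` and
#'   `manifest.json`.
#' @return A list with `features` (list of [feature()] objects, spectra
#'   attached), `spectra` (named list), `library` (list of
#'   [library_entry()]), `truth` (data frame: `feature_id`, `compound`,
#'   `ion_formula`, `true_class`, `is_decoy`) and `params`.
#' @export
generate_pseudane_dataset <- function(seed, ppm_sigma = 0.3,
                                      rt_intercept = 2.46, rt_slope = 0.70,
                                      rt_sigma = 0.005,
                                      include_isomers = TRUE,
                                      decoy_count = 5, dropout_rate = 0,
                                      intensity_jitter_sd = 0.2,
                                      out_dir = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (ppm_sigma < 0 || rt_sigma < 0 || intensity_jitter_sd < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]", call. = FALSE)
  if (dropout_rate >= 1 && include_isomers)
    stop("dropout_rate 1 with isomer twins is impossible: isomers need MS/MS evidence",
         call. = FALSE)
  set.seed(as.integer(seed))
  scaffold <- c(132, 146, 159, 172, 186, 200, 214)
  roman <- as.character(utils::as.roman(3:11))
  commercial <- c("IV", "VI", "VIII")
  ladder <- function(theo) c(scaffold[scaffold < floor(theo)], round(theo))

  ions <- lapply(3:11, function(n)
    formula_counts(c(C = n + 9L, H = 2L * n + 8L, O = 1L, N = 1L), "protonated_ion"))
  theo <- vapply(ions, ion_mz, 0)
  names(theo) <- roman

  lib <- lapply(seq_along(roman), function(i) {
    library_entry(paste0("Pseudane-", roman[i]), ions[[i]],
                  spectrum(theo[i], ladder(theo[i]), 100),
                  provenance = if (roman[i] %in% commercial)
                    "commercial_standard" else "literature")
  })

  jitter_int <- function(k) 100 * exp(stats::rnorm(k, 0, intensity_jitter_sd))
  features <- list(); truth <- list()
  add_feature <- function(id, compound, formula_str, theo_mz, rt, true_class,
                          frag, is_decoy = FALSE) {
    obs <- theo_mz * (1 + stats::rnorm(1, 0, ppm_sigma * 1e-6))
    sp <- spectrum(obs, frag, jitter_int(length(frag)), rt)
    if (dropout_rate > 0 && stats::runif(1) < dropout_rate) sp <- NULL
    features[[id]] <<- feature(id, rt, obs, 100, sp)
    truth[[id]] <<- data.frame(feature_id = id, compound = compound,
                               ion_formula = formula_str, true_class = true_class,
                               is_decoy = is_decoy, stringsAsFactors = FALSE)
  }

  for (i in seq_along(roman)) {
    n <- i + 2L
    rt <- rt_intercept + rt_slope * n + stats::rnorm(1, 0, rt_sigma)
    cls <- if (roman[i] %in% commercial) "identified_standard" else "putative_homolog"
    add_feature(paste0("syn_pseudane_", roman[i]), paste0("Pseudane-", roman[i]),
                format(ions[[i]]), theo[i], rt, cls, ladder(theo[i]))
  }
  if (include_isomers) {
    for (tw in list(list(n = 5L, off = -0.07, nm = "isomer_V_class"),
                    list(n = 6L, off = -0.14, nm = "isomer_VI_class"))) {
      i <- tw$n - 2L
      rt <- features[[paste0("syn_pseudane_", roman[i])]]$rt + tw$off
      add_feature(paste0("syn_", tw$nm), tw$nm, format(ions[[i]]), theo[i],
                  rt, "isomer_candidate", ladder(theo[i]))
    }
  }
  if (decoy_count > 0) {
    el <- mass_constants()$elements
    for (d in seq_len(decoy_count)) {
      repeat {
        cnt <- c(C = sample(5:25, 1), H = sample(6:40, 1),
                 N = sample(0:3, 1), O = sample(0:5, 1))
        cnt <- cnt[cnt > 0]
        mz <- sum(el[names(cnt)] * cnt) + mass_constants()$proton
        if (all(abs(ppm_error(mz, theo)) > 20)) break
      }
      frag <- sort(unique(round(stats::runif(5, 50, mz - 5))))
      add_feature(sprintf("syn_decoy_%02d", d), sprintf("decoy_%02d", d),
                  paste0(paste0(names(cnt), cnt, collapse = ""), "+H"),
                  mz, stats::runif(1, 1, 12), "unknown", frag, is_decoy = TRUE)
    }
  }
  truth <- do.call(rbind, c(unname(truth), list(make.row.names = FALSE)))
  spectra <- lapply(features, `[[`, "spectrum")
  spectra <- spectra[!vapply(spectra, is.null, TRUE)]
  params <- list(seed = as.integer(seed), ppm_sigma = ppm_sigma,
                 rt_intercept = rt_intercept, rt_slope = rt_slope,
                 rt_sigma = rt_sigma, include_isomers = include_isomers,
                 decoy_count = decoy_count, dropout_rate = dropout_rate,
                 intensity_jitter_sd = intensity_jitter_sd)
  ds <- list(features = features, spectra = spectra, library = lib,
             truth = truth, params = params)
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' Write a synthetic dataset to disk
#'
#' Writes `features.csv`, `spectra.mgf`, `library.msp`, `ground_truth.csv`
#' and a `manifest.json` recording the generation parameters. Output is
#' byte-identical for identical datasets.
#'
#' @param dataset a dataset list from [generate_pseudane_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(dataset$features, file.path(out_dir, "features.csv"),
                      extra = data.frame(compound = dataset$truth$compound))
  write_mgf(dataset$spectra, file.path(out_dir, "spectra.mgf"))
  write_msp(dataset$library, file.path(out_dir, "library.msp"))
  utils::write.csv(dataset$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$params, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Apply a single controlled corruption to a synthetic dataset
#'
#' Adversarial fixture builder for error-path testing. Exactly one
#' corruption is applied and recorded in the ground-truth table's
#' `corruption` column.
#'
#' @param dataset a dataset list from [generate_pseudane_dataset()].
#' @param mode one of `"shift_mass"` (multiply one feature's observed m/z by
#'   `1 + magnitude * 1e-6`, i.e. a ppm-scale shift), `"drop_ms2"` (remove
#'   one feature's MS/MS spectrum) or `"shuffle_rt"` (randomly permute the
#'   retention times of `ceiling(magnitude * n)` features; magnitude 0 is
#'   the identity).
#' @param magnitude corruption size: ppm for `shift_mass`, fraction of
#'   features for `shuffle_rt`, ignored for `drop_ms2`.
#' @param target feature id to corrupt; defaults to the heaviest canonical
#'   series member for `shift_mass` and the first isomer twin (else the
#'   first feature) for `drop_ms2`.
#' @return The corrupted dataset.
#' @export
corrupt_dataset <- function(dataset, mode, magnitude = 0, target = NULL) {
  ids <- names(dataset$features)
  tag <- function(id, what) {
    dataset$truth$corruption <- ifelse(
      dataset$truth$feature_id %in% id, what,
      if ("corruption" %in% names(dataset$truth)) dataset$truth$corruption else "")
    dataset
  }
  if (identical(mode, "shift_mass")) {
    if (is.null(target)) {
      series_ids <- dataset$truth$feature_id[!dataset$truth$is_decoy &
                                               dataset$truth$true_class != "isomer_candidate"]
      mzs <- vapply(dataset$features[series_ids], `[[`, 0, "mz")
      target <- series_ids[which.max(mzs)]
    }
    f <- dataset$features[[target]]
    f$mz <- f$mz * (1 + magnitude * 1e-6)
    if (!is.null(f$spectrum)) f$spectrum$precursor_mz <- f$mz
    dataset$features[[target]] <- f
    if (!is.null(f$spectrum)) dataset$spectra[[target]] <- f$spectrum
    return(tag(target, sprintf("shift_mass:%g ppm", magnitude)))
  }
  if (identical(mode, "drop_ms2")) {
    if (is.null(target)) {
      iso <- dataset$truth$feature_id[dataset$truth$true_class == "isomer_candidate"]
      target <- if (length(iso)) iso[1] else ids[1]
    }
    dataset$features[[target]]$spectrum <- NULL
    dataset$spectra[[target]] <- NULL
    return(tag(target, "drop_ms2"))
  }
  if (identical(mode, "shuffle_rt")) {
    k <- ceiling(magnitude * length(ids))
    if (k >= 2) {
      set.seed(dataset$params$seed + 1L)
      pick <- sample(ids, k)
      perm <- sample(pick)
      rts <- vapply(dataset$features[pick], `[[`, 0, "rt")
      for (i in seq_along(pick)) {
        dataset$features[[pick[i]]]$rt <- rts[[perm[i]]]
        if (!is.null(dataset$features[[pick[i]]]$spectrum)) {
          dataset$features[[pick[i]]]$spectrum$rt <- rts[[perm[i]]]
          dataset$spectra[[pick[i]]] <- dataset$features[[pick[i]]]$spectrum
        }
      }
      return(tag(pick, sprintf("shuffle_rt:%g", magnitude)))
    }
    return(tag(character(0), ""))
  }
  stop("unknown corruption mode '", mode, "'", call. = FALSE)
}
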