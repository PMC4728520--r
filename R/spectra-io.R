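#' Construct an MS/MS spectrum
#'
#' @param precursor_mz precursor m/z in Da (> 0).
#' @param fragment_mz numeric vector of fragment m/z values (> 0). Peaks are
#'   stored sorted by m/z. A fragment may exceed the precursor by at most
#'   1 Da (slack for nominal rounding of ion-trap fragments).
#' @param intensity fragment intensities (>= 0); recycled scalar allowed,
#'   default 100 for nominal-mass spectra printed without intensities.
#' @param rt retention time in minutes, or `NA`.
#' @return An object of class `aq_spectrum` with fields `precursor_mz`,
#'   `peaks` (two-column matrix `mz`, `intensity`) and `rt`.
#' @export
spectrum <- function(precursor_mz, fragment_mz = numeric(0), intensity = 100,
                     rt = NA_real_) {
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number", call. = FALSE)
  fragment_mz <- as.numeric(fragment_mz)
  intensity <- rep_len(as.numeric(intensity), length(fragment_mz))
  if (any(fragment_mz <= 0)) stop("fragment m/z must be positive", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (any(fragment_mz >= precursor_mz + 1.0))
    stop("fragment m/z beyond precursor + 1 Da", call. = FALSE)
  ord <- order(fragment_mz, intensity)
  structure(
    list(precursor_mz = precursor_mz,
         peaks = cbind(mz = fragment_mz[ord], intensity = intensity[ord]),
         rt = as.numeric(rt)),
    class = "aq_spectrum"
  )
}

#' @export
print.aq_spectrum <- function(x, ...) {
  cat(sprintf("<aq_spectrum> precursor %.4f, %d peak(s)%s\n",
              x$precursor_mz, nrow(x$peaks),
              if (is.na(x$rt)) "" else sprintf(", RT %.2f min", x$rt)))
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)

#' Construct an LC-MS feature
#'
#' One chromatographic peak: retention time, observed \eqn{[M+H]^+} m/z,
#' intensity, and an optional MS/MS spectrum.
#'
#' @param feature_id opaque identifier, unique within a table.
#' @param rt retention time in minutes (>= 0).
#' @param mz observed m/z in Da (> 0).
#' @param intensity peak intensity (arbitrary units).
#' @param spectrum optional `aq_spectrum`.
#' @return An object of class `aq_feature`.
#' @export
feature <- function(feature_id, rt, mz, intensity = NA_real_, spectrum = NULL) {
  if (!is.character(feature_id) || length(feature_id) != 1L || !nzchar(feature_id))
    stop("feature_id must be a non-empty string", call. = FALSE)
  if (!is.numeric(rt) || rt < 0) stop("rt must be >= 0", call. = FALSE)
  if (!is.numeric(mz) || mz <= 0) stop("mz must be > 0", call. = FALSE)
  if (!is.null(spectrum) && !inherits(spectrum, "aq_spectrum"))
    stop("spectrum must be an aq_spectrum or NULL", call. = FALSE)
  structure(
    list(feature_id = feature_id, rt = as.numeric(rt), mz = as.numeric(mz),
         intensity = as.numeric(intensity), spectrum = spectrum),
    class = "aq_feature"
  )
}

#' Construct a spectral-library entry
#'
#' @param name compound name.
#' @param ion_formula `aq_formula` with charge state `protonated_ion`.
#' @param spectrum reference `aq_spectrum`.
#' @param provenance one of `"commercial_standard"`, `"literature"`,
#'   `"in_house"`.
#' @param theoretical_mz optional; defaults to `ion_mz(ion_formula)` and must
#'   agree with it within 1e-4 Da.
#' @return An object of class `aq_library_entry`.
#' @export
library_entry <- function(name, ion_formula, spectrum,
                          provenance = c("literature", "commercial_standard", "in_house"),
                          theoretical_mz = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(ion_formula, "aq_formula"), inherits(spectrum, "aq_spectrum"))
  if (ion_formula$charge_state != "protonated_ion")
    stop("library ion_formula must be a protonated_ion composition", call. = FALSE)
  mz <- ion_mz(ion_formula)
  if (is.null(theoretical_mz)) theoretical_mz <- mz
  if (abs(theoretical_mz - mz) > 1e-4)
    stop(sprintf("entry '%s': PrecursorMZ %.5f disagrees with formula %s (%.5f)",
                 name, theoretical_mz, format(ion_formula), mz), call. = FALSE)
  structure(
    list(name = name, ion_formula = ion_formula, theoretical_mz = theoretical_mz,
         spectrum = spectrum, provenance = provenance),
    class = "aq_library_entry"
  )
}

#' @export
print.aq_library_entry <- function(x, ...) {
  cat(sprintf("<aq_library_entry> %s [%s] %.4f m/z, %d peak(s), %s\n",
              x$name, format(x$ion_formula), x$theoretical_mz,
              nrow(x$spectrum$peaks), x$provenance))
  invisible(x)
}

# ---- feature tables (CSV/TSV) ------------------------------------------

#' Read a feature table
#'
#' Reads a CSV/TSV feature table with required columns `rt_min`, `mz`,
#' `intensity` and optional columns `feature_id` and `spectrum_id` (the
#' latter links rows to MGF spectra by title). Row order is preserved.
#'
#' @param path file path.
#' @param sep field separator; guessed from the file extension by default
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param spectra optional named list of `aq_spectrum` objects keyed by
#'   spectrum id, as returned by [read_mgf()]; matched via `spectrum_id`.
#' @return A list of `aq_feature` objects, with the raw table attached as
#'   attribute `"table"`.
#' @export
read_feature_table <- function(path, sep = NULL, spectra = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = TRUE)
  required <- c("rt_min", "mz", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("feature table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    out <- list()
    attr(out, "table") <- df
    return(out)
  }
  errs <- character(0)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])))
    if (length(bad))
      errs <<- c(errs, sprintf("line %d: non-numeric %s '%s'",
                               bad + 1L, col, df[[col]][bad]))
    v
  }
  rt <- num("rt_min"); mz <- num("mz"); inten <- num("intensity")
  if (length(errs))
    stop("malformed feature table rows:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  ids <- if ("feature_id" %in% names(df)) df$feature_id else sprintf("F%03d", seq_len(nrow(df)))
  if (anyDuplicated(ids))
    stop("duplicated feature_id in ", path, call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sp <- NULL
    if (!is.null(spectra) && "spectrum_id" %in% names(df)) {
      sid <- df$spectrum_id[i]
      if (nzchar(sid) && sid %in% names(spectra)) sp <- spectra[[sid]]
    }
    out[[i]] <- feature(ids[i], rt[i], mz[i], inten[i], sp)
  }
  names(out) <- ids
  attr(out, "table") <- df
  out
}

#' Write a feature table
#'
#' @param features list of `aq_feature` objects.
#' @param path output path; `.tsv` extension selects tab separation.
#' @param extra optional data frame of extra columns (same row count).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, extra = NULL) {
  df <- data.frame(
    feature_id = vapply(features, `[[`, "", "feature_id"),
    rt_min = vapply(features, `[[`, 0, "rt"),
    mz = vapply(features, `[[`, 0, "mz"),
    intensity = vapply(features, `[[`, 0, "intensity"),
    spectrum_id = vapply(features, function(f)
      if (is.null(f$spectrum)) "" else f$feature_id, ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- MGF ----------------------------------------------------------------

#' Read and write Mascot generic format (MGF) spectra
#'
#' `read_mgf()` parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`,
#' optional `RTINSECONDS` (converted to minutes) and `TITLE` lines; peaks are
#' sorted on read. `write_mgf()` is its inverse; the round trip is stable to
#' 6 decimals.
#'
#' @param path file path.
#' @return `read_mgf()`: a named list of `aq_spectrum` objects (names from
#'   `TITLE`, or `spectrum_<i>`).
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  spectra <- list()
  i <- 1L; block <- 0L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      block <- block + 1L
      title <- sprintf("spectrum_%d", block)
      pep <- NA_real_; rt <- NA_real_
      fmz <- numeric(0); fint <- numeric(0)
      i <- i + 1L
      closed <- FALSE
      while (i <= length(lines)) {
        ln <- lines[i]
        if (ln == "END IONS") { closed <- TRUE; i <- i + 1L; break }
        if (grepl("^TITLE=", ln)) {
          title <- sub("^TITLE=", "", ln)
        } else if (grepl("^PEPMASS=", ln)) {
          pep <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]][1])
        } else if (grepl("^RTINSECONDS=", ln)) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
        } else if (grepl("^[0-9]", ln)) {
          v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          fmz <- c(fmz, v[1])
          fint <- c(fint, if (length(v) > 1L && !is.na(v[2])) v[2] else 100)
        }
        i <- i + 1L
      }
      if (!closed)
        stop("unterminated BEGIN IONS block ", block, " in ", path, call. = FALSE)
      if (is.na(pep))
        stop("block ", block, " in ", path, " lacks PEPMASS", call. = FALSE)
      spectra[[title]] <- spectrum(pep, fmz, fint, rt)
    } else {
      i <- i + 1L
    }
  }
  spectra
}

#' @rdname read_mgf
#' @param spectra named list of `aq_spectrum` objects.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  nm <- names(spectra)
  if (is.null(nm)) nm <- sprintf("spectrum_%d", seq_along(spectra))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", nm[k]), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.6f", s$rt * 60), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.6f %.6f", s$peaks[, "mz"], s$peaks[, "intensity"]), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

# ---- MSP ----------------------------------------------------------------

#' Read and write NIST-style MSP spectral libraries
#'
#' Entries consist of `Name:`, `Formula:` (ion composition), `PrecursorMZ:`,
#' `Comment:` carrying a `provenance=` tag, and `Num Peaks:` followed by peak
#' lines. Each entry is validated: the stated precursor must agree with the
#' formula's theoretical \eqn{[M+H]^+} m/z within 1e-4 Da, and the peak count
#' must match `Num Peaks`.
#'
#' @param path file path.
#' @return `read_msp()`: a list of `aq_library_entry` objects.
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  fields <- list(); peaks <- NULL; expected <- NA_integer_
  flush <- function() {
    if (is.null(fields$Name)) return()
    if (!is.na(expected) && (is.null(peaks) ||  nrow(peaks) != expected))
      stop("entry '", fields$Name, "' in ", path, ": Num Peaks ", expected,
           " but ", if (is.null(peaks)) 0L else nrow(peaks), " peak lines",
           call. = FALSE)
    prov <- "in_house"
    if (!is.null(fields$Comment)) {
      m <- regmatches(fields$Comment, regexpr("provenance=[A-Za-z_]+", fields$Comment))
      if (length(m)) prov <- sub("provenance=", "", m)
    }
    f <- parse_formula(fields$Formula, "protonated_ion")
    sp <- spectrum(as.numeric(fields$PrecursorMZ),
                   peaks[, 1], peaks[, 2])
    entries[[length(entries) + 1L]] <<- library_entry(
      fields$Name, f, sp, provenance = prov,
      theoretical_mz = as.numeric(fields$PrecursorMZ))
    fields <<- list(); peaks <<- NULL; expected <<- NA_integer_
  }
  for (ln in trimws(lines)) {
    if (!nzchar(ln)) { flush(); next }
    if (grepl("^Num Peaks:", ln)) {
      expected <- as.integer(trimws(sub("^Num Peaks:", "", ln)))
      peaks <- matrix(numeric(0), ncol = 2)
    } else if (grepl("^[0-9]", ln)) {
      v <- as.numeric(strsplit(ln, "[ \t;]+")[[1]])
      peaks <- rbind(peaks, v[1:2])
    } else if (grepl(":", ln, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", ln))
      fields[[key]] <- trimws(sub("^[^:]*:", "", ln))
    }
  }
  flush()
  entries
}

#' @rdname read_msp
#' @param entries list of `aq_library_entry` objects.
#' @export
write_msp <- function(entries, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (e in entries) {
    writeLines(c(
      paste0("Name: ", e$name),
      paste0("Formula: ", format(e$ion_formula)),
      sprintf("PrecursorMZ: %.6f", e$theoretical_mz),
      paste0("Comment: provenance=", e$provenance),
      sprintf("Num Peaks: %d", nrow(e$spectrum$peaks))
    ), con)
    if (nrow(e$spectrum$peaks))
      writeLines(sprintf("%.6f %.6f", e$spectrum$peaks[, "mz"],
                         e$spectrum$peaks[, "intensity"]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' aq_example()
#' aq_example("table1_features.csv")
#' @export
aq_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "aqscreen")))
  system.file("extdata", file, package = "aqscreen", mustWork = TRUE)
}
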