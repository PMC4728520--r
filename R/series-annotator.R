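#' Detect CH2 homologous series in a feature table
#'
#' Builds links between feature pairs whose m/z difference equals the
#' homologue unit `delta` within a ppm-scaled tolerance and whose retention
#' times differ by an amount inside `[rt_min_gap, rt_max_gap]` with the
#' heavier homologue eluting later (longer alkyl chains retain more on
#' reversed phase). Maximal link chains are assembled and scored; chains of
#' at least `min_length` features become series. Competing chains are ranked
#' by length, then by cumulative deviation of the mass spacing from `delta`,
#' then by the regularity (standard deviation) of their RT gaps, then by
#' member ids, so the result is deterministic and invariant to input order.
#' Features that share a member's m/z within `mz_tol_ppm` but are not on the
#' chain are attached to that member as isomer candidates, to be adjudicated
#' by [resolve_isomers()].
#'
#' @param features list of `aq_feature` objects.
#' @param delta homologue mass spacing in Da (default CH2, 14.0156500642).
#' @param mz_tol_ppm mass tolerance in ppm for spacing and isomer matching
#'   (default 5).
#' @param rt_min_gap,rt_max_gap allowed RT gap between consecutive members,
#'   minutes (defaults 0.2 and 1.5).
#' @param min_length minimum number of members for a series (default 3; two
#'   points cannot establish a regular interval).
#' @return A list of `aq_series` objects, each with `series_id`, `members`
#'   (data frame: `feature_id`, `rt`, `mz`, `member_index`) and `isomers`
#'   (data frame: `feature_id`, `rt`, `mz`, `member_index` of the matched
#'   member). Member indices are relative (lightest member = 0) until
#'   anchored with [anchor_series()].
#' @export
detect_series <- function(features, delta = mass_constants()$ch2,
                          mz_tol_ppm = 5, rt_min_gap = 0.2, rt_max_gap = 1.5,
                          min_length = 3L) {
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  if (!length(features)) return(list())
  df <- data.frame(
    feature_id = vapply(features, `[[`, "", "feature_id"),
    rt = vapply(features, `[[`, 0, "rt"),
    mz = vapply(features, `[[`, 0, "mz"),
    stringsAsFactors = FALSE
  )
  # canonical processing order, independent of input order
  df <- df[order(df$mz, df$rt, df$feature_id), , drop = FALSE]
  rownames(df) <- NULL
  remaining <- rep(TRUE, nrow(df))
  out <- list()
  sid <- 0L
  repeat {
    idx <- which(remaining)
    if (length(idx) < min_length) break
    chain <- .best_chain(df[idx, , drop = FALSE], delta, mz_tol_ppm,
                         rt_min_gap, rt_max_gap)
    if (length(chain) < min_length) break
    members <- df[idx[chain], , drop = FALSE]
    members$member_index <- seq_len(nrow(members)) - 1L
    rownames(members) <- NULL
    remaining[idx[chain]] <- FALSE
    # attach off-chain features sharing a member's m/z
    iso <- data.frame(feature_id = character(0), rt = numeric(0),
                      mz = numeric(0), member_index = integer(0),
                      status = character(0), stringsAsFactors = FALSE)
    for (k in which(remaining)) {
      dev <- abs(df$mz[k] - members$mz)
      hit <- which(dev <= mz_tol_ppm * 1e-6 * (df$mz[k] + members$mz))
      if (length(hit)) {
        hit <- hit[which.min(dev[hit])]
        iso <- rbind(iso, data.frame(
          feature_id = df$feature_id[k], rt = df$rt[k], mz = df$mz[k],
          member_index = members$member_index[hit],
          status = NA_character_, stringsAsFactors = FALSE))
        remaining[k] <- FALSE
      }
    }
    rownames(iso) <- NULL
    sid <- sid + 1L
    out[[sid]] <- structure(
      list(series_id = sprintf("S%d", sid), members = members, isomers = iso),
      class = "aq_series")
  }
  out
}

# best maximal chain in a feature frame; returns row indices along the chain
.best_chain <- function(df, delta, mz_tol_ppm, rt_min_gap, rt_max_gap,
                        max_paths = 20000L) {
  n <- nrow(df)
  succ <- vector("list", n)
  has_pred <- logical(n)
  for (i in seq_len(n)) {
    dmz <- df$mz - df$mz[i]
    drt <- df$rt - df$rt[i]
    # a difference of two measured masses carries both errors, so the
    # spacing tolerance is ppm-scaled by the sum of the masses
    ok <- which(abs(dmz - delta) <= mz_tol_ppm * 1e-6 * (df$mz + df$mz[i]) &
                  drt >= rt_min_gap & drt <= rt_max_gap)
    succ[[i]] <- ok
    has_pred[ok] <- TRUE
  }
  starts <- which(!has_pred & vapply(succ, length, 0L) > 0)
  if (!length(starts)) return(integer(0))
  paths <- list(); count <- 0L
  walk <- function(path) {
    if (count >= max_paths) return()
    nxt <- succ[[path[length(path)]]]
    if (!length(nxt)) {
      count <<- count + 1L
      paths[[count]] <<- path
      return()
    }
    for (j in nxt) walk(c(path, j))
  }
  for (s in starts) walk(s)
  if (!length(paths)) return(integer(0))
  score <- function(p) {
    if (length(p) < 2L) return(c(-length(p), 0, 0))
    gaps_mz <- abs(diff(df$mz[p]) - delta)
    gaps_rt <- diff(df$rt[p])
    c(-length(p), sum(gaps_mz),
      if (length(gaps_rt) > 1L) stats::sd(gaps_rt) else 0)
  }
  sc <- t(vapply(paths, score, numeric(3)))
  key <- vapply(paths, function(p) paste(df$feature_id[p], collapse = "|"), "")
  best <- order(sc[, 1], sc[, 2], sc[, 3], key)[1]
  paths[[best]]
}

#' @export
print.aq_series <- function(x, ...) {
  cat(sprintf("<aq_series> %s: %d canonical member(s), %d isomer candidate(s)\n",
              x$series_id, nrow(x$members), nrow(x$isomers)))
  invisible(x)
}

#' Anchor series member indices to alkyl chain length
#'
#' Pseudane nomenclature encodes the alkyl carbon count in a roman numeral
#' (pseudane-III has a C3 chain). When a canonical member's m/z matches a
#' library entry named `pseudane-<roman>` within `mz_tol_ppm`, the whole
#' series is shifted so that member indices equal the chain carbon count.
#' Without an anchor, indices stay relative (lightest member = 0) and the
#' series is flagged accordingly.
#'
#' @param series an `aq_series`.
#' @param library list of `aq_library_entry` objects.
#' @param mz_tol_ppm precursor matching tolerance (default 5).
#' @return The series with adjusted `member_index` columns and an `anchored`
#'   logical element.
#' @export
anchor_series <- function(series, library, mz_tol_ppm = 5) {
  stopifnot(inherits(series, "aq_series"))
  series$anchored <- FALSE
  for (e in library) {
    m <- regmatches(e$name, regexpr("(?i)pseudane[-_ ]([IVXLCDM]+)$", e$name, perl = TRUE))
    if (!length(m)) next
    n <- suppressWarnings(as.integer(utils::as.roman(sub("(?i)pseudane[-_ ]", "", m, perl = TRUE))))
    if (is.na(n)) next
    ppm <- abs(ppm_error(series$members$mz, e$theoretical_mz))
    hit <- which(ppm <= mz_tol_ppm)
    if (length(hit)) {
      shift <- n - series$members$member_index[hit[1]]
      series$members$member_index <- series$members$member_index + shift
      if (nrow(series$isomers))
        series$isomers$member_index <- series$isomers$member_index + shift
      series$anchored <- TRUE
      break
    }
  }
  series
}

#' Fit the retention-time trend of a homologous series
#'
#' Ordinary least squares of canonical members' retention time on member
#' index. On reversed-phase LC, each added CH2 increases retention by a
#' near-constant increment, so the trend is linear and its residuals
#' adjudicate which of several same-mass peaks is the series member.
#'
#' @param series an `aq_series` with at least 3 canonical members.
#' @return A list with `slope` (min per CH2), `intercept` (min),
#'   `residuals`, `fitted`, and the underlying `lm` fit.
#' @export
fit_rt_trend <- function(series) {
  stopifnot(inherits(series, "aq_series"))
  m <- series$members
  if (nrow(m) < 3L)
    stop("need at least 3 canonical members to fit an RT trend", call. = FALSE)
  fit <- stats::lm(rt ~ member_index, data = m)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = unname(stats::resid(fit)),
       fitted = unname(stats::fitted(fit)),
       fit = fit)
}

#' Resolve same-mass isomers within a homologous series
#'
#' For each group of features sharing a member's m/z (the canonical member
#' plus its attached isomer candidates), the feature whose RT lies closest
#' to the fitted RT-trend prediction becomes (or stays) the canonical
#' member; the others remain isomer candidates. A demoted feature is
#' labelled a same-scaffold isomer when its MS/MS spectrum carries the
#' diagnostic fragment and scores at least `isomer_min_score` against the
#' canonical member's spectrum — otherwise its status is `"unknown"` (a
#' mass duplicate without fragmentation evidence).
#'
#' To keep the adjudication honest when the detected chain may itself have
#' picked up an off-trend isomer, the trend used here is refitted on the
#' uncontested members only (those with no attached mass duplicate),
#' provided at least three remain; otherwise the full-series fit is used.
#'
#' @param series an `aq_series` with at least 3 canonical members.
#' @param features the feature list the series was detected in (used to look
#'   up MS/MS spectra by feature id).
#' @param rt_tol minimum RT separation, minutes, for two same-mass features
#'   to count as distinct isomers rather than a split peak (default 0.05).
#' @param frag_tol fragment tolerance in Da (default 0.35).
#' @param isomer_min_score minimum cosine between isomer and canonical
#'   spectra (default 0.6).
#' @param diagnostic_mz diagnostic fragment m/z (default 159, the
#'   alkyl-loss quinolone scaffold ion).
#' @return The series, with possibly swapped canonical members and an
#'   `isomers` data frame gaining a `status` column
#'   (`"isomer_candidate"` or `"unknown"`).
#' @export
resolve_isomers <- function(series, features, rt_tol = 0.05, frag_tol = 0.35,
                            isomer_min_score = 0.6, diagnostic_mz = 159) {
  stopifnot(inherits(series, "aq_series"))
  spectra <- stats::setNames(lapply(features, `[[`, "spectrum"),
                             vapply(features, `[[`, "", "feature_id"))
  iso <- series$isomers
  if (!nrow(iso)) return(series)
  clean <- series$members[!series$members$member_index %in% iso$member_index, ,
                          drop = FALSE]
  base <- if (nrow(clean) >= 3L) clean else series$members
  fit <- stats::lm(rt ~ member_index, data = base)
  trend <- list(intercept = unname(stats::coef(fit)[1]),
                slope = unname(stats::coef(fit)[2]))
  for (mi in unique(iso$member_index)) {
    mrow <- which(series$members$member_index == mi)
    irows <- which(iso$member_index == mi)
    group <- rbind(
      data.frame(feature_id = series$members$feature_id[mrow],
                 rt = series$members$rt[mrow], mz = series$members$mz[mrow],
                 stringsAsFactors = FALSE),
      data.frame(feature_id = iso$feature_id[irows], rt = iso$rt[irows],
                 mz = iso$mz[irows], stringsAsFactors = FALSE))
    pred <- trend$intercept + trend$slope * mi
    win <- which.min(abs(group$rt - pred))
    if (win != 1L) {
      # swap: the attached candidate fits the trend better than the member
      series$members[mrow, c("feature_id", "rt", "mz")] <- group[win, ]
      iso[irows[win - 1L], c("feature_id", "rt", "mz")] <- group[1L, ]
    }
    canon_sp <- spectra[[series$members$feature_id[mrow]]]
    for (r in irows) {
      sp <- spectra[[iso$feature_id[r]]]
      distinct <- abs(iso$rt[r] - series$members$rt[mrow]) > rt_tol
      has_diag <- !is.null(sp) && nrow(sp$peaks) > 0 &&
        any(abs(sp$peaks[, "mz"] - diagnostic_mz) <= frag_tol)
      sim <- if (!is.null(sp) && !is.null(canon_sp))
        cosine_similarity(sp, canon_sp, frag_tol)$score else 0
      iso$status[r] <- if (distinct && has_diag && sim >= isomer_min_score)
        "isomer_candidate" else "unknown"
    }
  }
  series$isomers <- iso
  series
}

#' Classify features into annotation classes
#'
#' Applies the evidence hierarchy to every feature and emits one annotation
#' record per feature. Classes, by the first matching rule:
#' \enumerate{
#'   \item `identified_standard` — the feature is not an isomer candidate and
#'     its best library hit at or above `min_score` comes from a commercial
#'     standard (identity confirmed against a purchased reference; a
#'     same-mass peak displaced from the series RT trend is never confirmed
#'     by a standard measured at the canonical RT, which is what demotes it
#'     to rule 3).
#'   \item `putative_homolog` — a canonical series member with at least one
#'     molecular-formula candidate and the diagnostic fragment in its MS/MS
#'     spectrum.
#'   \item `isomer_candidate` — flagged by [resolve_isomers()]: same formula
#'     as a canonical member, RT off the trend, shared scaffold
#'     fragmentation.
#'   \item `unknown` — everything else (decoys, mass duplicates without
#'     MS/MS evidence).
#' }
#'
#' @param features list of `aq_feature` objects.
#' @param formula_candidates named list (by feature id) of candidate frames
#'   from [enumerate_formulas()]; may be `NULL`.
#' @param library_hits named list (by feature id) of hit frames from
#'   [match_library()]; may be `NULL`.
#' @param series list of resolved `aq_series` objects; may be empty.
#' @param min_score minimum library score backing an identification
#'   (default 0.7).
#' @param diagnostic_mz,frag_tol diagnostic-fragment test (defaults 159,
#'   0.35 Da).
#' @return A data frame of class `aq_annotation`: `feature_id`, `rt_min`,
#'   `mz`, `class`, `best_formula`, `ppm`, `best_library_hit`, `score`,
#'   `series_id`, `member_index`, `evidence`.
#' @export
classify_features <- function(features, formula_candidates = NULL,
                              library_hits = NULL, series = list(),
                              min_score = 0.7, diagnostic_mz = 159,
                              frag_tol = 0.35) {
  canon <- .rbind_all(lapply(series, function(s)
    cbind(s$members, series_id = s$series_id, role = "canonical",
          status = NA_character_, stringsAsFactors = FALSE)))
  iso <- .rbind_all(lapply(series, function(s)
    if (nrow(s$isomers)) cbind(s$isomers, series_id = s$series_id,
                               role = "isomer", stringsAsFactors = FALSE)))
  rows <- lapply(features, function(f) {
    id <- f$feature_id
    cand <- formula_candidates[[id]]
    hits <- library_hits[[id]]
    best_cand <- if (!is.null(cand) && nrow(cand)) cand[1, ] else NULL
    best_hit <- if (!is.null(hits) && nrow(hits)) hits[1, ] else NULL
    in_canon <- !is.null(canon) && id %in% canon$feature_id
    in_iso <- !is.null(iso) && id %in% iso$feature_id
    iso_row <- if (in_iso) iso[iso$feature_id == id, ][1, ] else NULL
    is_isomer <- in_iso && identical(iso_row$status, "isomer_candidate")
    has_diag <- !is.null(f$spectrum) && nrow(f$spectrum$peaks) > 0 &&
      any(abs(f$spectrum$peaks[, "mz"] - diagnostic_mz) <= frag_tol)
    std_hit <- if (!is.null(hits) && nrow(hits)) {
      h <- hits[hits$provenance == "commercial_standard" & hits$score >= min_score, ]
      if (nrow(h)) h[1, ] else NULL
    } else NULL
    evidence <- character(0)
    if (!is.null(best_cand))
      evidence <- c(evidence, sprintf("formula %s (%+.3f ppm, RDBE %.1f)",
                                      best_cand$formula, best_cand$ppm_error,
                                      best_cand$rdbe))
    if (!is.null(best_hit))
      evidence <- c(evidence, sprintf("library hit %s (score %.3f, %s)",
                                      best_hit$name, best_hit$score,
                                      best_hit$provenance))
    if (has_diag)
      evidence <- c(evidence, sprintf("diagnostic fragment m/z %g present", diagnostic_mz))
    sinfo <- if (in_canon) {
      r <- canon[canon$feature_id == id, ][1, ]
      evidence <- c(evidence, sprintf("canonical member %d of series %s",
                                      r$member_index, r$series_id))
      r
    } else if (in_iso) {
      evidence <- c(evidence, sprintf("mass duplicate of member %d of series %s (%s)",
                                      iso_row$member_index, iso_row$series_id,
                                      iso_row$status))
      iso_row
    } else NULL
    cls <- if (!is_isomer && !is.null(std_hit)) {
      "identified_standard"
    } else if (in_canon && !is.null(best_cand) && has_diag) {
      "putative_homolog"
    } else if (is_isomer) {
      "isomer_candidate"
    } else {
      "unknown"
    }
    data.frame(
      feature_id = id, rt_min = f$rt, mz = f$mz, class = cls,
      best_formula = if (!is.null(best_cand)) best_cand$formula else NA_character_,
      ppm = if (!is.null(best_cand)) best_cand$ppm_error else NA_real_,
      best_library_hit = if (!is.null(best_hit)) best_hit$name else NA_character_,
      score = if (!is.null(best_hit)) best_hit$score else NA_real_,
      series_id = if (!is.null(sinfo)) sinfo$series_id else NA_character_,
      member_index = if (!is.null(sinfo)) sinfo$member_index else NA_integer_,
      evidence = paste(evidence, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- .rbind_all(rows)
  class(out) <- c("aq_annotation", "data.frame")
  out
}

.rbind_all <- function(rows) {
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.aq_annotation <- function(x, ...) {
  cat(sprintf("<aq_annotation> %d feature(s)\n", nrow(x)))
  tab <- table(factor(x$class, levels = c("identified_standard",
                                          "putative_homolog",
                                          "isomer_candidate", "unknown")))
  for (k in names(tab)) cat(sprintf("  %-20s %d\n", k, tab[[k]]))
  invisible(x)
}

#' @export
summary.aq_annotation <- function(object, ...) {
  as.list(table(factor(object$class,
                       levels = c("identified_standard", "putative_homolog",
                                  "isomer_candidate", "unknown"))))
}
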