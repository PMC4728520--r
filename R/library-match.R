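#' Cosine similarity between two MS/MS spectra
#'
#' Peaks of the two spectra are paired greedily one-to-one within a fragment
#' tolerance: candidate pairs are taken in descending order of the product of
#' their square-root-scaled intensities (ties broken by lower fragment m/z),
#' and each peak is used at most once. The score is the sum of matched
#' products divided by the product of the spectra's scaled Euclidean norms,
#' so it lies in [0, 1], is symmetric, and is invariant to uniform intensity
#' scaling of either spectrum. For uniform-intensity nominal spectra with
#' `n` and `m` peaks of which `k` match, the score reduces to
#' `k / sqrt(n * m)`.
#'
#' @param a,b `aq_spectrum` objects.
#' @param frag_tol fragment m/z tolerance in Da (default 0.35, suited to
#'   nominal ion-trap fragments).
#' @return A list with `score` in [0, 1] and `matched_peaks` (count). Empty
#'   spectra give score 0.
#' @examples
#' s1 <- spectrum(216.1382, c(132, 146, 159, 172, 186, 200, 216))
#' s2 <- spectrum(216.1382, c(132, 146, 159, 172, 186, 197, 216))
#' cosine_similarity(s1, s2)$score  # 6/7
#' @export
cosine_similarity <- function(a, b, frag_tol = 0.35) {
  stopifnot(inherits(a, "aq_spectrum"), inherits(b, "aq_spectrum"))
  if (frag_tol <= 0) stop("frag_tol must be positive", call. = FALSE)
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  if (na == 0L || nb == 0L) return(list(score = 0, matched_peaks = 0L))
  wa <- sqrt(a$peaks[, "intensity"]); wb <- sqrt(b$peaks[, "intensity"])
  # candidate pairs within tolerance
  dm <- abs(outer(a$peaks[, "mz"], b$peaks[, "mz"], "-"))
  idx <- which(dm <= frag_tol, arr.ind = TRUE)
  if (!nrow(idx)) return(list(score = 0, matched_peaks = 0L))
  prod <- wa[idx[, 1]] * wb[idx[, 2]]
  ord <- order(-prod, a$peaks[idx[, 1], "mz"], b$peaks[idx[, 2], "mz"])
  idx <- idx[ord, , drop = FALSE]; prod <- prod[ord]
  useda <- logical(na); usedb <- logical(nb)
  total <- 0; k <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (useda[i] || usedb[j]) next
    useda[i] <- TRUE; usedb[j] <- TRUE
    total <- total + prod[r]; k <- k + 1L
  }
  denom <- sqrt(sum(wa^2)) * sqrt(sum(wb^2))
  score <- if (denom > 0) total / denom else 0
  list(score = min(score, 1), matched_peaks = k)
}

#' Search a spectral library for a query spectrum
#'
#' Library entries are pre-filtered on precursor mass (absolute ppm error of
#' the query precursor against the entry's theoretical m/z), scored with
#' [cosine_similarity()], filtered on a minimum score, and returned sorted
#' by descending score, ties by smaller absolute precursor ppm, then by
#' entry name — the ordering is total, so results do not depend on library
#' order.
#'
#' @param query an `aq_spectrum`.
#' @param library list of `aq_library_entry` objects.
#' @param precursor_tol_ppm precursor tolerance in ppm (default 5).
#' @param frag_tol fragment tolerance in Da (default 0.35).
#' @param min_score minimum cosine score to report (default 0.7).
#' @return A data frame of hits: `name`, `score`, `matched_peaks`,
#'   `precursor_ppm`, `provenance` (zero rows if none).
#' @export
match_library <- function(query, library, precursor_tol_ppm = 5,
                          frag_tol = 0.35, min_score = 0.7) {
  stopifnot(inherits(query, "aq_spectrum"))
  if (precursor_tol_ppm <= 0) stop("precursor_tol_ppm must be positive", call. = FALSE)
  empty <- data.frame(name = character(0), score = numeric(0),
                      matched_peaks = integer(0), precursor_ppm = numeric(0),
                      provenance = character(0), stringsAsFactors = FALSE)
  if (!length(library)) return(empty)
  rows <- lapply(library, function(e) {
    ppm <- ppm_error(query$precursor_mz, e$theoretical_mz)
    if (abs(ppm) > precursor_tol_ppm) return(NULL)
    cs <- cosine_similarity(query, e$spectrum, frag_tol)
    if (cs$score < min_score) return(NULL)
    data.frame(name = e$name, score = cs$score,
               matched_peaks = cs$matched_peaks, precursor_ppm = ppm,
               provenance = e$provenance, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, abs(out$precursor_ppm), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragments common to a set of spectra
#'
#' Pools fragment m/z values across spectra and clusters them by
#' single-linkage within `frag_tol`; each spectrum contributes at most once
#' to a cluster. Clusters present in at least `min_presence` of the spectra
#' are returned sorted by m/z (cluster center = median of member m/z).
#' Applied to a compound class, the highest full-presence cluster is the
#' class's diagnostic fragment (m/z 159 for 2-alkylquinolin-4-ones, the
#' quinolone scaffold after alkyl-chain loss).
#'
#' @param spectra non-empty list of `aq_spectrum` objects.
#' @param frag_tol clustering tolerance in Da (default 0.5 for nominal mass).
#' @param min_presence minimum fraction of spectra containing the fragment,
#'   in (0, 1] (default 1 = present in all).
#' @return A data frame with `fragment_mz` (cluster median) and
#'   `presence_fraction`, sorted ascending by m/z.
#' @examples
#' sp <- read_mgf(aq_example("table1_spectra.mgf"))
#' common_fragments(sp)  # m/z 146 and 159 occur in all 11 spectra
#' @export
common_fragments <- function(spectra, frag_tol = 0.5, min_presence = 1) {
  if (!length(spectra)) stop("need at least one spectrum", call. = FALSE)
  if (min_presence <= 0 || min_presence > 1)
    stop("min_presence must be in (0, 1]", call. = FALSE)
  mz <- unlist(lapply(spectra, function(s) s$peaks[, "mz"]))
  src <- rep(seq_along(spectra), vapply(spectra, n_peaks, 0L))
  if (!length(mz))
    return(data.frame(fragment_mz = numeric(0), presence_fraction = numeric(0)))
  ord <- order(mz)
  mz <- mz[ord]; src <- src[ord]
  cluster <- cumsum(c(1, diff(mz) > frag_tol))
  centers <- tapply(mz, cluster, stats::median)
  presence <- tapply(src, cluster, function(s) length(unique(s))) / length(spectra)
  keep <- presence >= min_presence
  data.frame(fragment_mz = as.numeric(centers[keep]),
             presence_fraction = as.numeric(presence[keep]),
             row.names = NULL)
}
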