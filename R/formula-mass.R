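#' Monoisotopic mass constants
#'
#' IUPAC/CODATA monoisotopic atomic masses for the CHNOS element set used
#' throughout the package, plus the proton and electron masses and the mass
#' of a CH2 homologue unit. All values in Da.
#'
#' @return A named list with components `elements` (named numeric vector of
#'   monoisotopic masses for C, H, N, O, S), `proton` (mass of H+),
#'   `electron`, and `ch2` (the CH2 repeat unit, 14.0156500642 Da).
#' @examples
#' mc <- mass_constants()
#' mc$elements[["C"]]
#' # proton = H atom minus one electron
#' mc$elements[["H"]] - mc$electron - mc$proton
#' @export
mass_constants <- function() {
  list(
    elements = c(
      C = 12,
      H = 1.00782503207,
      N = 14.0030740048,
      O = 15.9949146196,
      S = 31.97207100
    ),
    proton   = 1.00727646688,
    electron = 0.00054857991,
    ch2      = 14.0156500642
  )
}

#' Round half away from zero
#'
#' Display rounding used for printed m/z values (so that e.g. x.xxxx5 rounds
#' up in magnitude rather than to even as [base::round()] does).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_away <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a molecular formula
#'
#' @param counts named integer vector of element counts (names are element
#'   symbols in the CHNOS set); zero counts are dropped.
#' @param charge_state `"neutral"` for a neutral molecule or
#'   `"protonated_ion"` for an \eqn{[M+H]^+} composition that already
#'   includes the ionizing proton's hydrogen.
#' @return An object of class `aq_formula`.
#' @examples
#' f <- formula_counts(c(C = 12, H = 14, O = 1, N = 1), "protonated_ion")
#' format(f)
#' @export
formula_counts <- function(counts, charge_state = c("neutral", "protonated_ion")) {
  charge_state <- match.arg(charge_state)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("formula counts must be a named vector", call. = FALSE)
  known <- names(mass_constants()$elements)
  bad <- setdiff(names(counts), known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- counts[counts != 0]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers", call. = FALSE)
  if (!length(counts))
    stop("formula must contain at least one atom", call. = FALSE)
  # canonical storage order: Hill (C, H, then alphabetical)
  counts <- counts[order(match(names(counts), c("C", "H", sort(setdiff(known, c("C", "H"))))))]
  structure(list(counts = counts, charge_state = charge_state), class = "aq_formula")
}

#' Parse a molecular formula string
#'
#' Accepts both Hill-style strings (`"C14H17NO"`) and the compact dialect in
#' which an implicit count of one precedes another symbol (`"C12H14ON"`).
#' Repeated element symbols accumulate.
#'
#' @param text formula string made of (element symbol, optional count) tokens.
#' @param charge_state see [formula_counts()].
#' @return An `aq_formula` object.
#' @examples
#' parse_formula("C12H14ON", "protonated_ion")
#' parse_formula("C2C3")   # counts accumulate to C5
#' @export
parse_formula <- function(text, charge_state = c("neutral", "protonated_ion")) {
  charge_state <- match.arg(charge_state)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty or non-string formula", call. = FALSE)
  text <- gsub("[_ ]", "", text)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || !length(tokens))
    stop("cannot parse formula string: '", text, "'", call. = FALSE)
  known <- names(mass_constants()$elements)
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    if (!sym %in% known)
      stop("unknown element symbol '", sym, "' in formula '", text, "'", call. = FALSE)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  formula_counts(counts, charge_state)
}

#' @rdname parse_formula
#' @param x an `aq_formula` object.
#' @param ... unused.
#' @export
format.aq_formula <- function(x, ...) {
  paste0(names(x$counts), ifelse(x$counts == 1L, "", x$counts), collapse = "")
}

#' @export
print.aq_formula <- function(x, ...) {
  cat(format(x), if (x$charge_state == "protonated_ion") "[M+H]+ ion" else "(neutral)", "\n")
  invisible(x)
}

#' @export
`==.aq_formula` <- function(e1, e2) {
  identical(format(e1), format(e2)) && identical(e1$charge_state, e2$charge_state)
}

#' Neutral monoisotopic mass of a composition
#'
#' @param f an `aq_formula` object.
#' @return Sum of element monoisotopic masses in Da (no charge correction).
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "aq_formula"))
  el <- mass_constants()$elements
  sum(el[names(f$counts)] * f$counts)
}

#' Theoretical m/z of the protonated molecular ion
#'
#' For a `protonated_ion` composition (which already contains the extra
#' hydrogen of \eqn{[M+H]^+}) the electron mass is subtracted from the sum of
#' atomic masses; for a `neutral` composition a proton mass is added. The two
#' conventions agree to better than 1e-9 Da for corresponding compositions,
#' and the electron correction is what makes sub-ppm mass errors attainable
#' on Orbitrap-class data.
#'
#' @param f an `aq_formula` object.
#' @return m/z of the singly protonated ion in Da.
#' @examples
#' ion_mz(parse_formula("C12H14ON", "protonated_ion"))  # 188.1070 at 4 dp
#' @export
ion_mz <- function(f) {
  stopifnot(inherits(f, "aq_formula"))
  mc <- mass_constants()
  if (f$charge_state == "protonated_ion") {
    monoisotopic_mass(f) - mc$electron
  } else {
    monoisotopic_mass(f) + mc$proton
  }
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values in Da; `theoretical_mz` must
#'   be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0))
    stop("theoretical_mz must be positive", call. = FALSE)
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE for a CHNOS composition, `C - H/2 + N/2 + 1`, computed on the neutral
#' molecule. Protonated-ion compositions first have the ionizing hydrogen
#' removed, so an \eqn{[M+H]^+} formula gives the RDBE of its neutral parent.
#' The 2-alkylquinolin-4(1H)-one scaffold has RDBE 7.
#'
#' @param f an `aq_formula` object.
#' @return A (half-)integer RDBE value.
#' @export
rdbe <- function(f) {
  stopifnot(inherits(f, "aq_formula"))
  n <- function(sym) if (sym %in% names(f$counts)) f$counts[[sym]] else 0L
  h <- n("H") - if (f$charge_state == "protonated_ion") 1L else 0L
  n("C") - h / 2 + n("N") / 2 + 1
}

# lattice of candidate ion compositions, cached per bounds vector
.aq_cache <- new.env(parent = emptyenv())

.formula_lattice <- function(bounds) {
  key <- paste(names(bounds), bounds, sep = "", collapse = "_")
  if (!is.null(.aq_cache[[key]])) return(.aq_cache[[key]])
  grid <- expand.grid(lapply(bounds, function(b) 0:b), KEEP.OUT.ATTRS = FALSE)
  el <- mass_constants()$elements
  mz <- as.numeric(as.matrix(grid) %*% el[names(bounds)]) - mass_constants()$electron
  lat <- list(grid = grid, mz = mz)
  .aq_cache[[key]] <- lat
  lat
}

#' Default element bounds for formula enumeration
#' @return Named integer vector of per-element maximum counts.
#' @export
default_element_bounds <- function() {
  c(C = 30L, H = 60L, N = 3L, O = 5L, S = 1L)
}

#' Enumerate molecular formulas matching an accurate mass
#'
#' Exhaustively scans the bounded CHNOS composition lattice for
#' \eqn{[M+H]^+} ion formulas whose electron-corrected theoretical m/z lies
#' within `tol_ppm` of the observed value, then filters on RDBE (computed on
#' the neutral parent) and optionally the nitrogen rule. Candidates are
#' sorted by increasing absolute ppm error; ties are broken by fewer
#' heteroatoms, then by the formula string, so the output is deterministic.
#'
#' @param observed_mz observed \eqn{[M+H]^+} m/z in Da.
#' @param tol_ppm mass tolerance in ppm (default 5).
#' @param bounds named vector of per-element maximum counts
#'   (default [default_element_bounds()]).
#' @param rdbe_min,rdbe_max RDBE window applied to the neutral parent
#'   (defaults 0 and 20).
#' @param nitrogen_rule if `TRUE`, require the nominal mass parity implied by
#'   the nitrogen count of the neutral molecule (off by default; the ions
#'   considered are even-electron).
#' @return A data frame with one row per candidate: `formula` (ion formula
#'   string), `theoretical_mz`, `ppm_error`, `rdbe`, ordered best first.
#'   Zero rows when nothing matches.
#' @examples
#' head(enumerate_formulas(216.1382), 3)  # C14H18ON ranks first
#' @export
enumerate_formulas <- function(observed_mz, tol_ppm = 5,
                               bounds = default_element_bounds(),
                               rdbe_min = 0, rdbe_max = 20,
                               nitrogen_rule = FALSE) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive", call. = FALSE)
  if (observed_mz <= 0) stop("observed_mz must be positive", call. = FALSE)
  lat <- .formula_lattice(bounds)
  tol_da <- tol_ppm * 1e-6 * observed_mz
  hit <- which(abs(lat$mz - observed_mz) <= tol_da)
  if (!length(hit)) return(.empty_candidates())
  g <- lat$grid[hit, , drop = FALSE]
  mz <- lat$mz[hit]
  # RDBE of the neutral parent (one H removed from the ion composition)
  cC <- if ("C" %in% names(g)) g$C else 0L
  cH <- if ("H" %in% names(g)) g$H else 0L
  cN <- if ("N" %in% names(g)) g$N else 0L
  r <- cC - (cH - 1L) / 2 + cN / 2 + 1
  keep <- cH >= 1L & r >= rdbe_min & r <= rdbe_max & rowSums(g) > 0
  if (nitrogen_rule) {
    nominal <- round(mz)
    keep <- keep & ((nominal %% 2 == 1) == (cN %% 2 == 0))
  }
  if (!any(keep)) return(.empty_candidates())
  g <- g[keep, , drop = FALSE]; mz <- mz[keep]; r <- r[keep]
  fstr <- apply(g, 1L, function(cnt) {
    cnt <- cnt[cnt > 0]
    paste0(names(cnt), ifelse(cnt == 1, "", cnt), collapse = "")
  })
  ppm <- ppm_error(observed_mz, mz)
  hetero <- rowSums(g[, setdiff(names(g), c("C", "H")), drop = FALSE])
  ord <- order(abs(ppm), hetero, fstr)
  data.frame(
    formula = fstr[ord],
    theoretical_mz = mz[ord],
    ppm_error = ppm[ord],
    rdbe = r[ord],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

.empty_candidates <- function() {
  data.frame(formula = character(0), theoretical_mz = numeric(0),
             ppm_error = numeric(0), rdbe = numeric(0),
             stringsAsFactors = FALSE)
}
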