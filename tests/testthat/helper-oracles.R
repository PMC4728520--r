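# independent brute-force formula enumerator: explicit loops over the
# composition lattice, masses rebuilt from first principles, its own sort.
# kept deliberately separate from the package's vectorised lattice scan.
oracle_enumerate <- function(observed_mz, tol_ppm, bounds,
                             rdbe_min = 0, rdbe_max = 20) {
  mC <- 12; mH <- 1.00782503207; mN <- 14.0030740048
  mO <- 15.9949146196; mS <- 31.97207100; me <- 0.00054857991
  tol_da <- tol_ppm * 1e-6 * observed_mz
  hvec <- 1:bounds[["H"]]  # ion must contain the proton's hydrogen
  rows <- list()
  for (cC in 0:bounds[["C"]]) for (cN in 0:bounds[["N"]])
    for (cO in 0:bounds[["O"]]) for (cS in 0:bounds[["S"]]) {
      mz <- cC * mC + hvec * mH + cN * mN + cO * mO + cS * mS - me
      ok <- which(abs(mz - observed_mz) <= tol_da)
      for (k in ok) {
        h <- hvec[k]
        r <- cC - (h - 1) / 2 + cN / 2 + 1
        if (r < rdbe_min || r > rdbe_max) next
        cnt <- c(C = cC, H = h, N = cN, O = cO, S = cS)
        cnt <- cnt[cnt > 0]
        rows[[length(rows) + 1L]] <- data.frame(
          formula = paste0(names(cnt), ifelse(cnt == 1, "", cnt), collapse = ""),
          theoretical_mz = mz[k],
          ppm_error = (observed_mz - mz[k]) / mz[k] * 1e6,
          hetero = cN + cO + cS,
          rdbe = r, stringsAsFactors = FALSE)
      }
    }
  if (!length(rows))
    return(data.frame(formula = character(0), theoretical_mz = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$ppm_error), out$hetero, out$formula), , drop = FALSE]
  rownames(out) <- NULL
  out
}
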