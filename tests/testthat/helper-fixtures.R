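# shared loaders and small builders for the test suite

fixture_spectra <- function() read_mgf(aq_example("table1_spectra.mgf"))

fixture_features <- function() {
  read_feature_table(aq_example("table1_features.csv"),
                     spectra = fixture_spectra())
}

fixture_library <- function() read_msp(aq_example("pseudane_library.msp"))

quiet_config <- function(...) pipeline_config(log_level = "quiet", ...)

# random nominal-mass spectrum for property tests
random_spectrum <- function(n_peaks = NULL, precursor = NULL) {
  if (is.null(precursor)) precursor <- runif(1, 150, 500)
  if (is.null(n_peaks)) n_peaks <- sample(1:12, 1)
  mz <- sort(sample(seq(50, floor(precursor)), n_peaks))
  spectrum(precursor, mz, runif(n_peaks, 1, 1000))
}

# printed Table 1 values used across tests
table1_printed <- function() {
  data.frame(
    rt = c(4.56, 5.32, 5.99, 6.09, 6.71, 6.83, 7.55, 8.29, 9.00, 9.67, 10.33),
    mz = c(188.1070, 202.1227, 216.1382, 216.1382, 230.1539, 230.1539,
           244.1695, 258.1851, 272.2007, 286.2164, 300.2322),
    ion_formula = c("C12H14ON", "C13H16ON", "C14H18ON", "C14H18ON",
                    "C15H20ON", "C15H20ON", "C16H22ON", "C17H24ON",
                    "C18H26ON", "C19H28ON", "C20H30ON"),
    stringsAsFactors = FALSE
  )
}
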