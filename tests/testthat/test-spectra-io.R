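test_that("spectrum construction normalises and validates peaks", {
  s <- spectrum(216.1382, c(200, 132, 159), c(10, 30, 20))
  expect_equal(s$peaks[, "mz"], c(132, 159, 200))
  expect_equal(s$peaks[, "intensity"], c(30, 20, 10))
  expect_error(spectrum(100, c(50, 102)), "precursor")
  expect_error(spectrum(100, -5), "positive")
  expect_identical(nrow(spectrum(100)$peaks), 0L)
})

test_that("the packaged feature fixture transcribes all 11 screened peaks", {
  feats <- fixture_features()
  expect_length(feats, 11L)
  printed <- table1_printed()
  expect_equal(vapply(feats, `[[`, 0, "rt"), printed$rt, ignore_attr = TRUE)
  expect_equal(vapply(feats, `[[`, 0, "mz"), printed$mz, ignore_attr = TRUE)
  # every feature carries its MS/MS spectrum, precursor consistent to 1e-4
  for (f in feats) {
    expect_s3_class(f$spectrum, "aq_spectrum")
    expect_equal(f$spectrum$precursor_mz, f$mz, tolerance = 1e-4)
  }
})

test_that("fixture fragment lists match the printed MS/MS fragment ions", {
  sp <- fixture_spectra()
  expect_length(sp, 11L)
  expect_equal(sp[["M2_01"]]$peaks[, "mz"], c(132, 146, 159, 170, 188))
  expect_equal(sp[["M2_04"]]$peaks[, "mz"], c(132, 146, 159, 172, 186, 197, 216))
  expect_equal(sp[["M2_11"]]$peaks[, "mz"], c(146, 159, 172, 186, 200, 214, 300))
  # both 230.1539 peaks print identical ladders
  expect_equal(sp[["M2_05"]]$peaks, sp[["M2_06"]]$peaks)
})

test_that("feature tables round-trip and report malformed input precisely", {
  feats <- fixture_features()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, tmp)
  back <- read_feature_table(tmp)
  expect_equal(vapply(back, `[[`, 0, "mz"), vapply(feats, `[[`, 0, "mz"))
  expect_equal(vapply(back, `[[`, "", "feature_id"),
               vapply(feats, `[[`, "", "feature_id"))

  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("feature_id,rt_min,mz,intensity", hdr)
  expect_length(read_feature_table(hdr), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rt_min,mz,intensity", "1.0,200.1,5", "2.0,oops,5"), bad)
  expect_error(read_feature_table(bad), "line 3.*oops")

  noc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rt_min,intensity", "1.0,5"), noc)
  expect_error(read_feature_table(noc), "mz")
})

test_that("MGF round-trips with RT unit conversion and sorted peaks", {
  sp <- list(a = spectrum(250.5, c(120, 80.25, 199), c(5, 50, 12), rt = 3.21),
             b = spectrum(180, numeric(0)))
  tmp <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, tmp)
  back <- read_mgf(tmp)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$peaks, sp$a$peaks, tolerance = 1e-6)
  expect_equal(back$a$rt, 3.21, tolerance = 1e-6)
  expect_identical(nrow(back$b$peaks), 0L)

  trunc <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "50 1"), trunc)
  expect_error(read_mgf(trunc), "unterminated")
})

test_that("MSP libraries round-trip and enforce their invariants", {
  lib <- fixture_library()
  expect_length(lib, 9L)
  std <- vapply(lib, `[[`, "", "provenance") == "commercial_standard"
  expect_identical(sort(vapply(lib[std], `[[`, "", "name")),
                   c("Pseudane-IV", "Pseudane-VI", "Pseudane-VIII"))
  for (e in lib)
    expect_equal(e$theoretical_mz, ion_mz(e$ion_formula), tolerance = 1e-4)

  tmp <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, tmp)
  back <- read_msp(tmp)
  expect_equal(vapply(back, `[[`, "", "name"), vapply(lib, `[[`, "", "name"))
  expect_equal(back[[3]]$spectrum$peaks, lib[[3]]$spectrum$peaks, tolerance = 1e-6)
  expect_equal(vapply(back, `[[`, "", "provenance"),
               vapply(lib, `[[`, "", "provenance"))

  mism <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: x", "Formula: C12H14ON", "PrecursorMZ: 188.106990",
               "Num Peaks: 3", "100 1", "120 1", ""), mism)
  expect_error(read_msp(mism), "Num Peaks")

  off <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: x", "Formula: C12H14ON", "PrecursorMZ: 188.2",
               "Num Peaks: 1", "100 1", ""), off)
  expect_error(read_msp(off), "disagrees")
})

test_that("fuzzed writer output is always readable (round-trip property)", {
  set.seed(11)
  for (i in 1:10) {
    sp <- setNames(lapply(1:4, function(j) random_spectrum()),
                   paste0("s", 1:4))
    tmp <- withr::local_tempfile(fileext = ".mgf")
    write_mgf(sp, tmp)
    back <- read_mgf(tmp)
    expect_length(back, 4L)
    for (j in seq_along(sp))
      expect_equal(back[[j]]$peaks, sp[[j]]$peaks, tolerance = 1e-6)
  }
})
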