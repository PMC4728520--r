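annotated_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- annotate_features(fixture_features(), fixture_library(),
                                 quiet_config())
    memo
  }
})

test_that("the screened peak list yields one series: 9 homologs + 2 isomer twins", {
  series <- detect_series(fixture_features())
  expect_length(series, 1L)
  s <- series[[1]]
  expect_identical(nrow(s$members), 9L)
  expect_identical(nrow(s$isomers), 2L)
  # canonical RT strictly increasing with index, m/z spaced by CH2
  expect_true(all(diff(s$members$rt) > 0))
  expect_equal(diff(s$members$mz), rep(mass_constants()$ch2, 8), tolerance = 2e-4)
  # the twins sit at the novel compounds' printed RTs
  expect_setequal(s$isomers$rt, c(5.99, 6.71))
})

test_that("series detection is invariant to feature order and idempotent", {
  feats <- fixture_features()
  ref <- detect_series(feats)[[1]]
  set.seed(5)
  for (perm in list(rev(seq_along(feats)), sample(seq_along(feats)),
                    sample(seq_along(feats)))) {
    s <- detect_series(feats[perm])[[1]]
    expect_identical(s$members$feature_id, ref$members$feature_id)
    expect_identical(s$isomers$feature_id, ref$isomers$feature_id)
  }
  # rerunning on only the canonical members returns the same chain
  again <- detect_series(feats[ref$members$feature_id])[[1]]
  expect_identical(again$members$feature_id, ref$members$feature_id)
})

test_that("member indices anchor to the pseudane chain length via the library", {
  s <- anchor_series(detect_series(fixture_features())[[1]], fixture_library())
  expect_true(s$anchored)
  expect_identical(s$members$member_index, 3:11)
  # without a library the indices stay relative
  s0 <- detect_series(fixture_features())[[1]]
  expect_identical(s0$members$member_index, 0:8)
})

test_that("observed m/z regressed on chain length recovers the CH2 unit", {
  s <- anchor_series(detect_series(fixture_features())[[1]], fixture_library())
  slope <- unname(coef(lm(mz ~ member_index, data = s$members))[2])
  # within a ppm-scale band of the member masses (~230 Da * 1e-6)
  expect_lt(abs(slope - mass_constants()$ch2), 2.5e-4)
})

test_that("the RT trend is linear with ~0.7 min per CH2 on the screened series", {
  s <- anchor_series(detect_series(fixture_features())[[1]], fixture_library())
  tr <- fit_rt_trend(s)
  expect_gt(tr$slope, 0.6); expect_lt(tr$slope, 0.8)

  # perfectly linear synthetic RTs give zero residuals
  feats <- lapply(0:4, function(i)
    feature(paste0("f", i), rt = 2 + 0.7 * i, mz = 188.107 + i * mass_constants()$ch2))
  lin <- detect_series(feats)[[1]]
  expect_equal(fit_rt_trend(lin)$residuals, rep(0, 5), tolerance = 1e-9)

  two <- lin; two$members <- two$members[1:2, ]
  expect_error(fit_rt_trend(two), "at least 3")
})

test_that("isomer resolution keeps the trend-consistent peak canonical", {
  feats <- fixture_features()
  s <- anchor_series(detect_series(feats)[[1]], fixture_library())
  s <- resolve_isomers(s, feats)
  # pseudane-V (6.09) and pseudane-VI (6.83) stay canonical; the earlier
  # same-mass novel peaks (5.99, 6.71) are same-scaffold isomer candidates
  expect_true(all(c(6.09, 6.83) %in% s$members$rt))
  expect_setequal(s$isomers$rt, c(5.99, 6.71))
  expect_identical(s$isomers$status, rep("isomer_candidate", 2))

  # even if the chain initially picked the off-trend twins, resolution swaps
  swapped <- s
  swapped$members[swapped$members$member_index == 5, c("feature_id", "rt")] <-
    list("M2_03", 5.99)
  swapped$isomers[1, c("feature_id", "rt")] <- list("M2_04", 6.09)
  fixed <- resolve_isomers(swapped, feats)
  expect_identical(fixed$members$feature_id[fixed$members$member_index == 5], "M2_04")

  # a mass duplicate without MS/MS cannot be an isomer candidate
  blind <- feats
  blind[["M2_05"]]$spectrum <- NULL
  s2 <- resolve_isomers(anchor_series(detect_series(blind)[[1]], fixture_library()),
                        blind)
  expect_identical(s2$isomers$status[s2$isomers$feature_id == "M2_05"], "unknown")
})

test_that("classification reproduces the screening outcome: 3 + 6 + 2, none unknown", {
  ann <- annotated_fixture()
  counts <- summary(ann)
  expect_identical(counts$identified_standard, 3L)
  expect_identical(counts$putative_homolog, 6L)
  expect_identical(counts$isomer_candidate, 2L)
  expect_identical(counts$unknown, 0L)
  df <- as.data.frame(ann)
  expect_setequal(df$feature_id[df$class == "identified_standard"],
                  c("M2_02", "M2_06", "M2_08"))
  expect_setequal(df$feature_id[df$class == "isomer_candidate"],
                  c("M2_03", "M2_05"))
  # every identification is backed by a commercial-standard hit >= 0.99
  std <- df[df$class == "identified_standard", ]
  expect_true(all(std$score >= 0.99))
  # all quinolone calls carry an evidence trail
  expect_true(all(nzchar(df$evidence)))
})

test_that("classification rules degrade gracefully without upstream evidence", {
  feats <- fixture_features()
  # a decoy far from the series and library stays unknown
  decoy <- feature("decoy", rt = 3.1, mz = 401.9981, intensity = 5,
                   spectrum = spectrum(401.9981, c(91, 207), c(10, 10)))
  ann <- annotate_features(c(feats, list(decoy)), fixture_library(), quiet_config())
  expect_identical(as.data.frame(ann)$class[12], "unknown")

  # series membership outranks a failed library match: empty library means
  # no identified standards, but homologs are still called from the series
  ann2 <- annotate_features(feats, list(), quiet_config())
  counts <- summary(ann2)
  expect_identical(counts$identified_standard, 0L)
  expect_gte(counts$putative_homolog, 9L)
})
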