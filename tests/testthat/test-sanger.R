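test_that("call_bases applies the secondary-peak ratio rule", {
  # A:1.0 / C:0.2 -> A (0.2 <= 0.25); A:0.7 / C:0.3 -> M; lone G -> G
  H <- rbind(c(1.0, 0.2, 0, 0),
             c(0.7, 0.3, 0, 0),
             c(0, 0, 1.0, 0))
  called <- call_bases(make_chrom(H), secondary_peak_threshold = 0.25)
  expect_identical(called$bases, "AMG")
  expect_identical(called$ambiguous_positions, 2L)
  # threshold boundary is strict: ratio exactly 0.25 is not ambiguous
  called2 <- call_bases(make_chrom(rbind(c(1.0, 0.25, 0, 0))))
  expect_identical(called2$bases, "A")
  # three-way mixture emits a three-fold code
  called3 <- call_bases(make_chrom(rbind(c(0.5, 0.3, 0.2, 0))))
  expect_identical(called3$bases, "V")
  # equal top peaks are ambiguous
  expect_identical(call_bases(make_chrom(rbind(c(0.5, 0.5, 0, 0))))$bases, "M")
  # all-zero position is malformed
  expect_error(call_bases(make_chrom(rbind(c(0, 0, 0, 0)))), "all-zero")
  # deterministic
  expect_identical(call_bases(make_chrom(H)), call_bases(make_chrom(H)))
})

test_that("qc_sequence fails on ambiguity or truncation, else passes", {
  ok <- call_bases(mix_chrom("ACGTACGT", 1))
  expect_identical(qc_sequence(ok, expected_length = 8)$qc_status, "pass")
  amb <- call_bases(make_chrom(rbind(c(0.6, 0.4, 0, 0), c(1, 0, 0, 0))))
  qcd <- qc_sequence(amb)
  expect_identical(qcd$qc_status, "fail")
  expect_identical(qcd$fail_reason, "ambiguous_calls")
  short <- call_bases(mix_chrom("ACGT", 1))
  qs <- qc_sequence(short, expected_length = 8, min_length_fraction = 0.9)
  expect_identical(qs$qc_status, "fail")
  expect_identical(qs$fail_reason, "truncated")
  # variable-sites-only mode ignores ambiguities off the diagnostic sites
  amb2 <- call_bases(make_chrom(rbind(c(0.6, 0.4, 0, 0), c(1, 0, 0, 0)),
                                positions = c(10L, 11L)))
  lax <- qc_sequence(amb2, qc_mode = "variable_sites_only",
                     variable_sites = c(11L))
  expect_identical(lax$qc_status, "pass")
  strict <- qc_sequence(amb2, qc_mode = "variable_sites_only",
                        variable_sites = c(10L))
  expect_identical(strict$qc_status, "fail")
})

test_that("two-template mixtures are ambiguous exactly when f/(1-f) > threshold", {
  panel <- tiny_panel()
  cfg <- tiny_config(chromatogram_noise_sd = 0)
  n_disc <- sum(strsplit(panel$sequences[[1]], "")[[1]] !=
                  strsplit(panel$sequences[[2]], "")[[1]])
  for (f in c(0.05, 0.1, 0.15, 0.2, 0.201, 0.25, 0.3, 0.45)) {
    prof <- setNames(c(1 - f, f, 0), panel$otu_ids)
    called <- call_bases(simulate_chromatogram(prof, panel, cfg))
    expected_ambiguous <- f / (1 - f) > 0.25
    expect_identical(length(called$ambiguous_positions) > 0L,
                     expected_ambiguous, label = paste("f =", f))
    if (expected_ambiguous)
      expect_length(called$ambiguous_positions, n_disc)
  }
})

test_that("extract_regions round-trips panel references and flags failures", {
  panel <- tiny_panel()
  for (otu in panel$otu_ids) {
    ex <- extract_regions(panel$sequences[[otu]], panel$anchors)
    expect_named(ex$regions, c("ITS1", "ITS2"))
    expect_identical(ex$regions$ITS1,
                     substr(panel$sequences[[otu]], panel$its1_span[1],
                            panel$its1_span[2]))
    expect_identical(ex$regions$ITS2,
                     substr(panel$sequences[[otu]], panel$its2_span[1],
                            panel$its2_span[2]))
  }
  # missing end motif -> flagged, not dropped
  broken <- sub("GGCC", "GGAA", panel$sequences[[1]], fixed = TRUE)
  ex <- extract_regions(broken, panel$anchors)
  expect_identical(unname(ex$failed["ITS2"]), "motif_not_found")
  expect_null(ex$regions$ITS2)
  expect_identical(ex$regions$ITS1,
                   substr(panel$sequences[[1]], 7, 14))
  # duplicated motif -> flagged as multiple
  dup <- paste0(panel$sequences[[1]], "GTAC")
  ex2 <- extract_regions(dup, panel$anchors)
  expect_identical(unname(ex2$failed["ITS1"]), "motif_multiple")
})

test_that("IUPAC ambiguity codes inside a region do not break extraction", {
  panel <- tiny_panel()
  s <- panel$sequences[[1]]
  in_its1 <- panel$its1_span[1] + 2L
  amb <- paste0(substr(s, 1, in_its1 - 1L), "M",
                substr(s, in_its1 + 1L, nchar(s)))
  ex <- extract_regions(amb, panel$anchors)
  expect_length(ex$failed, 0L)
  expect_true(grepl("M", ex$regions$ITS1, fixed = TRUE))
  # an ambiguity inside a motif still matches when the motif base is in its set
  pos <- find_motif(s, "GTAC")[1]
  amb2 <- paste0(substr(s, 1, pos - 1L), "K",   # K = G/T matches motif G
                 substr(s, pos + 1L, nchar(s)))
  ex2 <- extract_regions(amb2, panel$anchors, regions = "ITS1")
  expect_length(ex2$failed, 0L)
  # QC-failed sequences need the explicit override
  bad <- call_bases(mix_chrom(panel$sequences[1:2], c(0.6, 0.4)))
  bad <- qc_sequence(bad)
  expect_error(extract_regions(bad, panel$anchors), "failed QC")
  expect_silent(extract_regions(bad, panel$anchors, allow_qc_fail = TRUE))
})

test_that("single-template calls stay clean under realistic noise", {
  panel <- tiny_panel()
  cfgN <- tiny_config(chromatogram_noise_sd = 0.1)
  n_amb <- withr::with_seed(17, {
    sum(vapply(1:300, function(i) {
      ch <- simulate_chromatogram(setNames(c(1, 0, 0), panel$otu_ids),
                                  panel, cfgN)
      length(call_bases(ch)$ambiguous_positions)
    }, numeric(1)))
  })
  expect_identical(n_amb, 0)
})
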