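# build toy assignment/category/qc tables with a given pass pattern
toy_inputs <- function(n, n_pass, marker = "full_ITS",
                       categories = rep(1L, n)) {
  ids <- sprintf("S%03d", seq_len(n))
  pass <- seq_len(n) <= n_pass
  asg <- data.frame(sample_id = ids, marker = marker,
                    best_otu = ifelse(pass, "OTU1", NA),
                    best_identity = ifelse(pass, 100, NA),
                    second_best_identity = NA_real_,
                    status = ifelse(pass, "assigned", "qc_failed"),
                    stringsAsFactors = FALSE)
  qc <- data.frame(sample_id = ids, marker = marker,
                   qc_status = ifelse(pass, "pass", "fail"),
                   stringsAsFactors = FALSE)
  cats <- data.frame(sample_id = ids, category = categories,
                     dominant_otu = "OTU1", stringsAsFactors = FALSE)
  list(asg = asg, qc = qc, cats = cats)
}

test_that("success rates are n_passing / n_total in percent", {
  x <- toy_inputs(240, 183)
  conc <- concordance_table(x$asg, x$cats, x$qc)
  expect_equal(conc$per_marker$success_rate, 76.25)
  y <- toy_inputs(240, 198, marker = "ITS2_only")
  expect_equal(concordance_table(y$asg, y$cats, y$qc)$per_marker$success_rate,
               82.5)
  expect_equal(unname(conc$concordant_fraction["full_ITS"]), 1)
})

test_that("per-category proportions and the long table are consistent", {
  # 61 category-1 samples of which 54 pass; 16 category-5 samples all fail
  cats <- c(rep(1L, 61), rep(5L, 16))
  x <- toy_inputs(77, 54, categories = cats)
  conc <- concordance_table(x$asg, x$cats, x$qc)
  pc <- conc$per_category
  expect_equal(pc$proportion_pass[pc$category == 1], 54 / 61)
  expect_equal(round(100 * pc$proportion_pass[pc$category == 1], 2), 88.52)
  expect_equal(pc$proportion_pass[pc$category == 5], 0)
  expect_equal(pc$n_fail[pc$category == 5], 16)
  long <- conc$long
  for (cc in unique(long$category)) {
    sub <- long[long$category == cc, ]
    expect_equal(sum(sub$n), sum(cats == cc))
    expect_equal(sum(sub$proportion), 1)
  }
})

test_that("samples missing from one input are excluded and reported", {
  x <- toy_inputs(10, 10)
  cats <- x$cats[1:8, ]
  expect_message(conc <- concordance_table(x$asg, cats, x$qc), "2 sample")
  expect_equal(conc$per_marker$n_total, 8)
  expect_equal(nrow(conc$excluded), 2)
})

test_that("discordant assignments lower the concordant fraction", {
  x <- toy_inputs(10, 10)
  x$asg$best_otu[1] <- "OTU2"
  conc <- concordance_table(x$asg, x$cats, x$qc)
  expect_equal(unname(conc$concordant_fraction["full_ITS"]), 0.9)
})

test_that("resolution comparison joins markers and handles missing overlap", {
  a1 <- data.frame(sample_id = c("S1", "S2", "S3"),
                   best_otu = c("OTU1", "OTU2", "OTU1"),
                   status = c("assigned", "assigned", "qc_failed"),
                   stringsAsFactors = FALSE)
  a2 <- data.frame(sample_id = c("S1", "S2", "S4"),
                   best_otu = c("OTU1", "OTU3", "OTU1"),
                   status = c("assigned", "assigned", "assigned"),
                   stringsAsFactors = FALSE)
  dom <- data.frame(sample_id = paste0("S", 1:4),
                    dominant_otu = c("OTU1", "OTU2", "OTU1", "OTU1"),
                    stringsAsFactors = FALSE)
  r <- resolution_comparison(a1, a2, dom)
  expect_equal(r$n_complete, 2)      # S1, S2
  expect_equal(r$n_incomplete, 2)    # S3 (qc_failed ITS1), S4 (no ITS1)
  expect_equal(r$n_match, 1)         # S1 three-way; S2 ITS1 != ITS2
  expect_equal(r$fraction_match, 0.5)
  # empty overlap -> undefined, not zero
  r0 <- resolution_comparison(a1[a1$sample_id == "S3", ],
                              a2[a2$sample_id == "S4", ], dom)
  expect_true(r0$undefined)
  expect_true(is.na(r0$fraction_match))
})
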