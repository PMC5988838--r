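test_that("assign_sequence applies the floor/accept/margin criteria", {
  panel <- tiny_panel()
  refs <- panel$sequences
  # exact copy of OTU3 -> assigned at 100%
  r <- assign_sequence(refs[["OTU3"]], refs)
  expect_identical(r$status, "assigned")
  expect_identical(r$best_otu, "OTU3")
  expect_equal(r$best_identity, 100)
  expect_lte(r$second_best_identity, r$best_identity)
  # two references at 100% -> tie_at_top, excluded
  dup <- c(refs, OTU3b = unname(refs[["OTU3"]]))
  expect_identical(assign_sequence(refs[["OTU3"]], dup)$status, "tie_at_top")
  # best hit below the 99% acceptance -> not assigned
  q <- refs[["OTU1"]]
  substr(q, 8, 9) <- "GG"   # 2 mismatches in 40nt vs OTU1 -> 95%
  r2 <- assign_sequence(q, refs)
  expect_identical(r2$status, "no_clear_best")
  expect_lt(r2$best_identity, 99)
  # all hits below the 95% floor -> below_floor
  r3 <- assign_sequence(paste(rep("A", 40), collapse = ""), refs)
  expect_identical(r3$status, "below_floor")
  expect_true(is.na(r3$best_otu))
  # margin: best and runner-up closer than the margin -> no_clear_best
  close_refs <- c(X = "ACGTACGTACGTACGTACGA", Y = "ACGTACGTACGTACGTACGC")
  rm <- assign_sequence("ACGTACGTACGTACGTACGA", close_refs,
                        floor = 50, accept = 90, margin = 6)
  expect_identical(rm$status, "no_clear_best")
  expect_identical(assign_sequence("ACGTACGTACGTACGTACGA", close_refs,
                                   floor = 50, accept = 90, margin = 5)$status,
                   "assigned")
})

test_that("assign_to_otu extracts regions and propagates QC failures", {
  panel <- tiny_panel()
  called <- call_bases(mix_chrom(panel$sequences["OTU2"], 1,
                                 sample_id = "S7"))
  called <- qc_sequence(called)
  for (rg in c("full_ITS", "ITS1", "ITS2")) {
    a <- assign_to_otu(called, panel, region = rg)
    expect_identical(a$status, "assigned")
    expect_identical(a$best_otu, "OTU2")
    expect_equal(a$best_identity, 100)
  }
  bad <- qc_sequence(call_bases(mix_chrom(panel$sequences[1:2], c(0.6, 0.4))))
  expect_identical(assign_to_otu(bad, panel)$status, "qc_failed")
})

test_that("categorize_sample uses upper-inclusive bins with category 1 at exactly 0", {
  expect_identical(categorize_sample(c(A = 1, B = 0, C = 0))$category, 1L)
  expect_identical(categorize_sample(c(A = 0.65, B = 0.35, C = 0))$category, 5L)
  expect_identical(categorize_sample(c(A = 0.90, B = 0.10))$category, 2L)
  expect_identical(categorize_sample(c(A = 0.85, B = 0.15))$category, 3L)
  expect_identical(categorize_sample(c(A = 0.80, B = 0.20))$category, 3L)
  expect_identical(categorize_sample(c(A = 0.75, B = 0.25))$category, 4L)
  expect_identical(categorize_sample(c(A = 0.70, B = 0.30))$category, 4L)
  r <- categorize_sample(c(A = 0.55, B = 0.35, C = 0.10))
  expect_identical(r$category, 5L)
  expect_identical(r$dominant_otu, "A")
  expect_equal(r$secondary_fraction, 35)
  expect_error(categorize_sample(c(A = 0.5, B = 0.5)), "tie")
  expect_error(categorize_sample(c(A = 0.5, B = 0.4)), "sum to 1")
})

test_that("every random composition lands in exactly one category", {
  withr::with_seed(15, {
    for (k in 1:200) {
      f <- runif(4); f <- f / sum(f)
      names(f) <- paste0("O", 1:4)
      r <- tryCatch(categorize_sample(f), error = function(e) NULL)
      if (is.null(r)) next  # tie, excluded upstream
      expect_true(r$category %in% 1:5)
      s <- r$secondary_fraction
      expected <- if (s == 0) 1L else if (s <= 10) 2L else if (s <= 20) 3L
                  else if (s <= 30) 4L else 5L
      expect_identical(r$category, expected)
    }
  })
})

test_that("greedy clustering follows abundance order and the identity threshold", {
  s <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  same <- c(a = s, b = s, c = s)
  cl <- greedy_cluster(same)
  expect_identical(cl$n_clusters, 1L)
  expect_identical(unique(cl$membership$centroid), "a")
  # 98% pair at threshold 99 -> two clusters
  t <- s
  substr(t, 1, 2) <- "GG"
  cl2 <- greedy_cluster(c(a = s, b = t), identity_threshold = 99)
  expect_identical(cl2$n_clusters, 2L)
  expect_identical(greedy_cluster(c(a = s, b = t),
                                  identity_threshold = 97)$n_clusters, 1L)
  # most abundant founds the first centroid
  cl3 <- greedy_cluster(c(a = s, b = t), abundances = c(1, 5),
                        identity_threshold = 99)
  expect_identical(cl3$centroids[1], "b")
  # duplicating a member leaves the centroid set unchanged
  base <- c(a = s, b = t)
  dup <- c(a = s, b = t, b2 = t)
  expect_identical(greedy_cluster(base)$centroids, greedy_cluster(dup)$centroids)
})
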