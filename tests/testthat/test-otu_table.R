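mk_table <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("OTU%d", seq_len(ncol(m)))
  otu_table(m)
}

test_that("otu_table validates its contents", {
  expect_error(otu_table(matrix(1, 1, 1)), "names")
  expect_error(mk_table(matrix(-1, 2, 2)), "negative")
  m <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(otu_table(m), "duplicate sample")
})

test_that("abundance filter zeroes entries below the per-sample floor", {
  tbl <- mk_table(rbind(c(10000, 0, 0),
                        c(99999, 1, 0),
                        c(99995, 5, 0)))
  out <- filter_abundance(tbl, 5e-5)
  # 10000 >= 0.5 kept; 1 < 5 zeroed; 5 >= 5 kept (strictly-below rule)
  expect_equal(unname(out$counts[1, ]), c(10000L, 0L, 0L))
  expect_equal(unname(out$counts[2, ]), c(99999L, 0L, 0L))
  expect_equal(unname(out$counts[3, ]), c(99995L, 5L, 0L))
  expect_length(filter_log(out), 1L)
  # floor 0 changes nothing
  expect_identical(filter_abundance(tbl, 0)$counts, tbl$counts)
})

test_that("filters are idempotent and never increase counts", {
  set.seed(31)
  m <- matrix(rpois(60, 40) * rbinom(60, 1, 0.6), 10, 6)
  tbl <- mk_table(m)
  once <- filter_abundance(tbl, 0.02)
  twice <- filter_abundance(once, 0.02)
  expect_identical(twice$counts, once$counts)
  expect_true(all(once$counts <= tbl$counts))
  pv1 <- filter_prevalence(once, 0.3)
  pv2 <- filter_prevalence(pv1, 0.3)
  expect_identical(pv2$counts, pv1$counts)
})

test_that("prevalence filter uses ceiling(floor * n) with strict inequality", {
  expect_identical(prevalence_min_count(240, 0.05), 12L)
  # OTU present in exactly 12 of 240 samples is retained (12 is not < 12)
  m <- matrix(0L, 240, 2, dimnames = list(sprintf("S%03d", 1:240),
                                          c("keep", "drop")))
  m[, "keep"] <- 100L
  m[1:12, "drop"] <- 5L
  out <- filter_prevalence(otu_table(m), 0.05)
  expect_identical(otu_ids(out), c("keep", "drop"))
  expect_identical(attr(out, "min_presence"), 12L)
  m[12, "drop"] <- 0L   # now present in 11 < 12 -> removed
  out2 <- filter_prevalence(otu_table(m), 0.05)
  expect_identical(otu_ids(out2), "keep")
  expect_identical(attr(out2, "removed_otus"), "drop")
  # floor 0 removes nothing
  expect_identical(otu_ids(filter_prevalence(otu_table(m), 0)),
                   c("keep", "drop"))
})

test_that("predominant rescue restores rare-but-dominant OTUs only", {
  # OTU6-like column: present in 5 of 240 samples, predominant in all 5
  n <- 240
  m <- matrix(0L, n, 3, dimnames = list(sprintf("S%03d", 1:n),
                                        c("OTU1", "OTU6", "OTU7")))
  m[, "OTU1"] <- 1000L
  m[1:5, "OTU6"] <- 5000L        # dominant where present
  m[1:8, "OTU7"] <- 10L          # rare and never dominant
  before <- otu_table(m)
  after <- filter_prevalence(before, 0.05)
  expect_identical(otu_ids(after), "OTU1")
  rescued <- rescue_predominant(before, after)
  expect_identical(otu_ids(rescued), c("OTU1", "OTU6"))
  expect_identical(attr(rescued, "rescued_otus"), "OTU6")
  expect_equal(unname(rescued$counts[1:5, "OTU6"]), rep(5000L, 5))
  # ties do not confer predominance
  m2 <- m
  m2[1:5, "OTU6"] <- 1000L
  b2 <- otu_table(m2)
  r2 <- rescue_predominant(b2, filter_prevalence(b2, 0.05))
  expect_identical(otu_ids(r2), "OTU1")
  # nothing removed -> rescue is the identity on counts
  r3 <- rescue_predominant(after, after)
  expect_identical(r3$counts, after$counts)
})

test_that("rescue preserves the subset/superset sandwich", {
  set.seed(5)
  m <- matrix(rpois(200 * 8, 2) * rbinom(200 * 8, 1, 0.3), 200, 8)
  m[, 1] <- 500L
  tbl <- mk_table(m)
  ab <- filter_abundance(tbl, 5e-5)
  pv <- filter_prevalence(ab, 0.2)
  rs <- rescue_predominant(ab, pv)
  expect_true(all(otu_ids(pv) %in% otu_ids(rs)))
  expect_true(all(otu_ids(rs) %in% otu_ids(ab)))
})

test_that("relative abundances normalise rows and flag empty samples", {
  tbl <- mk_table(rbind(c(70, 30), c(0, 0), c(5, 15)))
  expect_warning(fr <- relative_abundances(tbl), "zero total")
  expect_equal(unname(fr[1, ]), c(0.7, 0.3))
  expect_equal(unname(rowSums(fr)), rep(1, 2), tolerance = 1e-9)
  expect_identical(attr(fr, "flagged_samples"), "S02")
})

test_that("OTU tables round-trip through TSV in both orientations", {
  tbl <- mk_table(rbind(c(12, 0, 3), c(0, 7, 1)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tbl, f, seed = 42)
  back <- read_otu_table(f)
  expect_identical(back$counts, tbl$counts)
  write_otu_table(tbl, f, transposed = TRUE)
  expect_identical(read_otu_table(f, transposed = TRUE)$counts, tbl$counts)
  writeLines(c("sample_id\tOTU1", "S1\t-3"), f)
  expect_error(read_otu_table(f), "negative")
})
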