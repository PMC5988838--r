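#' OTU count table
#'
#' Samples x OTUs matrix of non-negative integer read counts plus an
#' append-only log of the filters applied to it.
#'
#' @param counts numeric matrix (samples in rows, OTUs in columns) with
#'   unique, non-empty dimnames and no negative entries.
#' @param filter_log character vector of filter descriptions already
#'   applied (normally empty).
#' @return object of class `otu_table`.
#' @export
otu_table <- function(counts, filter_log = character()) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, filter_log = as.character(filter_log)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs;",
      sum(x$counts), "reads\n")
  if (length(x$filter_log))
    cat(paste0("  filter: ", x$filter_log, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Table accessors
#' @param table an [otu_table()].
#' @return character vector of ids, or the filter log.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(table) colnames(table$counts)

#' @rdname sample_ids
#' @export
filter_log <- function(table) table$filter_log

#' Per-sample relative abundance filter
#'
#' Within each sample, zeroes every OTU count strictly below
#' `floor` x (that sample's total read count, taken before any zeroing).
#' With the default floor of 5e-5 this removes occurrences below 0.005% of
#' the sample's reads, the standard guard against index bleed-through and
#' PCR/sequencing error in amplicon OTU tables.
#'
#' @param table an [otu_table()].
#' @param floor relative threshold in `[0, 1)`.
#' @return filtered [otu_table()] with the action appended to the log.
#' @export
filter_abundance <- function(table, floor = 5e-5) {
  stopifnot(inherits(table, "otu_table"), floor >= 0, floor < 1)
  counts <- table$counts
  thresh <- floor * rowSums(counts)
  zero <- sweep(counts, 1L, thresh, "<") & counts > 0L
  counts[zero] <- 0L
  otu_table(counts, c(table$filter_log,
                      sprintf("abundance filter: floor=%g, %d entries zeroed",
                              floor, sum(zero))))
}

#' Minimum presence count implied by a prevalence floor
#'
#' An OTU must be present (nonzero) in at least `ceiling(floor * n_samples)`
#' samples to survive [filter_prevalence()] ("present in less than
#' `floor`" removes it). With 240 samples and a 5% floor this is 12.
#'
#' @param n_samples number of samples.
#' @param floor prevalence floor in `[0, 1)`.
#' @return integer minimum number of samples.
#' @export
prevalence_min_count <- function(n_samples, floor = 0.05) {
  as.integer(ceiling(floor * n_samples))
}

#' Prevalence filter
#'
#' Removes every OTU column that is present (count > 0, normally after
#' [filter_abundance()]) in strictly fewer than
#' [prevalence_min_count()] samples.
#'
#' @param table an [otu_table()].
#' @param floor fraction-of-samples threshold in `[0, 1)`.
#' @return filtered [otu_table()]; the minimum presence count used is
#'   recorded in the filter log and in attribute `min_presence`, the
#'   removed OTU ids in attribute `removed_otus`.
#' @export
filter_prevalence <- function(table, floor = 0.05) {
  stopifnot(inherits(table, "otu_table"), floor >= 0, floor < 1)
  min_n <- prevalence_min_count(nrow(table$counts), floor)
  presence <- colSums(table$counts > 0L)
  drop <- presence < min_n
  out <- otu_table(table$counts[, !drop, drop = FALSE],
                   c(table$filter_log,
                     sprintf("prevalence filter: floor=%g, min presence=%d, %d OTU(s) removed",
                             floor, min_n, sum(drop))))
  attr(out, "min_presence") <- min_n
  attr(out, "removed_otus") <- colnames(table$counts)[drop]
  out
}

#' Restore OTUs that are predominant somewhere
#'
#' The prevalence filter can discard rare-but-dominant taxa (an OTU found
#' in few thalli yet the predominant photobiont of each of them). This
#' rescue restores any OTU removed between `table_before` and `table_after`
#' that is the strictly most abundant OTU in at least one sample of
#' `table_before`; ties for most-abundant do not confer predominance.
#' Predominance is judged on post-abundance-filter, pre-prevalence-filter
#' counts, i.e. `table_before` should be the table that entered
#' [filter_prevalence()].
#'
#' @param table_before the [otu_table()] before prevalence filtering.
#' @param table_after the [otu_table()] after prevalence filtering.
#' @return [otu_table()] with rescued columns restored (original column
#'   order); attribute `rescued_otus` lists them.
#' @export
rescue_predominant <- function(table_before, table_after) {
  stopifnot(inherits(table_before, "otu_table"),
            inherits(table_after, "otu_table"))
  removed <- setdiff(otu_ids(table_before), otu_ids(table_after))
  if (!setequal(sample_ids(table_before), sample_ids(table_after)))
    stop("tables must cover the same samples")
  cb <- table_before$counts
  rescued <- character(0)
  for (otu in removed) {
    col <- cb[, otu]
    rowmax <- apply(cb, 1L, max)
    is_unique_max <- col > 0L & col == rowmax &
      rowSums(cb == rowmax) == 1L
    if (any(is_unique_max)) rescued <- c(rescued, otu)
  }
  keep <- colnames(cb) %in% union(otu_ids(table_after), rescued)
  out <- otu_table(cb[, keep, drop = FALSE],
                   c(table_after$filter_log,
                     sprintf("predominant rescue: %d OTU(s) restored%s",
                             length(rescued),
                             if (length(rescued))
                               paste0(" (", paste(rescued, collapse = ", "), ")")
                             else "")))
  attr(out, "rescued_otus") <- rescued
  out
}

#' Row-normalised relative abundances
#'
#' @param table an [otu_table()].
#' @return numeric matrix of per-sample fractions (rows sum to 1). Samples
#'   with an all-zero row are excluded, flagged in attribute
#'   `flagged_samples`, and reported with a warning -- never silently
#'   dropped.
#' @export
relative_abundances <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  zero <- totals == 0
  if (any(zero))
    warning(sum(zero), " sample(s) with zero total reads excluded: ",
            paste(head(rownames(table$counts)[zero], 5L), collapse = ", "))
  fr <- table$counts[!zero, , drop = FALSE] / totals[!zero]
  attr(fr, "flagged_samples") <- rownames(table$counts)[zero]
  fr
}

#' Apply the full filter chain
#'
#' Abundance filter, then prevalence filter, then (optionally) the
#' predominant-OTU rescue -- the order in which the filters are defined.
#'
#' @param table an [otu_table()].
#' @param filters a [filter_config()].
#' @return filtered [otu_table()].
#' @export
apply_filters <- function(table, filters = filter_config()) {
  stopifnot(inherits(filters, "filter_config"))
  ab <- filter_abundance(table, filters$abundance_floor)
  pv <- filter_prevalence(ab, filters$prevalence_floor)
  if (filters$rescue_predominant) rescue_predominant(ab, pv) else pv
}
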