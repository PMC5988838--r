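#' Tabulate assignments / QC results as data frames
#'
#' @param results list of `assignment_result` objects.
#' @return data.frame, one row per result.
#' @export
assignment_df <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(sample_id = r$sample_id, marker = r$marker,
               best_otu = r$best_otu, best_identity = r$best_identity,
               second_best_identity = r$second_best_identity,
               status = r$status, stringsAsFactors = FALSE)))
}

#' @rdname assignment_df
#' @param called list of QC'd `called_sequence` objects.
#' @export
qc_df <- function(called) {
  do.call(rbind, lapply(called, function(x)
    data.frame(sample_id = x$sample_id, marker = x$marker,
               qc_status = x$qc_status, fail_reason = x$fail_reason,
               n_ambiguous = length(x$ambiguous_positions),
               stringsAsFactors = FALSE)))
}

#' Sanger-vs-metabarcoding concordance summary
#'
#' Joins per-sample QC outcomes, OTU assignments and abundance categories
#' and computes (i) the overall sequencing success rate per marker
#' (sequences passing QC and assigned, over all samples, in percent),
#' (ii) per-category pass/fail counts and proportions (the stacked-bar
#' summary of success against secondary-photobiont abundance), and
#' (iii) the concordant fraction: among assigned sequences, the fraction
#' whose assigned OTU equals the sample's dominant metabarcoding OTU.
#'
#' @param assignments data.frame with columns `sample_id`, `marker`,
#'   `best_otu`, `status` (see [assignment_df()]).
#' @param categories data.frame with columns `sample_id`, `category`,
#'   `dominant_otu` (see [categorize_table()]).
#' @param qc data.frame with columns `sample_id`, `marker`, `qc_status`
#'   (see [qc_df()]); defaults to deriving QC from assignment status
#'   (`qc_failed` = failed).
#' @return object of class `concordance_summary`: list with `per_marker`,
#'   `per_category`, `concordant_fraction` (named by marker), `long`
#'   (plot-ready long format) and `excluded` (samples missing from one of
#'   the inputs, counted but not joined).
#' @export
concordance_table <- function(assignments, categories, qc = NULL) {
  stopifnot(all(c("sample_id", "marker", "best_otu", "status") %in%
                  names(assignments)),
            all(c("sample_id", "category", "dominant_otu") %in%
                  names(categories)))
  if (is.null(qc)) {
    qc <- data.frame(sample_id = assignments$sample_id,
                     marker = assignments$marker,
                     qc_status = ifelse(assignments$status == "qc_failed",
                                        "fail", "pass"),
                     stringsAsFactors = FALSE)
  }
  j <- merge(assignments, qc[, c("sample_id", "marker", "qc_status")],
             by = c("sample_id", "marker"), all = FALSE)
  j <- merge(j, categories[, c("sample_id", "category", "dominant_otu")],
             by = "sample_id", all = FALSE)
  excluded <- data.frame(
    sample_id = union(
      setdiff(assignments$sample_id, categories$sample_id),
      setdiff(categories$sample_id, assignments$sample_id)),
    stringsAsFactors = FALSE)
  if (nrow(excluded))
    message(nrow(excluded), " sample(s) missing from one input; excluded ",
            "from joined statistics")

  j$pass <- j$qc_status == "pass" & j$status == "assigned"
  markers <- unique(j$marker)
  per_marker <- do.call(rbind, lapply(markers, function(mk) {
    d <- j[j$marker == mk, ]
    data.frame(marker = mk,
               n_total = nrow(d),
               n_pass_qc = sum(d$qc_status == "pass"),
               n_assigned = sum(d$status == "assigned"),
               success_rate = 100 * sum(d$pass) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  per_category <- do.call(rbind, lapply(markers, function(mk) {
    d <- j[j$marker == mk, ]
    do.call(rbind, lapply(sort(unique(d$category)), function(cc) {
      dc <- d[d$category == cc, ]
      data.frame(marker = mk, category = cc,
                 n_pass = sum(dc$pass), n_fail = sum(!dc$pass),
                 proportion_pass = mean(dc$pass),
                 stringsAsFactors = FALSE)
    }))
  }))
  concordant <- vapply(markers, function(mk) {
    d <- j[j$marker == mk & j$status == "assigned", ]
    if (nrow(d) == 0L) NA_real_ else mean(d$best_otu == d$dominant_otu)
  }, numeric(1))
  names(concordant) <- markers
  long <- do.call(rbind, lapply(seq_len(nrow(per_category)), function(i) {
    r <- per_category[i, ]
    data.frame(marker = r$marker, category = r$category,
               outcome = c("pass", "fail"),
               n = c(r$n_pass, r$n_fail),
               proportion = c(r$proportion_pass, 1 - r$proportion_pass),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_marker = per_marker, per_category = per_category,
                 concordant_fraction = concordant, long = long,
                 excluded = excluded, joined = j),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Concordance summary\n")
  print(x$per_marker, row.names = FALSE)
  cat("concordant fraction (assigned sequences matching dominant OTU):\n")
  print(round(x$concordant_fraction, 4))
  invisible(x)
}

#' ITS1-vs-ITS2 taxonomic resolution comparison
#'
#' For every sample assigned with both subregion markers, reports whether
#' the ITS1-based OTU, the ITS2-based OTU and the dominant metabarcoding
#' OTU agree (three-way match). Samples assigned with only one marker are
#' counted as incomplete, not as mismatches; an empty overlap yields an
#' undefined (`NA`) match fraction, flagged explicitly.
#'
#' @param its1_assignments,its2_assignments data.frames as from
#'   [assignment_df()].
#' @param dominant_otus data.frame with columns `sample_id`,
#'   `dominant_otu`.
#' @return list with `table` (per-sample), `n_complete`, `n_incomplete`,
#'   `n_match`, `fraction_match` (`NA` when no complete pairs) and
#'   `undefined` flag.
#' @export
resolution_comparison <- function(its1_assignments, its2_assignments,
                                  dominant_otus) {
  a1 <- its1_assignments[, c("sample_id", "best_otu", "status")]
  a2 <- its2_assignments[, c("sample_id", "best_otu", "status")]
  names(a1)[2:3] <- c("its1_otu", "its1_status")
  names(a2)[2:3] <- c("its2_otu", "its2_status")
  tab <- merge(merge(a1, a2, by = "sample_id", all = TRUE),
               dominant_otus[, c("sample_id", "dominant_otu")],
               by = "sample_id", all.x = TRUE)
  tab$complete <- !is.na(tab$its1_status) & tab$its1_status == "assigned" &
    !is.na(tab$its2_status) & tab$its2_status == "assigned" &
    !is.na(tab$dominant_otu)
  tab$match <- tab$complete & tab$its1_otu == tab$its2_otu &
    tab$its1_otu == tab$dominant_otu
  n_complete <- sum(tab$complete)
  list(table = tab,
       n_complete = n_complete,
       n_incomplete = nrow(tab) - n_complete,
       n_match = sum(tab$match),
       fraction_match = if (n_complete == 0L) NA_real_
                        else sum(tab$match) / n_complete,
       undefined = n_complete == 0L)
}
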