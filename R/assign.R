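#' Assign a query sequence to an OTU reference set
#'
#' Implements the acceptance criteria used when matching a Sanger sequence
#' against metabarcoding OTU representatives: hits below the `floor`
#' identity (default 95%) are discarded; the query is `assigned` only when
#' the best hit reaches `accept` identity (default 99%), is strictly
#' unique, and clears the second-best hit by at least `margin` percentage
#' points (the operationalisation of "second-best hit not significantly
#' lower"). Otherwise the status records why: `tie_at_top` (two references
#' share the maximum), `below_floor` (no hit at or above `floor`), or
#' `no_clear_best`.
#'
#' @param query nucleotide string (IUPAC codes allowed).
#' @param references named character vector of reference sequences.
#' @param floor,accept percent identity thresholds.
#' @param margin minimum best-minus-second-best identity in percentage
#'   points (default 0.5).
#' @return list with `best_otu`, `best_identity`, `second_best_identity`
#'   (`NA` if single hit) and `status`.
#' @export
assign_sequence <- function(query, references, floor = 95, accept = 99,
                            margin = 0.5) {
  if (length(references) == 0L) stop("reference set is empty")
  if (is.null(names(references)) || anyDuplicated(names(references)))
    stop("references must have unique names")
  ids <- vapply(references, function(r) pairwise_identity(query, r)$identity,
                numeric(1))
  ord <- order(-ids)
  best <- unname(ids[ord[1]])
  second <- if (length(ids) >= 2L) unname(ids[ord[2]]) else NA_real_
  res <- list(best_otu = names(references)[ord[1]],
              best_identity = best,
              second_best_identity = second,
              status = "no_clear_best")
  if (best < floor) {
    res$best_otu <- NA_character_
    res$status <- "below_floor"
  } else if (!is.na(second) && abs(best - second) < 1e-9) {
    res$best_otu <- NA_character_
    res$status <- "tie_at_top"
  } else if (best >= accept && (is.na(second) || second < floor ||
                                best - second >= margin)) {
    res$status <- "assigned"
  }
  res
}

#' Assign a called Sanger sequence to the OTU panel
#'
#' Wraps [assign_sequence()] for `called_sequence` objects: QC-failed
#' sequences get status `qc_failed`; for region `"ITS1"`/`"ITS2"` the
#' region is first extracted by anchor motifs and compared against the
#' panel's corresponding region sequences, while `"full_ITS"` compares the
#' whole call against the full references.
#'
#' @param called a `called_sequence` (or plain string, assumed QC-passed).
#' @param panel an `otu_panel`.
#' @param region `"full_ITS"`, `"ITS1"` or `"ITS2"`.
#' @param floor,accept,margin see [assign_sequence()].
#' @return object of class `assignment_result`: list with `sample_id`,
#'   `marker` (the region compared), `best_otu`, `best_identity`,
#'   `second_best_identity`, `status`.
#' @export
assign_to_otu <- function(called, panel,
                          region = c("full_ITS", "ITS2", "ITS1"),
                          floor = 95, accept = 99, margin = 0.5) {
  region <- match.arg(region)
  stopifnot(inherits(panel, "otu_panel"))
  sample_id <- if (inherits(called, "called_sequence")) called$sample_id else "query"
  base <- list(sample_id = sample_id, marker = region,
               best_otu = NA_character_, best_identity = NA_real_,
               second_best_identity = NA_real_, status = "qc_failed")
  if (inherits(called, "called_sequence")) {
    if (identical(called$qc_status, "fail"))
      return(structure(base, class = "assignment_result"))
    if (region == "ITS1" && identical(called$marker, "ITS2_only"))
      stop("ITS1 cannot be extracted from an ITS2-only sequence")
  }
  query <- if (region == "full_ITS") {
    if (inherits(called, "called_sequence")) called$bases else as.character(called)
  } else {
    ex <- extract_regions(called, panel$anchors, regions = region)
    if (length(ex$failed)) {
      base$status <- paste0("extraction_failed:", ex$failed[[1]])
      return(structure(base, class = "assignment_result"))
    }
    ex$regions[[region]]
  }
  refs <- panel_region_seqs(panel, if (region == "full_ITS") "full_ITS" else region)
  res <- assign_sequence(query, refs, floor = floor, accept = accept,
                         margin = margin)
  structure(c(base[c("sample_id", "marker")], res),
            class = "assignment_result")
}

#' Secondary-abundance category of a sample
#'
#' Classifies a sample by the relative abundance of its second most
#' abundant OTU: category 1 = exactly 0% (single photobiont), 2 = (0,10]%,
#' 3 = (10,20]%, 4 = (20,30]%, 5 = (30,100]% (upper-inclusive bins; the
#' boundary convention is fixed here because legend-style "10-20%" ranges
#' leave it open).
#'
#' @param rel_abund_row named numeric vector of one sample's relative
#'   abundances (sums to 1).
#' @return list with `category` (1-5), `secondary_fraction` (percent) and
#'   `dominant_otu`.
#' @export
categorize_sample <- function(rel_abund_row) {
  if (abs(sum(rel_abund_row) - 1) > 1e-9)
    stop("relative abundances must sum to 1")
  ord <- sort(rel_abund_row, decreasing = TRUE)
  if (length(ord) >= 2L && abs(ord[1] - ord[2]) < 1e-12)
    stop("tie for the dominant OTU; category undefined")
  secondary <- if (length(ord) >= 2L) unname(100 * ord[2]) else 0
  category <- if (secondary == 0) 1L
  else if (secondary <= 10) 2L
  else if (secondary <= 20) 3L
  else if (secondary <= 30) 4L
  else 5L
  list(category = category,
       secondary_fraction = secondary,
       dominant_otu = names(ord)[1])
}

#' Categorise every sample of a relative-abundance matrix
#'
#' @param rel_abund matrix from [relative_abundances()].
#' @return data.frame with columns `sample_id`, `category`,
#'   `secondary_fraction` (percent), `dominant_otu`. Samples with a tied
#'   dominant OTU are excluded and listed in attribute `flagged_samples`.
#' @export
categorize_table <- function(rel_abund) {
  res <- vector("list", nrow(rel_abund))
  flagged <- character(0)
  for (i in seq_len(nrow(rel_abund))) {
    r <- tryCatch(categorize_sample(rel_abund[i, ]), error = function(e) NULL)
    if (is.null(r)) flagged <- c(flagged, rownames(rel_abund)[i])
    res[[i]] <- r
  }
  keep <- !vapply(res, is.null, TRUE)
  out <- data.frame(
    sample_id = rownames(rel_abund)[keep],
    category = vapply(res[keep], `[[`, 1L, "category"),
    secondary_fraction = vapply(res[keep], `[[`, 1, "secondary_fraction"),
    dominant_otu = vapply(res[keep], `[[`, "", "dominant_otu"),
    stringsAsFactors = FALSE)
  attr(out, "flagged_samples") <- flagged
  out
}

#' Greedy abundance-sorted clustering at an identity threshold
#'
#' vsearch-style `cluster_size` clustering: sequences are visited in order
#' of decreasing abundance (ties by input order); each joins the first
#' existing centroid it matches at `identity_threshold` percent or higher
#' (centroids tried in founding order), otherwise it founds a new cluster.
#'
#' @param seqs named character vector of sequences.
#' @param abundances numeric abundances (default all 1).
#' @param identity_threshold percent identity (default 99).
#' @return list with `membership` (data.frame `seq_id`, `centroid`,
#'   `identity`), `centroids` (ids in founding order), `n_clusters`.
#' @export
greedy_cluster <- function(seqs, abundances = rep(1, length(seqs)),
                           identity_threshold = 99) {
  if (length(seqs) == 0L) stop("no sequences to cluster")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  stopifnot(length(abundances) == length(seqs))
  ord <- order(-abundances, seq_along(seqs))
  centroids <- character(0)
  assigned <- character(length(seqs))
  idty <- numeric(length(seqs))
  names(assigned) <- names(idty) <- names(seqs)
  for (i in ord) {
    hit <- NA_character_
    hid <- NA_real_
    for (cid in centroids) {
      id <- pairwise_identity(seqs[[i]], seqs[[cid]])$identity
      if (id >= identity_threshold) { hit <- cid; hid <- id; break }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, names(seqs)[i])
      assigned[i] <- names(seqs)[i]
      idty[i] <- 100
    } else {
      assigned[i] <- hit
      idty[i] <- hid
    }
  }
  list(membership = data.frame(seq_id = names(seqs), centroid = unname(assigned),
                               identity = unname(idty), stringsAsFactors = FALSE),
       centroids = centroids,
       n_clusters = length(centroids))
}
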