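#' Call bases from a chromatogram with the secondary-peak rule
#'
#' At each position let `h1 >= h2` be the two largest peak heights. If
#' `h2/h1` exceeds `secondary_peak_threshold` (default 25%), the position
#' is called as the IUPAC ambiguity code covering every base whose peak
#' exceeds `threshold * h1` -- two-, three- or four-fold codes, since
#' thalli can rarely host three abundant photobionts -- and recorded as
#' ambiguous; otherwise the base of the maximal peak is emitted. The call
#' is deterministic given the chromatogram.
#'
#' @param chromatogram a `chromatogram`.
#' @param secondary_peak_threshold ratio in (0,1); default 0.25.
#' @return object of class `called_sequence`: list with `sample_id`,
#'   `marker`, `bases` (IUPAC string), `ambiguous_positions` (indices into
#'   `bases`), `positions` (template coordinates), `qc_status`
#'   (`"pending"` until [qc_sequence()]), `fail_reason`.
#' @export
call_bases <- function(chromatogram, secondary_peak_threshold = 0.25) {
  stopifnot(inherits(chromatogram, "chromatogram"),
            secondary_peak_threshold > 0, secondary_peak_threshold < 1)
  H <- chromatogram$heights
  h1 <- apply(H, 1L, max)
  if (any(h1 <= 0))
    stop("malformed chromatogram: all-zero peaks at position(s) ",
         paste(head(which(h1 <= 0), 5L), collapse = ", "))
  above <- H > secondary_peak_threshold * h1  # maximal peak always qualifies
  mask <- as.integer(above %*% c(A = 1L, C = 2L, G = 4L, T = 8L))
  bases <- iupac_code(mask)
  ambiguous <- which(rowSums(above) > 1L)
  structure(list(sample_id = chromatogram$sample_id,
                 marker = chromatogram$marker,
                 bases = paste(bases, collapse = ""),
                 ambiguous_positions = as.integer(ambiguous),
                 positions = chromatogram$positions,
                 qc_status = "pending",
                 fail_reason = NA_character_),
            class = "called_sequence")
}

#' @export
print.called_sequence <- function(x, ...) {
  cat("Called sequence", x$sample_id, sprintf("(%s):", x$marker),
      nchar(x$bases), "nt,", length(x$ambiguous_positions),
      "ambiguous, QC", x$qc_status, "\n")
  invisible(x)
}

#' Quality-control a called sequence
#'
#' Mirrors manual electropherogram curation: sequences with unresolved
#' ambiguous base calls are excluded, as are severely shortened sequences.
#' The default zero-tolerance mode fails on any ambiguity (in simulated
#' panels every variable site is OTU-diagnostic); mode
#' `"variable_sites_only"` fails only when an ambiguity falls on a supplied
#' diagnostic site, for sensitivity analysis.
#'
#' @param called a `called_sequence`.
#' @param expected_length expected marker length in nt (`NULL` skips the
#'   length check).
#' @param min_length_fraction fail as `"truncated"` below this fraction of
#'   `expected_length` (default 0.9).
#' @param qc_mode `"any_ambiguity"` (default) or `"variable_sites_only"`.
#' @param variable_sites template coordinates of diagnostic sites (required
#'   for `"variable_sites_only"`).
#' @return the `called_sequence` with `qc_status` set to `"pass"` or
#'   `"fail"` and `fail_reason` one of `"ambiguous_calls"`, `"truncated"`.
#' @export
qc_sequence <- function(called, expected_length = NULL,
                        min_length_fraction = 0.9,
                        qc_mode = c("any_ambiguity", "variable_sites_only"),
                        variable_sites = NULL) {
  stopifnot(inherits(called, "called_sequence"), nchar(called$bases) > 0)
  qc_mode <- match.arg(qc_mode)
  relevant <- called$ambiguous_positions
  if (qc_mode == "variable_sites_only") {
    if (is.null(variable_sites))
      stop("variable_sites required for qc_mode = 'variable_sites_only'")
    relevant <- relevant[called$positions[relevant] %in% variable_sites]
  }
  if (length(relevant)) {
    called$qc_status <- "fail"
    called$fail_reason <- "ambiguous_calls"
  } else if (!is.null(expected_length) &&
             nchar(called$bases) < min_length_fraction * expected_length) {
    called$qc_status <- "fail"
    called$fail_reason <- "truncated"
  } else {
    called$qc_status <- "pass"
    called$fail_reason <- NA_character_
  }
  called
}

#' Extract ITS1/ITS2 regions by anchor motifs
#'
#' Locates each region's conserved start and end motif by exact,
#' IUPAC-aware match (an ambiguous base matches a motif base contained in
#' its set) and returns the enclosed subsequence. A motif found zero or
#' multiple times flags the region as failed rather than dropping it
#' silently. `ITS2_only` sequences carry only the ITS2 anchors, so only
#' ITS2 is extractable from them.
#'
#' @param called a `called_sequence`, or a plain nucleotide string.
#' @param anchors a [region_anchors()].
#' @param regions which regions to extract.
#' @param allow_qc_fail extract even from a QC-failed sequence.
#' @return list with `regions` (named list of subsequences), `coords`
#'   (1-based inclusive, relative to the input string) and `failed` (named
#'   character vector of failure reasons).
#' @export
extract_regions <- function(called, anchors, regions = c("ITS1", "ITS2"),
                            allow_qc_fail = FALSE) {
  stopifnot(inherits(anchors, "region_anchors"))
  regions <- match.arg(regions, several.ok = TRUE)
  if (inherits(called, "called_sequence")) {
    if (identical(called$qc_status, "fail") && !allow_qc_fail)
      stop("sequence failed QC (", called$fail_reason,
           "); use allow_qc_fail = TRUE to override")
    seq <- called$bases
    if (identical(called$marker, "ITS2_only")) regions <- intersect(regions, "ITS2")
  } else {
    seq <- as.character(called)
  }
  out <- list(regions = list(), coords = list(),
              failed = setNames(character(0), character(0)))
  for (rg in regions) {
    mo_start <- anchors[[paste0(tolower(rg), "_start_motif")]]
    mo_end <- anchors[[paste0(tolower(rg), "_end_motif")]]
    hs <- find_motif(seq, mo_start, iupac = TRUE)
    he <- find_motif(seq, mo_end, iupac = TRUE)
    reason <- NULL
    if (length(hs) == 0L || length(he) == 0L) reason <- "motif_not_found"
    else if (length(hs) > 1L || length(he) > 1L) reason <- "motif_multiple"
    else {
      from <- hs + nchar(mo_start)
      to <- he - 1L
      if (to < from) reason <- "motifs_out_of_order"
    }
    if (is.null(reason)) {
      out$regions[[rg]] <- substr(seq, from, to)
      out$coords[[rg]] <- c(start = from, end = to)
    } else {
      out$failed[rg] <- reason
    }
  }
  out
}
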