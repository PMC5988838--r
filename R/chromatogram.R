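#' Simulate a mixed-template Sanger chromatogram
#'
#' Direct Sanger sequencing of a mixed-template PCR product superimposes
#' the templates' signals: at each position the peak height of base `b` is
#' the summed relative abundance of the templates carrying `b` there,
#' perturbed by multiplicative Gaussian noise `(1 + e)`, `e ~ N(0, sd)`,
#' and clipped at 0. Positions where all templates agree therefore show a
#' single peak; positions where they differ show peaks proportional to the
#' template fractions -- the mechanism behind ambiguous base calls in
#' thalli hosting more than one photobiont.
#'
#' @param profile named numeric vector of template relative abundances
#'   (nonzero entries must name panel OTUs; fractions sum to 1).
#' @param panel an `otu_panel` (templates are pre-aligned, equal length).
#' @param config a [sim_config()] (noise sd).
#' @param marker `"full_ITS"` for the whole template, `"ITS2_only"` for the
#'   ITS2 region plus its anchor motifs (the metabarcoding amplicon).
#' @param sample_id label carried through to the called sequence.
#' @param seed optional integer seed for the noise draw; `NULL` (default)
#'   draws from the current RNG stream, so callers looping over samples
#'   seed once outside the loop.
#' @return object of class `chromatogram`: list with `heights` (positions x
#'   4 matrix, columns A/C/G/T), `positions` (template coordinates),
#'   `marker`, `sample_id`.
#' @export
simulate_chromatogram <- function(profile, panel, config,
                                  marker = c("full_ITS", "ITS2_only"),
                                  sample_id = "S1", seed = NULL) {
  marker <- match.arg(marker)
  stopifnot(inherits(panel, "otu_panel"))
  if (abs(sum(profile) - 1) > 1e-9) stop("profile fractions must sum to 1")
  active <- names(profile)[profile > 0]
  bad <- setdiff(active, panel$otu_ids)
  if (length(bad)) stop("profile references unknown OTU(s): ",
                        paste(bad, collapse = ", "))
  lens <- unique(nchar(panel$sequences[active]))
  if (length(lens) != 1L) stop("panel sequences must have equal length")

  ml <- nchar(panel$anchors$its2_start_motif)
  pos <- if (marker == "full_ITS") seq_len(lens) else
    (panel$its2_span[1] - ml):(min(lens, panel$its2_span[2] + ml))
  H <- matrix(0, nrow = length(pos), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (otu in active) {
    chars <- strsplit(substr(panel$sequences[[otu]], pos[1], pos[length(pos)]),
                      "", fixed = TRUE)[[1]]
    idx <- cbind(seq_along(pos), match(chars, c("A", "C", "G", "T")))
    H[idx] <- H[idx] + profile[[otu]]
  }
  if (config$chromatogram_noise_sd > 0) {
    add_noise <- function() {
      pmax(H * (1 + rnorm(length(H), 0, config$chromatogram_noise_sd)), 0)
    }
    H <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  }
  structure(list(heights = H, positions = as.integer(pos), marker = marker,
                 sample_id = sample_id),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("Chromatogram", x$sample_id, sprintf("(%s):", x$marker),
      nrow(x$heights), "positions\n")
  invisible(x)
}

#' Read / write chromatograms as TSV
#'
#' Plain-text trace dialect: comment header lines starting with `#`
#' (recording marker, sample id and, when given, the seed), then columns
#' `position`, `A`, `C`, `G`, `T`.
#'
#' @param chrom a `chromatogram`.
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @return `write_chromatogram` returns `path` invisibly;
#'   `read_chromatogram` returns a `chromatogram`.
#' @export
write_chromatogram <- function(chrom, path, seed = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  hdr <- c(sprintf("# sample_id: %s", chrom$sample_id),
           sprintf("# marker: %s", chrom$marker),
           if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
  df <- data.frame(position = chrom$positions,
                   A = chrom$heights[, "A"], C = chrom$heights[, "C"],
                   G = chrom$heights[, "G"], T = chrom$heights[, "T"])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1])) else NA
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("malformed chromatogram TSV: need columns ",
         paste(need, collapse = ", "))
  H <- as.matrix(df[, c("A", "C", "G", "T")])
  if (any(H < 0)) stop("negative peak height in ", path)
  marker <- field("marker")
  structure(list(heights = H, positions = as.integer(df$position),
                 marker = if (is.na(marker)) "full_ITS" else marker,
                 sample_id = if (is.na(field("sample_id"))) "S1"
                             else field("sample_id")),
            class = "chromatogram")
}
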