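# FASTA and TSV interfaces. FASTA parsing/writing is delegated to
# Biostrings; these wrappers add the pipeline's validation (unique ids,
# IUPAC alphabet, negative counts) and fix the dialects.

#' Read / write FASTA
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @param width line-wrap width (fixed dialect, default 70).
#' @return `read_fasta` returns a named character vector; duplicate record
#'   ids are rejected by name. `write_fasta` returns `path` invisibly;
#'   `read_fasta(write_fasta(x))` is the identity on ids and sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) iupac_mask(seqs[[i]])  # alphabet check
  setNames(seqs, ids)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write an OTU count table as TSV
#'
#' Dialect: optional `#`-prefixed header comment lines (seed, provenance),
#' then a header row whose first column is `sample_id` followed by OTU ids;
#' one row per sample. `transposed = TRUE` reads/writes OTUs in rows.
#'
#' @param path file path.
#' @param table an [otu_table()].
#' @param transposed orientation flag.
#' @param seed optional seed recorded as a header comment.
#' @return `read_otu_table` returns an [otu_table()]; malformed input
#'   (negative or non-numeric counts, duplicate ids) is rejected.
#' @export
read_otu_table <- function(path, transposed = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed OTU table: need id column plus counts")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed OTU table: non-numeric counts")
  if (any(m < 0)) stop("negative count in ", path)
  rownames(m) <- ids
  if (transposed) m <- t(m)
  otu_table(m)
}

#' @rdname read_otu_table
#' @export
write_otu_table <- function(table, path, transposed = FALSE, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  m <- if (transposed) t(table$counts) else table$counts
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (transposed) "otu_id" else "sample_id"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (length(table$filter_log))
    writeLines(paste0("# filter: ", table$filter_log), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed-dialect numeric TSV writer used for fraction matrices
write_matrix_tsv <- function(m, path, id_col = "sample_id", seed = NULL) {
  df <- data.frame(id = rownames(m),
                   format(m, digits = 12, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
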