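# Hand-built three-OTU panel (40 nt) used by unit tests, constructed
# directly rather than via generate_otu_panel so the two sides stay
# independent. Layout: AAGTAC | ITS1(8) | CCGGAAAATTAA | ITS2(8) | GGCCAT;
# anchors GTAC / CCGG / TTAA / GGCC each occur exactly once per sequence.
tiny_panel <- function() {
  its1 <- c(OTU1 = "ACACACAC", OTU2 = "ACACGCAT", OTU3 = "ATACACGC")
  its2 <- c(OTU1 = "GAGAGAGA", OTU2 = "GAGTGAGC", OTU3 = "GCGAGACA")
  seqs <- setNames(paste0("AAGTAC", its1, "CCGGAAAATTAA", its2, "GGCCAT"),
                   names(its1))
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  varsites <- sort(unique(unlist(lapply(combn(3, 2, simplify = FALSE),
    function(p) which(chars[[p[1]]] != chars[[p[2]]])))))
  structure(list(
    otu_ids = names(seqs),
    sequences = seqs,
    its1_span = c(7L, 14L),
    r58s_span = c(15L, 26L),
    its2_span = c(27L, 34L),
    anchors = sangermeta::region_anchors("GTAC", "CCGG", "TTAA", "GGCC"),
    variable_sites = varsites,
    private_sites = NULL,
    seed = NA_integer_), class = "otu_panel")
}

tiny_config <- function(...) {
  defaults <- list(n_otus = 3L, n_samples = 10L, seq_length = 600L,
                   hts_depth = 1000L, rng_seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# chromatogram object built directly from a heights matrix
make_chrom <- function(H, marker = "full_ITS", sample_id = "S1",
                       positions = seq_len(nrow(H))) {
  colnames(H) <- c("A", "C", "G", "T")
  structure(list(heights = H, positions = as.integer(positions),
                 marker = marker, sample_id = sample_id),
            class = "chromatogram")
}

# noise-free chromatogram for a mixture of plain sequences (equal length)
mix_chrom <- function(seqs, fracs, ...) {
  stopifnot(length(seqs) == length(fracs))
  n <- nchar(seqs[1])
  H <- matrix(0, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in seq_along(seqs)) {
    ch <- strsplit(seqs[k], "")[[1]]
    idx <- cbind(seq_len(n), match(ch, c("A", "C", "G", "T")))
    H[idx] <- H[idx] + fracs[k]
  }
  make_chrom(H, ...)
}
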