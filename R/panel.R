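#' Region anchor motifs
#'
#' Short conserved flanking motifs shared by all panel references, used to
#' locate ITS1 and ITS2 inside a called sequence (a deterministic stand-in
#' for HMM-based ITS extraction; real data should be pre-extracted with
#' ITSx). Each motif must occur exactly once in every panel reference.
#'
#' @param its1_start_motif,its1_end_motif,its2_start_motif,its2_end_motif
#'   nucleotide strings over A/C/G/T.
#' @return object of class `region_anchors`.
#' @export
region_anchors <- function(its1_start_motif, its1_end_motif,
                           its2_start_motif, its2_end_motif) {
  m <- list(its1_start_motif = its1_start_motif,
            its1_end_motif = its1_end_motif,
            its2_start_motif = its2_start_motif,
            its2_end_motif = its2_end_motif)
  for (nm in names(m)) {
    if (!is.character(m[[nm]]) || length(m[[nm]]) != 1L || nchar(m[[nm]]) < 4L)
      stop(nm, " must be a single nucleotide string of length >= 4")
    iupac_mask(m[[nm]])  # validates alphabet
  }
  structure(m, class = "region_anchors")
}

# region layout for a template of length L (1-based inclusive spans)
its_layout <- function(L, motif_length) {
  flank5 <- max(motif_length + 2L, round(L / 30))
  its1_len <- round(0.30 * L)
  r58s_len <- round(0.27 * L)
  its2_len <- round(0.33 * L)
  flank3 <- L - flank5 - its1_len - r58s_len - its2_len
  if (flank3 < motif_length || r58s_len < 2L * motif_length + 2L)
    stop("seq_length too short for the requested motif_length")
  its1 <- c(flank5 + 1L, flank5 + its1_len)
  r58s <- c(its1[2] + 1L, its1[2] + r58s_len)
  its2 <- c(r58s[2] + 1L, r58s[2] + its2_len)
  list(its1_span = its1, r58s_span = r58s, its2_span = its2)
}

#' Generate a panel of OTU reference haplotypes
#'
#' Builds `n_otus` equal-length full-ITS references (ITS1-5.8S-ITS2 with
#' conserved flanks) from one ancestral sequence by giving each OTU its own
#' private substitutions inside ITS1 and ITS2. Substitution positions are
#' disjoint across OTUs, so every pair differs at >= `n_variable_sites`
#' positions within ITS1 and within ITS2, while full-length pairwise
#' identity stays within [95%, 99%): mutually comparable under a 95% search
#' floor yet discriminable under a 99% acceptance rule. The 5.8S and the
#' flanking anchor motifs are identical across the panel, so anchor-based
#' region extraction is well defined.
#'
#' @param config a [sim_config()].
#' @return object of class `otu_panel`: list with `otu_ids`, `sequences`
#'   (named character), the shared `its1_span`/`r58s_span`/`its2_span`
#'   (1-based inclusive), `anchors` ([region_anchors()]), `variable_sites`
#'   (all diagnostic positions), `private_sites` (per OTU), and `seed`.
#' @examples
#' panel <- generate_otu_panel(sim_config(n_otus = 3, rng_seed = 7))
#' nchar(panel$sequences)
#' @export
generate_otu_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_otus < 2L)
    stop("panel needs at least 2 OTUs (n_otus >= 2)")
  L <- config$seq_length
  lay <- its_layout(L, config$motif_length)
  its1 <- lay$its1_span; its2 <- lay$its2_span

  # per-OTU substitutions per region: at least n_variable_sites, and enough
  # that total pairwise divergence 4*m pushes identity strictly below 99%
  m_region <- max(config$n_variable_sites,
                  ceiling((floor(0.01 * L) + 1) / 4))
  its1_len <- its1[2] - its1[1] + 1L
  its2_len <- its2[2] - its2[1] + 1L
  if (config$n_otus * m_region > min(its1_len, its2_len) ||
      4 * m_region > floor(0.05 * L))
    stop("config infeasible: cannot place ", m_region,
         " private variable sites per OTU per region within sequence length ",
         L, " while keeping pairwise identity >= 95%")

  seed <- derive_seed(config$rng_seed, "panel")
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    for (attempt in 1:100) {
      anc <- sample(bases, L, replace = TRUE)
      pos1 <- sample(its1[1]:its1[2], config$n_otus * m_region)
      pos2 <- sample(its2[1]:its2[2], config$n_otus * m_region)
      seqs <- character(config$n_otus)
      private <- vector("list", config$n_otus)
      for (k in seq_len(config$n_otus)) {
        idx <- ((k - 1L) * m_region + 1L):(k * m_region)
        pk <- sort(c(pos1[idx], pos2[idx]))
        s <- anc
        for (p in pk) s[p] <- sample(setdiff(bases, anc[p]), 1L)
        seqs[k] <- paste(s, collapse = "")
        private[[k]] <- pk
      }
      ml <- config$motif_length
      anc_str <- paste(anc, collapse = "")
      anchors <- region_anchors(
        its1_start_motif = substr(anc_str, its1[1] - ml, its1[1] - 1L),
        its1_end_motif   = substr(anc_str, its1[2] + 1L, its1[2] + ml),
        its2_start_motif = substr(anc_str, its2[1] - ml, its2[1] - 1L),
        its2_end_motif   = substr(anc_str, its2[2] + 1L, its2[2] + ml))
      unique_everywhere <- all(vapply(seqs, function(s)
        all(vapply(anchors, function(mo)
          length(find_motif(s, mo)) == 1L, TRUE)), TRUE))
      if (unique_everywhere) break
      if (attempt == 100) stop("could not generate a panel with unique anchor motifs")
    }
    ids <- paste0("OTU", seq_len(config$n_otus))
    names(seqs) <- ids
    names(private) <- ids
    structure(list(otu_ids = ids,
                   sequences = seqs,
                   its1_span = its1,
                   r58s_span = lay$r58s_span,
                   its2_span = its2,
                   anchors = anchors,
                   variable_sites = sort(unique(unlist(private))),
                   private_sites = private,
                   seed = seed),
              class = "otu_panel")
  })
}

#' @export
print.otu_panel <- function(x, ...) {
  cat("OTU reference panel:", length(x$otu_ids), "haplotypes of",
      nchar(x$sequences[[1]]), "nt\n")
  cat("  ITS1 span:", x$its1_span[1], "-", x$its1_span[2],
      " 5.8S:", x$r58s_span[1], "-", x$r58s_span[2],
      " ITS2:", x$its2_span[1], "-", x$its2_span[2], "\n")
  cat("  diagnostic sites:", length(x$variable_sites), "\n")
  invisible(x)
}

# region sequence of one reference (or all) for "full_ITS", "ITS1", "ITS2"
panel_region_seqs <- function(panel, region = c("full_ITS", "ITS1", "ITS2")) {
  region <- match.arg(region)
  if (region == "full_ITS") return(panel$sequences)
  span <- if (region == "ITS1") panel$its1_span else panel$its2_span
  vapply(panel$sequences, substr, "", span[1], span[2])
}
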