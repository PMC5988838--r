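#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults describe the
#' study design being emulated: 240 thalli (2 species x 6 sites x 20
#' individuals), a panel of 6 closely related *Trebouxia* ITS haplotypes
#' differing at >= 3 diagnostic sites per subregion, and per-sample
#' communities with one predominant photobiont and 0-2 minor ones.
#'
#' @param n_otus number of OTU reference haplotypes in the panel (>= 2).
#' @param n_samples number of simulated thalli.
#' @param n_variable_sites minimum number of diagnostic substitution sites
#'   between any two panel members, separately within ITS1 and within ITS2.
#' @param seq_length full ITS template length in nt (ITS1-5.8S-ITS2 plus
#'   short conserved SSU/LSU flanks).
#' @param hts_depth metabarcoding reads per sample.
#' @param category_design probabilities of the five secondary-abundance
#'   categories (secondary photobiont at 0%, (0,10], (10,20], (20,30],
#'   (30,50)% of the community). Normalised to sum to 1. Defaults anchor
#'   category 1 and 5 at the observed 61/240 and 16/240, remainder split
#'   equally.
#' @param p_tertiary probability that a sample with a secondary photobiont
#'   also carries a third, rarer one.
#' @param chromatogram_noise_sd relative (multiplicative Gaussian) peak
#'   intensity noise; 0 disables noise.
#' @param hts_error_rate per-base substitution probability of the sequencer;
#'   converted internally to an OTU-level cross-assignment probability (a
#'   read changes OTU only if errors flip at least half of the diagnostic
#'   sites separating two panel members).
#' @param cross_assignment_prob optional direct override of the count-level
#'   cross-assignment probability (NULL = derive from `hts_error_rate`).
#' @param motif_length length of the conserved anchor motifs used for
#'   ITS1/ITS2 extraction.
#' @param rng_seed integer seed; every stochastic stage derives its own
#'   substream from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_otus = 6L,
                       n_samples = 240L,
                       n_variable_sites = 3L,
                       seq_length = 600L,
                       hts_depth = 10000L,
                       category_design = c(61, 163 / 3, 163 / 3, 163 / 3, 16) / 240,
                       p_tertiary = 0.1,
                       chromatogram_noise_sd = 0.05,
                       hts_error_rate = 1e-3,
                       cross_assignment_prob = NULL,
                       motif_length = 12L,
                       rng_seed = 1L) {
  stopifnot(n_otus >= 1L, n_samples >= 0L, n_variable_sites >= 1L,
            seq_length >= 100L, hts_depth >= 0L, motif_length >= 4L)
  if (length(category_design) != 5L || any(category_design < 0) ||
      sum(category_design) <= 0)
    stop("category_design must be 5 non-negative weights")
  if (p_tertiary < 0 || p_tertiary >= 1) stop("p_tertiary must be in [0,1)")
  if (chromatogram_noise_sd < 0) stop("chromatogram_noise_sd must be >= 0")
  if (hts_error_rate < 0 || hts_error_rate >= 1)
    stop("hts_error_rate must be in [0,1)")
  if (!is.null(cross_assignment_prob) &&
      (cross_assignment_prob < 0 || cross_assignment_prob >= 1))
    stop("cross_assignment_prob must be in [0,1)")
  structure(list(
    n_otus = as.integer(n_otus),
    n_samples = as.integer(n_samples),
    n_variable_sites = as.integer(n_variable_sites),
    seq_length = as.integer(seq_length),
    hts_depth = as.integer(hts_depth),
    category_design = category_design / sum(category_design),
    p_tertiary = p_tertiary,
    chromatogram_noise_sd = chromatogram_noise_sd,
    hts_error_rate = hts_error_rate,
    cross_assignment_prob = cross_assignment_prob,
    motif_length = as.integer(motif_length),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

#' OTU-table filter configuration
#'
#' @param abundance_floor per-sample relative abundance threshold; OTU
#'   counts strictly below `abundance_floor` times the sample's total are
#'   zeroed. Default 5e-5 (0.005% of the sample's reads).
#' @param prevalence_floor fraction-of-samples threshold; OTUs present
#'   (nonzero after the abundance filter) in fewer than
#'   `ceiling(prevalence_floor * n_samples)` samples are dropped. Default 5%.
#' @param rescue_predominant if TRUE, OTUs removed by the prevalence filter
#'   are restored when they are the strictly most abundant OTU in at least
#'   one sample (the recommended guard against over-filtering biologically
#'   dominant taxa).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(abundance_floor = 5e-5,
                          prevalence_floor = 0.05,
                          rescue_predominant = FALSE) {
  stopifnot(abundance_floor >= 0, abundance_floor < 1,
            prevalence_floor >= 0, prevalence_floor < 1,
            is.logical(rescue_predominant), length(rescue_predominant) == 1L)
  structure(list(abundance_floor = abundance_floor,
                 prevalence_floor = prevalence_floor,
                 rescue_predominant = isTRUE(rescue_predominant)),
            class = "filter_config")
}

#' Pipeline configuration
#'
#' Houses every numeric threshold of the workflow exactly once: 25%
#' secondary-peak ratio for ambiguity calling, 95% identity floor and 99%
#' acceptance for OTU assignment, 99% clustering identity, and the
#' best-vs-second-best identity margin.
#'
#' @param simulation a [sim_config()].
#' @param filters a [filter_config()].
#' @param secondary_peak_threshold ratio in (0,1); a position is ambiguous
#'   when the second peak exceeds this fraction of the maximal peak.
#' @param identity_floor percent identity below which hits are discarded.
#' @param identity_accept percent identity required to accept an assignment.
#' @param clustering_identity percent identity for greedy ITS1 clustering.
#' @param margin minimum best-minus-second-best identity (percentage
#'   points) for a "clear" best hit.
#' @param min_length_fraction QC length floor as fraction of expected
#'   marker length.
#' @param output_dir directory where [run_pipeline()] writes its outputs.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            filters = filter_config(),
                            secondary_peak_threshold = 0.25,
                            identity_floor = 95,
                            identity_accept = 99,
                            clustering_identity = 99,
                            margin = 0.5,
                            min_length_fraction = 0.9,
                            output_dir = tempfile("sangermeta_run_")) {
  stopifnot(inherits(simulation, "sim_config"),
            inherits(filters, "filter_config"),
            secondary_peak_threshold > 0, secondary_peak_threshold < 1,
            identity_floor >= 0, identity_floor <= 100,
            identity_accept >= identity_floor, identity_accept <= 100,
            clustering_identity > 0, clustering_identity <= 100,
            margin >= 0, min_length_fraction > 0, min_length_fraction <= 1)
  structure(list(simulation = simulation,
                 filters = filters,
                 secondary_peak_threshold = secondary_peak_threshold,
                 identity_floor = identity_floor,
                 identity_accept = identity_accept,
                 clustering_identity = clustering_identity,
                 margin = margin,
                 min_length_fraction = min_length_fraction,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (JSON)
#'
#' Round-trips losslessly: `read_pipeline_config(write_pipeline_config(x, f))`
#' reproduces `x`.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- rapply(unclass(config), function(v) v, how = "list")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  drop_void <- function(l) l[!vapply(l, function(v)
    is.null(v) || length(v) == 0L || (length(v) == 1L && is.na(v)), TRUE)]
  sim <- do.call(sim_config, drop_void(x$simulation))
  flt <- do.call(filter_config, x$filters)
  rest <- x[setdiff(names(x), c("simulation", "filters"))]
  do.call(pipeline_config, c(list(simulation = sim, filters = flt), rest))
}
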