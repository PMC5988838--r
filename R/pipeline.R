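#' Run the full simulated Sanger-vs-metabarcoding experiment
#'
#' Executes every stage end to end: reference-panel generation, community
#' simulation, metabarcoding counts, OTU-table filtering, per-sample
#' chromatogram simulation and base calling for both Sanger datasets (full
#' ITS and ITS2-only), QC, OTU assignment (full ITS, ITS2, and ITS1
#' extracted from the full sequences), abundance categorisation,
#' per-category concordance summaries, greedy ITS1 clustering, and the
#' ITS1-vs-ITS2 resolution comparison. All stage outputs are written to
#' `config$output_dir` as FASTA/TSV plus a JSON manifest recording the
#' config, seed, package version and per-file checksums; re-running with an
#' identical config reproduces identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) object of class `sangermeta_run`: list with the
#'   in-memory stage results (`panel`, `communities`, `table_raw`,
#'   `table_filtered`, `categories`, `qc`, `assignments`, `concordance`,
#'   `clusters`, `resolution`), the `manifest`, and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$simulation
  if (sim$n_samples < 1L) stop("validation: n_samples must be >= 1")
  if (sim$n_otus < 2L) stop("validation: n_otus must be >= 2")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("output_dir is not writable: ", out)
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(out, name)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  log_line <- function(...) message(sprintf(...))

  panel <- stage("generate", generate_otu_panel(sim))
  write_fasta(panel$sequences, emit("panel.fasta"))
  log_line("[generate] %d OTUs x %d nt", length(panel$otu_ids),
           nchar(panel$sequences[[1]]))

  communities <- stage("simulate_communities", simulate_communities(panel, sim))
  write_matrix_tsv(communities$fractions, emit("communities.tsv"),
                   seed = sim$rng_seed)

  table_raw <- stage("simulate_hts", simulate_hts_table(communities, panel, sim))
  write_otu_table(table_raw, emit("otu_counts.tsv"), seed = sim$rng_seed)

  table_filtered <- stage("filter", apply_filters(table_raw, config$filters))
  write_otu_table(table_filtered, emit("otu_counts_filtered.tsv"),
                  seed = sim$rng_seed)
  log_line("[filter] %d -> %d OTUs (abundance floor %g, prevalence floor %g%s)",
           ncol(table_raw$counts), ncol(table_filtered$counts),
           config$filters$abundance_floor, config$filters$prevalence_floor,
           if (config$filters$rescue_predominant) ", rescue on" else "")

  rel <- stage("categorize", relative_abundances(table_filtered))
  categories <- stage("categorize", categorize_table(rel))
  utils::write.table(categories, emit("categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # one chromatogram per sample per marker, all under one derived stream
  ml <- nchar(panel$anchors$its2_start_motif)
  expected <- c(full_ITS = sim$seq_length,
                ITS2_only = (panel$its2_span[2] - panel$its2_span[1] + 1L) + 2L * ml)
  called <- stage("basecall", withr::with_seed(
    derive_seed(sim$rng_seed, "chromatograms"), {
      lapply(seq_len(nrow(communities$fractions)), function(i) {
        sid <- rownames(communities$fractions)[i]
        prof <- communities$fractions[i, ]
        lapply(c("full_ITS", "ITS2_only"), function(mk) {
          ch <- simulate_chromatogram(prof, panel, sim, marker = mk,
                                      sample_id = sid)
          qc_sequence(call_bases(ch, config$secondary_peak_threshold),
                      expected_length = expected[[mk]],
                      min_length_fraction = config$min_length_fraction)
        })
      })
    }))
  called_full <- lapply(called, `[[`, 1L)
  called_its2 <- lapply(called, `[[`, 2L)
  qc <- rbind(qc_df(called_full), qc_df(called_its2))
  utils::write.table(qc, emit("qc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_line("[basecall] QC pass: %d/%d (full ITS), %d/%d (ITS2)",
           sum(qc$qc_status == "pass" & qc$marker == "full_ITS"),
           length(called_full),
           sum(qc$qc_status == "pass" & qc$marker == "ITS2_only"),
           length(called_its2))
  pass_full <- Filter(function(x) x$qc_status == "pass", called_full)
  write_fasta(setNames(vapply(pass_full, `[[`, "", "bases"),
                       vapply(pass_full, `[[`, "", "sample_id")),
              emit("called_full_ITS.fasta"))
  pass_its2 <- Filter(function(x) x$qc_status == "pass", called_its2)
  write_fasta(setNames(vapply(pass_its2, `[[`, "", "bases"),
                       vapply(pass_its2, `[[`, "", "sample_id")),
              emit("called_ITS2.fasta"))

  assign_all <- function(calls, region, marker_label) {
    df <- assignment_df(lapply(calls, assign_to_otu, panel = panel,
                               region = region,
                               floor = config$identity_floor,
                               accept = config$identity_accept,
                               margin = config$margin))
    df$marker <- marker_label
    df
  }
  asg_full <- stage("assign", assign_all(called_full, "full_ITS", "full_ITS"))
  asg_its2 <- stage("assign", assign_all(called_its2, "ITS2", "ITS2_only"))
  asg_its1 <- stage("assign", assign_all(called_full, "ITS1", "ITS1"))
  assignments <- rbind(asg_full, asg_its2, asg_its1)
  utils::write.table(assignments, emit("assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  conc <- stage("concordance", concordance_table(
    rbind(asg_full, asg_its2), categories, qc))
  utils::write.table(conc$per_marker, emit("concordance_per_marker.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(conc$per_category, emit("concordance_per_category.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(conc$long, emit("success_by_category_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("[concordance] success rates: %s",
           paste(sprintf("%s=%.2f%%", conc$per_marker$marker,
                         conc$per_marker$success_rate), collapse = ", "))

  # ITS1 subregion sequences of QC-passed full-ITS calls, clustered greedily
  its1_seqs <- stage("cluster", {
    xs <- lapply(pass_full, function(x)
      extract_regions(x, panel$anchors, regions = "ITS1"))
    ok <- vapply(xs, function(e) length(e$failed) == 0L, TRUE)
    setNames(vapply(xs[ok], function(e) e$regions$ITS1, ""),
             vapply(pass_full[ok], `[[`, "", "sample_id"))
  })
  clusters <- if (length(its1_seqs))
    greedy_cluster(its1_seqs, identity_threshold = config$clustering_identity)
  else NULL
  if (!is.null(clusters))
    utils::write.table(clusters$membership, emit("its1_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  resolution <- stage("resolution", resolution_comparison(
    asg_its1, asg_its2,
    categories[, c("sample_id", "dominant_otu")]))
  utils::write.table(resolution$table, emit("resolution_its1_vs_its2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "sangermeta",
    version = as.character(utils::packageVersion("sangermeta")),
    seed = sim$rng_seed,
    config = rapply(unclass(config), function(v) v, how = "list"),
    n_samples = sim$n_samples,
    stage_counts = list(
      otus_raw = ncol(table_raw$counts),
      otus_filtered = ncol(table_filtered$counts),
      qc_pass_full_ITS = length(pass_full),
      qc_pass_ITS2 = length(pass_its2),
      its1_clusters = if (is.null(clusters)) 0L else clusters$n_clusters),
    checksums = as.list(tools::md5sum(unlist(paths))))
  names(manifest$checksums) <- names(paths)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  paths[["manifest.json"]] <- file.path(out, "manifest.json")

  invisible(structure(list(panel = panel, communities = communities,
                           table_raw = table_raw,
                           table_filtered = table_filtered,
                           categories = categories, qc = qc,
                           called_full = called_full,
                           called_its2 = called_its2,
                           assignments = assignments,
                           concordance = conc, clusters = clusters,
                           resolution = resolution,
                           manifest = manifest, paths = paths),
                      class = "sangermeta_run"))
}

#' @export
print.sangermeta_run <- function(x, ...) {
  cat("sangermeta pipeline run:", x$manifest$n_samples, "samples, seed",
      x$manifest$seed, "\n")
  print(x$concordance)
  invisible(x)
}
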