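#' Simulate per-thallus photobiont communities
#'
#' Draws, for each sample, a secondary-abundance category from the
#' configured design, a dominant OTU (the first `n_otus` samples cycle
#' through the panel so every OTU is predominant in at least one sample), a
#' secondary OTU fraction uniform within the category's bin (category 1:
#' exactly 0; 2: (0,10]%; 3: (10,20]%; 4: (20,30]%; 5: (30,50)%), and with
#' probability `p_tertiary` a third, rarer OTU. Fractions sum to 1, at most
#' three OTUs are nonzero, and the dominant OTU has a strictly unique
#' maximum by construction.
#'
#' @param panel an [generate_otu_panel()] result.
#' @param config a [sim_config()].
#' @return object of class `community_set`: list with `fractions`
#'   (n_samples x n_otus matrix, rows = samples, true relative abundances),
#'   `design_category` (integer 1-5), `design_secondary` (designed secondary
#'   fraction), `dominant_otu`, and `seed`.
#' @export
simulate_communities <- function(panel, config) {
  stopifnot(inherits(panel, "otu_panel"), inherits(config, "sim_config"))
  n <- config$n_samples
  k <- length(panel$otu_ids)
  if (k < 1L) stop("panel is empty")
  seed <- derive_seed(config$rng_seed, "communities")
  withr::with_seed(seed, {
    fr <- matrix(0, nrow = n, ncol = k,
                 dimnames = list(sprintf("S%04d", seq_len(n)), panel$otu_ids))
    cat_design <- integer(n)
    sec <- numeric(n)
    dom <- character(n)
    if (n == 0L) {
      return(structure(list(fractions = fr, design_category = cat_design,
                            design_secondary = sec, dominant_otu = dom,
                            seed = seed), class = "community_set"))
    }
    cats <- sample.int(5L, n, replace = TRUE, prob = config$category_design)
    for (i in seq_len(n)) {
      d <- if (i <= k) i else sample.int(k, 1L)
      f2 <- switch(cats[i],
                   0,
                   runif(1, 0, 0.10),
                   runif(1, 0.10, 0.20),
                   runif(1, 0.20, 0.30),
                   runif(1, 0.30, 0.50))
      f3 <- 0
      others <- setdiff(seq_len(k), d)
      o2 <- o3 <- NA_integer_
      if (f2 > 0 && k >= 2L) {
        o2 <- if (length(others) == 1L) others else sample(others, 1L)
        if (k >= 3L && runif(1) < config$p_tertiary) {
          f3max <- 0.9 * min(f2, 1 - 2 * f2)
          if (f3max > 1e-6) {
            f3 <- runif(1, 0, f3max)
            rest <- setdiff(others, o2)
            o3 <- if (length(rest) == 1L) rest else sample(rest, 1L)
          }
        }
      } else f2 <- 0
      f1 <- 1 - f2 - f3
      stopifnot(f1 > f2)  # unique maximum by construction
      fr[i, d] <- f1
      if (f2 > 0) fr[i, o2] <- f2
      if (f3 > 0) fr[i, o3] <- f3
      cat_design[i] <- if (f2 == 0) 1L else cats[i]
      sec[i] <- f2
      dom[i] <- panel$otu_ids[d]
    }
    structure(list(fractions = fr, design_category = cat_design,
                   design_secondary = sec, dominant_otu = dom, seed = seed),
              class = "community_set")
  })
}

#' @export
print.community_set <- function(x, ...) {
  cat("Simulated communities:", nrow(x$fractions), "samples x",
      ncol(x$fractions), "OTUs\n")
  cat("  category counts:",
      paste(sprintf("cat%d=%d", 1:5, tabulate(x$design_category, 5L)),
            collapse = " "), "\n")
  invisible(x)
}

# count-level cross-assignment probability implied by a per-base error
# rate: a read switches OTU only if errors flip >= half of the diagnostic
# sites separating the two closest panel members.
cross_assignment_prob <- function(panel, config) {
  if (!is.null(config$cross_assignment_prob))
    return(config$cross_assignment_prob)
  if (config$hts_error_rate == 0 || length(panel$otu_ids) < 2L) return(0)
  seqs <- strsplit(unname(panel$sequences), "", fixed = TRUE)
  dmin <- Inf
  for (i in seq_along(seqs)) for (j in seq_len(i - 1L))
    dmin <- min(dmin, sum(seqs[[i]] != seqs[[j]]))
  kk <- ceiling(dmin / 2)
  min(1, choose(dmin, kk) * config$hts_error_rate^kk)
}

#' Simulate metabarcoding read counts for one community profile
#'
#' A multinomial draw of `hts_depth` reads over the profile's fractions,
#' followed by symmetric count-level cross-assignment with the (usually
#' negligible) probability implied by `hts_error_rate` (see
#' [sim_config()]). Counts always sum to `hts_depth`.
#'
#' @param profile named numeric vector of relative abundances (one sample),
#'   names in `panel$otu_ids`, summing to 1.
#' @param panel an `otu_panel`.
#' @param config a [sim_config()].
#' @param seed optional integer seed; `NULL` (default) draws from the
#'   current RNG stream.
#' @return named integer count vector over the panel's OTUs.
#' @export
simulate_hts_counts <- function(profile, panel, config, seed = NULL) {
  stopifnot(inherits(panel, "otu_panel"))
  if (config$hts_depth <= 0L) stop("hts_depth must be > 0")
  if (abs(sum(profile) - 1) > 1e-9) stop("profile fractions must sum to 1")
  bad <- setdiff(names(profile)[profile > 0], panel$otu_ids)
  if (length(bad)) stop("profile references unknown OTU(s): ",
                        paste(bad, collapse = ", "))
  p <- setNames(numeric(length(panel$otu_ids)), panel$otu_ids)
  p[names(profile)] <- profile
  pc <- cross_assignment_prob(panel, config)
  if (is.null(seed)) draw_counts(p, config$hts_depth, pc)
  else withr::with_seed(seed, draw_counts(p, config$hts_depth, pc))
}

draw_counts <- function(p, depth, p_cross) {
  k <- length(p)
  counts <- as.integer(rmultinom(1, depth, p)[, 1])
  if (p_cross > 0 && k >= 2L) {
    moved <- rbinom(k, counts, p_cross)
    counts <- counts - moved
    for (i in seq_len(k)) if (moved[i] > 0L) {
      dest <- rmultinom(1, moved[i], rep(1 / (k - 1L), k - 1L))[, 1]
      counts[-i] <- counts[-i] + dest
    }
  }
  setNames(counts, names(p))
}

#' Simulate the full metabarcoding count table
#'
#' Applies [simulate_hts_counts()] to every sample of a community set under
#' a single derived random stream and returns an [otu_table()].
#'
#' @param communities a [simulate_communities()] result.
#' @param panel an `otu_panel`.
#' @param config a [sim_config()].
#' @return an [otu_table()] (samples x OTUs).
#' @export
simulate_hts_table <- function(communities, panel, config) {
  stopifnot(inherits(communities, "community_set"))
  if (config$hts_depth <= 0L) stop("hts_depth must be > 0")
  pc <- cross_assignment_prob(panel, config)
  seed <- derive_seed(config$rng_seed, "hts")
  fr <- communities$fractions
  withr::with_seed(seed, {
    counts <- t(apply(fr, 1L, draw_counts, depth = config$hts_depth,
                      p_cross = pc))
  })
  colnames(counts) <- colnames(fr)
  otu_table(counts)
}
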