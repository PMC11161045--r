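#' Backward-time demographic history of one species
#'
#' Converts a species' recorded abundance trajectory into a piecewise-
#' constant haploid effective-size function, `Ne(t) = alpha * abundance(t)`,
#' with time measured backward from the end of the forward simulation.
#' Consecutive epochs with equal size are merged, so abundance change-points
#' are preserved exactly.  Times older than the species' (most recent)
#' colonization are mapped to a large panmictic source pool in which
#' remaining lineages coalesce.
#'
#' @param run an [simulate_community()] result.
#' @param species_id id of a species extant at the end of the run.
#' @param alpha abundance-to-Ne scaling; default taken from the run's
#'   parameters.
#' @param source_pool_size haploid size of the regional source pool.
#' @return An object of class `demographic_history`: epoch `duration`s (in
#'   generations, most recent first) with their `ne` values (each >= 1),
#'   plus `pool_ne` and the colonization generation.
#' @export
build_history <- function(run, species_id, alpha = NULL,
                          source_pool_size = 1e5) {
  alpha <- alpha %||% run$params$alpha
  sp <- run$species[run$species$species_id == species_id, ]
  if (nrow(sp) == 0)
    stop("species ", species_id, " is not extant at the end of the run")
  # colonization_gen is the *most recent* colonization: earlier residences of
  # the same (metacommunity) species are a different lineage and are excluded
  colgen <- sp$colonization_gen
  # >= : a colonization in the closing event of generation g has colgen == g,
  # and the generation-g snapshot already reflects the new residence
  tr <- run$trajectory[run$trajectory$species_id == species_id &
                         run$trajectory$generation >= colgen, ]
  tr <- tr[order(tr$generation), ]
  gens <- tr$generation
  ab <- tr$abundance
  end_gen <- run$generations
  if (length(gens) == 0) {
    # no snapshot within the current residence: fall back to the final count
    gens <- end_gen
    ab <- sp$abundance
  }
  # backward epoch over snapshot interval (g[i-1], g[i]] takes the abundance
  # recorded at g[i]; most recent epoch first
  durations <- rev(diff(gens))
  sizes <- rev(pmax(1, alpha * ab[-1]))
  if (length(gens) > 0 && end_gen > gens[length(gens)]) {
    durations <- c(end_gen - gens[length(gens)], durations)
    sizes <- c(max(1, alpha * ab[length(ab)]), sizes)
  }
  # oldest snapshot extends back to colonization (the founding species,
  # colgen = -1, extends to generation 0; older than that is the pool)
  oldest <- gens[1] - max(colgen, 0)
  if (oldest > 0) {
    durations <- c(durations, oldest)
    sizes <- c(sizes, max(1, alpha * ab[1]))
  }
  keep <- durations > 0
  durations <- durations[keep]
  sizes <- sizes[keep]
  if (length(durations) == 0) {
    durations <- numeric(0)
    sizes <- numeric(0)
  } else {
    r <- rle(sizes)
    durations <- as.numeric(tapply(durations,
                                   rep(seq_along(r$lengths), r$lengths), sum))
    sizes <- r$values
  }
  structure(list(species_id = species_id, duration = durations, ne = sizes,
                 pool_ne = source_pool_size,
                 colonization_gen = sp$colonization_gen, alpha = alpha),
            class = "demographic_history")
}

#' @export
print.demographic_history <- function(x, ...) {
  cat("Demographic history for species", x$species_id, ":",
      length(x$duration), "epochs,",
      "Ne range [", min(x$ne), ",", max(x$ne), "], pool", x$pool_ne, "\n")
  invisible(x)
}

#' Hand-built demographic history
#'
#' Convenience constructor for analyses and tests that need a history not
#' derived from a simulation (e.g. constant size or an explicit bottleneck).
#'
#' @param duration,ne epoch durations (generations, most recent first) and
#'   haploid sizes.
#' @param pool_ne source-pool size for lineages older than the epochs.
#' @return A `demographic_history`.
#' @export
demographic_history <- function(duration, ne, pool_ne = 1e5) {
  stopifnot(length(duration) == length(ne), all(ne >= 1), all(duration > 0))
  structure(list(species_id = NA, duration = as.numeric(duration),
                 ne = as.numeric(ne), pool_ne = pool_ne,
                 colonization_gen = NA, alpha = NA),
            class = "demographic_history")
}

#' Coalescent nucleotide diversity for one species
#'
#' Runs a single-population Hudson coalescent with piecewise-constant
#' haploid Ne, drops infinite-sites mutations on branches at rate
#' `mu_per_site * locus_length_bp` per generation, and returns the mean
#' pairwise difference per site over all haplotype pairs.  With constant
#' `Ne` the expectation is the haploid `theta = 2 * Ne * mu_per_site`.
#'
#' @param history a [build_history()] / [demographic_history()] object.
#' @param n_haplotypes sample size (>= 2); default emulates a small
#'   single-locus mtDNA survey.
#' @param mu_per_site per-site, per-generation mutation rate.
#' @param locus_length_bp locus length in base pairs.
#' @param seed optional integer seed.
#' @return An object of class `genetic_sample` (also a one-row list):
#'   `species_id`, `n_haplotypes`, `locus_length_bp`, `segregating_sites`,
#'   `pi` (per site) and `tmrca` (generations).
#' @export
simulate_pi <- function(history, n_haplotypes = 10, mu_per_site = 1e-7,
                        locus_length_bp = 570, seed = NULL) {
  stopifnot(inherits(history, "demographic_history"))
  if (n_haplotypes < 2) stop("'n_haplotypes' must be >= 2")
  if (mu_per_site < 0) stop("'mu_per_site' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_coalescent_pi(history$duration, history$ne, history$pool_ne,
                           as.integer(n_haplotypes), mu_per_site,
                           as.integer(locus_length_bp))
  structure(list(species_id = history$species_id,
                 n_haplotypes = as.integer(n_haplotypes),
                 locus_length_bp = as.integer(locus_length_bp),
                 segregating_sites = res$segregating_sites,
                 pi = res$pi, tmrca = res$tmrca),
            class = "genetic_sample")
}

#' Per-species genetic diversity table for a whole run
#'
#' Builds one demographic history per extant species and simulates one
#' genetic sample from each, giving the genetic-diversity data axis of the
#' simulation.  Deterministic under a fixed seed.
#'
#' @param run an [simulate_community()] result.
#' @param n_haplotypes,mu_per_site,locus_length_bp see [simulate_pi()].
#' @param source_pool_size see [build_history()].
#' @param seed optional integer seed.
#' @return Data frame: `species_id`, `abundance`, `pi`,
#'   `segregating_sites`, `n_haplotypes`.
#' @export
community_pi <- function(run, n_haplotypes = 10, mu_per_site = 1e-7,
                         locus_length_bp = 570, source_pool_size = 1e5,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- run$species
  out <- lapply(seq_len(nrow(sp)), function(i) {
    h <- build_history(run, sp$species_id[i],
                       source_pool_size = source_pool_size)
    g <- simulate_pi(h, n_haplotypes, mu_per_site, locus_length_bp)
    data.frame(species_id = sp$species_id[i], abundance = sp$abundance[i],
               pi = g$pi, segregating_sites = g$segregating_sites,
               n_haplotypes = g$n_haplotypes)
  })
  do.call(rbind, out)
}
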