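#' Hill number of an abundance distribution
#'
#' Effective number of species of order `q`: with `p` the normalized
#' counts, `(sum p_i^q)^(1/(1-q))`, and the limit
#' `exp(-sum p_i log p_i)` at `q = 1`.  `q = 0` gives species richness.
#'
#' @param counts positive abundance (or proportion) vector.
#' @param q diversity order (>= 0).
#' @return A value in `[1, length(counts)]`.
#' @export
hill_abundance <- function(counts, q) {
  if (!is.numeric(q) || length(q) != 1 || q < 0)
    stop("'q' must be a single non-negative number")
  stopifnot(length(counts) > 0, all(counts > 0))
  p <- counts / sum(counts)
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Hill number of a genetic-diversity distribution
#'
#' Applies the Hill formula to per-species nucleotide diversities
#' normalized to proportions across species, so the order-`q` profile
#' describes how evenly genetic diversity is spread over the community.
#' An all-zero diversity vector is undefined and returns the `NA` sentinel
#' with a warning.
#'
#' @param pi_values non-negative per-species diversity values.
#' @param q diversity order (>= 0).
#' @export
hill_genetic <- function(pi_values, q) {
  stopifnot(length(pi_values) > 0, all(pi_values >= 0))
  if (sum(pi_values) == 0) {
    warning("all genetic diversities are zero; Hill number undefined")
    return(SENTINEL)
  }
  hill_abundance(pi_values[pi_values > 0], q)
}

#' Functional (attribute-diversity) Hill number of a trait distribution
#'
#' Chiu-Chao functional Hill number: pairwise trait distances
#' `d_ij = |z_i - z_j|` weighted by abundance proportions, with distances
#' normalized by Rao's quadratic entropy `Q = sum_ij d_ij p_i p_j` so the
#' result is invariant to rescaling all distances by a constant.  For
#' `q != 1`:
#' `FD(q) = (sum_{ij} (d_ij / Q) (p_i p_j)^q)^(1 / (2 (1 - q)))`,
#' with the corresponding limit at `q = 1`.  With equal distances and equal
#' abundances this reduces to the number of species.  Fewer than 2 species,
#' or all-identical traits (`Q = 0`), are degenerate and return the `NA`
#' sentinel.
#'
#' @param traits species trait values.
#' @param abundances species abundances (weights).
#' @param q diversity order (>= 0).
#' @export
hill_trait <- function(traits, abundances, q) {
  stopifnot(length(traits) == length(abundances), all(abundances > 0))
  if (!is.numeric(q) || length(q) != 1 || q < 0)
    stop("'q' must be a single non-negative number")
  if (length(traits) < 2) return(SENTINEL)
  p <- abundances / sum(abundances)
  d <- abs(outer(traits, traits, "-"))
  Q <- sum(d * outer(p, p))
  if (Q <= 0) {
    warning("all trait values identical; functional Hill number undefined")
    return(SENTINEL)
  }
  pp <- outer(p, p)
  if (abs(q - 1) < 1e-12) {
    w <- d / Q * pp
    return(exp(-0.5 * sum(w[w > 0] * log(pp[w > 0]))))
  }
  sum((d / Q) * pp^q)^(1 / (2 * (1 - q)))
}

#' First four moments of a data axis
#'
#' Sample mean, standard deviation, skewness and (excess-free, i.e. plain
#' `b2`-type) kurtosis.  Skewness needs at least 3 values and kurtosis at
#' least 4; below that the `NA` sentinel is returned for those entries.
#'
#' @param values numeric vector.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
axis_moments <- function(values) {
  n <- length(values)
  out <- c(mean = mean(values), sd = if (n > 1) sd(values) else SENTINEL,
           skewness = SENTINEL, kurtosis = SENTINEL)
  if (n >= 3 && sd(values) > 0)
    out["skewness"] <- e1071::skewness(values, type = 3)
  if (n >= 4 && sd(values) > 0)
    out["kurtosis"] <- e1071::kurtosis(values, type = 3)
  out
}

#' Spearman rank correlation between two data axes
#'
#' Both vectors must be indexed by the same species set (same order).
#' Ties receive average ranks.
#'
#' @param axis_a,axis_b per-species values, length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cross <- function(axis_a, axis_b) {
  stopifnot(length(axis_a) == length(axis_b))
  if (length(axis_a) < 3) return(SENTINEL)
  if (sd(axis_a) == 0 || sd(axis_b) == 0) return(SENTINEL)
  cor(axis_a, axis_b, method = "spearman")
}

#' Local-to-regional trait divergence
#'
#' Abundance-weighted local trait mean and SD minus the metacommunity
#' reference values.  Environmental filtering shrinks the local SD below
#' the regional one; competition can inflate it.
#'
#' @param local_traits species trait values in the local community.
#' @param local_abundances matching abundances.
#' @param meta a [generate_metacommunity()] pool (or any list with
#'   `trait_mean` and `trait_sd`).
#' @return Named vector `delta_mean`, `delta_sd`.
#' @export
trait_divergence <- function(local_traits, local_abundances, meta) {
  p <- local_abundances / sum(local_abundances)
  mu <- sum(p * local_traits)
  sdv <- sqrt(sum(p * (local_traits - mu)^2))
  c(delta_mean = mu - meta$trait_mean, delta_sd = sdv - meta$trait_sd)
}

hill_orders <- function() c(1, 2, 3, 4)

#' Summary-statistic schema
#'
#' The fixed, documented column order of the feature vector, with the data
#' axes each feature depends on.  Cross-axis Spearman correlations require
#' both of their axes; richness `S` is available whenever any axis is;
#' `lambda` is carried as run metadata and is never a classifier feature.
#'
#' @return Data frame with columns `column` and `axes` (comma-separated
#'   axis names, `"any"`, or `"meta"`).
#' @export
sumstats_schema <- function() {
  q <- hill_orders()
  rbind(
    data.frame(column = "S", axes = "any"),
    data.frame(column = c("abund_mean", "abund_sd", "abund_skewness",
                          "abund_kurtosis", paste0("abund_hill_", q)),
               axes = "abundance"),
    data.frame(column = c("pi_mean", "pi_sd", "pi_skewness", "pi_kurtosis",
                          paste0("pi_hill_", q)),
               axes = "genetic"),
    data.frame(column = c("trait_mean", "trait_sd", "trait_skewness",
                          "trait_kurtosis", paste0("trait_hill_", q),
                          "trait_delta_mean", "trait_delta_sd"),
               axes = "trait"),
    data.frame(column = "rho_abund_pi", axes = "abundance,genetic"),
    data.frame(column = "rho_abund_trait", axes = "abundance,trait"),
    data.frame(column = "rho_pi_trait", axes = "genetic,trait"),
    data.frame(column = "lambda", axes = "meta"))
}

#' Reduce one simulation (or one empirical-style dataset) to the feature vector
#'
#' Assembles the fixed-order summary-statistic row over the three data
#' axes: species abundances (moments of log abundance -- the conventional
#' scale for abundance distributions -- and abundance Hill numbers),
#' per-species genetic diversity (moments and proportion-normalized Hill
#' numbers of nucleotide diversity), and species trait values (one point
#' per species for the moments, abundance-weighted functional Hill numbers
#' and local-to-regional divergence).  Any axis may be omitted (`NULL`),
#' e.g. for empirical datasets lacking it; its columns then carry the `NA`
#' sentinel, never silently dropped.
#'
#' @param abundance per-species abundance counts (required).
#' @param pi per-species nucleotide diversities aligned with `abundance`,
#'   or `NULL` to mask the genetic axis.
#' @param traits per-species trait values aligned with `abundance`, or
#'   `NULL` to mask the trait axis.
#' @param meta metacommunity (needed for the trait-divergence features).
#' @param lambda realized colonization progress, if known.
#' @return One-row data frame following [sumstats_schema()].
#' @export
summarize_axes <- function(abundance, pi = NULL, traits = NULL, meta = NULL,
                           lambda = NA_real_) {
  stopifnot(length(abundance) > 0, all(abundance > 0))
  S <- length(abundance)
  q <- hill_orders()
  row <- list(S = as.numeric(S))

  mom <- axis_moments(log(abundance))
  row[paste0("abund_", names(mom))] <- mom
  for (k in q) row[[paste0("abund_hill_", k)]] <- hill_abundance(abundance, k)

  if (!is.null(pi)) {
    stopifnot(length(pi) == S, all(pi >= 0))
    mom <- axis_moments(pi)
    row[paste0("pi_", names(mom))] <- mom
    hg <- if (sum(pi) > 0) vapply(q, function(k) hill_genetic(pi, k),
                                  numeric(1))
          else suppressWarnings(rep(hill_genetic(0, 1), length(q)))
    for (i in seq_along(q)) row[[paste0("pi_hill_", q[i])]] <- hg[i]
  } else {
    row[c("pi_mean", "pi_sd", "pi_skewness", "pi_kurtosis",
          paste0("pi_hill_", q))] <- SENTINEL
  }

  if (!is.null(traits)) {
    stopifnot(length(traits) == S)
    mom <- axis_moments(traits)
    row[paste0("trait_", names(mom))] <- mom
    ht <- suppressWarnings(vapply(q, function(k)
      hill_trait(traits, abundance, k), numeric(1)))
    for (i in seq_along(q)) row[[paste0("trait_hill_", q[i])]] <- ht[i]
    if (!is.null(meta)) {
      dv <- trait_divergence(traits, abundance, meta)
      row[["trait_delta_mean"]] <- dv[["delta_mean"]]
      row[["trait_delta_sd"]] <- dv[["delta_sd"]]
    } else {
      row[c("trait_delta_mean", "trait_delta_sd")] <- SENTINEL
    }
  } else {
    row[c("trait_mean", "trait_sd", "trait_skewness", "trait_kurtosis",
          paste0("trait_hill_", q), "trait_delta_mean",
          "trait_delta_sd")] <- SENTINEL
  }

  row[["rho_abund_pi"]] <- if (!is.null(pi))
    spearman_cross(abundance, pi) else SENTINEL
  row[["rho_abund_trait"]] <- if (!is.null(traits))
    spearman_cross(abundance, traits) else SENTINEL
  row[["rho_pi_trait"]] <- if (!is.null(pi) && !is.null(traits))
    spearman_cross(pi, traits) else SENTINEL
  row[["lambda"]] <- lambda

  out <- as.data.frame(row[sumstats_schema()$column])
  rownames(out) <- NULL
  out
}

#' Summary statistics of a finished simulation
#'
#' Convenience wrapper assembling [summarize_axes()] from an
#' `assembly_run` and its [community_pi()] table.
#'
#' @param run an [simulate_community()] result.
#' @param pi_table matching [community_pi()] output (or `NULL` to mask the
#'   genetic axis).
#' @param meta the metacommunity used for the run (for trait divergence);
#'   if `NULL`, the reference trait moments stored on the run are used.
#' @return One-row data frame following [sumstats_schema()].
#' @export
summarize_run <- function(run, pi_table = NULL, meta = NULL) {
  sp <- run$species
  pi <- NULL
  if (!is.null(pi_table))
    pi <- pi_table$pi[match(sp$species_id, pi_table$species_id)]
  if (is.null(meta))
    meta <- list(trait_mean = run$meta_trait_mean,
                 trait_sd = run$meta_trait_sd)
  summarize_axes(sp$abundance, pi = pi, traits = sp$trait, meta = meta,
                 lambda = run$lambda)
}
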