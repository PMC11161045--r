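#' Species-aggregated pairwise/beta competition rates
#'
#' Exact fast path for the pairwise and beta competition kernels.  Because
#' all conspecifics share one trait value, the per-individual death rate of
#' any member of species `a` is
#' `q(a) = beta_intra * (n_a - 1) +
#'         beta_inter * sum_{b != a} n_b * exp(-s_E (z_a - z_b)^2)`,
#' which costs O(S^2) in the number of species rather than O(J^2) in
#' individuals.  With `beta_intra = beta_inter = 1` this equals the plain
#' pairwise competition rate for every member of species `a`.
#'
#' @param abundance positive integer vector of per-species counts.
#' @param traits numeric vector of species trait values (same length).
#' @param s_E selection strength.
#' @param beta_intra,beta_inter conspecific / heterospecific weights.
#' @return Numeric vector of per-individual death rates, one per species.
#' @export
aggregated_pairwise_rates <- function(abundance, traits, s_E,
                                      beta_intra = 1, beta_inter = 1) {
  stopifnot(length(abundance) == length(traits), all(abundance > 0))
  a <- -s_E * outer(traits, traits, "-")^2
  a[a < -700] <- -700
  K <- exp(a)
  cross <- as.numeric(K %*% abundance) - abundance  # K_aa = 1
  beta_intra * (abundance - 1) + beta_inter * cross
}

# raw per-species death rates for any model (one entry per species; all
# conspecifics share it).  zbar is recomputed from the current state.
species_death_rates <- function(abundance, traits, params) {
  J <- sum(abundance)
  switch(params$model,
    neutral = rep(1, length(abundance)),
    filtering = {
      a <- -params$s_E * (traits - params$z_E)^2
      a[a < -700] <- -700
      1 - exp(a)
    },
    mean = {
      zbar <- sum(abundance * traits) / J
      a <- -params$s_E * (traits - zbar)^2
      a[a < -700] <- -700
      exp(a)
    },
    pairwise = aggregated_pairwise_rates(abundance, traits, params$s_E, 1, 1),
    beta = aggregated_pairwise_rates(abundance, traits, params$s_E,
                                     params$beta_intra, params$beta_inter)
  )
}

#' Per-individual death probabilities
#'
#' Evaluates the selected assembly model's death rate for every individual
#' and normalizes by the community sum, so the result is a probability
#' vector of length `J`.  The neutral model returns the uniform vector
#' `1/J`; for `s_E = 0` the mean, pairwise and equal-beta models reduce to
#' it exactly.  If every raw rate is zero (e.g. filtering with all
#' individuals exactly at the optimum) the uniform vector is returned with
#' a warning, since the normalization is undefined there and uniform is the
#' `s_E -> 0`-consistent completion.
#'
#' @param community a [local_community()].
#' @param params an [assembly_params()]; for the filtering model `z_E` must
#'   be set (it defaults to the metacommunity trait mean only at simulation
#'   time).
#' @return Numeric vector of length `J`, non-negative, summing to 1;
#'   ordered as the individuals in `community$species_id`.
#' @export
death_weights <- function(community, params) {
  ab <- species_abundance(community)
  z <- as.numeric(community$traits[names(ab)])
  q <- species_death_rates(as.integer(ab), z, params)
  per_ind <- q[match(as.character(community$species_id), names(ab))]
  tot <- sum(per_ind)
  if (tot <= 1e-300) {
    warning("all death rates are zero; falling back to uniform weights")
    J <- length(community$species_id)
    return(rep(1 / J, J))
  }
  per_ind / tot
}
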