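#' Construct a local community state
#'
#' An explicit individual-level snapshot of the local community: each of the
#' `J` individuals carries a species identity, all conspecifics share one
#' trait value, and a colonist flag marks individuals descending from a
#' lineage that arrived (by immigration or in-situ speciation) after the
#' start of a simulation.
#'
#' @param species_id integer vector, one entry per individual.
#' @param traits named numeric vector mapping species id to trait value;
#'   every species present must have a trait.
#' @param colonist logical vector, one entry per individual.
#' @return An object of class `local_community`.
#' @export
local_community <- function(species_id, traits, colonist = NULL) {
  species_id <- as.integer(species_id)
  J <- length(species_id)
  if (J < 2) stop("a local community needs at least 2 individuals")
  if (is.null(colonist)) colonist <- rep(FALSE, J)
  if (length(colonist) != J)
    stop("'colonist' must have one entry per individual")
  need <- as.character(sort(unique(species_id)))
  if (!all(need %in% names(traits)))
    stop("every species present needs a trait value; missing: ",
         paste(setdiff(need, names(traits)), collapse = ", "))
  structure(list(species_id = species_id,
                 traits = traits[need],
                 colonist = as.logical(colonist)),
            class = "local_community")
}

#' @export
print.local_community <- function(x, ...) {
  ab <- species_abundance(x)
  cat("Local community: J =", length(x$species_id),
      "individuals,", length(ab), "species, lambda =",
      round(compute_lambda(x), 4), "\n")
  invisible(x)
}

#' Per-species abundances of a local community
#' @param community a [local_community()].
#' @return Named integer vector (names are species ids).
#' @export
species_abundance <- function(community) {
  tab <- table(community$species_id)
  setNames(as.integer(tab), names(tab))
}

#' Progress toward equilibrium
#'
#' The proportion of individuals descending from a lineage that colonized
#' the local community during the simulation.  Equals 0 for a founding
#' community and 1 once the initial conditions are no longer detectable.
#'
#' @param community a [local_community()] or [simulate_community()] result.
#' @return A value in `[0, 1]`.
#' @export
compute_lambda <- function(community) {
  if (inherits(community, "assembly_run")) return(community$lambda)
  mean(community$colonist)
}

#' One death-birth event (reference implementation)
#'
#' Advances a [local_community()] by exactly one event: a death index drawn
#' from [death_weights()], then replacement by an immigrant (probability
#' `m`) or by a copy of a uniformly chosen surviving individual, which with
#' probability `nu` founds a new species whose trait is the parent trait
#' perturbed by `Normal(0, sigma_sp)`.  This is the plain-R single-step
#' engine used for inspection and for cross-checking the compiled run loop;
#' long simulations should use [simulate_community()].
#'
#' @param community a [local_community()].
#' @param params an [assembly_params()]; `z_E` and `sigma_sp` must be set.
#' @param meta a [generate_metacommunity()] pool.
#' @return The updated `local_community` (community size unchanged).
#' @export
step_community <- function(community, params, meta) {
  J <- length(community$species_id)
  stopifnot(J == params$J)
  w <- death_weights(community, params)
  dead <- sample.int(J, 1, prob = w)
  sid <- community$species_id
  col <- community$colonist
  traits <- community$traits
  if (runif(1) < params$m) {
    imm <- sample_immigrant(meta, 1)
    sid[dead] <- imm
    col[dead] <- TRUE
    traits[as.character(imm)] <- meta$trait[imm]
  } else {
    parent <- sample(seq_len(J)[-dead], 1)
    if (params$nu > 0 && runif(1) < params$nu) {
      new_id <- max(c(sid, length(meta$species_id))) + 1L
      traits[as.character(new_id)] <-
        traits[as.character(sid[parent])] + rnorm(1, 0, params$sigma_sp)
      sid[dead] <- new_id
      col[dead] <- TRUE
    } else {
      sid[dead] <- sid[parent]
      col[dead] <- col[parent]
    }
  }
  keep <- as.character(sort(unique(sid)))
  local_community(sid, traits[keep], col)
}
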