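#' Run a community assembly simulation
#'
#' Forward-time zero-sum simulation: the community is founded by `J`
#' individuals of a single metacommunity species (drawn with probability
#' proportional to regional abundance), then iterated one death-birth event
#' at a time until the colonization progress statistic reaches
#' `lambda_target` (checked each generation; one generation = `J` events) or
#' `max_generations` elapses.  Per-species abundances are recorded every
#' `snapshot_every` generations; these trajectories later constrain the
#' per-species coalescent (see [community_pi()]).
#'
#' @param params an [assembly_params()].
#' @param meta a [generate_metacommunity()] pool.
#' @return An object of class `assembly_run` with components
#'   `species` (data frame: `species_id`, `trait`, `abundance`,
#'   `n_founder`, `n_colonist`, `colonization_gen`; -1 marks the founding
#'   species), `trajectory` (long data frame: `generation`, `species_id`,
#'   `abundance`), `timeline` (`generation`, `S`, `lambda`, `zbar`),
#'   realized `lambda`, `generations`, a `truncated` flag and the fully
#'   resolved parameter set (`params`, with `z_E`/`sigma_sp` filled in).
#' @examples
#' meta <- generate_metacommunity(metacommunity_spec(50, seed = 1))
#' run <- simulate_community(
#'   assembly_params(J = 100, m = 0.05, model = "neutral",
#'                   lambda_target = 1, seed = 1), meta)
#' run
#' @export
simulate_community <- function(params, meta) {
  stopifnot(inherits(params, "assembly_params"))
  validate_metacommunity(meta)
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(params$z_E)) params$z_E <- meta$trait_mean
  if (is.null(params$sigma_sp)) params$sigma_sp <- 0.1 * meta$trait_sd
  founder <- sample_immigrant(meta, 1)
  lt <- params$lambda_target %||% -1
  res <- cpp_run_assembly(params$J, params$m, params$nu, params$s_E,
                          params$z_E, params$beta_intra, params$beta_inter,
                          model_code(params$model),
                          cumsum(meta$rel_abundance), meta$trait,
                          params$sigma_sp, founder - 1L, lt,
                          params$max_generations, params$snapshot_every)
  if (res$fallback_events > 0)
    warning(sprintf("degenerate all-zero death rates in %g events; uniform weights used",
                    res$fallback_events))
  species <- data.frame(species_id = res$species_id, trait = res$trait,
                        abundance = res$abundance,
                        n_founder = res$n_founder,
                        n_colonist = res$n_colonist,
                        colonization_gen = res$colonization_gen)
  structure(list(
    species = species[order(species$species_id), , drop = FALSE],
    trajectory = data.frame(generation = res$traj_gen,
                            species_id = res$traj_id,
                            abundance = res$traj_n),
    timeline = data.frame(generation = res$tl_gen, S = res$tl_S,
                          lambda = res$tl_lambda, zbar = res$tl_zbar),
    lambda = res$lambda, generations = res$generations,
    truncated = res$truncated, founder_id = founder,
    params = params, meta_trait_mean = meta$trait_mean,
    meta_trait_sd = meta$trait_sd),
    class = "assembly_run")
}

#' @export
print.assembly_run <- function(x, ...) {
  cat("Assembly run [", x$params$model, "]: J =", x$params$J,
      "| S =", nrow(x$species),
      "| lambda =", round(x$lambda, 4),
      "| generations =", x$generations,
      if (x$truncated) "(truncated)" else "", "\n")
  invisible(x)
}

#' @export
summary.assembly_run <- function(object, ...) {
  print(object)
  ab <- object$species$abundance
  cat(sprintf("  abundance: max %d, median %.0f; trait range [%.3f, %.3f]\n",
              max(ab), stats::median(ab), min(object$species$trait),
              max(object$species$trait)))
  invisible(object)
}

#' Expand a finished run to an individual-level community
#'
#' Individuals are exchangeable within a species-by-lineage class, so the
#' snapshot lists founder-descended individuals first within each species.
#'
#' @param run an `assembly_run`.
#' @return A [local_community()].
#' @export
as_local_community <- function(run) {
  sp <- run$species
  sid <- rep(sp$species_id, sp$abundance)
  col <- unlist(lapply(seq_len(nrow(sp)), function(i)
    rep(c(FALSE, TRUE), c(sp$n_founder[i], sp$n_colonist[i]))))
  local_community(sid, setNames(sp$trait, sp$species_id), col)
}

#' Write a run's outputs as delimited text
#'
#' The trajectory goes to `<prefix>_trajectory.tsv` (long format), the final
#' individual-level snapshot to `<prefix>_community.tsv`, and a JSON
#' manifest with the resolved parameters, realized lambda and truncation
#' flag to `<prefix>_manifest.json`.
#'
#' @param run an `assembly_run`.
#' @param prefix output path prefix.
#' @export
write_assembly_run <- function(run, prefix) {
  write.table(run$trajectory, paste0(prefix, "_trajectory.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  com <- as_local_community(run)
  snap <- data.frame(individual_id = seq_along(com$species_id),
                     species_id = com$species_id,
                     trait = as.numeric(com$traits[as.character(com$species_id)]),
                     colonist_flag = com$colonist)
  write.table(snap, paste0(prefix, "_community.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(run$params[setdiff(names(run$params), "seed")],
                list(seed = run$params$seed %||% NA,
                     lambda = run$lambda, generations = run$generations,
                     truncated = run$truncated))
  jsonlite::write_json(manifest, paste0(prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}
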