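#' Experiment configuration
#'
#' Bundles everything a batch experiment needs: the metacommunity spec, the
#' per-parameter prior distributions, the per-model simulation counts, the
#' coalescent settings and a master seed from which every run seed is
#' derived deterministically.
#'
#' Default priors (uniform or log-uniform, all overridable): community size
#' `J` uniform integer over `[500, 2000]`; selection strength `s_E`
#' log-uniform over `[0.001, 1]`; migration `m` log-uniform over
#' `[1e-4, 1e-2]`; speciation `nu` zero with probability 1/3, otherwise
#' log-uniform over `[1e-4, 5e-3]`; the `beta_intra / beta_inter` ratio
#' log-uniform over `[1, 30]` with `beta_inter = 1`; abundance-to-Ne
#' scaling `alpha` log-uniform over `[100, 1e4]`; equilibrium target
#' `lambda_target` drawn from `{0.25, 0.5, 0.75, 1}`.
#'
#' @param models assembly models to simulate.
#' @param n_per_model simulations per model.
#' @param priors named list of prior specs, each
#'   `list(dist = "uniform"|"loguniform"|"choice", min =, max = / values =)`,
#'   merged over the defaults above.  `nu` additionally takes `p_zero`.
#' @param n_haplotypes,mu_per_site,locus_length_bp,source_pool_size
#'   coalescent settings (see [simulate_pi()]).
#' @param snapshot_points approximate number of trajectory snapshots kept
#'   per run (sets `snapshot_every` from the expected run length; the
#'   coalescent Ne resolution equals the recording resolution).
#' @param meta_spec a [metacommunity_spec()].
#' @param seed master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(models = ASSEMBLY_MODELS, n_per_model = 100,
                              priors = list(),
                              n_haplotypes = 10, mu_per_site = 1e-7,
                              locus_length_bp = 570, source_pool_size = 1e5,
                              snapshot_points = 500,
                              meta_spec = metacommunity_spec(),
                              seed = 1) {
  defaults <- list(
    J = list(dist = "uniform", min = 500, max = 2000, integer = TRUE),
    s_E = list(dist = "loguniform", min = 0.001, max = 1),
    m = list(dist = "loguniform", min = 1e-4, max = 1e-2),
    nu = list(dist = "loguniform", min = 1e-4, max = 5e-3, p_zero = 1 / 3),
    beta_ratio = list(dist = "loguniform", min = 1, max = 30),
    alpha = list(dist = "loguniform", min = 100, max = 1e4),
    lambda_target = list(dist = "choice", values = c(0.25, 0.5, 0.75, 1)))
  for (nm in names(priors)) defaults[[nm]] <-
    utils::modifyList(defaults[[nm]] %||% list(), priors[[nm]])
  bad <- setdiff(models, ASSEMBLY_MODELS)
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "))
  structure(list(models = models, n_per_model = n_per_model,
                 priors = defaults, n_haplotypes = n_haplotypes,
                 mu_per_site = mu_per_site,
                 locus_length_bp = locus_length_bp,
                 source_pool_size = source_pool_size,
                 snapshot_points = snapshot_points,
                 meta_spec = meta_spec, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read / write an experiment configuration
#'
#' Plain YAML round-trip of [experiment_config()]; every batch embeds a
#' copy of the realized configuration in its manifest.
#'
#' @param config an `experiment_config`.
#' @param file path.
#' @export
write_config <- function(config, file) {
  x <- unclass(config)
  x$meta_spec <- unclass(x$meta_spec)
  yaml::write_yaml(x, file, precision = 15)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  x$meta_spec <- do.call(metacommunity_spec, x$meta_spec)
  do.call(experiment_config, x)
}

# deterministic per-run seed below 2^31
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 65536 * 32003 + index * 2011 + 7919) %%
               2147483647)
}

draw_prior <- function(spec, n) {
  out <- switch(spec$dist,
    uniform = runif(n, spec$min, spec$max),
    loguniform = exp(runif(n, log(spec$min), log(spec$max))),
    choice = spec$values[sample.int(length(spec$values), n, replace = TRUE)],
    stop("unknown prior distribution: ", spec$dist))
  if (isTRUE(spec$integer)) out <- round(out)
  out
}

#' Draw simulation parameters from the configured priors
#'
#' @param config an [experiment_config()].
#' @param n draws per model.
#' @param models models to draw for (default: the config's).
#' @return Data frame, one row per simulation: `run_id`, `model`, the
#'   parameter draws and the derived per-run `seed`.  Neutral draws carry
#'   `s_E = 0`; non-beta draws carry `beta_intra = beta_inter = 1`.
#' @export
sample_priors <- function(config, n = config$n_per_model,
                          models = config$models) {
  set.seed(config$seed)
  rows <- list()
  idx <- 0L
  for (mod in models) {
    if (n == 0) next
    d <- data.frame(
      run_id = sprintf("%s_%04d", mod, seq_len(n)),
      model = mod,
      J = as.integer(draw_prior(config$priors$J, n)),
      s_E = draw_prior(config$priors$s_E, n),
      m = draw_prior(config$priors$m, n),
      nu = draw_prior(config$priors$nu, n),
      beta_intra = draw_prior(config$priors$beta_ratio, n),
      beta_inter = 1,
      alpha = draw_prior(config$priors$alpha, n),
      lambda_target = draw_prior(config$priors$lambda_target, n))
    pz <- config$priors$nu$p_zero %||% 0
    if (pz > 0) d$nu[runif(n) < pz] <- 0
    if (mod == "neutral") d$s_E <- 0
    if (mod != "beta") d$beta_intra <- 1
    d$seed <- derive_seed(config$seed, idx + seq_len(n))
    idx <- idx + n
    rows[[mod]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out %||% data.frame()
}

draw_to_params <- function(draw, config) {
  # expected generations to the lambda target sets the snapshot cadence so
  # each history has about snapshot_points epochs
  est <- if (draw$lambda_target >= 1) log(draw$J) / max(draw$m, 1e-6)
         else -log(1 - draw$lambda_target) / max(draw$m, 1e-6)
  snap <- max(1L, as.integer(ceiling(est / config$snapshot_points)))
  assembly_params(J = draw$J, m = draw$m, nu = draw$nu, model = draw$model,
                  s_E = draw$s_E, beta_intra = draw$beta_intra,
                  beta_inter = draw$beta_inter, alpha = draw$alpha,
                  lambda_target = draw$lambda_target,
                  snapshot_every = snap, seed = draw$seed)
}

#' Run a labelled batch of simulations
#'
#' For each prior draw: run the assembly simulation, the per-species
#' coalescent, and the summary-statistic reduction; collect one labelled
#' row per simulation.  With an output directory the batch is resumable:
#' completed run ids are skipped on re-invocation and rows are appended to
#' `summary_stats.tsv`, with the realized configuration and draw table
#' stored alongside.  Individual run failures are logged and skipped; the
#' batch fails only if more than 1% of runs fail.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for resumable operation.
#' @param progress print one line per 50 runs.
#' @return Data frame: `run_id`, `model`, the realized parameter draws,
#'   `truncated`, and the [sumstats_schema()] feature columns.
#' @export
run_batch <- function(config, out_dir = NULL, progress = FALSE) {
  meta <- generate_metacommunity(config$meta_spec)
  draws <- sample_priors(config)
  stats_file <- NULL
  done <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
    write.table(draws, file.path(out_dir, "draws.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    stats_file <- file.path(out_dir, "summary_stats.tsv")
    if (file.exists(stats_file))
      done <- read.table(stats_file, header = TRUE, sep = "\t")$run_id
  }
  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(draws))) {
    draw <- draws[i, ]
    if (draw$run_id %in% done) next
    row <- tryCatch({
      params <- draw_to_params(draw, config)
      run <- simulate_community(params, meta)
      pt <- community_pi(run, n_haplotypes = config$n_haplotypes,
                         mu_per_site = config$mu_per_site,
                         locus_length_bp = config$locus_length_bp,
                         source_pool_size = config$source_pool_size)
      ss <- summarize_run(run, pt, meta)
      cbind(draw[setdiff(names(draw), "seed")],
            seed = draw$seed, truncated = run$truncated, ss)
    }, error = function(e) {
      warning("run ", draw$run_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(row)) {
      failures <- c(failures, draw$run_id)
    } else {
      rows[[draw$run_id]] <- row
      if (!is.null(stats_file))
        suppressWarnings(write.table(
          row, stats_file, sep = "\t", row.names = FALSE, quote = FALSE,
          col.names = !file.exists(stats_file), append = file.exists(stats_file)))
    }
    if (progress && i %% 50 == 0)
      cat(sprintf("[batch] %d/%d runs\n", i, nrow(draws)))
  }
  if (length(failures) > 0.01 * nrow(draws))
    stop(length(failures), " of ", nrow(draws), " runs failed (> 1%): ",
         paste(head(failures, 5), collapse = ", "))
  out <- if (!is.null(stats_file) && file.exists(stats_file))
    read.table(stats_file, header = TRUE, sep = "\t")
  else do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Small deterministic fixture batch
#'
#' A tiny bundle (by default 20 simulations per model at `J = 200`) used by
#' the test-suite and documentation examples; regeneration is bit-stable
#' under the fixed seed.
#'
#' @param seed master seed.
#' @param n_per_model simulations per model.
#' @param out_dir optional directory to persist the table.
#' @return Labelled summary-statistic table (see [run_batch()]).
#' @export
make_fixtures <- function(seed = 42, n_per_model = 20, out_dir = NULL) {
  config <- experiment_config(
    n_per_model = n_per_model,
    priors = list(J = list(min = 200, max = 200),
                  m = list(min = 1e-3, max = 1e-2),
                  lambda_target = list(values = c(0.5, 1))),
    snapshot_points = 200,
    meta_spec = metacommunity_spec(n_species = 200, seed = seed),
    seed = seed)
  run_batch(config, out_dir = out_dir)
}

#' Scaled classification experiment
#'
#' The package's end-to-end protocol: simulate a labelled batch under the
#' configured priors, then cross-validate the random-forest classifier
#' under the three axis-mask scenarios (abundance+genetic, trait+genetic,
#' all three axes) on the same rows and fold seed, plus a label-shuffled
#' baseline on the trait+genetic mask.
#'
#' @param n_per_model simulations per model.
#' @param seed master seed (drives priors, simulations, folds and forests).
#' @param J_range community-size prior range.
#' @param k folds.
#' @param num_trees forest size.
#' @param table optional pre-computed batch table (skips simulation).
#' @return List with the batch `table`, `cv` (named list of
#'   [cross_validate()] results per mask) and `shuffled`
#'   (label-shuffled CV on trait+genetic).
#' @export
classification_experiment <- function(n_per_model = 500, seed = 1,
                                      J_range = c(500, 1000), k = 5,
                                      num_trees = 1000, table = NULL) {
  if (is.null(table)) {
    config <- experiment_config(
      n_per_model = n_per_model,
      priors = list(J = list(min = J_range[1], max = J_range[2])),
      seed = seed)
    table <- run_batch(config)
  }
  masks <- list(`sad+gen` = "sad+gen", `trait+gen` = "trait+gen",
                all = "all")
  cv <- lapply(masks, function(ax)
    cross_validate(table, axes = ax, k = k, num_trees = num_trees,
                   seed = seed))
  shuf <- table
  set.seed(seed + 1)
  shuf$model <- sample(shuf$model)
  shuffled <- cross_validate(shuf, axes = "trait+gen", k = k,
                             num_trees = num_trees, seed = seed)
  list(table = table, cv = cv, shuffled = shuffled)
}
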