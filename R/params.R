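#' Simulation parameters for local community assembly
#'
#' Bundles and validates the parameters of the zero-sum death-birth
#' simulation.  At every time step one individual dies -- chosen according to
#' the selected assembly model -- and is replaced either by an immigrant from
#' the metacommunity (probability `m`) or by offspring of a uniformly chosen
#' surviving local individual, which founds a new species with probability
#' `nu` (point-mutation speciation).  Selection acts on the death event only.
#'
#' Assembly models (unnormalized per-individual death rates; the death
#' probability is the rate normalized by its sum over the community):
#' \describe{
#'   \item{neutral}{uniform, `1/J` for every individual.}
#'   \item{filtering}{`1 - exp(-s_E (z_i - z_E)^2)`: individuals far from the
#'     environmental optimum `z_E` die more.}
#'   \item{mean}{`exp(-s_E (z_i - zbar)^2)` with `zbar` the community mean
#'     trait (mean-field competition).}
#'   \item{pairwise}{`sum_{j != i} exp(-s_E (z_i - z_j)^2)`: competition from
#'     every other individual, decaying with trait distance.}
#'   \item{beta}{as pairwise but each term weighted by `beta_intra` for
#'     conspecific pairs and `beta_inter` for heterospecific pairs
#'     (negative density dependence).  The regime `beta_intra < beta_inter`
#'     is excluded (it collapses to monodominance).}
#' }
#'
#' @param J local community size (number of individuals, >= 2).
#' @param m immigration probability per replacement, in `[0, 1]`.
#' @param nu point-mutation speciation probability per local birth.
#' @param model one of `"neutral"`, `"filtering"`, `"mean"`, `"pairwise"`,
#'   `"beta"`.
#' @param s_E selection strength (>= 0).
#' @param z_E environmental optimum for the filtering model; default
#'   (`NULL`) uses the metacommunity abundance-weighted trait mean.
#' @param beta_intra,beta_inter intra-/inter-specific competition weights
#'   (positive; `beta_intra >= beta_inter` required for `model = "beta"`).
#' @param alpha scaling from local abundance to haploid effective population
#'   size used by the coalescent stage.
#' @param lambda_target stop once the colonization progress statistic
#'   reaches this value in `(0, 1]`, checked each generation; `NULL` to run
#'   for `max_generations` exactly.
#' @param max_generations hard cap on generations (one generation = `J`
#'   death-birth events); runs hitting the cap before `lambda_target` are
#'   flagged truncated, not errored.
#' @param snapshot_every record the trajectory every this many generations.
#' @param sigma_sp standard deviation of the trait perturbation applied at
#'   speciation; default (`NULL`) is 10% of the metacommunity trait SD.
#' @param seed optional integer seed.
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(J = 1000, m = 5e-3, nu = 0,
                            model = c("neutral", "filtering", "mean",
                                      "pairwise", "beta"),
                            s_E = 0.1, z_E = NULL,
                            beta_intra = 1, beta_inter = 1, alpha = 1000,
                            lambda_target = 1, max_generations = NULL,
                            snapshot_every = 1, sigma_sp = NULL,
                            seed = NULL) {
  model <- match.arg(model)
  chk <- function(ok, msg) if (!ok) stop("invalid parameter: ", msg)
  chk(is.numeric(J) && length(J) == 1 && J == round(J) && J >= 2,
      "'J' must be an integer >= 2")
  chk(is.numeric(m) && m >= 0 && m <= 1, "'m' must lie in [0, 1]")
  chk(is.numeric(nu) && nu >= 0 && nu <= 1, "'nu' must lie in [0, 1]")
  chk(is.numeric(s_E) && s_E >= 0, "'s_E' must be >= 0")
  chk(is.numeric(beta_intra) && beta_intra > 0, "'beta_intra' must be > 0")
  chk(is.numeric(beta_inter) && beta_inter > 0, "'beta_inter' must be > 0")
  chk(is.numeric(alpha) && alpha > 0, "'alpha' must be > 0")
  if (model == "beta")
    chk(beta_intra >= beta_inter,
        "'beta_intra' must be >= 'beta_inter' for the beta model")
  if (!is.null(lambda_target))
    chk(is.numeric(lambda_target) && lambda_target > 0 && lambda_target <= 1,
        "'lambda_target' must lie in (0, 1]")
  if (is.null(max_generations)) {
    max_generations <- if (is.null(lambda_target)) 1000L else 200000L
  }
  chk(is.numeric(max_generations) && max_generations >= 1,
      "'max_generations' must be a positive integer")
  chk(is.numeric(snapshot_every) && snapshot_every >= 1,
      "'snapshot_every' must be a positive integer")
  structure(list(J = as.integer(J), m = m, nu = nu, model = model, s_E = s_E,
                 z_E = z_E, beta_intra = beta_intra, beta_inter = beta_inter,
                 alpha = alpha, lambda_target = lambda_target,
                 max_generations = as.integer(max_generations),
                 snapshot_every = as.integer(snapshot_every),
                 sigma_sp = sigma_sp, seed = seed),
            class = "assembly_params")
}

#' @export
print.assembly_params <- function(x, ...) {
  cat("Assembly parameters [", x$model, "]\n", sep = "")
  cat(sprintf("  J = %d, m = %g, nu = %g, s_E = %g\n", x$J, x$m, x$nu, x$s_E))
  if (x$model == "beta")
    cat(sprintf("  beta_intra = %g, beta_inter = %g\n",
                x$beta_intra, x$beta_inter))
  cat(sprintf("  alpha = %g, stop: %s (cap %d generations)\n", x$alpha,
              if (is.null(x$lambda_target)) "max generations"
              else paste0("lambda >= ", x$lambda_target),
              x$max_generations))
  invisible(x)
}

model_code <- function(model) {
  match(model, c("neutral", "filtering", "mean", "pairwise", "beta")) - 1L
}
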