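#' Specify a regional species pool
#'
#' The metacommunity is a very large, fixed regional pool that supplies
#' immigrants to the local community and defines the reference trait
#' distribution.  Relative abundances follow a Fisher log-series (the classic
#' neutral regional pool), and one trait value is attached to each species,
#' simulated either by Brownian motion along a Yule tree over the pool
#' (`"brownian_on_tree"`, the default, which gives traits phylogenetic
#' structure) or as independent normal draws (`"iid_normal"`).
#'
#' @param n_species number of species in the pool (>= 2).
#' @param sad_shape log-series parameter in (0, 1); values close to 1 give a
#'   longer abundance tail.
#' @param trait_model `"brownian_on_tree"` or `"iid_normal"`.
#' @param trait_rate variance scale of the trait process (Brownian rate per
#'   unit branch length, or the iid normal variance).
#' @param seed optional integer seed.
#' @return An object of class `metacommunity_spec`.
#' @seealso [generate_metacommunity()]
#' @export
metacommunity_spec <- function(n_species = 500, sad_shape = 0.98,
                               trait_model = c("brownian_on_tree", "iid_normal"),
                               trait_rate = 1, seed = NULL) {
  if (!is.numeric(n_species) || length(n_species) != 1 ||
      n_species != round(n_species) || n_species < 2)
    stop("invalid metacommunity spec: 'n_species' must be an integer >= 2")
  if (!is.numeric(sad_shape) || length(sad_shape) != 1 ||
      sad_shape <= 0 || sad_shape >= 1)
    stop("invalid metacommunity spec: 'sad_shape' must lie in (0, 1)")
  if (!is.numeric(trait_rate) || length(trait_rate) != 1 || trait_rate <= 0)
    stop("invalid metacommunity spec: 'trait_rate' must be positive")
  trait_model <- match.arg(trait_model)
  structure(list(n_species = as.integer(n_species), sad_shape = sad_shape,
                 trait_model = trait_model, trait_rate = trait_rate,
                 seed = seed),
            class = "metacommunity_spec")
}

# log-series sampler by inverse CDF; pmf p(k) = -shape^k / (k log(1 - shape))
rlogseries <- function(n, shape) {
  kmax <- 64L
  repeat {
    k <- seq_len(kmax)
    pmf <- -shape^k / (k * log1p(-shape))
    cum <- cumsum(pmf)
    if (cum[kmax] > 1 - 1e-12 || kmax > 2^22) break
    kmax <- kmax * 2L
  }
  findInterval(runif(n), cum) + 1L
}

#' Generate a metacommunity
#'
#' Draws per-species log-series abundances (normalized to relative
#' abundances) and species traits under the chosen trait model.  The
#' reference trait mean and standard deviation are abundance-weighted,
#' i.e. they describe the trait distribution over *individuals* in the
#' regional pool, which is what local communities sample from.
#'
#' @param spec a [metacommunity_spec()].
#' @return An object of class `metacommunity`: a list with `species_id`,
#'   `rel_abundance` (strictly positive, sums to 1), `trait`, the
#'   abundance-weighted `trait_mean` and `trait_sd`, the Yule `tree` used for
#'   Brownian traits (or `NULL`), and the generating `spec`.
#' @examples
#' meta <- generate_metacommunity(metacommunity_spec(100, seed = 1))
#' sum(meta$rel_abundance)
#' @export
generate_metacommunity <- function(spec) {
  if (!inherits(spec, "metacommunity_spec"))
    spec <- do.call(metacommunity_spec, as.list(spec))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_species
  counts <- rlogseries(n, spec$sad_shape)
  p <- counts / sum(counts)
  tree <- NULL
  if (spec$trait_model == "brownian_on_tree") {
    tree <- ape::rphylo(n, birth = 1, death = 0)
    zt <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(spec$trait_rate))
    # tip labels are t1..tn; species i takes tip i's trait
    z <- as.numeric(zt[match(paste0("t", seq_len(n)), names(zt))])
  } else {
    z <- rnorm(n, 0, sqrt(spec$trait_rate))
  }
  mu <- sum(p * z)
  sdv <- sqrt(sum(p * (z - mu)^2))
  structure(list(species_id = seq_len(n), rel_abundance = p, trait = z,
                 trait_mean = mu, trait_sd = sdv, tree = tree, spec = spec),
            class = "metacommunity")
}

validate_metacommunity <- function(meta) {
  stopifnot(inherits(meta, "metacommunity"))
  if (any(meta$rel_abundance <= 0))
    stop("metacommunity relative abundances must be strictly positive")
  if (abs(sum(meta$rel_abundance) - 1) > 1e-12)
    stop("metacommunity relative abundances must sum to 1")
  if (length(meta$trait) != length(meta$species_id))
    stop("metacommunity trait vector length must equal species count")
  invisible(meta)
}

#' Sample immigrant species from the pool
#'
#' @param meta a [generate_metacommunity()] object.
#' @param n number of draws.
#' @return Integer vector of species ids, drawn with probability
#'   proportional to regional relative abundance.
#' @export
sample_immigrant <- function(meta, n = 1) {
  validate_metacommunity(meta)
  sample(meta$species_id, n, replace = TRUE, prob = meta$rel_abundance)
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("Metacommunity:", length(x$species_id), "species,",
      "log-series shape", x$spec$sad_shape, "\n")
  cat("  trait model:", x$spec$trait_model,
      sprintf("(abundance-weighted mean %.3f, sd %.3f)\n",
              x$trait_mean, x$trait_sd))
  invisible(x)
}

#' Write / read a metacommunity as delimited text
#'
#' Columns: `species_id`, `rel_abundance`, `trait`.  If the pool carries a
#' Yule tree it can be written alongside in newick format.
#'
#' @param meta metacommunity object.
#' @param file output path (tab-separated).
#' @param tree_file optional newick output path.
#' @export
write_metacommunity <- function(meta, file, tree_file = NULL) {
  validate_metacommunity(meta)
  df <- data.frame(species_id = meta$species_id,
                   rel_abundance = meta$rel_abundance, trait = meta$trait)
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(tree_file) && !is.null(meta$tree))
    ape::write.tree(meta$tree, tree_file)
  invisible(file)
}

#' @rdname write_metacommunity
#' @param file path of a table written by [write_metacommunity()].
#' @export
read_metacommunity <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t")
  p <- df$rel_abundance / sum(df$rel_abundance)
  mu <- sum(p * df$trait)
  structure(list(species_id = df$species_id, rel_abundance = p,
                 trait = df$trait, trait_mean = mu,
                 trait_sd = sqrt(sum(p * (df$trait - mu)^2)),
                 tree = NULL, spec = NULL),
            class = "metacommunity")
}
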