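# Brute-force oracles and small generators shared across tests.

# naive O(J^2) per-individual pairwise/beta death rates: literal double loop
# over individuals, the independent check for the species-aggregated path
naive_pair_rates <- function(species_of, trait_of, s_E,
                             beta_intra = 1, beta_inter = 1) {
  J <- length(species_of)
  z <- trait_of[as.character(species_of)]
  q <- numeric(J)
  for (i in seq_len(J)) {
    acc <- 0
    for (j in seq_len(J)) {
      if (i == j) next
      b <- if (species_of[i] == species_of[j]) beta_intra else beta_inter
      acc <- acc + b * exp(-s_E * (z[i] - z[j])^2)
    }
    q[i] <- acc
  }
  q
}

# random species-level community state
random_state <- function(S = 20, J = 200) {
  ab <- as.integer(table(sample.int(S, J - S, replace = TRUE))) # may drop some
  ab <- c(ab, rep(1L, S - length(ab)))
  list(abundance = ab, traits = rnorm(length(ab), 0, 2))
}

tiny_meta <- function(n = 50, seed = 99, ...) {
  generate_metacommunity(metacommunity_spec(n_species = n, seed = seed, ...))
}

# two-point Chiu-Chao functional Hill number, closed form, for the oracle
two_point_fd <- function(p1, d, q) {
  p <- c(p1, 1 - p1)
  Q <- 2 * d * p[1] * p[2]
  terms <- 2 * (d / Q) * (p[1] * p[2])^q
  terms^(1 / (2 * (1 - q)))
}

# session-cached fixture batch (5 models x 20 sims at J = 200, fixed seed)
fixture_env <- new.env(parent = emptyenv())
fixture_table <- function() {
  if (is.null(fixture_env$table))
    fixture_env$table <- suppressWarnings(make_fixtures(seed = 42))
  fixture_env$table
}

# synthetic feature table matching the summary-statistic schema, with one
# informative column separating the classes; everything else is noise
toy_table <- function(n_per_class, classes = c("neutral", "filtering"),
                      sep = 10, seed = 1) {
  set.seed(seed)
  feats <- sumstats_schema()$column
  n <- n_per_class * length(classes)
  x <- as.data.frame(setNames(
    lapply(feats, function(f) rnorm(n)), feats))
  x$model <- rep(classes, each = n_per_class)
  x$S <- rnorm(n, mean = sep * (match(x$model, classes) - 1))
  x$lambda <- runif(n)
  x
}
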