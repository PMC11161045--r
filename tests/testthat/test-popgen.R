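# hand-built run object: one species, constant abundance 40 over 10
# generations, colonized at the founding
fake_run <- function(ab_by_gen, colgen = -1, alpha = 1000, gens = NULL) {
  gens <- gens %||% (seq_along(ab_by_gen) - 1)
  structure(list(
    species = data.frame(species_id = 1L, trait = 0,
                         abundance = ab_by_gen[length(ab_by_gen)],
                         n_founder = 0L,
                         n_colonist = ab_by_gen[length(ab_by_gen)],
                         colonization_gen = colgen),
    trajectory = data.frame(generation = gens, species_id = 1L,
                            abundance = ab_by_gen),
    generations = max(gens),
    params = list(alpha = alpha)), class = "assembly_run")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("constant abundance maps to a single backward size step", {
  run <- fake_run(rep(40, 11))
  h <- build_history(run, 1, alpha = 1000)
  expect_s3_class(h, "demographic_history")
  expect_equal(h$ne, 40000)
  expect_equal(h$duration, 10)
})

test_that("abundance change-points are preserved exactly", {
  run <- fake_run(c(rep(20, 5), rep(40, 6)))  # doubling at generation 5
  h <- build_history(run, 1)
  expect_equal(h$ne, c(40000, 20000))          # backward: recent first
  expect_equal(h$duration, c(6, 4))
  h2 <- build_history(run, 1, alpha = 2000)
  expect_equal(h2$ne, 2 * h$ne)                # exact linear scaling
  expect_equal(h2$duration, h$duration)
})

test_that("missing species and late colonization are handled", {
  run <- fake_run(rep(40, 11))
  expect_error(build_history(run, 99), "not extant")
  run2 <- fake_run(c(5, 30), colgen = 3.5, gens = c(4, 10))
  h <- build_history(run2, 1)
  # backward: 6 generations at n=30, then 0.5 at n=5 back to colonization
  expect_equal(h$ne, c(30000, 5000))
  expect_equal(h$duration, c(6, 0.5))
})

test_that("colonization at a generation boundary yields a valid history", {
  # the closing event of generation g records colonization_gen == g, so the
  # generation-g snapshot is the only record of the new residence
  run <- fake_run(3, colgen = 7, gens = 7)
  h <- build_history(run, 1)
  expect_s3_class(h, "demographic_history")
  expect_length(h$duration, 0)  # entire genealogy predates colonization
  g <- simulate_pi(h, n_haplotypes = 5, seed = 2)
  expect_gte(g$pi, 0)
})

test_that("zero mutation rate yields zero diversity", {
  g <- simulate_pi(demographic_history(100, 500), mu_per_site = 0, seed = 1)
  expect_equal(g$pi, 0)
  expect_equal(g$segregating_sites, 0)
  expect_error(simulate_pi(demographic_history(100, 500),
                           mu_per_site = -1), "non-negative")
  expect_error(simulate_pi(demographic_history(100, 500),
                           n_haplotypes = 1), ">= 2")
})

test_that("pairwise coalescence time matches the constant-Ne expectation", {
  # n = 2, haploid: TMRCA ~ Exp(mean Ne)
  ne <- 500
  h <- demographic_history(1e9, ne)
  set.seed(21)
  tm <- replicate(2000, simulate_pi(h, n_haplotypes = 2)$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - ne), 3 * se)
})

test_that("mean diversity matches theta = 2 Ne mu under constant size", {
  ne <- 2000; mu <- 5e-6
  h <- demographic_history(1e9, ne)
  set.seed(22)
  pis <- replicate(1000, simulate_pi(h, n_haplotypes = 10, mu_per_site = mu,
                                     locus_length_bp = 1000)$pi)
  theta <- 2 * ne * mu
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("a severe recent bottleneck depresses diversity", {
  ne <- 2000; mu <- 5e-6
  flat <- demographic_history(1e9, ne)
  # 100x size reduction lasting Ne/10 generations, then the flat control
  dip <- demographic_history(c(ne / 10, 1e9), c(ne / 100, ne))
  set.seed(23)
  p_flat <- replicate(2000, simulate_pi(flat, 10, mu, 500)$pi)
  p_dip <- replicate(2000, simulate_pi(dip, 10, mu, 500)$pi)
  expect_lt(t.test(p_dip, p_flat, alternative = "less")$p.value, 0.01)
})

test_that("diversity is invariant to the coalescent scaling c*Ne, mu/c", {
  set.seed(24)
  a <- replicate(2000, simulate_pi(demographic_history(1e9, 1000),
                                   10, 1e-5, 500)$pi)
  b <- replicate(2000, simulate_pi(demographic_history(1e9, 10000),
                                   10, 1e-6, 500)$pi)
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("community tables cover every extant species deterministically", {
  meta <- tiny_meta(40)
  run <- simulate_community(
    assembly_params(J = 150, m = 0.02, nu = 1e-3, model = "neutral",
                    lambda_target = 1, seed = 12), meta)
  t1 <- community_pi(run, seed = 5)
  t2 <- community_pi(run, seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), nrow(run$species))
  expect_setequal(t1$species_id, run$species$species_id)
  expect_true(all(t1$pi >= 0))
  expect_true(all(t1$pi[t1$segregating_sites == 0] == 0))
})
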