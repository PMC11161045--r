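make_community <- function(abundance, traits, colonist = NULL) {
  sid <- rep(seq_along(abundance), abundance)
  local_community(sid, setNames(traits, seq_along(abundance)), colonist)
}

test_that("neutral death weights are exactly uniform", {
  com <- make_community(c(600, 300, 100), c(-1, 0, 2))
  w <- death_weights(com, assembly_params(J = 1000, model = "neutral"))
  expect_identical(w, rep(1 / 1000, 1000))
})

test_that("filtering rates match the exponential-distance form", {
  # individual at squared distance 1 from the optimum, s_E = 0.1:
  # raw rate 1 - exp(-0.1); verified against a second individual at the
  # optimum plus epsilon to pin the normalization
  q <- assemblage:::species_death_rates(
    c(1L, 1L), c(1, 0),
    assembly_params(J = 2, model = "filtering", s_E = 0.1, z_E = 0))
  expect_equal(q[1], 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(q[1], 0.0951626, tolerance = 1e-6)
  expect_equal(q[2], 0, tolerance = 1e-12)
})

test_that("mean competition is uniform for a monomorphic community", {
  com <- make_community(c(500, 500), c(1.3, 1.3))
  w <- death_weights(com, assembly_params(J = 1000, model = "mean", s_E = 2))
  expect_equal(w, rep(1e-3, 1000), tolerance = 1e-12)
})

test_that("pairwise rates reproduce the three-individual hand example", {
  # two conspecifics at z = 0 and one individual at z = 1, s_E = 1:
  # q = (1 + e^-1, 1 + e^-1, 2 e^-1)
  q <- aggregated_pairwise_rates(c(2L, 1L), c(0, 1), s_E = 1)
  expect_equal(q, c(1 + exp(-1), 2 * exp(-1)), tolerance = 1e-12)
  expect_equal(q, c(1.36788, 0.73576), tolerance = 1e-5)
  com <- make_community(c(2, 1), c(0, 1))
  w <- death_weights(com, assembly_params(J = 3, model = "pairwise", s_E = 1))
  qq <- c(1 + exp(-1), 1 + exp(-1), 2 * exp(-1))
  expect_equal(w, qq / sum(qq), tolerance = 1e-12)
})

test_that("aggregated rates equal the naive per-individual double loop", {
  # the single-species boundary: self-exclusion only
  expect_equal(aggregated_pairwise_rates(10L, 0.7, s_E = 1), 9)
  set.seed(31)
  for (rep in 1:20) {
    st <- random_state(S = 15, J = 120)
    sid <- rep(seq_along(st$abundance), st$abundance)
    tof <- setNames(st$traits, seq_along(st$abundance))
    for (betas in list(c(1, 1), c(7, 0.5))) {
      agg <- aggregated_pairwise_rates(st$abundance, st$traits, 0.3,
                                       betas[1], betas[2])
      naive <- naive_pair_rates(sid, tof, 0.3, betas[1], betas[2])
      expect_lt(max(abs(rep(agg, st$abundance) - naive)), 1e-10)
    }
  }
})

test_that("beta with equal weights reduces to the pairwise kernel", {
  st <- random_state(S = 10, J = 80)
  com <- make_community(st$abundance, st$traits)
  wp <- death_weights(com, assembly_params(J = sum(st$abundance),
                                           model = "pairwise", s_E = 0.4))
  wb <- death_weights(com, assembly_params(J = sum(st$abundance),
                                           model = "beta", s_E = 0.4,
                                           beta_intra = 1, beta_inter = 1))
  expect_identical(wp, wb)
})

test_that("s_E = 0 gives exactly uniform weights for trait-blind kernels", {
  st <- random_state(S = 12, J = 100)
  J <- sum(st$abundance)
  com <- make_community(st$abundance, st$traits)
  for (mod in c("mean", "pairwise")) {
    w <- death_weights(com, assembly_params(J = J, model = mod, s_E = 0))
    expect_identical(w, rep(1 / J, J))
  }
  w <- death_weights(com, assembly_params(J = J, model = "beta", s_E = 0,
                                          beta_intra = 1, beta_inter = 1))
  expect_identical(w, rep(1 / J, J))
})

test_that("an all-zero rate vector falls back to uniform with a warning", {
  com <- make_community(c(5, 5), c(2, 2))
  p <- assembly_params(J = 10, model = "filtering", s_E = 1, z_E = 2)
  expect_warning(w <- death_weights(com, p), "uniform")
  expect_equal(w, rep(0.1, 10))
})

test_that("compiled per-species rates agree with the R reference", {
  set.seed(17)
  for (rep in 1:25) {
    st <- random_state(S = 18, J = 150)
    pars <- assembly_params(J = sum(st$abundance), model = "beta", s_E = 0.25,
                            z_E = 0.5, beta_intra = 4, beta_inter = 0.8)
    for (mod in c("neutral", "filtering", "mean", "pairwise", "beta")) {
      pars$model <- mod
      rr <- assemblage:::species_death_rates(st$abundance, st$traits, pars)
      cc <- assemblage:::cpp_species_rates(
        as.integer(st$abundance), st$traits, assemblage:::model_code(mod),
        pars$s_E, pars$z_E, pars$beta_intra, pars$beta_inter)
      expect_equal(cc, rr, tolerance = 1e-12)
    }
  }
})

test_that("death weights normalize to one for every model", {
  set.seed(23)
  st <- random_state(S = 25, J = 300)
  com <- make_community(st$abundance, st$traits)
  J <- sum(st$abundance)
  for (mod in c("neutral", "filtering", "mean", "pairwise", "beta")) {
    w <- death_weights(com, assembly_params(J = J, model = mod, s_E = 0.7,
                                            z_E = 0, beta_intra = 3,
                                            beta_inter = 1))
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-12)
  }
})
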