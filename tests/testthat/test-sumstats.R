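test_that("abundance Hill numbers match hand-computed values", {
  expect_equal(hill_abundance(rep(3, 10), 1), 10)
  expect_equal(hill_abundance(7, 2), 1)
  expect_equal(hill_abundance(c(0.5, 0.5), 2), 2)
  expect_equal(hill_abundance(c(0.9, 0.1), 2), 1 / 0.82, tolerance = 1e-12)
  expect_equal(hill_abundance(c(0.9, 0.1), 2), 1.2195, tolerance = 1e-4)
  expect_equal(hill_abundance(c(4, 2, 1, 1), 0), 4)  # order 0 is richness
  expect_error(hill_abundance(c(1, 2), -1), "non-negative")
})

test_that("genetic Hill numbers use proportion-normalized diversities", {
  expect_equal(hill_genetic(rep(0.01, 5), 2), 5)
  expect_equal(hill_genetic(c(0.3, 0, 0), 2), 1)
  expect_equal(hill_genetic(c(0.02, 0.01, 0.01), 1),
               exp(-sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25)))),
               tolerance = 1e-12)
  expect_equal(hill_genetic(c(0.02, 0.01, 0.01), 1), 2.8284,
               tolerance = 1e-4)
  expect_warning(out <- hill_genetic(c(0, 0), 2), "zero")
  expect_true(is.na(out))
})

test_that("trait Hill numbers match the brute-force functional form", {
  # two equally abundant, maximally distinct species: effective number 2
  expect_equal(hill_trait(c(0, 3), c(5, 5), 2), two_point_fd(0.5, 3, 2),
               tolerance = 1e-12)
  expect_equal(hill_trait(c(0, 3), c(5, 5), 2), 2, tolerance = 1e-12)
  # unequal abundances against the closed two-point form
  for (q in c(0.5, 2, 3)) {
    expect_equal(hill_trait(c(-1, 4), c(9, 1), q), two_point_fd(0.9, 5, q),
                 tolerance = 1e-12)
  }
  # scale invariance of the normalized-distance convention
  set.seed(4)
  z <- rnorm(8); ab <- sample(1:20, 8, replace = TRUE)
  for (q in 1:4) {
    expect_equal(hill_trait(z, ab, q), hill_trait(5.7 * z, ab, q),
                 tolerance = 1e-9)
  }
  # equal distances + equal abundances reduce to richness
  expect_equal(hill_trait(c(0, 1), c(3, 3), 3), 2, tolerance = 1e-12)
  # degenerate cases return the sentinel
  expect_true(is.na(hill_trait(1, 5, 2)))
  expect_warning(out <- hill_trait(c(2, 2, 2), c(1, 1, 1), 2), "identical")
  expect_true(is.na(out))
})

test_that("Hill profiles are non-increasing in q on random data", {
  set.seed(9)
  qs <- c(0, 0.5, 1, 1.5, 2, 3, 4)
  for (rep in 1:20) {
    counts <- sample(1:100, 12, replace = TRUE)
    prof <- vapply(qs, function(q) hill_abundance(counts, q), numeric(1))
    expect_true(all(diff(prof) <= 1e-9))
    pis <- runif(12, 0, 0.05)
    prof <- vapply(qs, function(q) hill_genetic(pis, q), numeric(1))
    expect_true(all(diff(prof) <= 1e-9))
  }
})

test_that("moments match hand arithmetic and large-sample limits", {
  m <- axis_moments(c(1, 2, 3))
  expect_equal(m[["mean"]], 2)
  expect_equal(m[["sd"]], 1)
  expect_equal(m[["skewness"]], 0)
  expect_true(is.na(m[["kurtosis"]]))  # needs 4 values
  m <- axis_moments(rep(5, 6))
  expect_equal(m[["sd"]], 0)
  expect_true(is.na(m[["skewness"]]) && is.na(m[["kurtosis"]]))
  set.seed(2)
  m <- axis_moments(rnorm(1e5))
  expect_lt(abs(m[["skewness"]]), 0.05)
  expect_lt(abs(m[["kurtosis"]]), 0.1)
})

test_that("Spearman correlations use average-rank ties", {
  expect_equal(spearman_cross(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)), 1)
  expect_equal(spearman_cross(1:5, 5:1), -1)
  expect_equal(spearman_cross(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearman_cross(c(1, 1, 1), c(1, 2, 3))))
})

test_that("trait divergence compares abundance-weighted local moments", {
  meta <- list(trait_mean = 1.5, trait_sd = 2)
  dv <- trait_divergence(c(1.5, 1.5), c(10, 5), meta)
  expect_equal(dv[["delta_mean"]], 0)
  expect_equal(dv[["delta_sd"]], -2)
  dv <- trait_divergence(4, 20, meta)  # single species: local SD is 0
  expect_equal(dv[["delta_mean"]], 2.5)
  expect_equal(dv[["delta_sd"]], -2)
})

test_that("feature vectors have fixed order and explicit sentinels", {
  sch <- sumstats_schema()
  ab <- c(20, 8, 3, 1)
  pis <- c(0.02, 0.01, 0, 0.005)
  z <- c(-1, 0, 0.5, 2)
  meta <- list(trait_mean = 0, trait_sd = 1)
  full <- summarize_axes(ab, pi = pis, traits = z, meta = meta, lambda = 0.8)
  expect_identical(names(full), sch$column)
  expect_true(!anyNA(full[, setdiff(sch$column, "lambda")]))

  masked <- summarize_axes(ab, pi = pis, traits = NULL, meta = meta,
                           lambda = 0.8)
  expect_identical(names(masked), sch$column)
  trait_cols <- sch$column[grepl("trait", sch$column)]
  expect_true(all(is.na(masked[, trait_cols])))
  other <- setdiff(sch$column, c(trait_cols, "lambda"))
  expect_true(!anyNA(masked[, other]))

  # recomputation is bit-identical
  expect_identical(full,
                   summarize_axes(ab, pi = pis, traits = z, meta = meta,
                                  lambda = 0.8))
})

test_that("features are invariant to species reordering", {
  set.seed(13)
  ab <- sample(1:50, 10); pis <- runif(10, 0, 0.03); z <- rnorm(10)
  meta <- list(trait_mean = 0, trait_sd = 1)
  a <- summarize_axes(ab, pis, z, meta, lambda = 1)
  o <- sample(10)
  b <- summarize_axes(ab[o], pis[o], z[o], meta, lambda = 1)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("richness consistency: order-0 abundance Hill equals S", {
  set.seed(14)
  ab <- sample(1:30, 17)
  expect_equal(hill_abundance(ab, 0), 17)
  row <- summarize_axes(ab)
  expect_equal(row$S, 17)
})
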