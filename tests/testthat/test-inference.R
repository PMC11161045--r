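test_that("axis masks select the documented feature columns", {
  all_feats <- mask_features("all")
  expect_false("lambda" %in% all_feats)
  expect_true("S" %in% mask_features(c("genetic")))
  tg <- mask_features("trait+gen")
  expect_true(all(c("pi_mean", "trait_sd", "rho_pi_trait") %in% tg))
  expect_false(any(c("abund_mean", "rho_abund_pi", "rho_abund_trait") %in% tg))
  sg <- mask_features("sad+gen")
  expect_true("rho_abund_pi" %in% sg)
  expect_false(any(grepl("trait", sg)))
  expect_error(mask_features("phylogeny"), "unknown data axes")
})

test_that("separable classes are learned almost perfectly", {
  tab <- toy_table(100, sep = 10, seed = 1)
  clf <- train_classifier(tab, axes = "all", num_trees = 300, seed = 5)
  expect_gte(clf$oob_accuracy, 0.99)
  # resubstitution: argmax recovers the generating label
  pr <- classify(clf, tab)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  hit <- names(pr)[max.col(as.matrix(pr))] == tab$model
  expect_gte(mean(hit), 0.95)
})

test_that("shuffled labels score at chance level", {
  tab <- toy_table(60, classes = c("neutral", "filtering", "mean",
                                   "pairwise", "beta"), sep = 0, seed = 2)
  cv <- cross_validate(tab, axes = "all", k = 5, num_trees = 300, seed = 3)
  n <- cv$n
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(cv$accuracy - 0.2), 3 * se)
  # off-diagonal mass ~ 80%
  expect_lt(abs(1 - cv$accuracy - 0.8), 3 * se)
})

test_that("training is deterministic under a fixed seed", {
  tab <- toy_table(50, sep = 3, seed = 4)
  c1 <- train_classifier(tab, num_trees = 200, seed = 11)
  c2 <- train_classifier(tab, num_trees = 200, seed = 11)
  expect_identical(classify(c1, tab), classify(c2, tab))
})

test_that("single-class training and schema mismatches error clearly", {
  tab <- toy_table(30, classes = "neutral")
  expect_error(train_classifier(tab), "2 distinct")
  tab2 <- toy_table(30, sep = 5)
  clf <- train_classifier(tab2, num_trees = 100, seed = 1)
  broken <- tab2[, setdiff(names(tab2), c("S", "pi_mean"))]
  expect_error(classify(clf, broken), "S")
  expect_error(classify(clf, broken), "pi_mean")
})

test_that("collapsing competition classes adds their probabilities exactly", {
  tab <- toy_table(40, classes = c("neutral", "pairwise", "beta"), sep = 2,
                   seed = 6)
  clf <- train_classifier(tab, num_trees = 200, seed = 7)
  p <- classify(clf, tab)
  pc <- classify(clf, tab, collapse_competition = TRUE)
  expect_identical(pc[["pairwise+beta"]], p$pairwise + p$beta)
  expect_true(all(abs(rowSums(pc) - 1) < 1e-9))
})

test_that("cross-validation bookkeeping is exact", {
  tab <- toy_table(40, classes = c("neutral", "filtering", "mean"), sep = 8,
                   seed = 8)
  cv <- cross_validate(tab, k = 5, num_trees = 200, seed = 9)
  expect_equal(as.integer(rowSums(cv$confusion)), rep(40L, 3))
  expect_gte(cv$accuracy, 0.95)  # separable toy: near-identity matrix
  expect_gte(cv$accuracy_collapsed, cv$accuracy)
  expect_error(cross_validate(tab, k = 50), "smallest class")
})

test_that("PCA handles rank-1 data, ratio ordering and isotropy", {
  sch_cols <- sumstats_schema()$column
  # exact line in feature space: PC1 carries all the variance
  n <- 50
  base <- seq_len(n)
  line <- as.data.frame(setNames(lapply(seq_along(sch_cols), function(i)
    base * i), sch_cols))
  line$lambda <- NA_real_
  p <- pca_projection(line, axes = "all", lambda_bins = NULL)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)

  tab <- toy_table(300, sep = 1, seed = 10)
  p <- pca_projection(tab, axes = "all")
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)

  # isotropic gaussian: every component explains ~ 1/d
  set.seed(11)
  d <- 10
  iso <- as.data.frame(matrix(rnorm(5000 * d), ncol = d))
  names(iso) <- mask_features("all")[1:d]
  fit <- prcomp(iso, scale. = TRUE)
  ratios <- fit$sdev^2 / sum(fit$sdev^2)
  expect_true(all(abs(ratios - 1 / d) < 0.02))

  # zero-variance columns are dropped with a warning
  tab$S <- 1
  expect_warning(pca_projection(tab, axes = "all"), "zero-variance")
})
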