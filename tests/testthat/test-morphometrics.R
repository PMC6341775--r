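make_traits <- function(values, species) {
  df <- data.frame(id = sprintf("i%03d", seq_along(species)),
                   species = species, cleft = FALSE,
                   stringsAsFactors = FALSE)
  for (tn in trait_names()) df[[tn]] <- 1
  df$corolla_width <- values
  trait_table(df)
}

test_that("one informative trait recovers the closed-form discriminant", {
  set.seed(1)
  tt <- make_traits(c(2 + rnorm(20, 0, 0.1), 3 + rnorm(20, 0, 0.1)),
                    rep(c("a_sp", "b_sp"), each = 20))
  m <- fit_lda(tt, features = "corolla_width")
  expect_equal(abs(unname(m$weights)), 1)
  expect_equal(diff(m$axis_group_centroids),
               mean(c(2, 3)[1]) - mean(c(2, 3)[2]) , tolerance = 0.2)
  # a point exactly midway between the group means scores (0.5, 0.5)
  mid <- mean(m$group_means[, "corolla_width"])
  post <- predict_lda(m, data.frame(id = "x", corolla_width = mid))
  expect_equal(post$a_sp, 0.5, tolerance = 1e-10)
  # at a group mean, that group's posterior exceeds 0.5
  post <- predict_lda(m, data.frame(id = "x",
                                    corolla_width = m$group_means[1, 1]))
  expect_gt(post$a_sp, 0.5)
})

test_that("identical group means give no discriminating direction", {
  v <- c(1.8, 1.9, 2.0, 2.1, 2.2)
  tt <- make_traits(c(v, v), rep(c("a_sp", "b_sp"), each = 5))
  expect_error(fit_lda(tt, features = "corolla_width"), "identical means")
})

test_that("classification is invariant to affine rescaling of a trait", {
  sim <- tiny_sim(5)
  m1 <- fit_lda(sim$traits)
  p1 <- predict_lda(m1, sim$traits)
  df <- as.data.frame(sim$traits)
  df$spur_length <- df$spur_length * 10 + 3
  tt2 <- trait_table(df)
  p2 <- predict_lda(fit_lda(tt2), tt2)
  expect_identical(p1$class, p2$class)
})

test_that("posteriors sum to one and match a density-formula oracle", {
  sim <- tiny_sim(6)
  m <- fit_lda(sim$traits)
  set.seed(2)
  X <- MASS::mvrnorm(100, colMeans(m$group_means), m$pooled_cov)
  colnames(X) <- m$trait_names
  df <- data.frame(id = seq_len(100), X, check.names = FALSE)
  p <- predict_lda(m, df)
  post <- as.matrix(p[, m$group_levels])
  expect_true(all(abs(rowSums(post) - 1) < 1e-12))
  for (i in seq_len(nrow(X))) {
    f1 <- oracle_mvn_density(X[i, ], m$group_means[1, ], m$pooled_cov)
    f2 <- oracle_mvn_density(X[i, ], m$group_means[2, ], m$pooled_cov)
    expect_equal(unname(post[i, 1]), as.numeric(f1 / (f1 + f2)),
                 tolerance = 1e-10)
  }
})

test_that("classifications agree with an independent LDA implementation", {
  sim <- tiny_sim(8)
  ref <- as.data.frame(sim$traits)
  ref <- ref[ref$species != UNKNOWN_LABEL, ]
  m <- fit_lda(sim$traits)
  ours <- predict_lda(m, trait_table(ref))
  fit <- MASS::lda(x = as.matrix(ref[trait_names()]),
                   grouping = factor(ref$species), prior = c(0.5, 0.5))
  theirs <- predict(fit, as.matrix(ref[trait_names()]))
  expect_identical(ours$class, as.character(theirs$class))
  expect_equal(ours[[m$group_levels[1]]],
               unname(theirs$posterior[, m$group_levels[1]]),
               tolerance = 1e-6)
})

test_that("cross-validation separates separable groups and not null ones", {
  set.seed(3)
  tt <- make_traits(c(rnorm(50, 0, 1), rnorm(50, 10, 1)) + 20,
                    rep(c("a_sp", "b_sp"), each = 50))
  cv <- repeated_kfold_cv(tt, repetitions = 30, seed = 4,
                          features = "corolla_width")
  expect_equal(cv$mean_error, 0)

  set.seed(5)
  null_tt <- make_traits(rnorm(100, 5, 1),
                         sample(rep(c("a_sp", "b_sp"), each = 50)))
  cv0 <- repeated_kfold_cv(null_tt, repetitions = 50, seed = 6,
                           features = "corolla_width")
  expect_lt(abs(cv0$mean_error - 0.5), 0.1)
})

test_that("cross-validation is deterministic and label-symmetric", {
  sim <- tiny_sim(9)
  cv1 <- repeated_kfold_cv(sim$traits, repetitions = 20, seed = 7)
  cv2 <- repeated_kfold_cv(sim$traits, repetitions = 20, seed = 7)
  expect_identical(cv1$per_repetition_errors, cv2$per_repetition_errors)
  expect_equal(cv1$mean_error, mean(cv1$per_repetition_errors))
  # relabelling the groups changes nothing
  df <- as.data.frame(sim$traits)
  df$species[df$species == "formosa"] <- "zz_formosa"
  cv3 <- repeated_kfold_cv(trait_table(df), repetitions = 20, seed = 7)
  expect_equal(cv3$mean_error, cv1$mean_error)
  expect_error(repeated_kfold_cv(sim$traits, k = 500), "smaller group")
})

test_that("trait summaries reproduce printed-style confidence bounds", {
  expect_equal(round(mean_se_ci(0.31, 0.01)[["ci_low"]], 2), 0.29)
  expect_equal(round(mean_se_ci(2.11, 0.04)[["ci_high"]], 2), 2.19)
  set.seed(8)
  x <- rnorm(50, 1, 0.2)
  ts <- trait_summary(x, trait = "spur_length", group = "formosa")
  expect_equal(ts$se, sd(x) / sqrt(50))
  expect_equal(ts$ci_low, ts$mean - 1.96 * ts$se)
  ts0 <- trait_summary(rep(2, 10))
  expect_equal(ts0$se, 0)
  expect_equal(ts0$ci_low, ts0$mean)
  expect_error(trait_summary(1), "at least 2")
})

test_that("Wilson proportion intervals match score-test inversion", {
  ci <- proportion_ci(36, 97)
  expect_equal(round(ci$ci_low, 2), 0.28)
  expect_equal(round(ci$ci_high, 2), 0.47)
  expect_equal(c(ci$ci_low, ci$ci_high), oracle_wilson_grid(36, 97),
               tolerance = 1e-5)
  # independent implementation: score interval from prop.test
  pt <- prop.test(36, 97, correct = FALSE)
  expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(pt$conf.int),
               tolerance = 1e-3)
  expect_equal(proportion_ci(0, 50)$ci_low, 0)
  expect_equal(proportion_ci(50, 50)$ci_high, 1)
})

test_that("pairwise trait correlations match the covariance formula", {
  sim <- tiny_sim(10)
  r <- pairwise_trait_correlations(sim$traits)
  expect_true(isSymmetric(r))
  expect_true(all(diag(r) == 1))
  X <- as.matrix(as.data.frame(sim$traits)[trait_names()])
  for (i in 1:6) for (j in (i + 1):7) {
    num <- mean((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j])))
    den <- sqrt(mean((X[, i] - mean(X[, i]))^2) * mean((X[, j] - mean(X[, j]))^2))
    expect_equal(r[i, j], num / den, tolerance = 1e-12)
  }
  # duplicated and anti-monotone traits
  df <- as.data.frame(sim$traits)
  df$lamina_width <- df$lamina_length
  df$sepal_width <- max(df$sepal_length) - df$sepal_length + 0.1
  r2 <- pairwise_trait_correlations(trait_table(df))
  expect_equal(r2["lamina_length", "lamina_width"], 1)
  expect_equal(r2["sepal_length", "sepal_width"], -1)
  df$spur_length <- 1
  r3 <- pairwise_trait_correlations(trait_table(df))
  expect_true(all(is.na(r3["spur_length", ])))
})
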