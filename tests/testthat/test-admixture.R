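small_cfg <- function(seed, runs = 2)
  admixture_config(burn_in = 500, iterations = 1000, n_runs = runs,
                   seed = seed)

test_that("Q rows normalise and reference Q is fixed by supervision", {
  sim <- tiny_sim(51)
  adm <- fit_supervised(sim$genotypes, small_cfg(1))
  expect_true(all(abs(adm$Q$Q_A + adm$Q$Q_B - 1) < 1e-9))
  refs <- adm$Q$is_reference
  expect_true(all(adm$Q$Q_A[refs] %in% c(0, 1)))
  expect_true(all(adm$Q$Q_A >= 0 & adm$Q$Q_A <= 1))
  expect_true(all(adm$Q$ci_low[!refs] <= adm$Q$Q_A[!refs] + 1e-9))
  expect_true(all(adm$Q$ci_high[!refs] >= adm$Q$Q_A[!refs] - 1e-9))
})

test_that("queries with species-private alleles assign almost fully", {
  # disjoint allele ladders built by hand: every query allele is private
  # to species A
  L <- 25; n_ref <- 8
  calls <- array(NA_real_, c(2 * n_ref + 2, L, 2))
  set.seed(52)
  for (j in seq_len(L)) {
    ladder_A <- 100 + j * 40 + c(0, 2)
    ladder_B <- 500 + j * 40 + c(0, 2)
    for (i in seq_len(n_ref))
      calls[i, j, ] <- sample(ladder_A, 2, replace = TRUE)
    for (i in n_ref + seq_len(n_ref))
      calls[i, j, ] <- sample(ladder_B, 2, replace = TRUE)
    for (i in 2 * n_ref + 1:2)
      calls[i, j, ] <- sample(ladder_A, 2, replace = TRUE)
  }
  gt <- genotype_table(
    data.frame(id = sprintf("i%02d", seq_len(2 * n_ref + 2)), site = "s",
               species = c(rep("a_sp", n_ref), rep("b_sp", n_ref),
                           rep(UNKNOWN_LABEL, 2)),
               is_reference = c(rep(TRUE, 2 * n_ref), FALSE, FALSE)),
    data.frame(name = sprintf("L%02d", seq_len(L)), motif_bp = 2), calls)
  adm <- fit_supervised(gt, small_cfg(2))
  q_a <- if (adm$species[1] == "a_sp") adm$Q$Q_A else adm$Q$Q_B
  expect_true(all(q_a[!adm$Q$is_reference] > 0.95))
})

test_that("an F1 swarm is estimated near half ancestry", {
  sim <- tiny_sim(53, n_hybrids = 30, hybrid_classes = c(F1 = 1),
                  divergence_F = 0.5)
  adm <- fit_supervised(sim$genotypes,
                        admixture_config(2000, 2000, n_runs = 2, seed = 3))
  q_formosa <- if (adm$species[1] == "formosa") adm$Q$Q_A else adm$Q$Q_B
  expect_equal(mean(q_formosa[!adm$Q$is_reference]), 0.5, tolerance = 0.05)
})

test_that("estimates are deterministic by seed and symmetric under relabel", {
  sim <- tiny_sim(54, n_hybrids = 10)
  a1 <- fit_supervised(sim$genotypes, small_cfg(4))
  a2 <- fit_supervised(sim$genotypes, small_cfg(4))
  expect_identical(a1$Q, a2$Q)
  # swap the two species labels: ancestry fractions swap
  gt2 <- sim$genotypes
  sp <- gt2$individuals$species
  gt2$individuals$species[sp == "formosa"] <- "flavescens"
  gt2$individuals$species[sp == "flavescens"] <- "formosa"
  a3 <- fit_supervised(gt2, admixture_config(2000, 2000, n_runs = 2, seed = 5))
  a1b <- fit_supervised(sim$genotypes,
                        admixture_config(2000, 2000, n_runs = 2, seed = 5))
  qq <- !a1b$Q$is_reference
  expect_equal(a3$Q$Q_A[qq], a1b$Q$Q_B[qq], tolerance = 0.03)
})

test_that("run averaging is the element-wise mean with SD diagnostics", {
  sim <- tiny_sim(55, n_hybrids = 4)
  e1 <- fit_supervised(sim$genotypes, small_cfg(6, runs = 1))
  e2 <- fit_supervised(sim$genotypes, small_cfg(7, runs = 1))
  avg <- average_runs(list(e1, e2))
  expect_equal(avg$Q$Q_A, (e1$Q$Q_A + e2$Q$Q_A) / 2)
  same <- average_runs(list(e1, e1))
  expect_equal(same$Q$Q_A, e1$Q$Q_A)
  expect_true(all(same$run_sd == 0))
  e3 <- e2; e3$Q <- e3$Q[-1, ]
  expect_error(average_runs(list(e1, e3)), "different individual")
})

test_that("across-run consistency is tight at default simulation scale", {
  sim <- tiny_sim(56)
  adm <- fit_supervised(sim$genotypes,
                        admixture_config(1000, 1000, n_runs = 4, seed = 8))
  expect_lt(max(adm$run_sd), 0.05)
})

test_that("missing references are an error", {
  sim <- tiny_sim(57)
  gt <- sim$genotypes
  gt$individuals$is_reference[gt$individuals$species == "formosa"] <- FALSE
  gt$individuals$species[gt$individuals$species == "formosa"] <- UNKNOWN_LABEL
  expect_error(fit_supervised(gt, small_cfg(9)), "two species")
})

test_that("leave-one-out posteriors match a brute-force Bayes oracle", {
  sim <- tiny_sim(58, n_ref_A = 6, n_ref_B = 6, n_hybrids = 2)
  ap <- assignment_posteriors(sim$genotypes, freq_prior_lambda = 1)
  gt <- sim$genotypes
  ind <- gt$individuals
  sp <- sort(unique(ind$species[ind$is_reference]))
  for (k in seq_len(nrow(ap))) {
    i <- which(ind$id == ap$id[k])
    logl <- sapply(sp, function(s) {
      others <- which(ind$is_reference & ind$species == s & seq_len(nrow(ind)) != i)
      ll <- 0
      for (j in seq_len(nrow(gt$loci))) {
        pool <- as.numeric(gt$calls[ind$is_reference | !ind$is_reference, j, ])
        states <- sort(unique(pool[!is.na(pool)]))
        cnt <- table(factor(as.numeric(gt$calls[others, j, ]), levels = states))
        tot <- sum(cnt) + length(states)
        for (a in gt$calls[i, j, ]) {
          if (is.na(a)) next
          ll <- ll + log((cnt[[as.character(a)]] + 1) / tot)
        }
      }
      ll
    })
    own <- ind$species[i]
    post <- exp(logl - max(logl)); post <- post / sum(post)
    expect_equal(ap$posterior_correct[k], unname(post[own]), tolerance = 1e-10)
  }
})

test_that("symmetric genotypes get a half-half assignment posterior", {
  calls <- array(NA_real_, c(5, 1, 2))
  for (i in 1:5) calls[i, 1, ] <- c(100, 102)
  gt <- genotype_table(
    data.frame(id = sprintf("r%d", 1:5), site = "s",
               species = c("a_sp", "a_sp", "b_sp", "b_sp", "a_sp"),
               is_reference = TRUE),
    data.frame(name = "L1", motif_bp = 2), calls)
  ap <- assignment_posteriors(gt)
  expect_true(all(abs(ap$posterior_correct - 0.5) < 1e-12))
})

test_that("single-reference species is flagged for leave-one-out", {
  calls <- array(rep(c(100, 102), each = 3), c(3, 1, 2))
  gt <- genotype_table(
    data.frame(id = c("r1", "r2", "r3"), site = "s",
               species = c("a_sp", "a_sp", "b_sp"), is_reference = TRUE),
    data.frame(name = "L1", motif_bp = 2), calls)
  expect_warning(ap <- assignment_posteriors(gt), "single reference")
  expect_true(is.na(ap$posterior_correct[ap$species == "b_sp"]))
})
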