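gt_from_calls <- function(calls_by_locus, motif = 2,
                          species = NULL, site = NULL) {
  # calls_by_locus: list of n x 2 matrices, one per locus
  n <- nrow(calls_by_locus[[1]])
  L <- length(calls_by_locus)
  calls <- array(NA_real_, c(n, L, 2))
  for (j in seq_len(L)) calls[, j, ] <- calls_by_locus[[j]]
  if (is.null(species)) species <- rep("formosa", n)
  if (is.null(site)) site <- rep("s1", n)
  genotype_table(
    data.frame(id = sprintf("i%02d", 1:n), site = site, species = species,
               is_reference = species != UNKNOWN_LABEL),
    data.frame(name = sprintf("L%02d", 1:L),
               motif_bp = rep_len(motif, L)),
    calls)
}

test_that("locus summaries have the right closed forms", {
  gt <- gt_from_calls(list(cbind(rep(100, 6), rep(100, 6)),
                           cbind(rep(100, 6), rep(102, 6))))
  ls <- locus_summaries(gt)
  expect_equal(ls$n_alleles, c(1, 2))
  expect_equal(ls$Ho, c(0, 1))
  expect_equal(ls$He, c(0, 0.5))
  expect_equal(ls$size_min[2], 100)
  expect_equal(ls$size_max[2], 102)
})

test_that("expected heterozygosity matches a counting oracle", {
  sim <- tiny_sim(31)
  ls <- locus_summaries(sim$genotypes)
  for (j in seq_len(nrow(ls))) {
    a <- as.numeric(sim$genotypes$calls[, j, ])
    expect_equal(ls$He[j], oracle_he(a[!is.na(a)]), tolerance = 1e-12)
  }
})

test_that("population summaries follow the unbiased estimator", {
  # all identical homozygotes: everything zero, Fis undefined
  gt <- gt_from_calls(list(cbind(rep(100, 5), rep(100, 5))))
  ps <- population_summaries(gt)
  expect_equal(ps$shannon_H, 0)
  expect_equal(ps$Ho, 0)
  expect_equal(ps$Hs, 0)
  expect_true(is.na(ps$Fis))
  # ten individuals all heterozygous A/B at one locus
  gt <- gt_from_calls(list(cbind(rep(100, 10), rep(102, 10))))
  ps <- population_summaries(gt)
  expect_equal(ps$Ho, 1)
  expect_equal(ps$Hs, 0.5)
  expect_equal(ps$Fis, -1)
  expect_equal(ps$shannon_H, log(2))
})

test_that("Bruvo distance reproduces the worked pairing example", {
  gt <- gt_from_calls(list(rbind(c(200, 203), c(200, 206))), motif = 3)
  D <- bruvo_distance(gt)
  expect_equal(D[1, 2], 0.25)
  # identical genotypes are at distance zero
  gt2 <- gt_from_calls(list(rbind(c(200, 203), c(203, 200))), motif = 3)
  expect_equal(bruvo_distance(gt2)[1, 2], 0)
})

test_that("Bruvo distance equals the pairing-enumeration oracle", {
  set.seed(32)
  motifs <- c(2, 3, 5)
  for (rep in 1:50) {
    calls <- lapply(motifs, function(m)
      matrix(sample(seq(100, 140, by = m), 4, replace = TRUE), 2, 2))
    gt <- gt_from_calls(calls)
    gt$loci$motif_bp <- motifs
    D <- bruvo_distance(gt)
    g1 <- t(vapply(calls, function(cl) cl[1, ], numeric(2)))
    g2 <- t(vapply(calls, function(cl) cl[2, ], numeric(2)))
    expect_equal(D[1, 2], oracle_bruvo_pair(g1, g2, motifs), tolerance = 1e-12)
    expect_equal(D[1, 2], D[2, 1])
  }
})

test_that("Bruvo handles missing loci by pairwise deletion", {
  calls <- list(rbind(c(200, 202), c(NA, NA)), rbind(c(300, 300), c(302, 304)))
  gt <- gt_from_calls(calls)
  D <- bruvo_distance(gt)
  # only locus 2 is shared
  expect_equal(D[1, 2], min(mean(c(1 - 2^-1, 1 - 2^-2)),
                            mean(c(1 - 2^-2, 1 - 2^-1))))
  calls <- list(rbind(c(200, 202), c(NA, NA)), rbind(c(NA, NA), c(302, 304)))
  expect_error(bruvo_distance(gt_from_calls(calls)), "no shared")
})

test_that("Bruvo matrix on simulated data is a valid bounded distance", {
  sim <- tiny_sim(33)
  D <- bruvo_distance(sim$genotypes)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("PCoA round-trips Euclidean configurations without correction", {
  set.seed(34)
  pts <- matrix(rnorm(8), 4, 2)
  rownames(pts) <- letters[1:4]
  D <- as.matrix(dist(pts))
  res <- pcoa_ordination(D)
  expect_false(res$correction_applied)
  emb <- as.matrix(dist(res$coordinates))
  expect_equal(unname(emb), unname(D), tolerance = 1e-9)
})

test_that("PCoA corrects non-Euclidean matrices and degenerate input", {
  D <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 2.8,
                1, 1, 2.8, 0), 4, 4)  # violates triangle embedding
  rownames(D) <- colnames(D) <- letters[1:4]
  res <- pcoa_ordination(D)
  expect_true(res$correction_applied)
  expect_true(all(res$eigenvalues >= -1e-8))
  res0 <- pcoa_ordination(matrix(0, 3, 3, dimnames = list(1:3, 1:3)))
  expect_true(all(res0$eigenvalues == 0))
  expect_error(pcoa_ordination(matrix(0, 2, 2)), "at least 3")
})

test_that("UPGMA agglomerates a three-taxon ultrametric matrix by hand", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(D, "upgma")
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  # two taxa: single split of total length d
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(sum(build_tree(D2, "upgma")$edge.length), 0.4)
  expect_equal(sum(build_tree(D2, "nj")$edge.length), 0.4)
})

test_that("NJ exactly recovers additive distance matrices", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr0)
  tr <- build_tree(D, "nj")
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
  set.seed(35)
  for (n in c(5, 8)) {
    rt <- ape::rtree(n)
    D <- ape::cophenetic.phylo(rt)
    tr <- build_tree(D, "nj")
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  D[1, 2] <- D[2, 1] <- NA
  expect_error(build_tree(D, "nj"), "NaN/NA")
})

test_that("UPGMA on simulated Bruvo distances is ultrametric", {
  sim <- tiny_sim(36)
  tr <- build_tree(bruvo_distance(sim$genotypes), "upgma")
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  expect_setequal(tr$tip.label, sim$genotypes$individuals$id)
})
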