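## Microsatellite summary statistics, Bruvo's genetic distance, principal
## coordinate analysis with negative-eigenvalue correction, and NJ/UPGMA
## distance trees.

#' Per-locus summary statistics (pooled over all individuals)
#'
#' For each locus with at least one complete call: allele size range (bp),
#' number of alleles, observed heterozygosity Ho (fraction of heterozygous
#' complete calls) and expected heterozygosity `He = 1 - sum(p^2)` over
#' pooled allele frequencies. Loci with no complete calls are omitted with
#' a warning.
#'
#' @param genotypes a [genotype_table()].
#' @return data.frame: `locus`, `motif_bp`, `size_min`, `size_max`,
#'   `n_alleles`, `Ho`, `He`.
#' @export
locus_summaries <- function(genotypes) {
  L <- nrow(genotypes$loci)
  rows <- lapply(seq_len(L), function(j) {
    a1 <- genotypes$calls[, j, 1]; a2 <- genotypes$calls[, j, 2]
    ok <- !is.na(a1)
    if (!any(ok)) {
      warning("locus ", genotypes$loci$name[j], " has no complete calls; omitted")
      return(NULL)
    }
    alleles <- c(a1[ok], a2[ok])
    p <- table(alleles) / length(alleles)
    data.frame(locus = genotypes$loci$name[j],
               motif_bp = genotypes$loci$motif_bp[j],
               size_min = min(alleles), size_max = max(alleles),
               n_alleles = length(p),
               Ho = mean(a1[ok] != a2[ok]),
               He = 1 - sum(p^2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Per-locus within-population statistics for one population's calls.
pop_locus_stats <- function(a1, a2) {
  ok <- !is.na(a1)
  if (!any(ok)) return(NULL)
  n <- sum(ok)
  alleles <- c(a1[ok], a2[ok])
  p <- as.numeric(table(alleles)) / (2 * n)
  Ho <- mean(a1[ok] != a2[ok])
  Hs <- if (n > 1) (n / (n - 1)) * (1 - sum(p^2) - Ho / (2 * n)) else NA_real_
  c(H = -sum(p * log(p)), Ho = Ho, Hs = Hs)
}

#' Per-population summary statistics
#'
#' Within each population (by default, field site), per-locus statistics are
#' averaged over loci: Shannon entropy of allele frequencies
#' `H = -sum(p log p)`, observed heterozygosity Ho, and Nei's unbiased gene
#' diversity `Hs = n/(n-1) (1 - sum(p^2) - Ho/(2n))`. The inbreeding
#' coefficient is `Fis = 1 - Ho/Hs` on the locus-averaged values (NA when
#' Hs = 0).
#'
#' @param genotypes a [genotype_table()].
#' @param grouping individuals column to group by (`"site"` or
#'   `"species"`).
#' @return data.frame: `population`, `n`, `shannon_H`, `Ho`, `Hs`, `Fis`.
#' @export
population_summaries <- function(genotypes, grouping = "site") {
  g <- genotypes$individuals[[grouping]]
  rows <- lapply(unique(g), function(pop) {
    idx <- which(g == pop)
    if (length(idx) < 2) stop("population '", pop, "' has fewer than 2 individuals")
    st <- vapply(seq_len(nrow(genotypes$loci)), function(j) {
      s <- pop_locus_stats(genotypes$calls[idx, j, 1], genotypes$calls[idx, j, 2])
      if (is.null(s)) c(H = NA_real_, Ho = NA_real_, Hs = NA_real_) else s
    }, c(H = 0, Ho = 0, Hs = 0))
    m <- rowMeans(st, na.rm = TRUE)
    data.frame(population = pop, n = length(idx),
               shannon_H = m["H"], Ho = m["Ho"], Hs = m["Hs"],
               Fis = if (is.finite(m["Hs"]) && m["Hs"] > 0)
                       1 - m["Ho"] / m["Hs"] else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

bruvo_allele <- function(x, y, motif) 1 - 2^(-abs(x - y) / motif)

#' Bruvo's genetic distance between diploid microsatellite genotypes
#'
#' Allele distance `1 - 2^(-|a - b| / motif)` under a symmetric geometric
#' mutation model; the per-locus genotype distance is the minimum over the
#' two one-to-one allele pairings of the mean allele distance, and the
#' individual distance is the mean over loci where both individuals have
#' complete calls (pairwise deletion). Fractional repeat differences are
#' used as-is.
#'
#' @param genotypes a [genotype_table()].
#' @return Symmetric matrix in \[0, 1\] with zero diagonal, dimnames =
#'   individual ids.
#' @export
bruvo_distance <- function(genotypes) {
  n <- nrow(genotypes$individuals)
  L <- nrow(genotypes$loci)
  total <- matrix(0, n, n)
  count <- matrix(0L, n, n)
  for (j in seq_len(L)) {
    motif <- genotypes$loci$motif_bp[j]
    a1 <- genotypes$calls[, j, 1]; a2 <- genotypes$calls[, j, 2]
    d11 <- bruvo_allele(outer(a1, a1, "-"), 0, motif)
    d22 <- bruvo_allele(outer(a2, a2, "-"), 0, motif)
    d12 <- bruvo_allele(outer(a1, a2, "-"), 0, motif)
    d21 <- bruvo_allele(outer(a2, a1, "-"), 0, motif)
    dloc <- pmin((d11 + d22) / 2, (d12 + d21) / 2)
    ok <- !is.na(dloc)
    total[ok] <- total[ok] + dloc[ok]
    count <- count + ok
  }
  if (any(count == 0 & row(count) != col(count))) {
    idx <- which(count == 0 & row(count) != col(count), arr.ind = TRUE)[1, ]
    stop("no shared complete loci between individuals '",
         genotypes$individuals$id[idx[1]], "' and '",
         genotypes$individuals$id[idx[2]], "'")
  }
  d <- total / count
  diag(d) <- 0
  dimnames(d) <- list(genotypes$individuals$id, genotypes$individuals$id)
  d
}

#' Principal coordinate analysis with negative-eigenvalue correction
#'
#' Gower-centred metric scaling of a distance matrix. If the uncorrected
#' decomposition yields eigenvalues below `-1e-8` (a non-Euclidean matrix),
#' the Cailliez (default) or Lingoes additive-constant correction is applied
#' and the decomposition repeated. Coordinates are scaled by the square root
#' of their eigenvalues.
#'
#' @param d symmetric distance matrix (n >= 3).
#' @param correction `"cailliez"`, `"lingoes"` or `"none"`.
#' @return list of class `pcoa_result`: `coordinates` (n x m),
#'   `eigenvalues` (descending), `correction_applied`.
#' @export
pcoa_ordination <- function(d, correction = c("cailliez", "lingoes", "none")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("PCoA needs at least 3 individuals")
  if (all(d == 0)) {
    return(structure(list(coordinates = matrix(0, nrow(d), 1,
                                               dimnames = list(rownames(d), "Axis.1")),
                          eigenvalues = rep(0, nrow(d)),
                          correction_applied = FALSE),
                     class = "pcoa_result"))
  }
  res <- ape::pcoa(d)
  eig <- res$values$Eigenvalues
  applied <- FALSE
  coords <- res$vectors
  if (min(eig) < -1e-8 && correction != "none") {
    res <- ape::pcoa(d, correction = correction)
    coords <- if (!is.null(res$vectors.cor)) res$vectors.cor else res$vectors
    eig <- if ("Corr_eig" %in% names(res$values)) res$values$Corr_eig
           else res$values$Eigenvalues
    applied <- TRUE
  }
  colnames(coords) <- paste0("Axis.", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 correction_applied = applied),
            class = "pcoa_result")
}

#' Distance trees by neighbour joining or UPGMA
#'
#' NJ uses the Saitou-Nei Q-criterion; UPGMA is average-linkage
#' agglomeration (ultrametric output). NJ can produce small negative branch
#' lengths; with `clamp_negative = TRUE` these are set to zero and the
#' deficit transferred to the adjacent edge.
#'
#' @param d symmetric distance matrix with individual ids as dimnames.
#' @param method `"nj"` or `"upgma"`.
#' @param clamp_negative clamp negative NJ branch lengths (default FALSE).
#' @return An [ape::phylo] tree whose tip labels are the input ids.
#' @export
build_tree <- function(d, method = c("nj", "upgma"), clamp_negative = FALSE) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (any(is.na(d))) stop("distance matrix contains NaN/NA")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 individuals")
  if (method == "nj") {
    if (n == 2) {
      txt <- sprintf("(%s:%g,%s:%g);", rownames(d)[1], d[1, 2] / 2,
                     rownames(d)[2], d[1, 2] / 2)
      return(ape::read.tree(text = txt))
    }
    tree <- ape::nj(stats::as.dist(d))
    if (clamp_negative && any(tree$edge.length < 0)) {
      for (e in which(tree$edge.length < 0)) {
        parent <- tree$edge[e, 1]
        sib <- which(tree$edge[, 1] == parent & seq_along(tree$edge.length) != e)
        if (length(sib))
          tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + tree$edge.length[e]
        tree$edge.length[e] <- 0
      }
    }
    tree
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    ape::as.phylo(hc)
  }
}
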