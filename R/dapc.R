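## Discriminant analysis of principal components (DAPC) for two reference
## groups: allele dosages are centred/scaled, projected onto principal
## components, and a linear discriminant is fitted on the retained PCs. The
## number of PCs is chosen by the a-score (observed reassignment proportion
## minus the reassignment expected under random group permutation).

#' Individual-by-allele dosage matrix
#'
#' One column per (locus, allele length) pair; entries are allele counts
#' divided by two (0, 0.5, 1). Missing calls give NA dosages.
#'
#' @param genotypes a [genotype_table()].
#' @param columns optional character vector `"locus:length"` fixing the
#'   column set (unseen alleles in `genotypes` are dropped).
#' @return numeric matrix, rownames = individual ids.
#' @export
allele_dosage_matrix <- function(genotypes, columns = NULL) {
  n <- nrow(genotypes$individuals)
  cols <- list()
  for (j in seq_len(nrow(genotypes$loci))) {
    a1 <- genotypes$calls[, j, 1]; a2 <- genotypes$calls[, j, 2]
    lens <- sort(unique(c(a1, a2)))
    lens <- lens[!is.na(lens)]
    for (al in lens) {
      nm <- paste0(genotypes$loci$name[j], ":", al)
      dos <- ((a1 == al) + (a2 == al)) / 2
      cols[[nm]] <- dos
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- genotypes$individuals$id
  if (!is.null(columns)) {
    extra <- setdiff(colnames(X), columns)
    if (length(extra))
      warning(length(extra), " allele column(s) absent from model dropped")
    out <- matrix(0, n, length(columns),
                  dimnames = list(rownames(X), columns))
    common <- intersect(columns, colnames(X))
    out[, common] <- X[, common]
    # loci wholly missing in an individual stay NA for known columns
    for (cm in common) out[is.na(X[, cm]), cm] <- NA
    X <- out
  }
  X
}

reassignment_prop <- function(scores, groups) {
  m <- lda_core(scores, groups, colnames(scores), ridge = 1e-6)
  post <- posterior_core(m, scores, c(0.5, 0.5))
  pred <- m$group_levels[ifelse(post[, 1] >= 0.5, 1, 2)]
  mean(pred == as.character(groups))
}

#' Fit a DAPC model on reference individuals
#'
#' Centres and unit-scales the allele dosage matrix (zero-variance columns
#' dropped, missing dosages mean-imputed), projects onto principal
#' components, and fits a two-group linear discriminant on the retained
#' PCs. With `n_pcs = "auto"`, each candidate PC count is scored by its
#' a-score (observed reassignment proportion minus the mean reassignment
#' under `n_perm` random permutations of the group labels) and the count
#' with the highest a-score is retained.
#'
#' @param genotypes a [genotype_table()]; only reference individuals (two
#'   species, >= 3 each) are used.
#' @param n_pcs `"auto"` or a fixed PC count (clamped to those available,
#'   with a warning).
#' @param n_perm permutations per candidate for the a-score (default 100).
#' @param seed integer RNG seed or `NULL`.
#' @return list of class `dapc_model`: dosage `columns`, `center`/`scale`
#'   vectors, PC `rotation`, `n_pcs_retained`, the inner `discriminant`
#'   model, `a_score`, the full `a_score_table`, and axis
#'   `group_centroids`.
#' @export
dapc_fit <- function(genotypes, n_pcs = "auto", n_perm = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- subset_genotypes(genotypes, genotypes$individuals$is_reference)
  groups <- factor(ref$individuals$species)
  if (nlevels(groups) != 2 || any(table(groups) < 3))
    stop("need two reference groups with >= 3 individuals each")
  X <- allele_dosage_matrix(ref)
  ctr <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2, ctr)
  X[is.na(X)] <- 0                          # mean imputation after centring
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  X <- sweep(X[, keep, drop = FALSE], 2, scl[keep], "/")
  pca <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  n <- nrow(X)
  pos <- sum(pca$sdev > 1e-9)
  max_pc <- min(pos, n - 4, 20)
  if (max_pc < 1) stop("too few individuals for DAPC")
  scores <- pca$x
  if (identical(n_pcs, "auto")) {
    cand <- seq_len(max_pc)
    atab <- vapply(cand, function(np) {
      sc <- scores[, seq_len(np), drop = FALSE]
      obs <- reassignment_prop(sc, groups)
      perm <- vapply(seq_len(n_perm), function(i) {
        reassignment_prop(sc, sample(groups))
      }, 0)
      c(n_pcs = np, observed = obs, a_score = obs - mean(perm))
    }, c(n_pcs = 0, observed = 0, a_score = 0))
    atab <- as.data.frame(t(atab))
    np <- atab$n_pcs[which.max(atab$a_score)]
    a_score <- max(atab$a_score)
  } else {
    np <- as.integer(n_pcs)
    if (np > max_pc) {
      warning("requested ", np, " PCs; only ", max_pc, " usable - clamped")
      np <- max_pc
    }
    sc <- scores[, seq_len(np), drop = FALSE]
    obs <- reassignment_prop(sc, groups)
    perm <- vapply(seq_len(n_perm), function(i)
      reassignment_prop(sc, sample(groups)), 0)
    a_score <- obs - mean(perm)
    atab <- data.frame(n_pcs = np, observed = obs, a_score = a_score)
  }
  disc <- lda_core(scores[, seq_len(np), drop = FALSE], groups,
                   colnames(scores)[seq_len(np)], ridge = 1e-6)
  structure(list(columns = names(ctr), center = ctr,
                 scale = scl, keep = keep,
                 rotation = pca$rotation[, seq_len(np), drop = FALSE],
                 n_pcs_retained = np, discriminant = disc,
                 a_score = a_score, a_score_table = atab,
                 group_centroids = disc$axis_group_centroids,
                 group_levels = disc$group_levels),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("<dapc_model> %s vs %s; %d PCs retained (a-score %.3f)\n",
              x$group_levels[1], x$group_levels[2],
              x$n_pcs_retained, x$a_score))
  invisible(x)
}

#' Score query genotypes on a fitted DAPC axis
#'
#' Query dosages are centred/scaled with the model's vectors (alleles unseen
#' by the model are dropped with a warning; missing dosages imputed to the
#' model mean), projected through the stored PC loadings, and scored on the
#' discriminant axis with equal-prior Gaussian posteriors.
#'
#' @param model a `dapc_model`.
#' @param genotypes a [genotype_table()] of query individuals.
#' @return data.frame: `id`, `score`, posterior columns for the two groups,
#'   `class`.
#' @export
dapc_predict <- function(model, genotypes) {
  X <- allele_dosage_matrix(genotypes, columns = model$columns)
  X <- sweep(X, 2, model$center)
  X[is.na(X)] <- 0
  X <- sweep(X[, model$keep, drop = FALSE], 2,
             model$scale[model$keep], "/")
  sc <- X %*% model$rotation
  post <- posterior_core(model$discriminant, sc, c(0.5, 0.5))
  out <- data.frame(id = genotypes$individuals$id,
                    score = as.numeric(sc %*% model$discriminant$weights),
                    stringsAsFactors = FALSE)
  out[[model$group_levels[1]]] <- post[, 1]
  out[[model$group_levels[2]]] <- post[, 2]
  out$class <- model$group_levels[ifelse(post[, 1] >= 0.5, 1, 2)]
  out
}
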