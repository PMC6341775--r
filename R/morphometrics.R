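## Two-group linear discriminant analysis of floral traits, repeated k-fold
## cross-validation, and the descriptive statistics used for trait tables
## (mean/SE/normal CI) and proportions (Wilson score interval).

# Core two-group LDA on a numeric matrix. Returns loadings proportional to
# pooled_cov^{-1} (mu1 - mu2), scaled to unit length, sign fixed so group 1
# projects above group 2. `ridge` adds a small multiple of the mean diagonal
# to the pooled covariance; used by DAPC where a PC can have zero
# within-group variance under perfect separation.
lda_core <- function(X, groups, feature_names = colnames(X), ridge = 0) {
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("exactly two groups are required, got: ",
         paste(levels(groups), collapse = ", "))
  ns <- table(groups)
  if (any(ns < 2))
    stop("each group needs at least 2 complete rows (",
         paste(names(ns)[ns < 2], collapse = ", "), ")")
  X <- as.matrix(X)
  mu1 <- colMeans(X[groups == levels(groups)[1], , drop = FALSE])
  mu2 <- colMeans(X[groups == levels(groups)[2], , drop = FALSE])
  S1 <- stats::cov(X[groups == levels(groups)[1], , drop = FALSE])
  S2 <- stats::cov(X[groups == levels(groups)[2], , drop = FALSE])
  Sp <- ((ns[1] - 1) * S1 + (ns[2] - 1) * S2) / (sum(ns) - 2)
  if (ridge > 0)
    Sp <- Sp + diag(ridge * max(mean(diag(Sp)), 1e-12), ncol(Sp))
  if (rcond(Sp) < 1e-12) {
    cc <- stats::cov2cor(Sp)
    worst <- which(abs(cc) > 0.999 & row(cc) < col(cc), arr.ind = TRUE)
    hint <- if (nrow(worst)) paste(feature_names[worst[1, 1]], "~",
                                   feature_names[worst[1, 2]])
            else "near-zero variance"
    stop("pooled within-group covariance is singular (", hint, ")")
  }
  w <- solve(Sp, mu1 - mu2)
  nrm <- sqrt(sum(w^2))
  if (nrm < 1e-12 || sum(w * (mu1 - mu2)) <= 0)
    stop("groups have identical means: no discriminating direction")
  w <- w / nrm
  structure(list(group_levels = levels(groups),
                 group_means = rbind(mu1, mu2),
                 pooled_cov = Sp,
                 weights = stats::setNames(w, feature_names),
                 axis_group_centroids = c(sum(w * mu1), sum(w * mu2)),
                 priors = c(0.5, 0.5),
                 trait_names = feature_names),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("<discriminant_model>", paste(x$group_levels, collapse = " vs "), "\n")
  print(round(x$weights, 3))
  cat("axis centroids:", paste(round(x$axis_group_centroids, 3), collapse = ", "), "\n")
  invisible(x)
}

complete_trait_rows <- function(traits, features) {
  ok <- stats::complete.cases(as.data.frame(traits)[features])
  if (!all(ok))
    message(sum(!ok), " row(s) with missing traits excluded")
  traits[ok, , drop = FALSE]
}

#' Fit a two-group linear discriminant of floral traits
#'
#' Fits the Fisher discriminant between the two labelled species in a trait
#' table: loadings are proportional to `pooled_cov^-1 (mu1 - mu2)`,
#' normalised to unit length, with sign fixed so the first group's centroid
#' lies above the second's on the axis. Rows with any missing feature are
#' excluded (complete-case).
#'
#' @param traits a [trait_table()]; rows labelled `UNKNOWN` are ignored.
#' @param features feature columns to use; defaults to the seven continuous
#'   traits. The binary cleft-laminae flag can be added as a 0/1 feature
#'   with `include_cleft = TRUE`.
#' @param include_cleft logical; append `cleft` (as 0/1) to the features.
#' @return A `discriminant_model` with group means, pooled covariance,
#'   unit-length loadings, axis centroids and priors.
#' @export
fit_lda <- function(traits, features = trait_names(), include_cleft = FALSE) {
  df <- as.data.frame(traits)
  df <- df[df$species != UNKNOWN_LABEL, , drop = FALSE]
  if (include_cleft) {
    df$cleft_num <- as.numeric(df$cleft)
    features <- c(features, "cleft_num")
  }
  df <- df[stats::complete.cases(df[features]), , drop = FALSE]
  lda_core(as.matrix(df[features]), df$species, features)
}

# Gaussian class posteriors with shared covariance; rows of X complete.
posterior_core <- function(model, X, priors) {
  d1 <- stats::mahalanobis(X, model$group_means[1, ], model$pooled_cov)
  d2 <- stats::mahalanobis(X, model$group_means[2, ], model$pooled_cov)
  l1 <- log(priors[1]) - d1 / 2
  l2 <- log(priors[2]) - d2 / 2
  m <- pmax(l1, l2)
  p1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  cbind(p1, 1 - p1)
}

#' Score and classify specimens with a fitted discriminant
#'
#' Computes each row's discriminant score (`weights . x`) and the posterior
#' probabilities of the two groups from Gaussian class densities with the
#' model's group means and pooled covariance, weighted by the priors (equal
#' by default). Rows missing any feature are skipped with a warning.
#'
#' @param model a `discriminant_model` from [fit_lda()].
#' @param traits a [trait_table()] (or data.frame with the model features).
#' @param priors two prior probabilities summing to 1.
#' @return data.frame: `id`, `score`, posterior columns named after the two
#'   groups, and `class` (the higher-posterior group).
#' @export
predict_lda <- function(model, traits, priors = c(0.5, 0.5)) {
  stopifnot(abs(sum(priors) - 1) < 1e-9)
  df <- as.data.frame(traits)
  feats <- model$trait_names
  if ("cleft_num" %in% feats && !"cleft_num" %in% names(df))
    df$cleft_num <- as.numeric(df$cleft)
  ok <- stats::complete.cases(df[feats])
  if (!all(ok))
    warning(sum(!ok), " row(s) skipped: missing traits")
  df <- df[ok, , drop = FALSE]
  X <- as.matrix(df[feats])
  post <- posterior_core(model, X, priors)
  out <- data.frame(id = if ("id" %in% names(df)) df$id else seq_len(nrow(df)),
                    score = as.numeric(X %*% model$weights),
                    stringsAsFactors = FALSE)
  out[[model$group_levels[1]]] <- post[, 1]
  out[[model$group_levels[2]]] <- post[, 2]
  out$class <- model$group_levels[ifelse(post[, 1] >= 0.5, 1, 2)]
  out
}

#' Repeated stratified k-fold cross-validation of the discriminant
#'
#' In each repetition the labelled rows are randomly partitioned into k
#' folds (stratified by group so every training set contains both groups);
#' the discriminant is fitted on k-1 folds and the misclassification rate on
#' the held-out fold is averaged over folds. The mean over repetitions is
#' the reported error.
#'
#' @param traits a [trait_table()] with two labelled groups.
#' @param k folds (default 5).
#' @param repetitions number of random repetitions (default 1000).
#' @param seed integer RNG seed or `NULL`.
#' @param features feature columns, as in [fit_lda()].
#' @return list of class `cv_result`: `mean_error`, `per_repetition_errors`,
#'   `k`, `repetitions`, `seed`.
#' @export
repeated_kfold_cv <- function(traits, k = 5, repetitions = 1000, seed = NULL,
                              features = trait_names()) {
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(traits)
  df <- df[df$species != UNKNOWN_LABEL, , drop = FALSE]
  df <- df[stats::complete.cases(df[features]), , drop = FALSE]
  grp <- factor(df$species)
  if (min(table(grp)) < k)
    stop("k exceeds the smaller group's size")
  X <- as.matrix(df[features])
  errs <- vapply(seq_len(repetitions), function(rep) {
    fold <- integer(nrow(df))
    for (g in levels(grp)) {
      idx <- which(grp == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold_err <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- lda_core(X[tr, , drop = FALSE], grp[tr], features)
      post <- posterior_core(m, X[!tr, , drop = FALSE], c(0.5, 0.5))
      pred <- m$group_levels[ifelse(post[, 1] >= 0.5, 1, 2)]
      mean(pred != as.character(grp[!tr]))
    }, 0)
    mean(fold_err)
  }, 0)
  structure(list(mean_error = mean(errs), per_repetition_errors = errs,
                 k = k, repetitions = repetitions, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold x %d reps: mean error %.4g\n",
              x$k, x$repetitions, x$mean_error))
  invisible(x)
}

#' Normal-approximation confidence interval from a mean and standard error
#'
#' `mean +/- z * se`, with z = 1.96 exactly at 95% confidence (the
#' convention used in printed trait tables), and the corresponding normal
#' quantile otherwise.
#'
#' @param mean,se sample mean and standard error.
#' @param confidence confidence level (default 0.95).
#' @return c(ci_low, ci_high).
#' @export
mean_se_ci <- function(mean, se, confidence = 0.95) {
  z <- if (isTRUE(all.equal(confidence, 0.95))) 1.96
       else stats::qnorm(1 - (1 - confidence) / 2)
  c(ci_low = mean - z * se, ci_high = mean + z * se)
}

#' Summary statistics for one trait in one group
#'
#' @param values numeric vector (NA dropped); needs n >= 2.
#' @param confidence confidence level for the normal CI.
#' @param trait,group optional labels carried into the result.
#' @return data.frame of class `trait_summary`: `trait`, `group`, `mean`,
#'   `n`, `se`, `ci_low`, `ci_high`.
#' @export
trait_summary <- function(values, confidence = 0.95, trait = NA, group = NA) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  ci <- mean_se_ci(m, se, confidence)
  out <- data.frame(trait = trait, group = group, mean = m, n = n, se = se,
                    ci_low = ci[1], ci_high = ci[2], row.names = NULL)
  class(out) <- c("trait_summary", "data.frame")
  out
}

#' Wilson score confidence interval for a proportion
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param confidence confidence level (default 0.95, z = 1.96).
#' @return data.frame of class `proportion_summary`: `successes`, `n`,
#'   `p_hat`, `ci_low`, `ci_high`.
#' @export
proportion_ci <- function(successes, n, confidence = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  z <- if (isTRUE(all.equal(confidence, 0.95))) 1.96
       else stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- data.frame(successes = successes, n = n, p_hat = p,
                    ci_low = max(0, centre - half),
                    ci_high = min(1, centre + half))
  class(out) <- c("proportion_summary", "data.frame")
  out
}

#' Pairwise Pearson correlations among the seven floral traits
#'
#' Pairwise-complete Pearson correlations; traits with zero variance get NA
#' rows/columns.
#'
#' @param traits a [trait_table()] (any subset of rows).
#' @return 7x7 symmetric correlation matrix with unit diagonal.
#' @export
pairwise_trait_correlations <- function(traits) {
  X <- as.matrix(as.data.frame(traits)[trait_names()])
  if (sum(stats::complete.cases(X)) < 3)
    stop("need at least 3 complete rows")
  suppressWarnings(r <- stats::cor(X, use = "pairwise.complete.obs"))
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  r[v == 0, ] <- NA
  r[, v == 0] <- NA
  diag(r)[v > 0] <- 1
  r
}
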