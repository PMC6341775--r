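## Supervised Bayesian admixture (two source populations). Allele
## frequencies are learned only from flagged reference individuals, so
## their full conditional never depends on the query assignments and
## cluster labels are fixed by construction (no label switching). Queries'
## ancestry fractions q are sampled by Gibbs updates of per-allele-copy
## origin indicators.

#' Settings for the supervised admixture sampler
#'
#' @param burn_in,iterations Gibbs sweeps to discard / retain per run.
#' @param n_runs independent runs to average (consistency diagnostic).
#' @param alpha symmetric Dirichlet (Beta) concentration on each query's
#'   ancestry fraction q.
#' @param freq_prior_lambda Dirichlet concentration on allele frequencies;
#'   guarantees nonzero probability for alleles absent from the references.
#' @param seed integer RNG seed or `NULL`.
#' @return list of class `admixture_config`.
#' @export
admixture_config <- function(burn_in = 10000, iterations = 10000,
                             n_runs = 20, alpha = 1, freq_prior_lambda = 1,
                             seed = NULL) {
  stopifnot(burn_in >= 1, iterations >= 1, n_runs >= 1,
            alpha > 0, freq_prior_lambda > 0)
  structure(list(burn_in = burn_in, iterations = iterations,
                 n_runs = n_runs, alpha = alpha,
                 freq_prior_lambda = freq_prior_lambda, seed = seed),
            class = "admixture_config")
}

# Flattened allele-column layout shared by sampler and closed-form scorer:
# one column per (locus, allele length) seen anywhere in the table.
admix_layout <- function(genotypes) {
  L <- nrow(genotypes$loci)
  col_locus <- integer(0); col_allele <- numeric(0)
  for (j in seq_len(L)) {
    lens <- sort(unique(as.numeric(genotypes$calls[, j, ])))
    lens <- lens[!is.na(lens)]
    col_locus <- c(col_locus, rep(j, length(lens)))
    col_allele <- c(col_allele, lens)
  }
  list(col_locus = col_locus, col_allele = col_allele,
       ncol = length(col_locus))
}

# column index of each allele copy for one individual; NA loci dropped
copy_columns <- function(genotypes, i, layout) {
  idx <- integer(0)
  for (j in seq_len(nrow(genotypes$loci))) {
    a <- genotypes$calls[i, j, ]
    if (is.na(a[1])) next
    for (al in a)
      idx <- c(idx, which(layout$col_locus == j & layout$col_allele == al))
  }
  idx
}

ref_counts <- function(genotypes, layout, which_rows) {
  counts <- numeric(layout$ncol)
  for (i in which_rows) {
    cc <- copy_columns(genotypes, i, layout)
    t <- tabulate(cc, nbins = layout$ncol)
    counts <- counts + t
  }
  counts
}

#' Estimate ancestry fractions by supervised Bayesian admixture
#'
#' Gibbs sampler with two fixed source clusters (the two reference
#' species). Each sweep draws (i) per-species allele frequencies from
#' `Dirichlet(lambda + reference allele counts)` -- reference-only
#' updating, (ii) an origin indicator for every query allele copy with
#' probability proportional to `q_k * p_k(allele)`, and (iii) each query's
#' q from `Beta(alpha + n_A, alpha + n_B)` given its origin counts.
#' `n_runs` independent runs are averaged with [average_runs()]; reference
#' individuals' Q is fixed at (1,0)/(0,1).
#'
#' @param genotypes a [genotype_table()] with reference individuals of both
#'   species and at least one query.
#' @param config an [admixture_config()].
#' @return list of class `ancestry_estimate`: `Q` (data.frame `id`,
#'   `is_reference`, `Q_A`, `Q_B`, `ci_low`, `ci_high` -- central 90%
#'   credible interval of q_A for queries), `runs` (query Q_A per run),
#'   `run_sd` (across-run SD), `species` (labels of clusters A and B) and
#'   `config`.
#' @export
fit_supervised <- function(genotypes, config = admixture_config()) {
  ind <- genotypes$individuals
  sp <- sort(unique(ind$species[ind$is_reference]))
  if (length(sp) != 2)
    stop("need reference individuals of exactly two species")
  refA <- which(ind$is_reference & ind$species == sp[1])
  refB <- which(ind$is_reference & ind$species == sp[2])
  qry <- which(!ind$is_reference)
  if (!length(qry)) stop("no query individuals")
  layout <- admix_layout(genotypes)
  countA <- ref_counts(genotypes, layout, refA)
  countB <- ref_counts(genotypes, layout, refB)
  qcols <- lapply(qry, copy_columns, genotypes = genotypes, layout = layout)
  ncopies <- vapply(qcols, length, 1L)
  if (any(ncopies == 0)) stop("query with no complete calls")
  colidx <- unlist(qcols)
  ind_of_copy <- rep(seq_along(qry), ncopies)
  nq <- length(qry)
  lam <- config$freq_prior_lambda
  loc <- layout$col_locus

  one_run <- function(run_seed) {
    set.seed(run_seed)
    qA <- rep(0.5, nq)
    keep <- matrix(NA_real_, config$iterations, nq)
    total <- config$burn_in + config$iterations
    shapeA <- lam + countA
    shapeB <- lam + countB
    for (it in seq_len(total)) {
      gA <- stats::rgamma(layout$ncol, shape = shapeA)
      gB <- stats::rgamma(layout$ncol, shape = shapeB)
      pA <- gA / rowsum(gA, loc)[loc]
      pB <- gB / rowsum(gB, loc)[loc]
      wA <- qA[ind_of_copy] * pA[colidx]
      wB <- (1 - qA[ind_of_copy]) * pB[colidx]
      zA <- stats::runif(length(colidx)) < wA / (wA + wB)
      nA <- tabulate(ind_of_copy[zA], nbins = nq)
      qA <- stats::rbeta(nq, config$alpha + nA,
                         config$alpha + ncopies - nA)
      if (it > config$burn_in) keep[it - config$burn_in, ] <- qA
    }
    keep
  }

  base_seed <- if (is.null(config$seed)) sample.int(2^31 - 2, 1) else config$seed
  run_estimates <- lapply(seq_len(config$n_runs), function(r) {
    keep <- one_run(base_seed + r - 1)
    qmean <- colMeans(keep)
    ci <- apply(keep, 2, stats::quantile, probs = c(0.05, 0.95))
    Q <- data.frame(id = ind$id, is_reference = ind$is_reference,
                    Q_A = NA_real_, Q_B = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
    Q$Q_A[ind$is_reference] <- as.numeric(ind$species[ind$is_reference] == sp[1])
    Q$Q_A[qry] <- qmean
    Q$Q_B <- 1 - Q$Q_A
    Q$ci_low[qry] <- ci[1, ]
    Q$ci_high[qry] <- ci[2, ]
    structure(list(Q = Q, species = sp, config = config),
              class = "ancestry_estimate")
  })
  avg <- average_runs(run_estimates)
  avg$config <- config
  avg
}

#' Average ancestry estimates across independent runs
#'
#' Element-wise mean of Q across runs (cluster labels are fixed by the
#' supervision, so no label alignment is needed); the across-run standard
#' deviation per individual is retained as a consistency diagnostic.
#'
#' @param estimates list of `ancestry_estimate` objects over the same
#'   individuals.
#' @return An `ancestry_estimate` with averaged `Q`, per-run query Q_A in
#'   `runs`, and `run_sd`.
#' @export
average_runs <- function(estimates) {
  ids <- estimates[[1]]$Q$id
  for (e in estimates)
    if (!identical(e$Q$id, ids)) stop("runs cover different individual sets")
  qa <- vapply(estimates, function(e) e$Q$Q_A, numeric(length(ids)))
  qa <- matrix(qa, nrow = length(ids))
  Q <- estimates[[1]]$Q
  Q$Q_A <- rowMeans(qa)
  Q$Q_B <- 1 - Q$Q_A
  Q$ci_low <- rowMeans(vapply(estimates, function(e) e$Q$ci_low,
                              numeric(length(ids))))
  Q$ci_high <- rowMeans(vapply(estimates, function(e) e$Q$ci_high,
                               numeric(length(ids))))
  structure(list(Q = Q, species = estimates[[1]]$species,
                 runs = qa,
                 run_sd = apply(qa, 1, stats::sd),
                 config = estimates[[1]]$config),
            class = "ancestry_estimate")
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  qq <- x$Q[!x$Q$is_reference, ]
  cat(sprintf("<ancestry_estimate> clusters %s/%s; %d queries, mean Q_A %.3f\n",
              x$species[1], x$species[2], nrow(qq), mean(qq$Q_A)))
  invisible(x)
}

#' Leave-one-out assignment posteriors for reference individuals
#'
#' Each reference individual is scored against point-estimate allele
#' frequencies learned from the remaining references
#' (`(count + lambda) / (2n + lambda * n_alleles)` per locus), with the
#' likelihood the product of its allele-copy frequencies over loci and
#' equal priors. A species with a single reference individual cannot be
#' scored leave-one-out and gets NA with a warning.
#'
#' @param genotypes a [genotype_table()].
#' @param freq_prior_lambda Dirichlet prior mass per allele.
#' @return data.frame: `id`, `species`, `posterior_correct`.
#' @export
assignment_posteriors <- function(genotypes, freq_prior_lambda = 1) {
  ind <- genotypes$individuals
  sp <- sort(unique(ind$species[ind$is_reference]))
  if (length(sp) != 2)
    stop("need reference individuals of exactly two species")
  layout <- admix_layout(genotypes)
  refs <- which(ind$is_reference)
  countA <- ref_counts(genotypes, layout, refs[ind$species[refs] == sp[1]])
  countB <- ref_counts(genotypes, layout, refs[ind$species[refs] == sp[2]])
  nalleles <- tabulate(layout$col_locus, nbins = nrow(genotypes$loci))
  loglik <- function(counts, n_ind, cc) {
    tot <- 2 * n_ind + freq_prior_lambda * nalleles[layout$col_locus[cc]]
    sum(log((counts[cc] + freq_prior_lambda) / tot))
  }
  out <- data.frame(id = ind$id[refs], species = ind$species[refs],
                    posterior_correct = NA_real_, stringsAsFactors = FALSE)
  nA <- sum(ind$species[refs] == sp[1]); nB <- sum(ind$species[refs] == sp[2])
  if (nA < 2 || nB < 2)
    warning("a species has a single reference individual; leave-one-out ",
            "posterior unavailable for it")
  for (k in seq_along(refs)) {
    i <- refs[k]
    own_A <- ind$species[i] == sp[1]
    if ((own_A && nA < 2) || (!own_A && nB < 2)) next
    cc <- copy_columns(genotypes, i, layout)
    t <- tabulate(cc, nbins = layout$ncol)
    cA <- countA - if (own_A) t else 0
    cB <- countB - if (own_A) 0 else t
    lA <- loglik(cA, nA - own_A, cc)
    lB <- loglik(cB, nB - !own_A, cc)
    m <- max(lA, lB)
    pA <- exp(lA - m) / (exp(lA - m) + exp(lB - m))
    out$posterior_correct[k] <- if (own_A) pA else 1 - pA
  }
  out
}
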