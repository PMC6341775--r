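## Hybrid-swarm simulator with known ancestry ground truth. The generative
## model deliberately matches the assumptions of the downstream estimators:
## Balding-Nichols drift for parental allele frequencies, independent
## allele-origin draws given the ancestry fraction q, additive trait means,
## maternally inherited plastid haplotypes.

# Default parental floral trait values (cm): typical herbarium-scale
# measurements for A. formosa (A) and A. flavescens (B). `se`/`n` give the
# sampling scale from which the default within-population SD is derived.
floral_trait_defaults <- function() {
  data.frame(
    trait = trait_names(),
    mean_A = c(1.45, 1.74, 1.11, 0.31, 0.39, 2.11, 0.74),
    se_A   = c(0.03, 0.03, 0.03, 0.01, 0.01, 0.04, 0.02),
    n_A    = c(90, 93, 96, 95, 92, 97, 98),
    mean_B = c(1.88, 1.48, 0.68, 0.58, 0.65, 1.96, 0.72),
    se_B   = c(0.04, 0.03, 0.02, 0.02, 0.02, 0.04, 0.02),
    n_B    = c(80, 78, 79, 81, 80, 80, 75),
    stringsAsFactors = FALSE
  )
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulation settings for a synthetic hybrid-swarm dataset
#'
#' Defaults mirror a field study of two divergent parental populations and
#' one admixed swarm: 12 reference individuals per species, 29 hybrids, 11
#' microsatellite loci. Parental floral trait means are typical values for
#' *Aquilegia formosa* (species A) and *A. flavescens* (species B); the
#' default within-population trait SD is half the range-wide herbarium-scale
#' SD, reflecting that single allopatric populations are phenotypically much
#' tighter than a species' whole range.
#'
#' @param n_ref_A,n_ref_B number of reference individuals per species.
#' @param n_hybrids number of hybrid-swarm individuals.
#' @param hybrid_classes named proportions over pedigree classes `F1`, `F2`,
#'   `BC_A`, `BC_B`, or `Q_<q>` for a fixed ancestry fraction (e.g.
#'   `Q_0.5`); must sum to 1.
#' @param n_loci number of microsatellite loci.
#' @param motif_bp repeat-unit length (bp) per locus, recycled to `n_loci`.
#' @param n_allele_states number of allele states on each locus's ladder.
#' @param allele_base_bp shortest allele length per locus (ladder is
#'   `base + k * motif_bp`).
#' @param divergence_F Balding-Nichols drift parameter in (0, 1); larger
#'   values give more divergent parental allele frequencies.
#' @param trait_means_A,trait_means_B named 7-vectors of parental trait
#'   means (cm), in [trait_names()] order.
#' @param trait_cov 7x7 positive-definite trait covariance (cm^2).
#' @param cleft_p_A,cleft_p_B probability of cleft petal laminae per
#'   species; hybrids use the `q`-weighted mixture.
#' @param colour_mu_A,colour_mu_B,colour_sd parental means and common SD of
#'   sepal colour on the log R/G scale.
#' @param plastid_length alignment length in columns.
#' @param n_substitution_diffs substitutions separating the two parental
#'   plastid haplotypes.
#' @param indel_start,indel_width species-diagnostic plastid gap: species A
#'   carries a gap of `indel_width` columns starting at `indel_start`.
#' @param maternal_p_A probability a hybrid's maternal parent is species A.
#' @param geo_center_A,geo_center_B,geo_center_H `(lat, lon)` centres of the
#'   two parental ranges and the hybrid site, decimal degrees (west
#'   negative).
#' @param geo_sd_deg isotropic SD of specimen coordinates (degrees).
#' @param species_labels length-2 character vector naming species A and B.
#' @param seed integer RNG seed or `NULL`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ref_A = 12, n_ref_B = 12, n_hybrids = 29,
                       hybrid_classes = c(F1 = 0.5, F2 = 0.3,
                                          BC_A = 0.1, BC_B = 0.1),
                       n_loci = 11,
                       motif_bp = c(3, 3, 3, 2, 3, 2, 3, 2, 2, 3, 5),
                       n_allele_states = 8,
                       allele_base_bp = 200,
                       divergence_F = 0.5,
                       trait_means_A = NULL, trait_means_B = NULL,
                       trait_cov = NULL,
                       cleft_p_A = 0.37, cleft_p_B = 0,
                       colour_mu_A = 0.5, colour_mu_B = -0.5,
                       colour_sd = 0.1,
                       plastid_length = 300, n_substitution_diffs = 3,
                       indel_start = 101, indel_width = 5,
                       maternal_p_A = 1,
                       geo_center_A = c(50.5, -123.5),
                       geo_center_B = c(49.5, -116.5),
                       geo_center_H = c(51.11, -121.83),
                       geo_sd_deg = 0.8,
                       species_labels = c("formosa", "flavescens"),
                       seed = NULL) {
  defs <- floral_trait_defaults()
  if (is.null(trait_means_A))
    trait_means_A <- stats::setNames(defs$mean_A, defs$trait)
  if (is.null(trait_means_B))
    trait_means_B <- stats::setNames(defs$mean_B, defs$trait)
  if (is.null(trait_cov)) {
    sd_range <- (defs$se_A * sqrt(defs$n_A) + defs$se_B * sqrt(defs$n_B)) / 2
    trait_cov <- diag((0.5 * sd_range)^2)
    dimnames(trait_cov) <- list(defs$trait, defs$trait)
  }
  if (abs(sum(hybrid_classes) - 1) > 1e-9)
    stop("hybrid_classes proportions must sum to 1")
  if (!(divergence_F > 0 && divergence_F < 1))
    stop("divergence_F must lie in the open interval (0, 1)")
  ev <- eigen(trait_cov, symmetric = TRUE, only.values = TRUE)$values
  if (!isSymmetric(unname(trait_cov)) || any(ev <= 0))
    stop("trait_cov must be symmetric positive-definite")
  if (n_allele_states < 2) stop("n_allele_states must be >= 2")
  cfg <- list(n_ref_A = n_ref_A, n_ref_B = n_ref_B, n_hybrids = n_hybrids,
              hybrid_classes = hybrid_classes, n_loci = n_loci,
              motif_bp = rep_len(motif_bp, n_loci),
              n_allele_states = rep_len(n_allele_states, n_loci),
              allele_base_bp = rep_len(allele_base_bp, n_loci),
              divergence_F = divergence_F,
              trait_means_A = trait_means_A[trait_names()],
              trait_means_B = trait_means_B[trait_names()],
              trait_cov = trait_cov,
              cleft_p_A = cleft_p_A, cleft_p_B = cleft_p_B,
              colour_mu_A = colour_mu_A, colour_mu_B = colour_mu_B,
              colour_sd = colour_sd,
              plastid_length = plastid_length,
              n_substitution_diffs = n_substitution_diffs,
              indel_start = indel_start, indel_width = indel_width,
              maternal_p_A = maternal_p_A,
              geo_center_A = geo_center_A, geo_center_B = geo_center_B,
              geo_center_H = geo_center_H, geo_sd_deg = geo_sd_deg,
              species_labels = species_labels, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw divergent parental allele frequencies (Balding-Nichols model)
#'
#' Per locus, ancestral frequencies over the allele-length ladder are drawn
#' from a flat Dirichlet, and each species' frequencies from
#' `Dirichlet(ancestral * (1 - F) / F)`, so the expected squared frequency
#' difference between the two species at an allele with ancestral frequency
#' p is `2 F p (1 - p)`.
#'
#' @param config a [sim_config()].
#' @return A list with one element per locus: `lengths` (allele ladder, bp),
#'   `p_A`, `p_B` (frequency vectors summing to 1).
#' @export
simulate_parental_frequencies <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  FF <- config$divergence_F
  lapply(seq_len(config$n_loci), function(j) {
    S <- config$n_allele_states[j]
    lengths <- config$allele_base_bp[j] + (0:(S - 1)) * config$motif_bp[j]
    anc <- rdirichlet1(rep(1, S))
    list(lengths = lengths,
         p_A = rdirichlet1(anc * (1 - FF) / FF),
         p_B = rdirichlet1(anc * (1 - FF) / FF))
  })
}

class_q <- function(cls) {
  switch(cls, F1 = 0.5, F2 = 0.5, BC_A = 0.75, BC_B = 0.25,
         {
           if (!grepl("^Q_", cls)) stop("unknown hybrid class: ", cls)
           q <- as.numeric(sub("^Q_", "", cls))
           if (is.na(q) || q < 0 || q > 1)
             stop("bad Q_ class: ", cls)
           q
         })
}

draw_genotype <- function(freq, origin_A) {
  # origin_A: logical length 2 per locus-copy; returns 2 allele lengths
  vapply(1:2, function(cp) {
    p <- if (origin_A[cp]) freq$p_A else freq$p_B
    sample(freq$lengths, 1, prob = p)
  }, numeric(1))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate a complete hybrid-swarm dataset with known truth
#'
#' Generates all five input tables consumed by the pipeline plus the ground
#' truth. Genotypes: reference individuals draw both allele copies from
#' their own species' frequency table; an F1 draws exactly one copy per
#' locus from each species; other classes draw each copy independently from
#' species A with probability equal to the class's ancestry fraction q.
#' Traits are multivariate normal with mean `q * mu_A + (1 - q) * mu_B`
#' (additive inheritance); the cleft-laminae flag is Bernoulli with the
#' q-weighted mixture probability. Sepal colour is normal on the log R/G
#' scale and back-transformed to R and G channel means at fixed G; hybrids
#' additionally receive a visual integer score equal to their log R/G
#' quintile. Plastids: one haplotype per species, differing by
#' `n_substitution_diffs` substitutions plus a species-diagnostic indel;
#' hybrids inherit the haplotype of their maternal species. Coordinates are
#' isotropic Gaussian around the species (or hybrid-site) centre.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes`, `traits`, `colours`, `plastid`,
#'   `geo`, `truth` (data.frame: `id`, `true_q`, `class`,
#'   `maternal_species`) and `frequencies` (the generating allele-frequency
#'   tables).
#' @export
simulate_dataset <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  freqs <- local({
    cfg2 <- config; cfg2$seed <- NULL       # RNG already seeded
    simulate_parental_frequencies(cfg2)
  })
  lab <- c(A = config$species_labels[1], B = config$species_labels[2])

  nA <- config$n_ref_A; nB <- config$n_ref_B; nH <- config$n_hybrids
  classes <- sample(names(config$hybrid_classes), nH, replace = TRUE,
                    prob = config$hybrid_classes)
  ids <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)),
           sprintf("H%02d", seq_len(nH)))
  species <- c(rep(lab["A"], nA), rep(lab["B"], nB), rep(UNKNOWN_LABEL, nH))
  site <- c(rep("refA", nA), rep("refB", nB), rep("hybrid", nH))
  is_ref <- c(rep(TRUE, nA + nB), rep(FALSE, nH))
  true_q <- c(rep(1, nA), rep(0, nB), vapply(classes, class_q, 0))
  maternal <- c(rep("A", nA), rep("B", nB),
                ifelse(stats::runif(nH) < config$maternal_p_A, "A", "B"))

  n <- nA + nB + nH
  L <- config$n_loci
  calls <- array(NA_real_, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    cls <- if (i <= nA) "REF_A" else if (i <= nA + nB) "REF_B"
           else classes[i - nA - nB]
    for (j in seq_len(L)) {
      origin_A <- switch(cls,
        REF_A = c(TRUE, TRUE),
        REF_B = c(FALSE, FALSE),
        F1 = sample(c(TRUE, FALSE)),
        stats::runif(2) < true_q[i])
      calls[i, j, ] <- draw_genotype(freqs[[j]], origin_A)
    }
  }
  genotypes <- genotype_table(
    data.frame(id = ids, site = site, species = species,
               is_reference = is_ref, stringsAsFactors = FALSE),
    data.frame(name = sprintf("L%02d", seq_len(L)),
               motif_bp = config$motif_bp, stringsAsFactors = FALSE),
    calls)

  mu <- outer(true_q, config$trait_means_A) +
        outer(1 - true_q, config$trait_means_B)
  traits_m <- mu + MASS::mvrnorm(n, rep(0, 7), config$trait_cov)
  traits_m <- pmax(traits_m, 0)
  colnames(traits_m) <- trait_names()
  cleft_p <- true_q * config$cleft_p_A + (1 - true_q) * config$cleft_p_B
  traits <- trait_table(data.frame(id = ids, species = species, traits_m,
                                   cleft = stats::runif(n) < cleft_p,
                                   stringsAsFactors = FALSE))

  lrg <- stats::rnorm(n, true_q * config$colour_mu_A +
                         (1 - true_q) * config$colour_mu_B, config$colour_sd)
  G <- 80
  score <- rep(NA_integer_, n)
  hy <- which(!is_ref)
  # empirical quintile rank (1-5) of each hybrid's log R/G score
  score[hy] <- as.integer(ceiling(rank(lrg[hy], ties.method = "first") * 5 /
                                    length(hy)))
  colours <- colour_table(data.frame(id = ids,
                                     mean_R = pmin(255, G * exp(lrg)),
                                     mean_G = G, mean_B = 40,
                                     score = score, stringsAsFactors = FALSE))

  hapB <- random_seq(config$plastid_length)
  span <- config$indel_start:(config$indel_start + config$indel_width - 1)
  if (max(span) > config$plastid_length)
    stop("indel span exceeds plastid_length")
  bases <- strsplit(hapB, "")[[1]]
  hapA_b <- bases
  hapA_b[span] <- "-"
  sub_sites <- sample(setdiff(seq_len(config$plastid_length), span),
                      config$n_substitution_diffs)
  for (s in sub_sites)
    hapA_b[s] <- sample(setdiff(c("A", "C", "G", "T"), bases[s]), 1)
  hapA <- paste(hapA_b, collapse = "")
  seqs <- ifelse(maternal == "A", hapA, hapB)
  plastid <- plastid_alignment(ids, species, seqs)

  centers <- rbind(A = config$geo_center_A, B = config$geo_center_B,
                   H = config$geo_center_H)
  grp <- c(rep("A", nA), rep("B", nB), rep("H", nH))
  geo <- geo_table(data.frame(
    id = ids, species = species,
    lat_deg = centers[grp, 1] + stats::rnorm(n, 0, config$geo_sd_deg),
    lon_deg = centers[grp, 2] + stats::rnorm(n, 0, config$geo_sd_deg),
    stringsAsFactors = FALSE))

  truth <- data.frame(id = ids, true_q = true_q,
                      class = c(rep("REF_A", nA), rep("REF_B", nB), classes),
                      maternal_species = lab[maternal],
                      stringsAsFactors = FALSE)
  list(genotypes = genotypes, traits = traits, colours = colours,
       plastid = plastid, geo = geo, truth = truth, frequencies = freqs)
}

#' Simulate a geographic introgression cline for herbarium-style specimens
#'
#' Emulates range-wide morphological introgression: each specimen of a
#' species sits at a position interpolated between its own range centre and
#' the other species' centre, and its ancestry fraction decays linearly from
#' pure (q = 1 at its own centre) to half-admixed (q = 0.5) at the far end.
#' Traits follow the additive model of [simulate_dataset()]. With
#' `introgression = FALSE`, all specimens are pure and positions are
#' independent of phenotype, giving the null of no clinal association.
#'
#' @param n_per_species specimens per species.
#' @param introgression logical; simulate the cline or the null.
#' @param config a [sim_config()] providing trait and geographic settings.
#' @param seed integer RNG seed or `NULL`.
#' @return A list with `traits` (trait_table), `geo` (geo_table) and
#'   `true_q` per specimen.
#' @export
simulate_cline <- function(n_per_species = 80, introgression = TRUE,
                           config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_per_species
  own <- rbind(matrix(config$geo_center_A, n_per_species, 2, byrow = TRUE),
               matrix(config$geo_center_B, n_per_species, 2, byrow = TRUE))
  other <- rbind(matrix(config$geo_center_B, n_per_species, 2, byrow = TRUE),
                 matrix(config$geo_center_A, n_per_species, 2, byrow = TRUE))
  species <- rep(config$species_labels, each = n_per_species)
  u <- stats::runif(n)                      # 0 = own centre, 1 = far end
  pos <- own + 0.8 * u * (other - own) +
    matrix(stats::rnorm(2 * n, 0, 0.3), n, 2)
  q_own <- if (introgression) 1 - 0.5 * u else rep(1, n)
  # ancestry fraction from species A
  qA <- ifelse(species == config$species_labels[1], q_own, 1 - q_own)
  mu <- outer(qA, config$trait_means_A) + outer(1 - qA, config$trait_means_B)
  traits_m <- pmax(mu + MASS::mvrnorm(n, rep(0, 7), config$trait_cov), 0)
  colnames(traits_m) <- trait_names()
  ids <- sprintf("S%03d", seq_len(n))
  list(traits = trait_table(data.frame(id = ids, species = species, traits_m,
                                       cleft = NA, stringsAsFactors = FALSE)),
       geo = geo_table(data.frame(id = ids, species = species,
                                  lat_deg = pos[, 1], lon_deg = pos[, 2],
                                  stringsAsFactors = FALSE)),
       true_q = qA)
}
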