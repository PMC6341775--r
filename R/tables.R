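#' hybridscan: multi-evidence analysis of plant hybrid swarms
#'
#' Implements a complete desk-reproducible pipeline for diagnosing hybrid
#' populations: floral morphometrics (two-group linear discriminant analysis
#' with repeated k-fold cross-validation), a sepal-colour metric (log R/G),
#' microsatellite population genetics (locus and population summaries, Bruvo
#' distance, principal coordinate analysis, distance trees, DAPC), supervised
#' Bayesian admixture with reference-only allele-frequency updating, plastid
#' haplotype networks with simple indel coding, and a spherical
#' range-centroid statistic for clinal introgression. A hybrid-swarm
#' simulator with known ancestry ground truth ties the stages together.
#'
#' @importFrom stats cor cov dist hclust as.dist rnorm runif rbeta rgamma
#'   rbinom rmultinom quantile sd var complete.cases setNames prcomp
#'   mahalanobis qnorm cor.test lm coef
#' @importFrom utils read.csv write.csv head
#' @keywords internal
"_PACKAGE"

#' Names of the seven continuous floral traits
#'
#' The fixed trait set used throughout the morphometric analyses: corolla
#' width, spur length, anther exsertion, petal lamina length, petal lamina
#' width, sepal length and sepal width, all in cm.
#'
#' @export
trait_names <- function() {
  c("corolla_width", "spur_length", "anther_exsertion",
    "lamina_length", "lamina_width", "sepal_length", "sepal_width")
}

#' Sentinel species label for individuals of unknown ancestry
#' @export
UNKNOWN_LABEL <- "UNKNOWN"

## ---- GenotypeTable ----------------------------------------------------

#' Construct a diploid microsatellite genotype table
#'
#' Holds diploid allele lengths (bp) per individual per locus, together with
#' site labels, species labels and a reference flag. Reference individuals
#' (analogous to POPFLAG = 1 specimens in a supervised admixture analysis)
#' must carry a known species label.
#'
#' @param individuals data.frame with columns `id`, `site`, `species`,
#'   `is_reference`.
#' @param loci data.frame with columns `name` (unique locus names) and
#'   `motif_bp` (positive integer repeat-unit length).
#' @param calls integer array of dim `c(n_individuals, n_loci, 2)`; a call is
#'   either two positive allele lengths or wholly `NA` (missing). Half calls
#'   are rejected.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, loci, calls) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "site", "species", "is_reference") %in% names(individuals)),
            all(c("name", "motif_bp") %in% names(loci)))
  if (anyDuplicated(individuals$id))
    stop("individual ids must be unique")
  if (anyDuplicated(loci$name))
    stop("locus names must be unique")
  if (any(loci$motif_bp <= 0 | loci$motif_bp != round(loci$motif_bp)))
    stop("motif_bp must be positive integers")
  if (any(individuals$is_reference & individuals$species == UNKNOWN_LABEL))
    stop("reference individuals must have a known species label")
  rownames(individuals) <- NULL
  rownames(loci) <- NULL
  loci$motif_bp <- as.integer(loci$motif_bp)
  calls <- array(as.numeric(calls),
                 dim = c(nrow(individuals), nrow(loci), 2),
                 dimnames = list(individuals$id, loci$name, NULL))
  half <- xor(is.na(calls[, , 1, drop = FALSE]), is.na(calls[, , 2, drop = FALSE]))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)
    stop(sprintf("half-called genotype for individual '%s' at locus '%s'",
                 individuals$id[idx[1, 1]], loci$name[idx[1, 2]]))
  }
  if (any(calls <= 0, na.rm = TRUE))
    stop("allele lengths must be positive")
  structure(list(individuals = individuals, loci = loci, calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci (%d reference, %d query)\n",
              nrow(x$individuals), nrow(x$loci),
              sum(x$individuals$is_reference), sum(!x$individuals$is_reference)))
  invisible(x)
}

#' Subset a genotype table by individual
#'
#' @param genotypes a `genotype_table`.
#' @param keep logical or integer index over individuals.
#' @return A `genotype_table` restricted to the selected individuals.
#' @export
subset_genotypes <- function(genotypes, keep) {
  genotype_table(genotypes$individuals[keep, , drop = FALSE],
                 genotypes$loci,
                 genotypes$calls[keep, , , drop = FALSE])
}

## ---- TraitTable -------------------------------------------------------

#' Construct a floral trait table
#'
#' @param df data.frame with columns `id`, `species`, the seven traits named
#'   by [trait_names()] (cm), and `cleft` (logical, may be `NA`).
#' @return data.frame of class `trait_table`.
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "species", trait_names(), "cleft")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait table lacks columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  bad <- which(apply(df[trait_names()], 1, function(r) any(!is.na(r) & r < 0)))
  if (length(bad))
    stop("negative trait value in row(s): ", paste(bad, collapse = ", "))
  df$cleft <- as.logical(df$cleft)
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

## ---- ColourTable ------------------------------------------------------

#' Construct a sepal colour table
#'
#' Channel values are calibrated mean pixel values in RGB space, each in
#' \[0, 255\]. `score` is an optional visually assigned integer colour score
#' (1--5 along the yellow-to-red axis) used to validate the log R/G metric.
#'
#' @param df data.frame with columns `id`, `mean_R`, `mean_G`, `mean_B` and
#'   optionally `score`.
#' @return data.frame of class `colour_table`.
#' @export
colour_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "mean_R", "mean_G", "mean_B")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("colour table lacks columns: ", paste(miss, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_integer_
  chans <- as.matrix(df[, c("mean_R", "mean_G", "mean_B")])
  bad <- which(apply(chans, 1, function(r) any(is.na(r) | r < 0 | r > 255)))
  if (length(bad))
    stop("channel mean outside [0, 255] in row(s): ", paste(bad, collapse = ", "))
  df <- df[, c("id", "mean_R", "mean_G", "mean_B", "score")]
  rownames(df) <- NULL
  class(df) <- c("colour_table", "data.frame")
  df
}

## ---- PlastidAlignment --------------------------------------------------

#' Construct an aligned plastid sequence set
#'
#' @param ids character vector of sequence ids.
#' @param species species label per sequence (`UNKNOWN` allowed).
#' @param seqs character vector of equal-length aligned sequences over
#'   `A,C,G,T,N,-`.
#' @return An object of class `plastid_alignment`.
#' @export
plastid_alignment <- function(ids, species, seqs) {
  ids <- as.character(ids); species <- as.character(species)
  seqs <- toupper(as.character(seqs))
  stopifnot(length(ids) == length(seqs), length(species) == length(seqs))
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("illegal character in sequence(s): ", paste(ids[bad], collapse = ", "))
  structure(list(ids = ids, species = species, seqs = seqs,
                 length = if (length(lens)) lens[1] else 0L),
            class = "plastid_alignment")
}

#' @export
print.plastid_alignment <- function(x, ...) {
  cat(sprintf("<plastid_alignment> %d sequences x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Alignment as a character matrix (sequences x columns)
#' @param alignment a `plastid_alignment`.
#' @return character matrix with rownames = sequence ids.
#' @export
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(m) <- alignment$ids
  m
}

## ---- GeoTable ----------------------------------------------------------

#' Construct a specimen coordinate table
#'
#' Longitude is stored in signed decimal degrees (west negative).
#'
#' @param df data.frame with columns `id`, `species`, `lat_deg`, `lon_deg`.
#' @return data.frame of class `geo_table`.
#' @export
geo_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "species", "lat_deg", "lon_deg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("geo table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$lat_deg) | abs(df$lat_deg) > 90)
  if (length(bad))
    stop("latitude out of [-90, 90] in row(s): ", paste(bad, collapse = ", "))
  bad <- which(is.na(df$lon_deg) | abs(df$lon_deg) > 180)
  if (length(bad))
    stop("longitude out of [-180, 180] in row(s): ", paste(bad, collapse = ", "))
  df <- df[, need]
  rownames(df) <- NULL
  class(df) <- c("geo_table", "data.frame")
  df
}
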