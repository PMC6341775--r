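## File readers/writers for the pipeline's plain-text formats. All CSVs are
## comma-separated, UTF-8, "." decimal; no locale handling.

read_nonempty_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty table in file: ", path)
  df
}

#' Read a microsatellite genotype CSV
#'
#' Expected header: `id,site,species,is_reference`, followed by two columns
#' per locus named `<locus>.m<motif>.a1` and `<locus>.m<motif>.a2`, where
#' `<motif>` is the repeat-unit length in bp. Empty allele cells are allowed
#' only in pairs (a wholly missing call); a single empty member of a pair is
#' a half-call error.
#'
#' @param path path to the CSV file.
#' @return A [genotype_table()].
#' @export
read_genotype_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("id", "site", "species", "is_reference")
  if (!all(meta_cols %in% names(df)))
    stop("genotype CSV header must contain: ", paste(meta_cols, collapse = ", "))
  if (nrow(df) == 0) stop("empty table in file: ", path)
  allele_cols <- setdiff(names(df), meta_cols)
  m <- regmatches(allele_cols,
                  regexec("^(.+)\\.m([0-9]+)\\.a([12])$", allele_cols))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("unrecognised allele column name(s): ",
         paste(allele_cols[bad], collapse = ", "))
  info <- data.frame(col = allele_cols,
                     locus = vapply(m, `[`, "", 2L),
                     motif = as.integer(vapply(m, `[`, "", 3L)),
                     copy = as.integer(vapply(m, `[`, "", 4L)),
                     stringsAsFactors = FALSE)
  loci <- unique(info[, c("locus", "motif")])
  names(loci) <- c("name", "motif_bp")
  for (lc in loci$name) {
    cps <- sort(info$copy[info$locus == lc])
    if (!identical(cps, 1:2))
      stop("locus '", lc, "' must have exactly columns .a1 and .a2")
  }
  n <- nrow(df); L <- nrow(loci)
  calls <- array(NA_real_, dim = c(n, L, 2))
  for (j in seq_len(L)) {
    for (cp in 1:2) {
      col <- info$col[info$locus == loci$name[j] & info$copy == cp]
      v <- df[[col]]
      v[v %in% c("", "NA")] <- NA
      calls[, j, cp] <- suppressWarnings(as.numeric(v))
    }
  }
  individuals <- df[meta_cols]
  individuals$is_reference <- as.logical(individuals$is_reference)
  genotype_table(individuals, loci, calls)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_csv()]: wholly missing calls become empty cells.
#'
#' @param genotypes a `genotype_table`.
#' @param path output path.
#' @export
write_genotype_csv <- function(genotypes, path) {
  df <- genotypes$individuals
  for (j in seq_len(nrow(genotypes$loci))) {
    nm <- sprintf("%s.m%d.a%d", genotypes$loci$name[j],
                  genotypes$loci$motif_bp[j], 1:2)
    df[[nm[1]]] <- genotypes$calls[, j, 1]
    df[[nm[2]]] <- genotypes$calls[, j, 2]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a floral trait CSV
#'
#' Expected columns: `id,species`, the seven traits of [trait_names()] (cm),
#' and `cleft` (TRUE/FALSE, 0/1, or empty for unrecorded).
#'
#' @param path path to the CSV file.
#' @return A [trait_table()].
#' @export
read_trait_csv <- function(path) {
  df <- read_nonempty_csv(path)
  trait_table(df)
}

#' @rdname read_trait_csv
#' @param table the table object to serialise.
#' @export
write_trait_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a sepal colour CSV
#'
#' Expected columns: `id,mean_R,mean_G,mean_B` and optionally `score`
#' (integer 1--5 visual colour score).
#'
#' @param path path to the CSV file.
#' @return A [colour_table()].
#' @export
read_colour_csv <- function(path) {
  colour_table(read_nonempty_csv(path))
}

#' @rdname read_colour_csv
#' @param table the table object to serialise.
#' @export
write_colour_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a specimen coordinate CSV
#'
#' Expected columns: `id,species,lat_deg,lon_deg`; west longitudes are
#' negative decimal degrees.
#'
#' @param path path to the CSV file.
#' @return A [geo_table()].
#' @export
read_geo_csv <- function(path) {
  geo_table(read_nonempty_csv(path))
}

#' @rdname read_geo_csv
#' @param table the table object to serialise.
#' @export
write_geo_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read one or more aligned FASTA files as a plastid alignment
#'
#' Record ids are taken from the FASTA header up to the first whitespace; an
#' optional second whitespace-separated token is interpreted as the species
#' label (otherwise `UNKNOWN`). When several paths are given (e.g. two
#' plastid regions), the files must contain identical id sets and the
#' alignments are concatenated in the id order of the first file.
#'
#' @param paths character vector of FASTA paths.
#' @return A [plastid_alignment()].
#' @export
read_fasta_alignment <- function(paths) {
  read_one <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                               whole.header = TRUE)
    if (!length(recs)) stop("no FASTA records in: ", path)
    headers <- vapply(recs, function(r) attr(r, "Annot"), "")
    headers <- sub("^>", "", headers)
    toks <- strsplit(trimws(headers), "[[:space:]]+")
    ids <- vapply(toks, `[`, "", 1L)
    species <- vapply(toks, function(t) if (length(t) >= 2) t[2] else UNKNOWN_LABEL, "")
    plastid_alignment(ids, species, vapply(recs, as.character, ""))
  }
  alns <- lapply(paths, read_one)
  out <- alns[[1]]
  for (a in alns[-1]) {
    if (!setequal(out$ids, a$ids))
      stop("FASTA files to concatenate must share the same id set")
    ord <- match(out$ids, a$ids)
    out <- plastid_alignment(out$ids, out$species,
                             paste0(out$seqs, a$seqs[ord]))
  }
  out
}

#' Write a plastid alignment as FASTA
#'
#' Headers are `>id species`, the inverse of [read_fasta_alignment()].
#'
#' @param alignment a `plastid_alignment`.
#' @param path output path.
#' @export
write_fasta_alignment <- function(alignment, path) {
  seqinr::write.fasta(as.list(alignment$seqs),
                      names = paste(alignment$ids, alignment$species),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write an ancestry (Q) matrix CSV
#'
#' Columns `id,Q_A,Q_B` with values printed to six decimal places. Rows must
#' sum to one within 1e-9.
#'
#' @param ancestry an `ancestry_estimate` (see [fit_supervised()]) or a
#'   data.frame with columns `id`, `Q_A`, `Q_B`.
#' @param path output path.
#' @export
write_qmatrix <- function(ancestry, path) {
  df <- if (inherits(ancestry, "ancestry_estimate")) ancestry$Q else ancestry
  if (any(!is.finite(df$Q_A)) || any(!is.finite(df$Q_B)))
    stop("non-finite Q values")
  if (any(abs(df$Q_A + df$Q_B - 1) > 1e-9))
    stop("Q rows must sum to 1")
  out <- data.frame(id = df$id,
                    Q_A = sprintf("%.6f", df$Q_A),
                    Q_B = sprintf("%.6f", df$Q_B))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
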