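## Simple indel coding, haplotype collapse and a minimum-spanning haplotype
## network. Each maximal gap run with distinct endpoints becomes one binary
## character; a gap strictly containing another character's span makes that
## character inapplicable. Alignment columns are 1-based inclusive.

gap_runs <- function(chars) {
  r <- rle(chars == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simple indel coding of an aligned sequence set
#'
#' Every maximal gap run with a distinct (start, end) becomes one binary
#' character. A sequence scores `absent` for a character when it carries
#' exactly that gap, `inapplicable` when its own gap strictly contains the
#' character's span, and `present` (bases present) otherwise.
#'
#' @param alignment a [plastid_alignment()].
#' @return list of class `indel_characters`: `characters` (data.frame
#'   `start`, `end`) and `states` (sequences x characters matrix over
#'   `"present"`, `"absent"`, `"inapplicable"`).
#' @export
simple_indel_coding <- function(alignment) {
  m <- alignment_matrix(alignment)
  runs <- lapply(seq_len(nrow(m)), function(i) gap_runs(m[i, ]))
  all_runs <- unique(do.call(rbind, runs))
  if (is.null(all_runs) || nrow(all_runs) == 0) {
    return(structure(list(characters = data.frame(start = integer(0),
                                                  end = integer(0)),
                          states = matrix(character(0), nrow(m), 0,
                                          dimnames = list(alignment$ids, NULL))),
                     class = "indel_characters"))
  }
  all_runs <- all_runs[order(all_runs[, "start"], all_runs[, "end"]), ,
                       drop = FALSE]
  states <- matrix("present", nrow(m), nrow(all_runs),
                   dimnames = list(alignment$ids, NULL))
  for (i in seq_len(nrow(m))) {
    own <- runs[[i]]
    if (!nrow(own)) next
    for (k in seq_len(nrow(all_runs))) {
      s <- all_runs[k, "start"]; e <- all_runs[k, "end"]
      exact <- any(own[, "start"] == s & own[, "end"] == e)
      contains <- any(own[, "start"] <= s & own[, "end"] >= e &
                      (own[, "end"] - own[, "start"] > e - s))
      states[i, k] <- if (exact) "absent"
                      else if (contains) "inapplicable" else "present"
    }
  }
  structure(list(characters = data.frame(start = all_runs[, "start"],
                                         end = all_runs[, "end"]),
                 states = states),
            class = "indel_characters")
}

#' Collapse aligned sequences into unique haplotypes
#'
#' A haplotype signature consists of the states at variable substitution
#' columns (only columns free of gaps and ambiguities in every sequence)
#' plus the indel-character states. Identical signatures merge, accumulating
#' counts and species membership.
#'
#' @param alignment a [plastid_alignment()].
#' @param indel_chars result of [simple_indel_coding()] on the same
#'   alignment (computed if omitted).
#' @return list of class `haplotype_set`: `signatures` (haplotypes x
#'   signature-element character matrix), `count`, `member_ids` (list),
#'   `species_membership` (list of label multisets), `substitution_cols`
#'   (alignment columns used).
#' @export
collapse_haplotypes <- function(alignment, indel_chars = NULL) {
  if (is.null(indel_chars)) indel_chars <- simple_indel_coding(alignment)
  m <- alignment_matrix(alignment)
  clean <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  variable <- clean & apply(m, 2, function(col) length(unique(col)) > 1)
  sub_cols <- which(variable)
  sig <- cbind(m[, sub_cols, drop = FALSE], indel_chars$states)
  if (ncol(sig))
    colnames(sig) <- c(paste0("col", sub_cols, recycle0 = TRUE),
                       sprintf("indel%.0f.%.0f", indel_chars$characters$start,
                               indel_chars$characters$end))
  key <- apply(sig, 1, paste, collapse = "|")
  uk <- unique(key)
  idx <- lapply(uk, function(k) which(key == k))
  structure(list(signatures = sig[match(uk, key), , drop = FALSE],
                 count = vapply(idx, length, 1L),
                 member_ids = lapply(idx, function(i) alignment$ids[i]),
                 species_membership = lapply(idx, function(i) alignment$species[i]),
                 substitution_cols = sub_cols),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes from %d sequences\n",
              length(x$count), sum(x$count)))
  invisible(x)
}

# mutational steps between two signature rows: substitution differences
# plus indel-character differences (inapplicable states are not compared)
signature_steps <- function(sig, i, j) {
  a <- sig[i, ]; b <- sig[j, ]
  comparable <- a != "inapplicable" & b != "inapplicable"
  sum(a[comparable] != b[comparable])
}

#' Minimum-spanning haplotype network
#'
#' Pairwise step counts are substitution differences plus indel-character
#' differences (each indel counts as a single mutation). The network keeps
#' every edge that appears in some minimum spanning tree (co-minimal ties
#' retained), optionally dropping edges longer than `connection_limit`.
#'
#' @param haplotypes a `haplotype_set`.
#' @param connection_limit maximum steps for an edge, or `NULL` for no
#'   limit (network then connected).
#' @return list of class `haplotype_network`: `edges` (data.frame `from`,
#'   `to`, `steps`), `steps` (full step-count matrix), `count`,
#'   `species_membership`.
#' @export
build_network <- function(haplotypes, connection_limit = NULL) {
  H <- length(haplotypes$count)
  steps <- matrix(0, H, H)
  if (H > 1)
    for (i in seq_len(H - 1))
      for (j in (i + 1):H)
        steps[i, j] <- steps[j, i] <-
          signature_steps(haplotypes$signatures, i, j)
  edges <- data.frame(from = integer(0), to = integer(0), steps = integer(0))
  if (H > 1) {
    comp <- seq_len(H)                      # union-find by relabelling
    cand <- which(upper.tri(steps), arr.ind = TRUE)
    w <- steps[cand]
    for (wt in sort(unique(w))) {
      at <- cand[w == wt, , drop = FALSE]
      # edges co-minimal at this weight: endpoints in different components
      # *before* any weight-wt merge
      use <- at[comp[at[, 1]] != comp[at[, 2]], , drop = FALSE]
      if (nrow(use))
        edges <- rbind(edges, data.frame(from = use[, 1], to = use[, 2],
                                         steps = wt))
      for (k in seq_len(nrow(use))) {
        c1 <- comp[use[k, 1]]; c2 <- comp[use[k, 2]]
        if (c1 != c2) comp[comp == c2] <- c1
      }
    }
    if (!is.null(connection_limit))
      edges <- edges[edges$steps <= connection_limit, , drop = FALSE]
  }
  structure(list(edges = edges, steps = steps,
                 count = haplotypes$count,
                 species_membership = haplotypes$species_membership),
            class = "haplotype_network")
}

#' Classify query haplotypes by maternal origin
#'
#' A haplotype carried by query (unknown-species) individuals matches
#' species S when its signature is identical to a haplotype carried by S's
#' reference individuals; haplotypes identical to both species are
#' `ambiguous`, to neither `private`.
#'
#' @param haplotypes a `haplotype_set`.
#' @param reference_species character vector of the two species labels.
#' @return data.frame with one row per haplotype containing queries:
#'   `haplotype` (index), `n_queries`, `classification` (`matches_A`,
#'   `matches_B`, `ambiguous` or `private` -- A/B in `reference_species`
#'   order).
#' @export
maternal_origin <- function(haplotypes, reference_species) {
  stopifnot(length(reference_species) == 2)
  inA <- vapply(haplotypes$species_membership,
                function(s) reference_species[1] %in% s, TRUE)
  inB <- vapply(haplotypes$species_membership,
                function(s) reference_species[2] %in% s, TRUE)
  nq <- vapply(haplotypes$species_membership,
               function(s) sum(s == UNKNOWN_LABEL), 1L)
  rows <- which(nq > 0)
  cls <- function(h) {
    key <- paste(haplotypes$signatures[h, ], collapse = "|")
    mA <- any(vapply(which(inA), function(k)
      paste(haplotypes$signatures[k, ], collapse = "|") == key, TRUE))
    mB <- any(vapply(which(inB), function(k)
      paste(haplotypes$signatures[k, ], collapse = "|") == key, TRUE))
    if (mA && mB) "ambiguous" else if (mA) "matches_A"
    else if (mB) "matches_B" else "private"
  }
  data.frame(haplotype = rows, n_queries = nq[rows],
             classification = vapply(rows, cls, ""),
             stringsAsFactors = FALSE)
}
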