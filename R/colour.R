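## Sepal colour metric: log ratio of mean red to mean green channel values.
## In additive RGB, red + green = yellow, so R/G captures the human-visible
## yellow-to-red axis; the log centres the ratio around zero.

#' Log R/G colour scores
#'
#' `log(mean_R / mean_G)` per specimen. The base only rescales the score
#' (orderings and correlations are base-invariant); natural log is the
#' default.
#'
#' @param colours a [colour_table()].
#' @param base logarithm base (default `exp(1)`).
#' @return data.frame: `id`, `log_rg`.
#' @export
log_rg <- function(colours, base = exp(1)) {
  df <- as.data.frame(colours)
  bad <- df$mean_R <= 0 | df$mean_G <= 0
  if (any(bad))
    stop("non-positive channel mean for id(s): ",
         paste(df$id[bad], collapse = ", "))
  data.frame(id = df$id, log_rg = log(df$mean_R / df$mean_G, base = base),
             stringsAsFactors = FALSE)
}

#' Validate colour scores against visual integer scores
#'
#' Pearson correlation between continuous log R/G scores and visually
#' assigned integer colour scores (1--5 along the yellow-to-red axis) for
#' the specimens having both.
#'
#' @param scores data.frame from [log_rg()].
#' @param colours a [colour_table()] carrying the `score` column (or a
#'   numeric vector of integer scores aligned with `scores`).
#' @return Pearson correlation coefficient.
#' @export
score_correlation <- function(scores, colours) {
  ints <- if (is.numeric(colours)) colours
          else as.data.frame(colours)$score[match(scores$id,
                                                  as.data.frame(colours)$id)]
  keep <- !is.na(ints) & !is.na(scores$log_rg)
  x <- scores$log_rg[keep]; y <- ints[keep]
  if (length(x) < 3) stop("need at least 3 paired scores")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}
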