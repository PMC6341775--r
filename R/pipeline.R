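## End-to-end driver: morphometrics -> colour -> popgen -> admixture ->
## plastid -> geospatial on whichever inputs are available. A stage whose
## inputs are missing is skipped with a warning, not a failure.

#' Run the full hybrid-diagnosis pipeline
#'
#' Inputs come either from files (`config$inputs`: paths `genotypes`,
#' `traits`, `colours`, `plastid` -- one or more FASTA paths -- and `geo`)
#' or from a simulation block (`config$simulate`, a [sim_config()]). All
#' artifacts are written under `out_dir` together with a machine-readable
#' `summary.json`; identical seed and inputs give identical outputs.
#'
#' @param config list with optional elements `seed` (integer), `simulate`,
#'   `inputs`, `cv` (list: `k`, `repetitions`), `admixture` (an
#'   [admixture_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with each stage's results and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  summary <- list(seed = seed)

  data <- list()
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- seed
    data <- simulate_dataset(sim_cfg)
    write_genotype_csv(data$genotypes, file.path(out_dir, "genotypes.csv"))
    write_trait_csv(data$traits, file.path(out_dir, "traits.csv"))
    write_colour_csv(data$colours, file.path(out_dir, "colours.csv"))
    write_fasta_alignment(data$plastid, file.path(out_dir, "plastid.fasta"))
    write_geo_csv(data$geo, file.path(out_dir, "geo.csv"))
    utils::write.csv(data$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  } else {
    inp <- config$inputs
    if (!is.null(inp$genotypes)) data$genotypes <- read_genotype_csv(inp$genotypes)
    if (!is.null(inp$traits)) data$traits <- read_trait_csv(inp$traits)
    if (!is.null(inp$colours)) data$colours <- read_colour_csv(inp$colours)
    if (!is.null(inp$plastid)) data$plastid <- read_fasta_alignment(inp$plastid)
    if (!is.null(inp$geo)) data$geo <- read_geo_csv(inp$geo)
  }

  results <- list(data = data)
  species <- NULL

  ## morphometrics
  lda_scores <- NULL
  if (!is.null(data$traits)) {
    cv_cfg <- config$cv
    if (is.null(cv_cfg)) cv_cfg <- list()
    k <- if (is.null(cv_cfg$k)) 5 else cv_cfg$k
    reps <- if (is.null(cv_cfg$repetitions)) 1000 else cv_cfg$repetitions
    model <- fit_lda(data$traits)
    species <- model$group_levels
    cv <- repeated_kfold_cv(data$traits, k = k, repetitions = reps,
                            seed = seed + 1L)
    lda_scores <- predict_lda(model, data$traits)
    utils::write.csv(data.frame(trait = model$trait_names,
                                loading = model$weights),
                     file.path(out_dir, "lda_loadings.csv"), row.names = FALSE)
    utils::write.csv(lda_scores, file.path(out_dir, "lda_scores.csv"),
                     row.names = FALSE)
    results$morpho <- list(model = model, cv = cv, scores = lda_scores)
    summary$cv_error <- cv$mean_error
    summary$lda_centroids <- unname(model$axis_group_centroids)
  } else warning("no trait table: morphometrics stage skipped")

  ## colour
  if (!is.null(data$colours)) {
    scores <- log_rg(data$colours)
    utils::write.csv(scores, file.path(out_dir, "colour_scores.csv"),
                     row.names = FALSE)
    results$colour <- list(scores = scores)
    if (any(!is.na(as.data.frame(data$colours)$score))) {
      r <- score_correlation(scores, data$colours)
      results$colour$score_correlation <- r
      summary$colour_score_correlation <- r
    }
  } else warning("no colour table: colour stage skipped")

  ## population genetics
  if (!is.null(data$genotypes)) {
    gt <- data$genotypes
    loc <- locus_summaries(gt)
    pop <- population_summaries(gt)
    D <- bruvo_distance(gt)
    ord <- pcoa_ordination(D)
    utils::write.csv(loc, file.path(out_dir, "locus_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(pop, file.path(out_dir, "population_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(D), file.path(out_dir, "bruvo_distance.csv"))
    utils::write.csv(as.data.frame(ord$coordinates),
                     file.path(out_dir, "pcoa_coordinates.csv"))
    write_newick(build_tree(D, "nj"), file.path(out_dir, "nj.nwk"))
    write_newick(build_tree(D, "upgma"), file.path(out_dir, "upgma.nwk"))
    dapc <- dapc_fit(gt, seed = seed + 2L)
    dapc_scores <- dapc_predict(dapc, gt)
    utils::write.csv(dapc_scores, file.path(out_dir, "dapc_scores.csv"),
                     row.names = FALSE)
    results$popgen <- list(locus = loc, population = pop, bruvo = D,
                           pcoa = ord, dapc = dapc, dapc_scores = dapc_scores)
    summary$mean_He <- mean(loc$He)
    summary$dapc_a_score <- dapc$a_score

    ## admixture
    adm_cfg <- if (!is.null(config$admixture)) config$admixture
               else admixture_config()
    adm_cfg$seed <- seed + 3L
    adm <- fit_supervised(gt, adm_cfg)
    write_qmatrix(adm, file.path(out_dir, "qmatrix.csv"))
    utils::write.csv(data.frame(id = adm$Q$id, run_sd = adm$run_sd),
                     file.path(out_dir, "admixture_consistency.csv"),
                     row.names = FALSE)
    results$admixture <- adm
    qq <- adm$Q[!adm$Q$is_reference, ]
    summary$mean_query_Q_A <- mean(qq$Q_A)
  } else warning("no genotype table: popgen and admixture stages skipped")

  ## plastid
  if (!is.null(data$plastid)) {
    ic <- simple_indel_coding(data$plastid)
    haps <- collapse_haplotypes(data$plastid, ic)
    net <- build_network(haps)
    ref_sp <- setdiff(unique(data$plastid$species), UNKNOWN_LABEL)
    hap_df <- data.frame(haplotype = seq_along(haps$count),
                         count = haps$count,
                         members = vapply(haps$member_ids, paste, "",
                                          collapse = ";"))
    utils::write.csv(hap_df, file.path(out_dir, "haplotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(net$edges, file.path(out_dir, "haplotype_edges.csv"),
                     row.names = FALSE)
    results$plastid <- list(indels = ic, haplotypes = haps, network = net)
    if (length(ref_sp) == 2) {
      mo <- maternal_origin(haps, sort(ref_sp))
      utils::write.csv(mo, file.path(out_dir, "maternal_origin.csv"),
                       row.names = FALSE)
      results$plastid$maternal <- mo
      summary$n_haplotypes <- length(haps$count)
    }
  } else warning("no plastid alignment: plastid stage skipped")

  ## geospatial clines
  if (!is.null(data$geo) && !is.null(lda_scores)) {
    geo_known <- as.data.frame(data$geo)
    if (length(setdiff(unique(geo_known$species), UNKNOWN_LABEL)) == 2) {
      rec <- cline_records(lda_scores, data$geo)
      assoc <- clinal_association(rec)
      utils::write.csv(rec, file.path(out_dir, "cline_records.csv"),
                       row.names = FALSE)
      utils::write.csv(assoc, file.path(out_dir, "clinal_association.csv"),
                       row.names = FALSE)
      results$geo <- list(records = rec, association = assoc)
      summary$clinal_r_pooled <- assoc$r[assoc$group == "pooled"]
    }
  } else if (is.null(data$geo))
    warning("no coordinate table: geospatial stage skipped")

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(out_dir, "summary.json"))
  results$summary <- summary
  invisible(results)
}
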