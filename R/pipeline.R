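# Provenance header lines shared by all report writers.
provenance_lines <- function(config, extra = character(0)) {
  cfg <- unclass(config)
  c(paste0("ksmc ", as.character(packageVersion("ksmc"))),
    paste("config:", paste(sprintf("%s=%s", names(cfg),
                                   vapply(cfg, format, "")), collapse = " ")),
    paste("seed:", config$seed),
    extra)
}

#' Run the full prediction pipeline
#'
#' Executes similarity computation (unless precomputed matrices are
#' supplied), network adjustment, heterogeneous assembly, matrix
#' completion and ranking in one call, and optionally writes the ranked
#' score table.
#'
#' @param kinases,substrates Named character vectors of sequences (from
#'   [read_fasta()]).
#' @param interactions An [interaction_list()] of known positives.
#' @param config A [run_config()].
#' @param sim_kin,sim_sub Optional precomputed similarity matrices.
#' @param out Optional output path for the ranked score table
#'   ([write_scores()] format, with provenance header).
#' @return List with `scores` (ranked data frame over all m x n pairs,
#'   known pairs flagged), `completion` (the `completion_result`), and the
#'   similarity matrices used.
#' @export
run_predict <- function(kinases, substrates, interactions,
                        config = run_config(), sim_kin = NULL, sim_sub = NULL,
                        out = NULL) {
  stopifnot(inherits(interactions, "interaction_list"))
  if (is.null(sim_kin)) sim_kin <- build_similarity_matrix(kinases)
  if (is.null(sim_sub)) sim_sub <- build_similarity_matrix(substrates)
  res <- complete_network(interactions, sim_kin, sim_sub, config)
  sb <- res$score_block
  known <- suppressWarnings(build_interaction_matrix(interactions)) == 1
  scores <- data.frame(kinase_id = rep(rownames(sb), times = ncol(sb)),
                       substrate_id = rep(colnames(sb), each = nrow(sb)),
                       score = as.vector(sb),
                       known = as.vector(known),
                       stringsAsFactors = FALSE)
  scores <- rank_scores(scores)
  if (!is.null(out)) write_scores(scores, out, provenance_lines(config))
  list(scores = scores, completion = res, sim_kin = sim_kin, sim_sub = sim_sub)
}

#' Run ten-fold cross-validation and write a report
#'
#' Thin orchestration over [cross_validate()]: runs the protocol and
#' optionally writes a TSV report with one row per fold plus the pooled
#' AUC, under a provenance header recording config and seed.
#'
#' @inheritParams run_predict
#' @param n_folds Number of folds.
#' @return The [cross_validate()] result list.
#' @export
run_crossval <- function(kinases, substrates, interactions,
                         config = run_config(), sim_kin = NULL, sim_sub = NULL,
                         n_folds = 10L, out = NULL) {
  cv <- cross_validate(kinases, substrates, interactions, config,
                       sim_kin = sim_kin, sim_sub = sim_sub, n_folds = n_folds)
  if (!is.null(out)) {
    con <- file(out, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# ", provenance_lines(config)), con)
    writeLines("fold\tauc", con)
    writeLines(sprintf("%d\t%.10g", seq_len(n_folds), cv$fold_auc), con)
    writeLines(sprintf("pooled\t%.10g", cv$pooled_auc), con)
  }
  cv
}

#' Run de-novo tests for one kinase or all eligible kinases
#'
#' For `kinase_id = "all"`, every kinase with at least one known substrate
#' is queried in turn (kinases without any known substrate are skipped
#' with a warning, not an error). Similarity matrices are computed once
#' and shared across queries.
#'
#' @inheritParams run_predict
#' @param kinase_id A kinase id, or `"all"`.
#' @return List with `summary` (data frame: kinase_id, n_pos, auc) and
#'   `results` (list of [de_novo_test()] results).
#' @export
run_denovo <- function(kinases, substrates, interactions, kinase_id = "all",
                       config = run_config(), sim_kin = NULL, sim_sub = NULL,
                       out = NULL) {
  stopifnot(inherits(interactions, "interaction_list"))
  if (is.null(sim_kin)) sim_kin <- build_similarity_matrix(kinases)
  if (is.null(sim_sub)) sim_sub <- build_similarity_matrix(substrates)
  targets <- if (identical(kinase_id, "all")) {
    interactions$kinase_ids
  } else {
    kinase_id
  }
  eligible <- targets %in% interactions$pairs$kinase
  if (any(!eligible)) {
    if (identical(kinase_id, "all")) {
      warning("skipping kinase(s) with no known substrate: ",
              paste(targets[!eligible], collapse = ", "))
      targets <- targets[eligible]
    } # a single explicitly named ineligible kinase still errors below
  }
  results <- lapply(targets, function(k) {
    de_novo_test(kinases, substrates, interactions, k, config,
                 sim_kin = sim_kin, sim_sub = sim_sub)
  })
  summary <- data.frame(kinase_id = vapply(results, `[[`, "", "kinase_id"),
                        n_pos = vapply(results, `[[`, 0L, "n_pos"),
                        auc = vapply(results, `[[`, 0, "auc"),
                        stringsAsFactors = FALSE)
  if (!is.null(out)) {
    con <- file(out, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# ", provenance_lines(config)), con)
    writeLines("kinase_id\tn_pos\tauc", con)
    if (nrow(summary) > 0L) {
      writeLines(sprintf("%s\t%d\t%.10g", summary$kinase_id, summary$n_pos,
                         summary$auc), con)
    }
  }
  list(summary = summary, results = results)
}
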