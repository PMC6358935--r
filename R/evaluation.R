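#' Random fold assignment for cross-validation
#'
#' Partitions the known positive pairs uniformly at random into folds of
#' size differing by at most one. Deterministic for a fixed seed.
#'
#' @param interactions An [interaction_list()] (or a data frame of pairs).
#' @param seed Integer seed.
#' @param n_folds Number of folds (default 10).
#' @return Integer vector of fold labels in `1..n_folds`, one per pair,
#'   in the order of the pair table; the seed is attached as an attribute.
#' @export
ten_fold_split <- function(interactions, seed, n_folds = 10L) {
  pairs <- if (inherits(interactions, "interaction_list")) {
    interactions$pairs
  } else {
    interactions
  }
  n <- nrow(pairs)
  if (n < n_folds) {
    stop("need at least ", n_folds, " positive pairs for ", n_folds,
         "-fold cross-validation, got ", n)
  }
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  attr(fold, "seed") <- as.integer(seed)
  fold
}

#' ROC curve and AUC from scores and binary labels
#'
#' Sweeps a threshold over the distinct score values (equal scores are
#' grouped at a single threshold), computing the true positive rate
#' `TP / (TP + FN)` and false positive rate `FP / (FP + TN)` at each, and
#' integrates the curve by the trapezoid rule. With tied scores the
#' trapezoid rule credits ties one half, so the AUC equals the normalized
#' Mann-Whitney U statistic.
#'
#' @param scores Numeric vector of prediction scores (higher = more
#'   confidently positive).
#' @param labels Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return An object of class `roc_result`: list with `thresholds`
#'   (distinct scores, descending), `tpr`, `fpr` (each starting at 0 and
#'   ending at 1), and `auc`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  group_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l)[group_end]
  fp <- group_end - tp
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = s[group_end], tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

# Run adjust -> assemble -> complete on a training interaction list and
# return the score block. Shared by cross_validate, de_novo_test and
# run_predict. `held_out` (a pair data frame) is an instrumentation hook:
# the training matrix entering the adjustment stage is asserted to carry
# no held-out positive.
complete_network <- function(train_il, sim_kin, sim_sub, config,
                             held_out = NULL) {
  ks <- suppressWarnings(build_interaction_matrix(train_il))
  if (!is.null(held_out) && nrow(held_out) > 0L) {
    idx <- cbind(match(held_out$kinase, rownames(ks)),
                 match(held_out$substrate, colnames(ks)))
    if (any(ks[idx] != 0)) {
      stop("leakage: held-out positive present in the training matrix ",
           "at the adjustment stage")
    }
  }
  ks_adj <- adjust_interactions(ks, sim_sub = sim_sub, sim_kin = sim_kin,
                                t = config$t, mode = config$adjust_mode)
  hs <- assemble_hetero(sim_kin, ks_adj, sim_sub,
                        omega_policy = config$omega_policy)
  params <- svt_params(tau = config$tau, delta = config$delta,
                       max_iter = config$max_iter, tol = config$tol)
  svt_complete(hs, params)
}

#' Ten-fold cross-validation of the prediction pipeline
#'
#' Randomly splits the known positives into folds; each fold in turn is
#' removed from the interaction matrix *before* the similarity-based
#' adjustment (which is recomputed per fold, so no held-out label can leak
#' into the training network), the completion pipeline is run on the
#' training network, and the held-out positives are ranked against all
#' pairs never observed as positive. Training positives are excluded from
#' the scored pool. Per-fold AUCs and the pooled (micro-averaged) ROC over
#' all folds are reported.
#'
#' @param kinases,substrates Named character vectors of sequences.
#' @param interactions An [interaction_list()] of known positives.
#' @param config A [run_config()]; its `seed` drives the fold split.
#' @param sim_kin,sim_sub Optional precomputed similarity matrices (computed
#'   from the sequences when `NULL`).
#' @param n_folds Number of folds (default 10).
#' @return List with `fold_auc` (numeric vector), `mean_auc`, `sd_auc`,
#'   `pooled_roc` (a `roc_result`), `pooled_auc`, `fold_assignment`, and
#'   `leakage_checked = TRUE` (every fold passed the no-leakage assertion).
#' @export
cross_validate <- function(kinases, substrates, interactions, config = run_config(),
                           sim_kin = NULL, sim_sub = NULL, n_folds = 10L) {
  stopifnot(inherits(interactions, "interaction_list"))
  if (is.null(sim_kin)) sim_kin <- build_similarity_matrix(kinases)
  if (is.null(sim_sub)) sim_sub <- build_similarity_matrix(substrates)
  pairs <- interactions$pairs
  fold <- ten_fold_split(interactions, seed = config$seed, n_folds = n_folds)
  full_ks <- suppressWarnings(build_interaction_matrix(interactions))
  neg_idx <- which(full_ks == 0)
  pooled_scores <- vector("list", n_folds)
  pooled_labels <- vector("list", n_folds)
  fold_auc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- pairs[fold == f, , drop = FALSE]
    if (nrow(test) == 0L) stop("fold ", f, " has no test positives")
    train_il <- interaction_list(pairs[fold != f, , drop = FALSE],
                                 interactions$kinase_ids,
                                 interactions$substrate_ids)
    res <- complete_network(train_il, sim_kin, sim_sub, config,
                            held_out = test)
    sb <- res$score_block
    pos_scores <- sb[cbind(match(test$kinase, rownames(sb)),
                           match(test$substrate, colnames(sb)))]
    neg_scores <- sb[neg_idx]
    sc <- c(pos_scores, neg_scores)
    lb <- c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores)))
    fold_auc[f] <- roc_points(sc, lb)$auc
    pooled_scores[[f]] <- sc
    pooled_labels[[f]] <- lb
  }
  pooled <- roc_points(unlist(pooled_scores), unlist(pooled_labels))
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc), sd_auc = sd(fold_auc),
       pooled_roc = pooled, pooled_auc = pooled$auc,
       fold_assignment = fold, n_folds = n_folds,
       seed = config$seed, leakage_checked = TRUE)
}

#' De-novo (leave-one-kinase-out) evaluation
#'
#' Deletes every known interaction of the queried kinase, reruns the full
#' pipeline (adjustment included) on the remaining network, and scores the
#' queried kinase's row: its true substrates are the positives, all its
#' other substrates the negatives. This measures the ability to propose
#' substrates for a kinase with no annotated interaction at all.
#'
#' @inheritParams cross_validate
#' @param kinase_id Id of the kinase to query; it must have at least one
#'   known substrate.
#' @return List with `kinase_id`, `roc` (a `roc_result`), `auc`, `n_pos`,
#'   and `leakage_checked`.
#' @export
de_novo_test <- function(kinases, substrates, interactions, kinase_id,
                         config = run_config(), sim_kin = NULL, sim_sub = NULL) {
  stopifnot(inherits(interactions, "interaction_list"))
  if (!kinase_id %in% interactions$kinase_ids) {
    stop("unknown kinase id: ", kinase_id)
  }
  pairs <- interactions$pairs
  held_out <- pairs[pairs$kinase == kinase_id, , drop = FALSE]
  if (nrow(held_out) == 0L) {
    stop("kinase ", kinase_id, " has no known substrate; de-novo test undefined")
  }
  if (is.null(sim_kin)) sim_kin <- build_similarity_matrix(kinases)
  if (is.null(sim_sub)) sim_sub <- build_similarity_matrix(substrates)
  train_il <- interaction_list(pairs[pairs$kinase != kinase_id, , drop = FALSE],
                               interactions$kinase_ids,
                               interactions$substrate_ids)
  res <- complete_network(train_il, sim_kin, sim_sub, config,
                          held_out = held_out)
  row_scores <- res$score_block[kinase_id, ]
  labels <- as.integer(names(row_scores) %in% held_out$substrate)
  roc <- roc_points(row_scores, labels)
  list(kinase_id = kinase_id, roc = roc, auc = roc$auc,
       n_pos = nrow(held_out), leakage_checked = TRUE)
}
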