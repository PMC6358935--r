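make_pairs <- function(n) {
  data.frame(kinase = paste0("K", seq_len(n)), substrate = paste0("S", seq_len(n)))
}

test_that("fold assignment is balanced, exhaustive and deterministic", {
  f20 <- ten_fold_split(make_pairs(20), seed = 5)
  expect_equal(unname(table(f20)), rep(2L, 10), ignore_attr = TRUE)

  f23 <- ten_fold_split(make_pairs(23), seed = 5)
  sizes <- sort(as.integer(table(f23)))
  expect_equal(sizes, c(rep(2L, 7), rep(3L, 3)))

  expect_identical(ten_fold_split(make_pairs(23), seed = 5), f23)
  expect_false(identical(ten_fold_split(make_pairs(23), seed = 6), f23))
  expect_error(ten_fold_split(make_pairs(9), seed = 1), "at least 10")

  # union of folds is the positive set, folds pairwise disjoint: every pair
  # carries exactly one fold label in 1..10
  expect_true(all(f23 %in% 1:10))
  expect_equal(length(f23), 23L)
})

test_that("ROC handles perfect, anti-perfect and tied inputs", {
  r <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_points(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))$auc, 0.0)
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1); expect_equal(r$fpr[length(r$fpr)], 1)
  expect_error(roc_points(c(1, 2), c(1, 1)), "positive and.*negative")
})

test_that("ROC AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(55)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # force both classes
    scores <- round(rnorm(n), sample(c(0, 1, 8), 1))  # induce ties often
    r <- roc_points(scores, labels)
    expect_equal(r$auc, auc_mw_oracle(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
  }
})

test_that("cross-validation is deterministic and leakage-checked", {
  fx <- small_fixture()
  cfg <- run_config(seed = 9, max_iter = 200L)
  cv1 <- cross_validate(fx$inst$kinases, fx$inst$substrates,
                        fx$inst$interactions, cfg,
                        sim_kin = fx$sim_kin, sim_sub = fx$sim_sub)
  cv2 <- cross_validate(fx$inst$kinases, fx$inst$substrates,
                        fx$inst$interactions, cfg,
                        sim_kin = fx$sim_kin, sim_sub = fx$sim_sub)
  expect_identical(cv1$pooled_auc, cv2$pooled_auc)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  expect_true(cv1$leakage_checked)
  expect_length(cv1$fold_auc, 10L)
  # folds partition the positive pairs
  expect_equal(length(cv1$fold_assignment), nrow(fx$inst$interactions$pairs))
})

test_that("de novo test recovers a structured kinase and not a shuffled one", {
  fx <- default_fixture()
  inst <- fx$inst
  cfg <- run_config(seed = 3)
  deg <- table(inst$interactions$pairs$kinase)
  k <- names(deg)[deg >= 5][1]
  dn <- de_novo_test(inst$kinases, inst$substrates, inst$interactions, k, cfg,
                     sim_kin = fx$sim_kin, sim_sub = fx$sim_sub)
  expect_gt(dn$auc, 0.8)
  expect_true(dn$leakage_checked)

  # same kinase, interactions shuffled so substrates carry no structure
  null_il <- shuffle_interactions(inst$interactions, seed = 77)
  stopifnot(k %in% null_il$pairs$kinase)
  dn0 <- de_novo_test(inst$kinases, inst$substrates, null_il, k, cfg,
                      sim_kin = fx$sim_kin, sim_sub = fx$sim_sub)
  expect_gt(dn0$auc, 0.3)
  expect_lt(dn0$auc, 0.7)
})

test_that("deleting a kinase's edges leaves other kinases untouched", {
  fx <- small_fixture()
  inst <- fx$inst
  k <- inst$interactions$pairs$kinase[1]
  train <- interaction_list(
    inst$interactions$pairs[inst$interactions$pairs$kinase != k, ],
    inst$interactions$kinase_ids, inst$interactions$substrate_ids)
  full_m <- suppressWarnings(build_interaction_matrix(inst$interactions))
  train_m <- suppressWarnings(build_interaction_matrix(train))
  expect_true(all(train_m[k, ] == 0))
  others <- setdiff(rownames(full_m), k)
  expect_equal(train_m[others, ], full_m[others, ])

  expect_error(de_novo_test(inst$kinases, inst$substrates, train, k,
                            run_config(), fx$sim_kin, fx$sim_sub),
               "no known substrate")
})
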