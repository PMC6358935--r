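# Independent oracles used across the suite. Each is deliberately coded by
# the most direct route available (full DP tables, triple loops, pairwise
# comparisons) and never shares code with the implementation it checks.

# Brute-force Smith-Waterman affine-gap DP with full H/E/F tables.
# Gap of length L costs open + (L - 1) * ext.
sw_oracle <- function(a, b, sub, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (move along b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (move along a)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[ca[i - 1], cb[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# Triple-loop network adjustment over (kinase, source node, target node).
adjust_oracle <- function(ks, sim_sub = NULL, sim_kin = NULL, t, mode) {
  out <- ks
  if (mode %in% c("substrate", "both")) {
    for (k in seq_len(nrow(ks))) {
      for (s1 in seq_len(ncol(ks))) {
        if (ks[k, s1] == 1) {
          for (s2 in seq_len(ncol(ks))) {
            if (s2 != s1 && sim_sub[s1, s2] > t) out[k, s2] <- 1
          }
        }
      }
    }
  }
  if (mode %in% c("kinase", "both")) {
    for (s in seq_len(ncol(ks))) {
      for (k1 in seq_len(nrow(ks))) {
        if (ks[k1, s] == 1) {
          for (k2 in seq_len(nrow(ks))) {
            if (k2 != k1 && sim_kin[k1, k2] > t) out[k2, s] <- 1
          }
        }
      }
    }
  }
  out
}

# Tie-corrected Mann-Whitney AUC by explicit pairwise comparison.
auc_mw_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Soft-thresholding oracle: SVD of the *transpose*, reconstruct, transpose
# back (different computational path through LAPACK than the implementation).
soft_threshold_oracle <- function(X, tau) {
  sv <- svd(t(X))
  d <- pmax(sv$d - tau, 0)
  t(sv$u %*% diag(d, length(d)) %*% t(sv$v))
}

random_aa_seq <- function(len) {
  paste(sample(ksmc::amino_acids, len, replace = TRUE), collapse = "")
}

# The frozen planted completion instance: symmetric rank-2 10x10 with a 70%
# symmetric observation mask. Seed 2 is the first seed whose instance an
# independent nuclear-norm minimizer certifies as identifiable (the
# minimum-nuclear-norm completion IS the planted matrix), so recovery
# failure on it indicts the solver, not the instance.
planted_rank2_instance <- function(seed = 2L, n = 10L, r = 2L, density = 0.7) {
  withr::with_seed(seed, {
    U <- matrix(rnorm(n * r), n, r)
    M <- U %*% t(U)
    mask <- matrix(FALSE, n, n)
    up <- which(upper.tri(mask, diag = TRUE))
    mask[sample(up, round(density * length(up)))] <- TRUE
    mask <- mask | t(mask)
    list(M = M, mask = mask)
  })
}

# Default end-to-end fixture (planted instance + its similarity matrices),
# computed once per test run and shared across files.
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(.fixture_cache$f)) {
    inst <- generate_planted_instance(seed = 1L)
    .fixture_cache$f <- list(
      inst = inst,
      sim_kin = build_similarity_matrix(inst$kinases),
      sim_sub = build_similarity_matrix(inst$substrates)
    )
  }
  .fixture_cache$f
}

# A deliberately small instance for fast structural/pipeline tests.
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    inst <- generate_planted_instance(n_clusters = 2L, kinases_per_cluster = 3L,
                                      substrates_per_cluster = 5L, length = 60L,
                                      mutation_rate = 0.05, seed = 4L)
    .fixture_cache$small <- list(
      inst = inst,
      sim_kin = build_similarity_matrix(inst$kinases),
      sim_sub = build_similarity_matrix(inst$substrates)
    )
  }
  .fixture_cache$small
}
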