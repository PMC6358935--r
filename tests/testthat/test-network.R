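# helper: similarity matrix with a given off-diagonal structure
sim2 <- function(v) matrix(c(1, v, v, 1), 2, 2,
                           dimnames = list(c("S1", "S2"), c("S1", "S2")))

test_that("interaction matrices are indicator matrices of the pair set", {
  il <- interaction_list(data.frame(kinase = "K1", substrate = "S1"),
                         c("K1", "K2"), c("S1", "S2"))
  expect_equal(build_interaction_matrix(il),
               matrix(c(1, 0, 0, 0), 2, 2,
                      dimnames = list(c("K1", "K2"), c("S1", "S2"))))

  empty <- interaction_list(data.frame(kinase = character(),
                                       substrate = character()),
                            c("K1", "K2"), c("S1", "S2"))
  expect_warning(m <- build_interaction_matrix(empty), "no known interactions")
  expect_true(all(m == 0))
})

test_that("interaction matrix carries exactly one 1 per pair at data scale", {
  # shape of the motivating dataset: 216 kinases, 724 substrates, 1256 pairs
  kin <- paste0("K", 1:216)
  sub <- paste0("S", 1:724)
  set.seed(11)
  idx <- sample(216L * 724L, 1256L)
  pairs <- data.frame(kinase = kin[(idx - 1L) %% 216L + 1L],
                      substrate = sub[(idx - 1L) %/% 216L + 1L])
  m <- build_interaction_matrix(interaction_list(pairs, kin, sub))
  expect_equal(sum(m), 1256)
  expect_equal(dim(m), c(216L, 724L))
})

test_that("adjustment follows the strict-threshold propagation rule", {
  ks <- matrix(c(1, 0), 1, 2, dimnames = list("K1", c("S1", "S2")))
  expect_equal(adjust_interactions(ks, sim_sub = sim2(0.95), t = 0.9,
                                   mode = "substrate"),
               matrix(c(1, 1), 1, 2, dimnames = dimnames(ks)))
  # "greater than t" is strict: similarity exactly t propagates nothing
  expect_equal(adjust_interactions(ks, sim_sub = sim2(0.90), t = 0.9,
                                   mode = "substrate"), ks)
})

test_that("adjustment equals triple-loop enumeration on random instances", {
  set.seed(21)
  for (rep in 1:10) {
    ks <- matrix(rbinom(48, 1, 0.2), 6, 8)
    ss <- matrix(runif(64), 8, 8); ss <- (ss + t(ss)) / 2; diag(ss) <- 1
    kk <- matrix(runif(36), 6, 6); kk <- (kk + t(kk)) / 2; diag(kk) <- 1
    t0 <- runif(1, 0.3, 0.8)
    for (mode in c("substrate", "kinase", "both")) {
      got <- adjust_interactions(ks, sim_sub = ss, sim_kin = kk, t = t0,
                                 mode = mode)
      expect_equal(got, adjust_oracle(ks, ss, kk, t0, mode), info = mode)
      # monotone: the 1-set never shrinks, and stays binary
      expect_true(all(got >= ks))
      expect_true(all(got %in% c(0, 1)))
    }
    # t = 1 with strict inequality is the identity
    expect_equal(adjust_interactions(ks, sim_sub = ss, sim_kin = kk, t = 1,
                                     mode = "both"), ks)
  }
})

test_that("adjustment validates conforming dimensions and orderings", {
  ks <- matrix(c(1, 0), 1, 2, dimnames = list("K1", c("S1", "S2")))
  expect_error(adjust_interactions(ks, sim_sub = matrix(1, 3, 3), t = 0.9),
               "does not match")
  bad <- sim2(0.5)[2:1, 2:1]
  expect_error(adjust_interactions(ks, sim_sub = bad, t = 0.9), "ordering")
})

test_that("hetero assembly lays out the symmetric block matrix", {
  one <- matrix(1, 1, 1, dimnames = list("K1", "K1"))
  ks <- matrix(1, 1, 1, dimnames = list("K1", "S1"))
  ssub <- matrix(1, 1, 1, dimnames = list("S1", "S1"))
  hs <- assemble_hetero(one, ks, ssub)
  expect_equal(unname(hs$M), matrix(1, 2, 2))

  kk <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("K1", "K2"), c("K1", "K2")))
  ks <- matrix(c(1, 0), 2, 1, dimnames = list(c("K1", "K2"), "S1"))
  hs <- assemble_hetero(kk, ks, ssub)
  expect_equal(unname(hs$M[3, 1:2]), c(1, 0))      # transpose block
  expect_identical(hs$M, t(hs$M))
  expect_equal(unname(hs$M[1:2, 1:2]), unname(kk)) # block equality
})

test_that("omega counts observed cells per policy", {
  ssub2 <- matrix(c(1, 0.2, 0.2, 1), 2, 2, dimnames = list(c("S1", "S2"), c("S1", "S2")))
  one <- matrix(1, 1, 1, dimnames = list("K1", "K1"))

  ks <- matrix(1, 1, 1, dimnames = list("K1", "S1"))
  hs <- assemble_hetero(one, ks, matrix(1, 1, 1, dimnames = list("S1", "S1")))
  expect_equal(sum(hs$omega), 4L)

  ks <- matrix(c(1, 0), 1, 2, dimnames = list("K1", c("S1", "S2")))
  hs <- assemble_hetero(one, ks, ssub2, omega_policy = "positives_only")
  expect_equal(sum(hs$omega), 7L)  # the (K1,S2) zero is unobserved
  expect_identical(hs$omega, t(hs$omega))

  hs <- assemble_hetero(one, ks, ssub2, omega_policy = "all_bipartite")
  expect_equal(sum(hs$omega), 9L)
})
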