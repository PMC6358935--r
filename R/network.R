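#' Build the binary kinase-substrate interaction matrix
#'
#' @param interactions An [interaction_list()].
#' @return m x n numeric matrix of 0/1 with kinase ids as rownames and
#'   substrate ids as colnames; entry (i,j) is 1 iff the pair is a known
#'   interaction. Warns when no interaction is present (completion on an
#'   empty network is meaningless).
#' @export
build_interaction_matrix <- function(interactions) {
  stopifnot(inherits(interactions, "interaction_list"))
  m <- length(interactions$kinase_ids)
  n <- length(interactions$substrate_ids)
  ks <- matrix(0, m, n,
               dimnames = list(interactions$kinase_ids, interactions$substrate_ids))
  if (nrow(interactions$pairs) > 0L) {
    ks[cbind(match(interactions$pairs$kinase, interactions$kinase_ids),
             match(interactions$pairs$substrate, interactions$substrate_ids))] <- 1
  } else {
    warning("interaction matrix has no known interactions")
  }
  ks
}

#' Similarity-based adjustment of the interaction network
#'
#' Augments the bipartite network under the assumption that similar
#' substrates tend to be phosphorylated by the same kinases: for every
#' known edge (k, s1) and every other substrate s2 whose similarity to s1
#' is strictly greater than `t`, an edge (k, s2) is added
#' (`mode = "substrate"`). `mode = "kinase"` applies the mirror rule on the
#' kinase side; `mode = "both"` applies both rules to the original matrix
#' in a single pass (no chaining through newly added edges);
#' `mode = "none"` returns the input. Original edges are always preserved.
#'
#' @param ks 0/1 interaction matrix from [build_interaction_matrix()].
#' @param sim_sub Substrate similarity matrix (n x n), conforming to the
#'   columns of `ks`.
#' @param sim_kin Kinase similarity matrix (m x m), conforming to the rows
#'   of `ks`; only needed for modes `"kinase"` and `"both"`.
#' @param t Similarity threshold in \[0,1\]; default 0.9.
#' @param mode Adjustment mode (see Details).
#' @return Adjusted 0/1 matrix of the same shape and dimnames.
#' @export
adjust_interactions <- function(ks, sim_sub = NULL, sim_kin = NULL, t = 0.9,
                                mode = c("substrate", "kinase", "both", "none")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(ks), all(ks %in% c(0, 1)), t >= 0, t <= 1)
  if (mode == "none") return(ks)
  out <- ks
  if (mode %in% c("substrate", "both")) {
    if (is.null(sim_sub)) stop("substrate similarity matrix required")
    if (ncol(ks) != nrow(sim_sub)) {
      stop("substrate similarity dimension (", nrow(sim_sub),
           ") does not match interaction columns (", ncol(ks), ")")
    }
    if (!is.null(colnames(ks)) && !is.null(rownames(sim_sub)) &&
        !identical(colnames(ks), rownames(sim_sub))) {
      stop("substrate id ordering differs between interaction and similarity matrices")
    }
    prop <- (sim_sub > t)
    diag(prop) <- FALSE
    out <- out + (ks %*% prop > 0)
  }
  if (mode %in% c("kinase", "both")) {
    if (is.null(sim_kin)) stop("kinase similarity matrix required")
    if (nrow(ks) != nrow(sim_kin)) {
      stop("kinase similarity dimension (", nrow(sim_kin),
           ") does not match interaction rows (", nrow(ks), ")")
    }
    if (!is.null(rownames(ks)) && !is.null(rownames(sim_kin)) &&
        !identical(rownames(ks), rownames(sim_kin))) {
      stop("kinase id ordering differs between interaction and similarity matrices")
    }
    prop <- (sim_kin > t)
    diag(prop) <- FALSE
    out <- out + (prop %*% ks > 0)
  }
  (out > 0) + 0
}

#' Assemble the heterogeneous kinase-substrate block matrix
#'
#' Stacks the three sub-networks into the symmetric (m+n) x (m+n) matrix
#' \deqn{M = \begin{bmatrix} M_{KK} & M_{KS} \\ M_{KS}^T & M_{SS}
#' \end{bmatrix}}{M = [M_KK M_KS; M_KS' M_SS]}
#' with kinases first, substrates second, and builds its observation mask
#' via [build_omega()].
#'
#' @param sim_kin Kinase similarity matrix (m x m).
#' @param ks (Adjusted) 0/1 interaction matrix (m x n).
#' @param sim_sub Substrate similarity matrix (n x n).
#' @param omega_policy Observation policy, see [build_omega()].
#' @return An object of class `hetero_system`: list with elements `M`
#'   ((m+n) x (m+n) matrix), `omega` (logical mask of the same shape),
#'   `m`, `n`, `kinase_ids`, `substrate_ids`.
#' @export
assemble_hetero <- function(sim_kin, ks, sim_sub,
                            omega_policy = c("positives_only", "all_bipartite")) {
  omega_policy <- match.arg(omega_policy)
  check_similarity_matrix(sim_kin, "kinase similarity matrix")
  check_similarity_matrix(sim_sub, "substrate similarity matrix")
  m <- nrow(ks); n <- ncol(ks)
  if (nrow(sim_kin) != m) stop("kinase similarity / interaction dimension mismatch")
  if (nrow(sim_sub) != n) stop("substrate similarity / interaction dimension mismatch")
  M <- rbind(cbind(sim_kin, ks), cbind(t(ks), sim_sub))
  ids <- c(rownames(ks), colnames(ks))
  dimnames(M) <- list(ids, ids)
  hs <- structure(list(M = M, omega = NULL, m = m, n = n,
                       kinase_ids = rownames(ks), substrate_ids = colnames(ks)),
                  class = "hetero_system")
  hs$omega <- build_omega(hs, omega_policy)
  hs
}

#' Observation mask for the heterogeneous matrix
#'
#' Decides which entries of the block matrix are constrained during
#' completion. Under `"positives_only"` (default) the two similarity
#' blocks and the 1-entries of the interaction blocks are observed, while
#' interaction zeros are unknowns to be predicted; under
#' `"all_bipartite"` every entry is observed. The mask is symmetric by
#' construction.
#'
#' @param hs A `hetero_system` (its `M` block layout is used).
#' @param policy `"positives_only"` or `"all_bipartite"`.
#' @return Logical (m+n) x (m+n) matrix; `TRUE` marks observed entries.
#' @export
build_omega <- function(hs, policy = c("positives_only", "all_bipartite")) {
  policy <- match.arg(policy)
  m <- hs$m; n <- hs$n
  omega <- matrix(TRUE, m + n, m + n)
  if (policy == "positives_only") {
    ks_block <- hs$M[seq_len(m), m + seq_len(n), drop = FALSE]
    observed <- ks_block != 0
    omega[seq_len(m), m + seq_len(n)] <- observed
    omega[m + seq_len(n), seq_len(m)] <- t(observed)
  }
  omega
}

#' @export
print.hetero_system <- function(x, ...) {
  cat(sprintf("hetero_system: %d kinases + %d substrates; |Omega| = %d of %d entries\n",
              x$m, x$n, sum(x$omega), length(x$omega)))
  invisible(x)
}
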